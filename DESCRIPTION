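Package: screenbias
Title: Representation Bias Diagnostics and Correction for Pooled CRISPR Screens
Version: 0.1.0
Authors@R:
    person("screenbias", "developers", email = "screenbias@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify and correct guide-RNA library representation
    bias in pooled CRISPR knockout screens. Provides reading and writing of
    guide libraries, count matrices and gene-effect score tables; reads-per-
    million normalization and sample-level quality control; log2 fold-change
    gene effect scoring with rank-based essential-gene calling; equal-count
    binning of genes by plasmid-DNA representation with Spearman rank-
    correlation bias diagnostics; estimation of false-positive and false-
    negative essential calls attributable to representation bias, including
    elbow detection by maximum perpendicular distance; per-bin z-score
    correction and low-representation filtering with an evaluation battery
    (correlation groups, PCA distances, rank-sum tests); and a generative
    multinomial bottleneck simulator of pooled screens with ground truth for
    estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
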