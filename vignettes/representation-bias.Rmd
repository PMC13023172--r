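---
title: "Quantifying guide-RNA representation bias in pooled CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying guide-RNA representation bias in pooled CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenbias)
```

## The phenomenon

In a pooled CRISPR knockout screen, every measurement layer is a finite
sample from the layer before it: cells are transduced in proportion to each
construct's plasmid (pDNA) abundance, a fixed number of cells is reseeded at
every passage, and a fixed number of reads is sequenced per sample. For a
construct holding a fraction $\pi$ of a pool sampled $N$ times, the count is
$\mathrm{Binomial}(N, \pi)$, so the standard deviation of its log-abundance
scales like $1/\sqrt{N\pi}$. Constructs with low initial representation
therefore accumulate more noise at every layer, and their log2 fold changes
(log2FC) are systematically more extreme in both directions — without any
biological signal. Because essential genes are called by rank (the bottom
15\% of gene effect scores), this extra spread converts directly into false
essential calls concentrated at low representation, balanced by false
negatives elsewhere (the call size is fixed).

`screenbias` implements the diagnostic, the false-call estimator, two
post-hoc corrections, an evaluation battery, and a generative simulator that
reproduces exactly this mechanism with known ground truth.

## The bias diagnostic

Given per-gene pDNA representation $p_g$ (RPM; for multi-construct libraries
the mean RPM over a gene's constructs, `gene_pdna()`) and a per-gene score
statistic $y_g$ (typically `mean_abs_score()`, the mean of $|$score$|$ over
screens):

1. `equal_count_bins()` sorts genes by $(p_g, \text{label})$ and cuts them
   into $B$ contiguous bins whose sizes differ by at most one gene
   (remainder to the lowest bins). Equal counts matter: pDNA distributions
   are heavily right-skewed, and equal-width bins would confound density
   with representation.
2. `representation_bias()` computes, per bin, the median of $y_g$, its
   25th/75th percentiles and SD, and the mean $p_g$, then Spearman's rank
   correlation (two-sided, average ranks on ties) between bin mean pDNA and
   bin medians — one point per bin.

Using the bin *rank* instead of the bin mean pDNA gives the identical
Spearman result (bin means of any increasing function of $p_g$ are ordered
with the bins); the test suite asserts this. A Pearson option exists behind
`method = "pearson"`. If all bin medians are tied, the result is reported as
$\rho = 0$, $p = 1$ with a `degenerate` flag rather than an error, since
trivial fixtures hit this case. `loess_bins()` (local-linear, span 0.75,
direct surface) smooths bin medians for display only — the correlation is
never computed on smoothed values.

`difference_bias()` applies the same machinery to the per-gene mean of
$|A - B|$ over paired screens (cross-library or replicate comparisons), and
`per_bin_sd_profile()` gives the per-bin SD of the raw (signed) statistic.

## Gene effect scores

`score_screens()` computes per-construct
$\log_2\!\big((r_t + c)/(r_0 + c)\big)$ on RPM-normalized counts against the
screen's first timepoint, averages constructs per gene (controls excluded),
and median-centers each screen.

Two numerical choices deserve explanation:

* **Pseudocount** $c = 1$ RPM, added to numerator and denominator, keeps
  dropped-out constructs finite. It is configurable; the default follows
  the most common convention.
* **Median centering** (default `center = TRUE`). Counts are compositional:
  when the ~15\% essential genes deplete, every neutral gene's *relative*
  abundance rises by the same factor, so uncentered neutral log2FC sits at a
  positive offset. The pseudocount shrinks that offset more at low
  representation, which manufactures a monotone trend across bins that has
  nothing to do with sampling noise (it does not attenuate with coverage).
  Centering pins the median (neutral) gene at zero — the convention
  gene-effect scores follow — and removes the artifact. `center = FALSE`
  restores raw log2FC.

`call_essentials()` flags the bottom $\lfloor f \cdot n \rfloor$ genes
(default $f = 0.15$, the fraction of true dependencies a typical cell line
is estimated to carry), breaking boundary ties by ascending gene label so
calls are reproducible across platforms. Recall against a common-essential
reference drops reference genes absent from the library from the
denominator: recall should measure screen quality, not library content.

## Estimating false positives and negatives

For one screen, `estimate_fp_fn()` chains four steps:

* **Threshold curve.** For every attained pDNA value $t$:
  $n_{\le t}$ genes at or below $t$, the count of called-essential genes
  among them, their ratio, the representation-independent expectation
  $f \cdot n_{\le t}$, and `predicted_fp` = observed − expected.
* **Elbow.** On the (threshold, ratio) points restricted to
  $n_{\le t} \ge$ `min_genes_below` (default 100 — the raw left edge of the
  ratio is a quotient of tiny counts and must be stabilized; the exclusion
  threshold is deliberately configurable because the quantity is not
  scale-free), the elbow is the point maximizing the perpendicular distance
  to the chord joining the first and last restricted points; ties resolve to
  the smallest threshold, exact collinearity returns the smallest threshold
  with a degenerate flag. Distances are measured in raw data units by
  default (`normalize = TRUE` rescales both axes to $[0,1]$ first). The
  implementation is exact — the test suite checks it against brute-force
  enumeration on random monotone curves.
* **Per-bin accounting.** With observed essential calls $o_b$ and expected
  $f \cdot n_b$ per bin: $\mathrm{FP}_b = \max(o_b - f n_b, 0)$,
  $\mathrm{FN}_b = \max(f n_b - o_b, 0)$, so each bin contributes to exactly
  one side. When the bins partition all genes and $f \cdot n$ is integral,
  $\sum_b \mathrm{FP}_b = \sum_b \mathrm{FN}_b$ exactly (the call size is
  fixed). Counts stay fractional; rounding is presentation-only.
* **KS comparison.** Two-sample Kolmogorov–Smirnov between the pDNA values
  of called-essential and non-called genes (asymptotic two-sided p). A
  one-sample variant against uniformity of the essential genes' pDNA ranks
  is available via `ks_flavor = "uniform"`; the two-sample form is primary
  because it is the sharper statement of "essential calls sit left on the
  representation axis".

**Known limitation — the placement floor.** The one-sided per-bin sums have
a positive expectation even when calls are unbiased: with $n_b$ genes per
bin, $\mathbb{E} \sum_b \max(\mathrm{Binomial}(n_b, f) - f n_b, 0)$ is about
28 genes at 2000 genes / 20 bins / $f = 0.15$, independent of sequencing
coverage. The estimator therefore never reports totals near zero, and its
totals should be read relative to that floor when the true bias is small. On
the simulator's default world the estimator's totals nevertheless track the
truth-defined false-call counts closely (within ~15\% on average over ten
seeds), because at screening coverage real swaps dominate.

## Corrections and evaluation

`zscore_by_bin()` standardizes scores within each (bin, screen) group using
the sample SD; zero-SD groups map to zeros with a warning; singleton bins
are an error. The grouping is per screen because a per-gene standardization
across screens is impossible for a single screen; a pooled cross-screen
variant exists behind `cross_screen = TRUE`. Z-scoring within bins equalizes
the spread across the representation axis, so the bias diagnostic flattens
(the test suite requires a reduction of $|\rho|$ on every seed tried) — but
it cannot restore information never measured, and scores lose their absolute
scale.

`filter_low_representation()` drops units below a representation threshold
(default 50 RPM, an elbow-derived operating point for genome-scale libraries
whose mean RPM is near 50; for smaller simulated libraries choose a
comparable quantile instead) or, as a negative control, an equal number of
randomly chosen high-representation units. `pca_distances()` (gene-centered,
no variance scaling — gene effect scores share a scale), correlation groups
(same cell line/different library vs different cell line/same library,
Spearman by default with Pearson behind a flag) and `wilcoxon_compare()`
(signed-rank when paired, rank-sum otherwise) form the evaluation battery;
`correction_report()` bundles before/after recall and group correlations.

## The simulator

`sim_config()` states the world:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | genes (× `constructs_per_gene` constructs) |
| `f_essential` | 0.15 | fraction of truly essential genes |
| `s_range` | (−0.5, 0) | essential fitness per population doubling |
| `pdna_sdlog` | 1.1 | log-normal spread of pDNA weights |
| `coverage_cells` | 500 | cells per construct at every bottleneck |
| `coverage_reads` | 500 | sequencing reads per construct |
| `doublings` | 0, 5, 10, 14 | timepoint schedule (population doublings) |

Defaults mirror the screening protocol the package targets: ≥500× cell and
read coverage, at least three timepoints to ~14 population doublings.
`pdna_sdlog = 1.1` makes the RPM range span roughly three orders of
magnitude across a few thousand constructs, the dynamic range typical of
genome-wide libraries; no published dispersion estimate exists for the
libraries in question, so this is a calibration to qualitative range, and it
is user-tunable. The essential fitness range $U(-0.5, 0)$ gives endpoint
depletions between 0 and −7 log2 units with a continuum down to neutrality;
an earlier draft used $U(-0.5, -0.1)$, but a forbidden fitness zone adjacent
to zero is unrealistic and makes the essential/neutral boundary artificially
immune to noise. Non-essential fitness is exactly zero; an optional
enriching fraction is available (`f_enriching`).

`simulate_library()` draws log-normal weights and realizes integer pDNA
counts by one multinomial draw (the library validation sequencing); truth is
drawn independently of representation — the null the estimator assumes.
`simulate_screen()` then iterates: expected abundance multiplier
$2^{\Delta d\,(1+s_g)}$ per construct between timepoints, multinomial
bottleneck back to the fixed cell number (the fixed-cell reseed at every
passage, which is the dominant representation-dependent noise source),
multinomial sequencing at each timepoint. All totals conserve exactly, and
in the infinite-coverage limit a construct with fitness $s$ depletes by
$s \cdot d$ log2 units after $d$ doublings — the calibration the acceptance
script checks ($s = -0.2$, $d = 14 \Rightarrow -2.8$). Sampling is integer
multinomial throughout (no Gaussian approximation), so dropout at low
representation emerges naturally. The root seed is expanded into independent
per-stage streams keyed by stage name and screen id, so extending the
timepoint schedule or adding screens never perturbs earlier draws.
Sample metadata maps doublings to days at 1.5 days/doubling, so a
14-doubling endpoint lands on day 21, consistent with the QC rule that
excludes samples with >0.5\% undetected guides before day 21.

**What the simulator does not emulate:** guide cutting efficiency,
off-target activity, copy-number artifacts, media-dependent fitness, batch
effects between libraries beyond their independent pDNA realizations, and
PCR amplification bias. A green test on simulated data therefore
demonstrates that the statistics behave correctly under representation-
driven sampling noise alone; it does not certify behavior under the other
noise sources real screens carry.

**What attenuates with coverage — and what does not.** The magnitude of the
bias shrinks like $1/\sqrt{\text{coverage}}$ (the lowest bin's median
|log2FC| drops from ~2.0 at 50× to ~0.15 at 5000× under defaults). The
*rank* signature does not: the ratio of noise between low- and high-
representation bins is coverage-independent, so Spearman's $\rho$ — blind to
scale — stays near −1 at any coverage under this purely multinomial model.
$|\rho|$ only attenuates when a representation-independent noise floor
(biological or technical) competes with the sampling noise; such a floor is
deliberately absent from the simulator. Practically: on real data, a strong
$\rho$ flags the presence of the gradient, while the per-bin medians, IQRs
and the FP/FN totals measure whether it is large enough to matter.

## Degenerate inputs and tie policy, in one place

* All-zero count vectors cannot be RPM-normalized (error); a zero 10th
  percentile yields an infinite skew ratio (not an error — late timepoints
  legitimately contain dropouts).
* Rank ties: essential calls and bin assignment break ties by ascending
  gene label; Spearman uses average ranks.
* All bin medians tied → $\rho = 0$, $p = 1$, degenerate flag. Collinear
  threshold curves → smallest threshold, degenerate flag. All-zero paired
  differences → Wilcoxon $p = 1$, degenerate flag.
* Zero-SD z-score groups → zeros with a warning; singleton bins → error.

## Reproducibility

Every pipeline command (`cmd_simulate()` … `cmd_evaluate()`, or the
`exec/screenbias` CLI) is deterministic given config + seed, writes a
manifest (seed, config hash, package version) next to its outputs, validates
its JSON against shipped schemas, and reruns byte-identically.
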