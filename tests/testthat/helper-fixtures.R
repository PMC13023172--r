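# Fixtures are generated in code; nothing binary ships with the tests.

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tiny_library_file <- function(sep = "\t") {
  write_lines_tmp(c(
    paste("construct_id", "gene", "is_control", "pdna_count", sep = sep),
    paste("c1", "GENE1", "FALSE", "1", sep = sep),
    paste("c2", "GENE2", "FALSE", "1", sep = sep),
    paste("c3", "CTRL", "TRUE", "2", sep = sep)))
}

# One full simulated world: library, truth, screens, scores, partition.
sim_world <- function(seed, n_genes = 1000, coverage = 500, n_screens = 2,
                      n_bins = 20, ...) {
  cfg <- sim_config(seed = seed, n_genes = n_genes,
                    coverage_cells = coverage, coverage_reads = coverage,
                    ...)
  sim <- simulate_library(cfg)
  cm <- simulate_screens(sim$library, sim$truth, cfg,
                         screen_ids = paste0("S", seq_len(n_screens)))
  scores <- score_screens(cm, sim$library)
  pdna <- gene_pdna(sim$library)[rownames(scores)]
  list(config = cfg, sim = sim, cm = cm, scores = scores, pdna = pdna,
       partition = equal_count_bins(pdna, n_bins))
}
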