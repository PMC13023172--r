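#' Configuration of the synthetic pooled-screen generator
#'
#' The generator states the world the diagnostics assume: a log-normal
#' plasmid library (the default `pdna_sdlog = 1.1` spans roughly three
#' orders of magnitude of RPM at a few thousand genes), ~15% truly essential
#' genes with negative per-doubling fitness, neutral non-essentials, cell
#' and sequencing coverage of 500 per construct, and a screen running to 14
#' population doublings sampled at several timepoints. Truth is assigned
#' independently of representation -- the null the false-positive estimator
#' assumes.
#'
#' @param n_genes number of genes (default 2000).
#' @param constructs_per_gene constructs targeting each gene (default 1).
#' @param f_essential fraction of truly essential genes (default 0.15).
#' @param s_range fitness range of essential genes, per population doubling
#'   (default `c(-0.5, 0)`; drawn uniformly, so essential effect sizes form
#'   a continuum down to neutrality as in real screens).
#' @param f_enriching optional fraction of genes whose knockout enriches
#'   (fitness > 0; default 0).
#' @param s_enrich_range fitness range for enriching genes.
#' @param pdna_meanlog,pdna_sdlog log-normal parameters of the pDNA
#'   representation weights.
#' @param coverage_cells cells per construct at transduction and at every
#'   passage bottleneck (default 500).
#' @param coverage_reads sequencing reads per construct (default 500).
#' @param doublings non-decreasing timepoint schedule in population
#'   doublings, starting at 0 (default `c(0, 5, 10, 14)`).
#' @param n_libraries independent library realizations sharing the gene
#'   truth (default 1).
#' @param seed root seed; expanded into independent per-stage streams so
#'   adding a timepoint or screen never perturbs earlier draws.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, constructs_per_gene = 1,
                       f_essential = 0.15, s_range = c(-0.5, 0),
                       f_enriching = 0, s_enrich_range = c(0.05, 0.2),
                       pdna_meanlog = 0, pdna_sdlog = 1.1,
                       coverage_cells = 500, coverage_reads = 500,
                       doublings = c(0, 5, 10, 14), n_libraries = 1,
                       seed = 1) {
  # f_essential = 0 is admitted for the fully neutral calibration world
  if (f_essential < 0 || f_essential >= 1) {
    stop("f_essential must be in [0, 1)", call. = FALSE)
  }
  if (coverage_cells < 1 || coverage_reads < 1) {
    stop("coverage values must be >= 1", call. = FALSE)
  }
  if (doublings[1] != 0 || is.unsorted(doublings)) {
    stop("doublings must be non-decreasing and start at 0", call. = FALSE)
  }
  if (any(s_range > 0) || all(s_range == 0)) {
    stop("essential fitness range must be negative", call. = FALSE)
  }
  cfg <- list(n_genes = n_genes, constructs_per_gene = constructs_per_gene,
              f_essential = f_essential, s_range = s_range,
              f_enriching = f_enriching, s_enrich_range = s_enrich_range,
              pdna_meanlog = pdna_meanlog, pdna_sdlog = pdna_sdlog,
              coverage_cells = coverage_cells,
              coverage_reads = coverage_reads, doublings = doublings,
              n_libraries = n_libraries, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a guide library (or several sharing one gene truth)
#'
#' pDNA representation weights are drawn log-normal per construct and
#' converted to integer read counts by a single multinomial draw of
#' `coverage_reads * n_constructs` total reads (the library validation
#' sequencing). Gene truth -- fitness and essential flags, with exactly
#' `floor(f_essential * n_genes)` essential genes -- is drawn once and
#' shared by all library realizations, independent of representation.
#'
#' @param config a `sim_config`.
#' @return list: `library` (first realization), `libraries` (list of
#'   `guide_library`), `truth` (a `sim_truth` data.frame: `gene`,
#'   `fitness`, `is_essential`).
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  genes <- sprintf("G%05d", seq_len(n))
  set.seed(stage_seed(config$seed, "truth"))
  n_ess <- floor(config$f_essential * n)
  ess <- sample(genes, n_ess)
  fitness <- setNames(rep(0, n), genes)
  fitness[ess] <- runif(n_ess, config$s_range[1], config$s_range[2])
  if (config$f_enriching > 0) {
    pool <- setdiff(genes, ess)
    n_enr <- floor(config$f_enriching * n)
    enr <- sample(pool, n_enr)
    fitness[enr] <- runif(n_enr, config$s_enrich_range[1],
                          config$s_enrich_range[2])
  }
  truth <- data.frame(gene = genes, fitness = as.numeric(fitness),
                      is_essential = genes %in% ess,
                      stringsAsFactors = FALSE)
  class(truth) <- c("sim_truth", "data.frame")

  cpg <- config$constructs_per_gene
  n_constructs <- n * cpg
  construct_gene <- rep(genes, each = cpg)
  construct_id <- paste0(construct_gene, "_", rep(seq_len(cpg), times = n))
  libraries <- lapply(seq_len(config$n_libraries), function(l) {
    set.seed(stage_seed(config$seed, "library", l))
    w <- rlnorm(n_constructs, config$pdna_meanlog, config$pdna_sdlog)
    total_reads <- round(config$coverage_reads * n_constructs)
    counts <- as.numeric(rmultinom(1, total_reads, w))
    lib <- guide_library(construct_id = construct_id,
                         gene = construct_gene,
                         is_control = rep(FALSE, n_constructs),
                         pdna_count = counts)
    attr(lib, "weights") <- w
    lib
  })
  list(library = libraries[[1]], libraries = libraries, truth = truth)
}

#' Simulate one pooled screen from a library and its truth
#'
#' The mechanism generating representation-dependent noise: cells receive
#' guides by a multinomial draw of `coverage_cells * n_constructs` cells
#' with probabilities proportional to pDNA counts; between timepoints
#' separated by `dd` population doublings each construct's expected
#' abundance is multiplied by `2^(dd * (1 + s_gene))` and the pool is
#' bottlenecked back to the fixed cell number by another multinomial draw
#' (the fixed-reseed passage); at every scheduled timepoint sequencing reads
#' are a multinomial draw of `coverage_reads * n_constructs` reads
#' proportional to cell counts. Every sampling layer conserves its total
#' exactly. Low-representation constructs get fewer effective draws at each
#' layer, hence noisier fold changes -- no explicit noise term is added.
#'
#' In the infinite-coverage limit a construct with fitness `s` depletes by
#' `s * d` log2 units after `d` doublings relative to the neutral pool.
#'
#' @param library a `guide_library` from [simulate_library()].
#' @param truth the matching `sim_truth`.
#' @param config the `sim_config`.
#' @param screen_id label for this screen; also salts the per-stage RNG
#'   streams, so different ids give independent screens sharing the truth.
#' @return a raw `count_matrix` with one sample per timepoint and metadata
#'   columns `screen_id`, `replicate`, `timepoint_day` (1.5 days per
#'   doubling), `doublings`, `media`.
#' @export
simulate_screen <- function(library, truth, config, screen_id = "S1") {
  stopifnot(inherits(config, "sim_config"))
  n_constructs <- nrow(library)
  total_cells <- round(config$coverage_cells * n_constructs)
  total_reads <- round(config$coverage_reads * n_constructs)
  s <- truth$fitness[match(library$gene, truth$gene)]
  s[is.na(s)] <- 0  # controls, if any, are neutral
  w0 <- library$pdna_count
  if (sum(w0) <= 0) stop("library has no represented constructs",
                         call. = FALSE)
  set.seed(stage_seed(config$seed, paste0("cells0:", screen_id)))
  cells <- as.numeric(rmultinom(1, total_cells, w0))
  tps <- config$doublings
  counts <- matrix(0, nrow = n_constructs, ncol = length(tps))
  d_prev <- 0
  for (k in seq_along(tps)) {
    dd <- tps[k] - d_prev
    if (dd > 0) {
      w <- cells * 2^(dd * (1 + s))
      if (sum(w) <= 0) stop("entire pool went extinct", call. = FALSE)
      set.seed(stage_seed(config$seed, paste0("growth:", screen_id), k))
      cells <- as.numeric(rmultinom(1, total_cells, w))
    }
    set.seed(stage_seed(config$seed, paste0("seq:", screen_id), k))
    counts[, k] <- as.numeric(rmultinom(1, total_reads, cells))
    d_prev <- tps[k]
  }
  rownames(counts) <- library$construct_id
  colnames(counts) <- paste0(screen_id, "_d", tps)
  samples <- data.frame(sample = colnames(counts), screen_id = screen_id,
                        replicate = 1L,
                        timepoint_day = as.integer(round(1.5 * tps)),
                        doublings = tps, media = "DMEM",
                        stringsAsFactors = FALSE)
  count_matrix(counts, samples, normalized = FALSE)
}

#' Simulate several screens sharing a library and truth
#'
#' Convenience wrapper: independent replicate screens (distinct RNG streams)
#' merged into one raw `count_matrix`.
#'
#' @param library,truth,config as in [simulate_screen()].
#' @param screen_ids labels, one per screen.
#' @return a `count_matrix` whose samples span all screens.
#' @export
simulate_screens <- function(library, truth, config,
                             screen_ids = c("S1", "S2")) {
  cms <- lapply(screen_ids, function(id) {
    simulate_screen(library, truth, config, screen_id = id)
  })
  counts <- do.call(cbind, lapply(cms, function(cm) cm$counts))
  samples <- do.call(rbind, lapply(cms, function(cm) cm$samples))
  count_matrix(counts, samples, normalized = FALSE)
}

#' Confusion counts of an essential call against simulation truth
#'
#' @param truth a `sim_truth`.
#' @param call an `essential_call` (or character vector) over the truth's
#'   gene universe.
#' @param partition optional `bin_partition`; when given, per-bin confusion
#'   counts are attached.
#' @return list: `tp`, `fp`, `fn`, `tn`, and `bins` (data.frame `bin`,
#'   `n`, `fp`, `fn`, `tp`, `tn`) when a partition is supplied.
#' @export
truth_confusion <- function(truth, call, partition = NULL) {
  called <- truth$gene %in% as.character(call)
  ess <- truth$is_essential
  out <- list(tp = sum(called & ess), fp = sum(called & !ess),
              fn = sum(!called & ess), tn = sum(!called & !ess))
  if (!is.null(partition)) {
    idx <- match(partition$gene, truth$gene)
    c_b <- called[idx]
    e_b <- ess[idx]
    out$bins <- data.frame(
      bin = as.integer(names(tapply(c_b, partition$bin, sum))),
      n = as.numeric(tapply(c_b, partition$bin, length)),
      tp = as.numeric(tapply(c_b & e_b, partition$bin, sum)),
      fp = as.numeric(tapply(c_b & !e_b, partition$bin, sum)),
      fn = as.numeric(tapply(!c_b & e_b, partition$bin, sum)),
      tn = as.numeric(tapply(!c_b & !e_b, partition$bin, sum)),
      row.names = NULL)
  }
  out
}

#' Write simulation truth as TSV
#'
#' @param truth a `sim_truth`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  write_tsv(as.data.frame(truth), path)
}

#' Read simulation truth from TSV
#'
#' @param path path written by [write_truth()].
#' @return a `sim_truth` data.frame.
#' @export
read_truth <- function(path) {
  df <- read_delim_auto(path)
  df$is_essential <- parse_logical(df$is_essential)
  class(df) <- c("sim_truth", "data.frame")
  df
}
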