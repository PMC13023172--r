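#' Build a pipeline run configuration
#'
#' Collects every tunable of the pipeline with its documented default:
#' essential-call fraction 0.15, 20 representation bins, pseudocount 1 RPM,
#' low-representation threshold 50 RPM, elbow restriction of 100 genes,
#' Spearman correlations, two-sample KS, per-screen z-scoring.
#'
#' @param out_dir output directory (created if needed).
#' @param fraction essential-call fraction.
#' @param n_bins representation bins.
#' @param pseudocount log2FC pseudocount (RPM).
#' @param threshold_rpm low-representation filter threshold (RPM).
#' @param min_genes_below elbow restriction.
#' @param seed root seed.
#' @param n_genes,coverage_cells,coverage_reads,doublings,n_screens
#'   simulator settings for `cmd_simulate`.
#' @param correlation_method `"spearman"` or `"pearson"`.
#' @param ks_flavor `"two_sample"` or `"uniform"`.
#' @param zscore_mode `"per_screen"` or `"cross_screen"`.
#' @param library_path,counts_path,samples_path,scores_path,truth_path,
#'   reference_path,screen_meta_path input/output file paths; defaults live
#'   under `out_dir`.
#' @param ... further overrides stored verbatim.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = ".", fraction = 0.15, n_bins = 20,
                       pseudocount = 1, threshold_rpm = 50,
                       min_genes_below = 100, seed = 1, n_genes = 2000,
                       coverage_cells = 500, coverage_reads = 500,
                       doublings = c(0, 5, 10, 14), n_screens = 2,
                       correlation_method = "spearman",
                       ks_flavor = "two_sample",
                       zscore_mode = "per_screen",
                       library_path = NULL, counts_path = NULL,
                       samples_path = NULL, scores_path = NULL,
                       truth_path = NULL, reference_path = NULL,
                       screen_meta_path = NULL, ...) {
  cfg <- list(out_dir = out_dir, fraction = fraction, n_bins = n_bins,
              pseudocount = pseudocount, threshold_rpm = threshold_rpm,
              min_genes_below = min_genes_below, seed = seed,
              n_genes = n_genes, coverage_cells = coverage_cells,
              coverage_reads = coverage_reads, doublings = doublings,
              n_screens = n_screens,
              correlation_method = correlation_method,
              ks_flavor = ks_flavor, zscore_mode = zscore_mode,
              library_path = library_path %||%
                file.path(out_dir, "library.tsv"),
              counts_path = counts_path %||%
                file.path(out_dir, "counts.tsv"),
              samples_path = samples_path %||%
                file.path(out_dir, "samples.tsv"),
              scores_path = scores_path %||%
                file.path(out_dir, "scores.tsv"),
              truth_path = truth_path %||%
                file.path(out_dir, "truth.tsv"),
              reference_path = reference_path,
              screen_meta_path = screen_meta_path)
  extra <- list(...)
  cfg[names(extra)] <- extra
  class(cfg) <- "run_config"
  cfg
}

#' Read a flat key-value configuration file
#'
#' One `key: value` pair per line (YAML-compatible subset; `#` comments and
#' blank lines ignored). Numeric-looking values are coerced; comma-separated
#' values become numeric vectors. The parsed pairs override [run_config()]
#' defaults.
#'
#' @param path configuration file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3]
  if (length(bad) > 0) {
    stop("cannot parse config line(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  vals <- lapply(kv, function(m) {
    v <- trimws(strsplit(m[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(v))
    out <- if (anyNA(num)) v else num
    if (length(out) == 1 && is.character(out)) {
      if (tolower(out) %in% c("true", "false")) {
        out <- tolower(out) == "true"
      }
    }
    out
  })
  names(vals) <- vapply(kv, `[`, character(1), 2)
  do.call(run_config, vals)
}

#' Write the effective configuration next to outputs
#'
#' @param config a `run_config`.
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  scalar <- config[!vapply(config, is.null, logical(1))]
  lines <- vapply(names(scalar), function(k) {
    paste0(k, ": ", paste(scalar[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Run manifest: config hash (order-independent of list storage), seed,
# package version -- written alongside every command's outputs.
config_hash <- function(config) {
  keys <- sort(names(config))
  txt <- paste(vapply(keys, function(k) {
    paste0(k, "=", paste(format(config[[k]], digits = 15), collapse = ","))
  }, character(1)), collapse = ";")
  v <- utf8ToInt(txt)
  h <- 0
  for (chunk in split(v, ceiling(seq_along(v) / 512))) {
    h <- (h * 31 + sum(chunk * seq_along(chunk))) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

write_manifest <- function(config, stage, outputs) {
  path <- file.path(config$out_dir, paste0("manifest_", stage, ".json"))
  write_report_json(list(stage = stage, seed = config$seed,
                         config_hash = config_hash(config),
                         version = as.character(packageVersion("screenbias")),
                         outputs = outputs),
                    path)
}

ensure_out_dir <- function(config) {
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
}

#' Pipeline command: simulate a screen experiment
#'
#' Writes `library.tsv`, `counts.tsv`, `samples.tsv`, `truth.tsv` and a
#' manifest under the configured output directory.
#'
#' @param config a `run_config`.
#' @return invisibly, the list of written paths.
#' @export
cmd_simulate <- function(config) {
  ensure_out_dir(config)
  scfg <- sim_config(n_genes = config$n_genes,
                     coverage_cells = config$coverage_cells,
                     coverage_reads = config$coverage_reads,
                     doublings = config$doublings, seed = config$seed)
  sim <- simulate_library(scfg)
  ids <- paste0("S", seq_len(config$n_screens))
  cm <- simulate_screens(sim$library, sim$truth, scfg, screen_ids = ids)
  write_library(sim$library, config$library_path)
  write_count_matrix(cm, config$counts_path, config$samples_path)
  write_truth(sim$truth, config$truth_path)
  out <- c(config$library_path, config$counts_path, config$samples_path,
           config$truth_path)
  write_manifest(config, "simulate", out)
  invisible(out)
}

#' Pipeline command: score screens by log2 fold change
#'
#' Reads the library and count matrix, scores every screen against its first
#' timepoint, writes the genes x screens table.
#'
#' @param config a `run_config`.
#' @return invisibly, the scores path.
#' @export
cmd_score <- function(config) {
  ensure_out_dir(config)
  library <- read_library(config$library_path)
  cm <- read_count_matrix(config$counts_path, config$samples_path,
                          library = library)
  scores <- score_screens(cm, library, pseudocount = config$pseudocount)
  write_scores(scores, config$scores_path)
  write_manifest(config, "score", config$scores_path)
  invisible(config$scores_path)
}

#' Pipeline command: representation-bias diagnostic
#'
#' Bins genes by pDNA representation and writes the bias JSON
#' (`bias.json`): Spearman rho and p over per-bin medians of mean absolute
#' score, per-bin summaries, and the display LOESS curve.
#'
#' @param config a `run_config`.
#' @return invisibly, the `bias_result`.
#' @export
cmd_diagnose <- function(config) {
  ensure_out_dir(config)
  library <- read_library(config$library_path)
  scores <- import_scores(config$scores_path, "log2fc", library = library)
  pdna <- gene_pdna(library)[rownames(scores)]
  partition <- equal_count_bins(pdna, config$n_bins)
  stat <- mean_abs_score(scores)
  res <- representation_bias(stat, partition,
                             method = config$correlation_method)
  smooth <- if (nrow(res$bins) >= 4) loess_bins(res) else NULL
  path <- file.path(config$out_dir, "bias.json")
  payload <- list(rho = res$rho, p_value = res$p_value,
                  n_bins = res$n_bins, degenerate = res$degenerate,
                  method = res$method, bins = res$bins, loess = smooth)
  write_report_json(payload, path)
  validate_report(path, "bias")
  write_manifest(config, "diagnose", path)
  invisible(res)
}

#' Pipeline command: false positive / negative estimation
#'
#' Runs [estimate_fp_fn()] on each screen column and writes `fpfn.json`
#' (per-screen reports) plus per-screen threshold-curve TSVs.
#'
#' @param config a `run_config`.
#' @return invisibly, the list of `fpfn_report`s.
#' @export
cmd_estimate <- function(config) {
  ensure_out_dir(config)
  library <- read_library(config$library_path)
  scores <- import_scores(config$scores_path, "log2fc", library = library)
  pdna <- gene_pdna(library)[rownames(scores)]
  reports <- lapply(colnames(scores), function(s) {
    estimate_fp_fn(setNames(unclass(scores)[, s], rownames(scores)), pdna,
                   fraction = config$fraction, n_bins = config$n_bins,
                   min_genes_below = config$min_genes_below,
                   ks_flavor = config$ks_flavor)
  })
  names(reports) <- colnames(scores)
  path <- file.path(config$out_dir, "fpfn.json")
  payload <- lapply(reports, function(r) {
    list(elbow_threshold = r$elbow_threshold, fraction = r$fraction,
         total_fp = r$total_fp, total_fn = r$total_fn,
         total_misclassified = r$total_misclassified,
         ks = list(D = r$ks$D, p = r$ks$p), bins = r$bins)
  })
  write_report_json(payload, path)
  for (s in names(reports)) {
    write_threshold_curve(reports[[s]]$curve,
                          file.path(config$out_dir,
                                    paste0("threshold_curve_", s, ".tsv")))
  }
  validate_report(path, "fpfn")
  write_manifest(config, "estimate", path)
  invisible(reports)
}

#' Pipeline command: per-bin z-score correction
#'
#' Writes the corrected genes x screens table and `correct.json` with the
#' before/after bias rho.
#'
#' @param config a `run_config`.
#' @return invisibly, the corrected `gene_effect` matrix.
#' @export
cmd_correct <- function(config) {
  ensure_out_dir(config)
  library <- read_library(config$library_path)
  scores <- import_scores(config$scores_path, "log2fc", library = library)
  pdna <- gene_pdna(library)[rownames(scores)]
  partition <- equal_count_bins(pdna, config$n_bins)
  corrected <- zscore_by_bin(scores, partition,
                             cross_screen = config$zscore_mode ==
                               "cross_screen")
  before <- representation_bias(mean_abs_score(scores), partition,
                                method = config$correlation_method)
  after <- representation_bias(mean_abs_score(corrected), partition,
                               method = config$correlation_method)
  corrected_path <- file.path(config$out_dir, "corrected_scores.tsv")
  write_scores(corrected, corrected_path)
  path <- file.path(config$out_dir, "correct.json")
  write_report_json(list(rho_before = before$rho, p_before = before$p_value,
                         rho_after = after$rho, p_after = after$p_value,
                         n_bins = config$n_bins,
                         zscore_mode = config$zscore_mode),
                    path)
  validate_report(path, "correct")
  write_manifest(config, "correct", c(corrected_path, path))
  invisible(corrected)
}

#' Pipeline command: screen-comparability evaluation
#'
#' Correlation-group contrast (needs screen metadata with `cell_line` and
#' `library` columns), PCA pairwise distances for 3+ screens, and recall
#' against a reference list when configured; writes `evaluate.json`.
#'
#' @param config a `run_config`.
#' @return invisibly, the evaluation payload list.
#' @export
cmd_evaluate <- function(config) {
  ensure_out_dir(config)
  library <- read_library(config$library_path)
  scores <- import_scores(config$scores_path, "log2fc", library = library)
  payload <- list()
  if (!is.null(config$screen_meta_path) &&
      file.exists(config$screen_meta_path)) {
    meta <- read_delim_auto(config$screen_meta_path)
    cg <- withCallingHandlers(
      correlation_groups(scores, meta, method = config$correlation_method),
      warning = function(w) invokeRestart("muffleWarning"))
    payload$correlation_groups <- list(pairs = cg$pairs,
                                       wilcoxon = cg$wilcoxon)
  }
  if (ncol(scores) >= 3) {
    pd <- pca_distances(scores, n_pc = min(2, ncol(scores) - 1))
    payload$pca <- list(var_explained = pd$var_explained,
                        distances = pairwise_distances(pd))
  }
  if (!is.null(config$reference_path) &&
      file.exists(config$reference_path)) {
    reference <- read_gene_list(config$reference_path)
    payload$recall <- vapply(colnames(scores), function(s) {
      sc <- setNames(unclass(scores)[, s], rownames(scores))
      recall_common_essentials(call_essentials(sc, config$fraction),
                               reference, genes = names(sc))
    }, numeric(1))
  }
  path <- file.path(config$out_dir, "evaluate.json")
  write_report_json(payload, path)
  write_manifest(config, "evaluate", path)
  invisible(payload)
}

#' Validate an output JSON against a shipped schema
#'
#' Minimal structural check: every field named in the schema's `required`
#' array must be present at the top level, and when the schema declares
#' `each_required`, in every top-level element (used for per-screen
#' collections). Schemas live under `inst/schema/`.
#'
#' @param path JSON file to check.
#' @param schema schema name (`"bias"`, `"fpfn"`, `"correct"`).
#' @return `TRUE` invisibly; error when a required field is missing.
#' @export
validate_report <- function(path, schema) {
  schema_path <- system.file("schema", paste0(schema, ".json"),
                             package = "screenbias")
  if (schema_path == "") stop("unknown schema: ", schema, call. = FALSE)
  sch <- jsonlite::read_json(schema_path)
  obj <- jsonlite::read_json(path)
  missing <- setdiff(unlist(sch$required), names(obj))
  if (length(missing) > 0) {
    stop("report ", path, " is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  each <- unlist(sch$each_required)
  if (length(each) > 0) {
    for (nm in names(obj)) {
      miss <- setdiff(each, names(obj[[nm]]))
      if (length(miss) > 0) {
        stop("report element '", nm, "' is missing field(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
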