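#' Read a guide library annotation table
#'
#' Parses a delimited (tab or comma, sniffed from the header) table with
#' columns `construct_id`, `gene`, `is_control` and `pdna_count` into a
#' `guide_library`. The pDNA counts are the construct's representation in the
#' plasmid library before screening; an RPM-normalized view (`pdna_rpm`) is
#' attached so downstream diagnostics can work on a scale that is comparable
#' across libraries. Row order of the input file is preserved.
#'
#' @param path path to the library table.
#' @return a `guide_library`: a data.frame with columns `construct_id`,
#'   `gene`, `is_control`, `pdna_count` and `pdna_rpm`.
#' @export
read_library <- function(path) {
  df <- read_delim_auto(path)
  needed <- c("construct_id", "gene", "is_control", "pdna_count")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("library table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  guide_library(construct_id = as.character(df$construct_id),
                gene = as.character(df$gene),
                is_control = parse_logical(df$is_control),
                pdna_count = as.numeric(df$pdna_count))
}

#' Construct a guide library
#'
#' @param construct_id unique construct identifiers.
#' @param gene target gene symbol per construct (or a control label).
#' @param is_control logical flag; control constructs are excluded from the
#'   gene universe.
#' @param pdna_count non-negative raw pDNA read counts.
#' @return a `guide_library` data.frame.
#' @export
guide_library <- function(construct_id, gene, is_control, pdna_count) {
  dup <- construct_id[duplicated(construct_id)]
  if (length(dup) > 0) {
    stop("duplicate construct_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(pdna_count)) || any(pdna_count < 0)) {
    stop("pdna_count must be non-negative and non-missing", call. = FALSE)
  }
  lib <- data.frame(construct_id = construct_id, gene = gene,
                    is_control = is_control, pdna_count = pdna_count,
                    stringsAsFactors = FALSE)
  lib$pdna_rpm <- rpm_normalize(pdna_count)
  class(lib) <- c("guide_library", "data.frame")
  lib
}

#' @export
print.guide_library <- function(x, ...) {
  cat(sprintf("guide_library: %d constructs, %d genes, %d controls\n",
              nrow(x), length(library_genes(x)), sum(x$is_control)))
  print.data.frame(head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Gene universe of a guide library
#'
#' Unique gene symbols targeted by non-control constructs.
#'
#' @param library a `guide_library`.
#' @return character vector of gene symbols.
#' @export
library_genes <- function(library) {
  unique(library$gene[!library$is_control])
}

#' Per-gene pDNA representation (RPM)
#'
#' The gene-level representation key used for binning: the mean RPM-normalized
#' pDNA count over a gene's constructs (the mean matters for multi-construct
#' libraries; for one construct per gene it is the construct's RPM).
#'
#' @param library a `guide_library`.
#' @return named numeric vector, one value per non-control gene.
#' @export
gene_pdna <- function(library) {
  keep <- !library$is_control
  rpm <- library$pdna_rpm[keep]
  gene <- library$gene[keep]
  out <- tapply(rpm, gene, mean)
  setNames(as.numeric(out), names(out))
}

#' Write a guide library table
#'
#' @param library a `guide_library`.
#' @param path output path; always tab-delimited.
#' @export
write_library <- function(library, path) {
  write_tsv(as.data.frame(library)[c("construct_id", "gene", "is_control",
                                     "pdna_count")], path)
}

#' Reads-per-million normalization
#'
#' @param counts non-negative numeric vector with at least one positive entry.
#' @return vector summing to 1e6 with the input's proportions.
#' @export
rpm_normalize <- function(counts) {
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) stop("all-zero sample cannot be RPM-normalized",
                       call. = FALSE)
  counts / total * 1e6
}

#' Sample-level quality control for one sequencing sample
#'
#' Computes the dropout fraction (constructs with zero reads), the skew ratio
#' (90th / 10th percentile of raw construct counts; reported as `Inf` when the
#' 10th percentile is zero, which is legitimate at late timepoints), and the
#' exclusion decision: a sample is excluded when more than 0.5% of constructs
#' are undetected before day 21 of the screen, since guide dropout is only
#' expected after extended selection.
#'
#' @param counts raw (not RPM) counts for one sample.
#' @param timepoint_day integer day of harvest.
#' @return a `sample_qc` list: `skew_ratio`, `dropout_fraction`,
#'   `reads_per_construct`, `excluded`.
#' @export
sample_qc <- function(counts, timepoint_day) {
  if (any(counts < 0)) stop("raw counts must be non-negative", call. = FALSE)
  dropout <- mean(counts == 0)
  q <- quantile(counts, c(0.1, 0.9), names = FALSE, type = 7)
  skew <- if (q[1] == 0) Inf else q[2] / q[1]
  out <- list(skew_ratio = skew,
              dropout_fraction = dropout,
              reads_per_construct = mean(counts),
              excluded = dropout > 0.005 && timepoint_day < 21)
  class(out) <- "sample_qc"
  out
}

#' @export
print.sample_qc <- function(x, ...) {
  cat(sprintf(
    "sample_qc: skew %.3g, dropout %.4f, reads/construct %.1f, excluded %s\n",
    x$skew_ratio, x$dropout_fraction, x$reads_per_construct, x$excluded))
  invisible(x)
}

#' Construct a count matrix container
#'
#' Constructs x samples counts with per-sample metadata and an explicit
#' normalization flag (raw vs RPM); mixing scales is an error by contract.
#'
#' @param counts numeric matrix, rownames = construct ids, colnames = samples.
#' @param samples data.frame with one row per sample (column `sample` plus
#'   `screen_id`, `replicate`, `timepoint_day`, `doublings`, `media`).
#' @param normalized logical; `TRUE` when `counts` is RPM.
#' @return a `count_matrix` list.
#' @export
count_matrix <- function(counts, samples = NULL, normalized = FALSE) {
  if (is.null(samples)) {
    samples <- data.frame(sample = colnames(counts),
                          stringsAsFactors = FALSE)
  }
  if (!all(colnames(counts) %in% samples$sample)) {
    stop("every counts column needs a row in the sample metadata",
         call. = FALSE)
  }
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  out <- list(counts = counts, samples = samples, normalized = normalized)
  class(out) <- "count_matrix"
  out
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d constructs x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) "RPM" else "raw"))
  invisible(x)
}

#' Read a construct count matrix (plus optional sample metadata sidecar)
#'
#' @param path delimited table, first column `construct_id`, remaining
#'   columns one per sample.
#' @param meta_path optional sidecar TSV with per-sample metadata
#'   (columns `sample`, `screen_id`, `replicate`, `timepoint_day`,
#'   `doublings`, `media`).
#' @param library optional `guide_library`; rows are checked to be a subset
#'   of its construct ids.
#' @param normalized whether the stored values are RPM (default raw).
#' @return a `count_matrix`.
#' @export
read_count_matrix <- function(path, meta_path = NULL, library = NULL,
                              normalized = FALSE) {
  df <- read_delim_auto(path)
  if (names(df)[1] != "construct_id") {
    stop("count matrix must have 'construct_id' as its first column",
         call. = FALSE)
  }
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stop("count matrix contains non-numeric values",
                           call. = FALSE)
  rownames(m) <- df$construct_id
  if (!is.null(library) && !all(rownames(m) %in% library$construct_id)) {
    bad <- setdiff(rownames(m), library$construct_id)
    stop("constructs absent from the library: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  samples <- if (!is.null(meta_path)) read_delim_auto(meta_path) else NULL
  count_matrix(m, samples, normalized = normalized)
}

#' Write a count matrix (and its sample metadata sidecar)
#'
#' @param cm a `count_matrix`.
#' @param path output TSV for the counts.
#' @param meta_path optional output TSV for the sample metadata.
#' @export
write_count_matrix <- function(cm, path, meta_path = NULL) {
  df <- data.frame(construct_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  if (!is.null(meta_path)) write_tsv(cm$samples, meta_path)
  invisible(path)
}

#' RPM-normalize every sample of a count matrix
#'
#' Idempotent up to the normalization flag: normalizing an already-RPM matrix
#' returns the same values.
#'
#' @param cm a `count_matrix`.
#' @return the `count_matrix` with RPM values and `normalized = TRUE`.
#' @export
normalize_rpm <- function(cm) {
  cm$counts <- apply(cm$counts, 2, rpm_normalize)
  cm$normalized <- TRUE
  cm
}

#' Import an externally produced gene-effect score table
#'
#' Reads a genes x screens table (e.g. Chronos gene effects or MAGeCK MLE
#' beta scores exported as plain text). Rows carrying control labels or genes
#' absent from the library's gene universe are dropped with a warning; any
#' non-numeric cell is an error naming its location.
#'
#' @param path delimited table, first column `gene`.
#' @param source_tag one of `"log2fc"`, `"chronos"`, `"mageck_mle"`.
#' @param library optional `guide_library` used to restrict to its gene
#'   universe.
#' @return numeric matrix (genes x screens) with attribute `source_tag`.
#' @export
import_scores <- function(path, source_tag = c("log2fc", "chronos",
                                               "mageck_mle"),
                          library = NULL) {
  source_tag <- match.arg(source_tag)
  sep <- sniff_sep(path)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character",
                   comment.char = "")
  if (names(df)[1] != "gene") {
    stop("score table must have 'gene' as its first column", call. = FALSE)
  }
  genes <- df$gene
  if (anyDuplicated(genes)) {
    stop("duplicate gene row(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(df[-1])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell at gene '%s', screen '%s'",
                 genes[bad[1, 1]], colnames(vals)[bad[1, 2]]),
         call. = FALSE)
  }
  rownames(num) <- genes
  if (!is.null(library)) {
    keep <- genes %in% library_genes(library)
    if (any(!keep)) {
      warning(sum(!keep), " row(s) not in the library gene universe ",
              "dropped: ", paste(head(genes[!keep], 5), collapse = ", "),
              call. = FALSE)
      num <- num[keep, , drop = FALSE]
    }
  }
  gene_effect(num, source_tag)
}

#' Tag a genes x screens matrix as a gene-effect matrix
#'
#' @param scores numeric matrix, rownames = genes, colnames = screens.
#' @param source_tag provenance: internal `"log2fc"` or imported
#'   `"chronos"` / `"mageck_mle"`.
#' @return the matrix with class `gene_effect` and a `source_tag` attribute.
#' @export
gene_effect <- function(scores, source_tag = "log2fc") {
  stopifnot(is.matrix(scores), is.numeric(scores))
  if (anyDuplicated(rownames(scores))) {
    stop("gene rows must be unique", call. = FALSE)
  }
  if (any(!is.finite(scores))) {
    stop("gene effect scores must be finite (handle dropouts upstream ",
         "with a pseudocount)", call. = FALSE)
  }
  attr(scores, "source_tag") <- source_tag
  class(scores) <- c("gene_effect", class(scores))
  scores
}

#' Write a gene-effect matrix as a genes x screens TSV
#'
#' @param scores matrix (genes x screens).
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(gene = rownames(scores), unclass(scores),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a gene list (one symbol per line)
#'
#' Used for the common-essential reference list. Blank lines are dropped.
#'
#' @param path plain-text file.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
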