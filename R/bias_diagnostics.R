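#' Assign genes to equal-count representation bins
#'
#' Sorts genes by `(key, gene label)` ascending and splits them into
#' `n_bins` contiguous chunks whose sizes differ by at most one gene;
#' remainder genes go to the lowest bins. The key is normally the per-gene
#' pDNA representation in RPM (see [gene_pdna()]); for cross-library
#' analyses use the mean of the two libraries' per-gene RPM.
#'
#' @param values named numeric vector: per-gene ordering key.
#' @param n_bins number of bins (default 20).
#' @return a `bin_partition` data.frame with columns `gene`, `key`, `bin`
#'   (bin 1 holds the lowest keys) and attribute `n_bins`.
#' @export
equal_count_bins <- function(values, n_bins = 20) {
  n <- length(values)
  if (is.null(names(values))) stop("values must be named by gene",
                                   call. = FALSE)
  if (n_bins < 2) stop("need at least 2 bins", call. = FALSE)
  if (n_bins > n) stop("more bins (", n_bins, ") than genes (", n, ")",
                       call. = FALSE)
  ord <- stable_order(values, names(values))
  base <- n %/% n_bins
  sizes <- rep(base, n_bins)
  r <- n %% n_bins
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  out <- data.frame(gene = names(values)[ord],
                    key = as.numeric(values[ord]),
                    bin = rep(seq_len(n_bins), times = sizes),
                    stringsAsFactors = FALSE)
  attr(out, "n_bins") <- n_bins
  class(out) <- c("bin_partition", "data.frame")
  out
}

#' Mean absolute gene effect score across screens
#'
#' @param scores a genes x screens matrix.
#' @param screens columns to include (default all).
#' @return named per-gene vector of mean |score| over the selected screens.
#' @export
mean_abs_score <- function(scores, screens = NULL) {
  m <- unclass(scores)
  if (!is.null(screens)) m <- m[, screens, drop = FALSE]
  if (ncol(m) < 1) stop("select at least one screen", call. = FALSE)
  rowMeans(abs(m))
}

# Per-bin summaries of a per-gene statistic: the engine behind the bias
# diagnostics. Quantiles use linear interpolation (type 7); SD is sample SD.
bin_summaries <- function(per_gene_stat, partition) {
  missing <- setdiff(names(per_gene_stat), partition$gene)
  if (length(missing) > 0) {
    stop("partition does not cover gene(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  part <- partition[partition$gene %in% names(per_gene_stat), , drop = FALSE]
  stat <- per_gene_stat[part$gene]
  split_stat <- split(as.numeric(stat), part$bin)
  split_key <- split(part$key, part$bin)
  bins <- as.integer(names(split_stat))
  data.frame(
    bin = bins,
    mean_pdna = vapply(split_key, mean, numeric(1)),
    median = vapply(split_stat, median, numeric(1)),
    q25 = vapply(split_stat, function(x) quantile(x, 0.25, names = FALSE),
                 numeric(1)),
    q75 = vapply(split_stat, function(x) quantile(x, 0.75, names = FALSE),
                 numeric(1)),
    sd = vapply(split_stat,
                function(x) if (length(x) > 1) sd(x) else NA_real_,
                numeric(1)),
    n = vapply(split_stat, length, numeric(1)),
    row.names = NULL)
}

#' Representation-bias diagnostic
#'
#' The core statistic: per representation bin, the median of a per-gene score
#' statistic (typically mean |log2 fold change| or mean |Chronos score|),
#' correlated against the bin's mean pDNA representation by Spearman rank
#' correlation (one point per bin; ties get average ranks). A negative rho
#' means poorly represented genes carry systematically more extreme scores.
#' Identical medians across all bins are reported as `rho = 0`, `p = 1` with
#' `degenerate = TRUE` rather than an error.
#'
#' @param per_gene_stat named per-gene statistic (e.g. [mean_abs_score()]).
#' @param partition a `bin_partition` covering the genes of the statistic.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return a `bias_result` list: `rho`, `p_value`, `degenerate`, `n_bins`,
#'   `method`, `bins` (per-bin summary data.frame with `bin`, `mean_pdna`,
#'   `median`, `q25`, `q75`, `sd`, `n`).
#' @export
representation_bias <- function(per_gene_stat, partition,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  bins <- bin_summaries(per_gene_stat, partition)
  degenerate <- length(unique(bins$median)) == 1
  if (degenerate) {
    rho <- 0
    p <- 1
  } else {
    ct <- suppressWarnings(cor.test(bins$mean_pdna, bins$median,
                                    method = method, exact = FALSE))
    rho <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(list(rho = rho, p_value = p, degenerate = degenerate,
                 n_bins = nrow(bins), method = method, bins = bins),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("bias_result (%s): rho = %.3f, p = %.3g over %d bins%s\n",
              x$method, x$rho, x$p_value, x$n_bins,
              if (x$degenerate) " [degenerate: all bin medians tied]" else ""))
  invisible(x)
}

#' Per-bin standard deviation profile of raw per-gene scores
#'
#' @param per_gene_stat named per-gene values (typically raw mean scores,
#'   not absolute).
#' @param partition a `bin_partition`.
#' @return data.frame `bin`, `mean_pdna`, `sd` (`NA` for singleton bins),
#'   `n`.
#' @export
per_bin_sd_profile <- function(per_gene_stat, partition) {
  bin_summaries(per_gene_stat, partition)[c("bin", "mean_pdna", "sd", "n")]
}

#' Difference-based representation bias between two score matrices
#'
#' Per gene, the mean over paired screens of |A - B| (cross-library or
#' replicate comparisons), then the standard bias diagnostic on that
#' statistic. For cross-library mode the partition should be keyed on the
#' mean of the two libraries' per-gene pDNA RPM.
#'
#' @param scoresA,scoresB genes x screens matrices with paired columns.
#' @param partition a `bin_partition` keyed on the appropriate pDNA.
#' @param method correlation flavor, as in [representation_bias()].
#' @return a `bias_result`.
#' @export
difference_bias <- function(scoresA, scoresB, partition,
                            method = "spearman") {
  shared <- intersect(rownames(scoresA), rownames(scoresB))
  if (length(shared) == 0) stop("no shared genes between score matrices",
                                call. = FALSE)
  a <- unclass(scoresA)[shared, , drop = FALSE]
  b <- unclass(scoresB)[shared, , drop = FALSE]
  if (ncol(a) != ncol(b)) {
    stop("matrices must have the same number of paired screens",
         call. = FALSE)
  }
  stat <- rowMeans(abs(a - b))
  representation_bias(stat, partition, method = method)
}

#' LOESS smoothing of per-bin medians (display only)
#'
#' Local-linear fit of the bin medians over bin mean pDNA, evaluated at the
#' bin abscissae. Purely cosmetic: the rank correlation is never computed on
#' the smoothed curve.
#'
#' @param bins a `bias_result` or its `bins` data.frame.
#' @param span LOESS span (default 0.75).
#' @return data.frame `mean_pdna`, `smoothed`, or `NULL` with a warning for
#'   fewer than 4 bins.
#' @export
loess_bins <- function(bins, span = 0.75) {
  if (inherits(bins, "bias_result")) bins <- bins$bins
  if (nrow(bins) < 4) {
    warning("fewer than 4 bins; smoothing skipped", call. = FALSE)
    return(NULL)
  }
  fit <- loess(median ~ mean_pdna, data = bins, span = span, degree = 1,
               family = "gaussian",
               control = loess.control(surface = "direct"))
  data.frame(mean_pdna = bins$mean_pdna,
             smoothed = as.numeric(predict(fit, bins$mean_pdna)))
}

#' Serialize a bias result as JSON
#'
#' Layout: `{rho, p_value, n_bins, degenerate, method, bins: [{bin,
#' mean_pdna, median, q25, q75, sd, n}]}`.
#'
#' @param result a `bias_result`.
#' @param path output path.
#' @export
write_bias_json <- function(result, path) {
  payload <- list(rho = result$rho, p_value = result$p_value,
                  n_bins = result$n_bins, degenerate = result$degenerate,
                  method = result$method,
                  bins = result$bins)
  write_report_json(payload, path)
}
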