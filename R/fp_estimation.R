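#' Essential-ratio threshold curve over pDNA representation
#'
#' For each candidate pDNA threshold, counts the genes at or below it
#' (`n_below`), how many of those carry the essential flag (`ess_below`),
#' the observed ratio, the count expected if essential calls were
#' independent of representation (`fraction * n_below`), and the predicted
#' false positives `ess_below - expected` (the excess of observed essential
#' calls over the representation-independent expectation).
#'
#' @param pdna named per-gene pDNA representation (RPM).
#' @param essential essential genes: character vector (e.g. an
#'   [call_essentials()] result) or named logical aligned with `pdna`.
#' @param fraction the call fraction the flags were produced at (default
#'   0.15).
#' @param thresholds candidate thresholds; default all distinct attained
#'   pDNA values. A threshold below the minimum yields `n_below = 0` and a
#'   missing ratio.
#' @return a `threshold_curve` data.frame: `threshold`, `n_below`,
#'   `ess_below`, `ratio`, `expected`, `predicted_fp`.
#' @export
threshold_curve <- function(pdna, essential, fraction = 0.15,
                            thresholds = NULL) {
  flags <- as_essential_flags(pdna, essential)
  if (!any(flags)) stop("no essential genes flagged", call. = FALSE)
  if (is.null(thresholds)) thresholds <- sort(unique(as.numeric(pdna)))
  thresholds <- sort(thresholds)
  x <- sort(as.numeric(pdna))
  xe <- sort(as.numeric(pdna)[flags])
  n_below <- findInterval(thresholds, x)
  ess_below <- findInterval(thresholds, xe)
  ratio <- ifelse(n_below > 0, ess_below / n_below, NA_real_)
  out <- data.frame(threshold = thresholds, n_below = n_below,
                    ess_below = ess_below, ratio = ratio,
                    expected = fraction * n_below,
                    predicted_fp = ess_below - fraction * n_below)
  attr(out, "fraction") <- fraction
  class(out) <- c("threshold_curve", "data.frame")
  out
}

as_essential_flags <- function(pdna, essential) {
  if (is.logical(essential)) {
    if (!is.null(names(essential))) essential <- essential[names(pdna)]
    if (length(essential) != length(pdna) || anyNA(essential)) {
      stop("logical essential flags must align with pdna", call. = FALSE)
    }
    essential
  } else {
    names(pdna) %in% as.character(essential)
  }
}

#' Elbow detection by maximum perpendicular distance
#'
#' On the points `(threshold, ratio)` of a threshold curve -- restricted to
#' thresholds with at least `min_genes_below` genes beneath them, which
#' stabilizes the noisy left edge of the ratio -- draws the chord from the
#' first to the last restricted point and returns the threshold maximizing
#' the perpendicular point-to-chord distance. Ties go to the smallest
#' threshold; exactly collinear curves return the smallest threshold with a
#' degenerate flag.
#'
#' @param curve a `threshold_curve`.
#' @param min_genes_below minimum `n_below` for a point to participate
#'   (default 100; use 0 for tiny fixtures).
#' @param normalize rescale both axes to \[0, 1\] before measuring distances
#'   (default `FALSE`: distances are taken in raw data units).
#' @return list: `threshold`, `distance`, `degenerate`.
#' @export
detect_elbow <- function(curve, min_genes_below = 100, normalize = FALSE) {
  keep <- curve$n_below >= min_genes_below & !is.na(curve$ratio)
  pts <- curve[keep, , drop = FALSE]
  if (nrow(pts) < 3) {
    stop("fewer than 3 curve points after restriction (have ", nrow(pts),
         ")", call. = FALSE)
  }
  x <- pts$threshold
  y <- pts$ratio
  if (normalize) {
    x <- (x - min(x)) / max(diff(range(x)), .Machine$double.eps)
    y <- (y - min(y)) / max(diff(range(y)), .Machine$double.eps)
  }
  n <- length(x)
  dx <- x[n] - x[1]
  dy <- y[n] - y[1]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) stop("zero-length chord", call. = FALSE)
  d <- abs(dx * (y[1] - y) - dy * (x[1] - x)) / len
  best <- which.max(d)
  list(threshold = pts$threshold[best], distance = d[best],
       degenerate = d[best] == 0)
}

#' Per-bin false positive / false negative accounting
#'
#' Within each representation bin, the expected number of essential calls
#' under representation-independence is `fraction * bin size`; the excess of
#' observed calls is counted as false positives, the deficit as false
#' negatives (each bin contributes to exactly one side). When the bins
#' partition the full gene set and the call size is exactly
#' `fraction * n` the totals conserve: sum(fp) = sum(fn).
#'
#' Counts are kept fractional (expectations are non-integer); round only at
#' presentation.
#'
#' @param pdna named per-gene pDNA representation (RPM).
#' @param essential as in [threshold_curve()].
#' @param partition a `bin_partition` covering the flagged genes.
#' @param fraction call fraction (default 0.15).
#' @return an `fpfn_estimate` list: `bins` (data.frame `bin`, `mean_pdna`,
#'   `n`, `observed`, `expected`, `fp`, `fn`), `total_fp`, `total_fn`,
#'   `total_misclassified`, `fraction`.
#' @export
per_bin_fp_fn <- function(pdna, essential, partition, fraction = 0.15) {
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  flags <- as_essential_flags(pdna, essential)
  names(flags) <- names(pdna)
  missing <- setdiff(names(pdna)[flags], partition$gene)
  if (length(missing) > 0) {
    stop("partition does not cover flagged gene(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  part <- partition
  obs <- tapply(part$gene %in% names(flags)[flags], part$bin, sum)
  n_b <- tapply(part$gene, part$bin, length)
  mean_pdna <- tapply(part$key, part$bin, mean)
  expected <- fraction * as.numeric(n_b)
  observed <- as.numeric(obs)
  fp <- pmax(observed - expected, 0)
  fn <- pmax(expected - observed, 0)
  bins <- data.frame(bin = as.integer(names(n_b)),
                     mean_pdna = as.numeric(mean_pdna),
                     n = as.numeric(n_b), observed = observed,
                     expected = expected, fp = fp, fn = fn,
                     row.names = NULL)
  structure(list(bins = bins, total_fp = sum(fp), total_fn = sum(fn),
                 total_misclassified = sum(fp) + sum(fn),
                 fraction = fraction),
            class = "fpfn_estimate")
}

#' @export
print.fpfn_estimate <- function(x, ...) {
  cat(sprintf(
    "fpfn_estimate: %.1f FP, %.1f FN over %d bins (fraction %.2f)\n",
    x$total_fp, x$total_fn, nrow(x$bins), x$fraction))
  invisible(x)
}

#' Two-sample KS comparison of essential vs non-essential pDNA distributions
#'
#' D = sup |ECDF_essential - ECDF_nonessential| over pDNA values, with the
#' asymptotic two-sided p-value. A leftward shift of the essential group
#' (positive D with essential mass at low pDNA) is the signature of
#' representation-driven essential calls.
#'
#' @param pdna named per-gene pDNA representation (RPM).
#' @param essential as in [threshold_curve()]; both groups must be
#'   non-empty.
#' @return list: `ks_stat`, `ks_p`, `ecdf_essential`, `ecdf_nonessential`
#'   (step functions).
#' @export
ecdf_ks <- function(pdna, essential) {
  flags <- as_essential_flags(pdna, essential)
  ess <- as.numeric(pdna)[flags]
  non <- as.numeric(pdna)[!flags]
  if (length(ess) == 0 || length(non) == 0) {
    stop("both the essential and non-essential group must be non-empty",
         call. = FALSE)
  }
  kt <- suppressWarnings(ks.test(ess, non, exact = FALSE))
  list(ks_stat = unname(kt$statistic), ks_p = kt$p.value,
       ecdf_essential = ecdf(ess), ecdf_nonessential = ecdf(non))
}

#' One-sample KS of essential pDNA ranks against uniformity
#'
#' Alternative flavor: tests whether essential genes' positions in the
#' pDNA ranking deviate from a uniform spread. The two-sample [ecdf_ks()]
#' is the primary diagnostic.
#'
#' @inheritParams ecdf_ks
#' @return list: `ks_stat`, `ks_p`.
#' @export
ecdf_ks_uniform <- function(pdna, essential) {
  flags <- as_essential_flags(pdna, essential)
  if (!any(flags)) stop("no essential genes flagged", call. = FALSE)
  r <- rank(as.numeric(pdna), ties.method = "average")
  u <- r[flags] / length(pdna)
  kt <- suppressWarnings(ks.test(u, "punif", exact = FALSE))
  list(ks_stat = unname(kt$statistic), ks_p = kt$p.value)
}

#' Full false-positive / false-negative estimation for one screen
#'
#' Orchestrates the estimator: calls essentials at `fraction`, builds the
#' threshold curve, detects the elbow, computes per-bin FP/FN counts and the
#' essential vs non-essential KS comparison.
#'
#' @param scores named gene scores for one screen.
#' @param pdna named per-gene pDNA representation (RPM), same universe.
#' @param fraction call fraction (default 0.15).
#' @param n_bins number of representation bins (default 20).
#' @param min_genes_below elbow restriction (default 100).
#' @param ks_flavor `"two_sample"` (default) or `"uniform"`.
#' @return an `fpfn_report` list: `fraction`, `n_bins`, `elbow_threshold`,
#'   `total_fp`, `total_fn`, `total_misclassified`, `ks` (`D`, `p`),
#'   `bins`, `curve`, `call`.
#' @export
estimate_fp_fn <- function(scores, pdna, fraction = 0.15, n_bins = 20,
                           min_genes_below = 100,
                           ks_flavor = c("two_sample", "uniform")) {
  ks_flavor <- match.arg(ks_flavor)
  if (!setequal(names(scores), names(pdna))) {
    stop("scores and pdna must cover the same gene universe", call. = FALSE)
  }
  pdna <- pdna[names(scores)]
  call <- call_essentials(scores, fraction)
  curve <- threshold_curve(pdna, call, fraction)
  elbow <- tryCatch(detect_elbow(curve, min_genes_below),
                    error = function(e) {
                      warning("elbow detection failed: ",
                              conditionMessage(e), call. = FALSE)
                      list(threshold = NA_real_, distance = NA_real_,
                           degenerate = TRUE)
                    })
  partition <- equal_count_bins(pdna, n_bins)
  est <- per_bin_fp_fn(pdna, call, partition, fraction)
  ks <- if (ks_flavor == "two_sample") {
    ecdf_ks(pdna, call)
  } else {
    ecdf_ks_uniform(pdna, call)
  }
  structure(list(fraction = fraction, n_bins = n_bins,
                 elbow_threshold = elbow$threshold,
                 elbow_degenerate = elbow$degenerate,
                 total_fp = est$total_fp, total_fn = est$total_fn,
                 total_misclassified = est$total_misclassified,
                 ks = list(D = ks$ks_stat, p = ks$ks_p,
                           flavor = ks_flavor),
                 bins = est$bins, curve = curve, call = call),
            class = "fpfn_report")
}

#' Serialize an FP/FN report as JSON
#'
#' Layout: `{elbow_threshold, fraction, total_fp, total_fn,
#' total_misclassified, ks: {D, p}, bins: [...]}`.
#'
#' @param report an `fpfn_report` from [estimate_fp_fn()].
#' @param path output path.
#' @export
write_fpfn_json <- function(report, path) {
  payload <- list(elbow_threshold = report$elbow_threshold,
                  fraction = report$fraction,
                  n_bins = report$n_bins,
                  total_fp = report$total_fp,
                  total_fn = report$total_fn,
                  total_misclassified = report$total_misclassified,
                  ks = list(D = report$ks$D, p = report$ks$p),
                  bins = report$bins)
  write_report_json(payload, path)
}

#' Write a threshold curve as TSV
#'
#' @param curve a `threshold_curve`.
#' @param path output path.
#' @export
write_threshold_curve <- function(curve, path) {
  write_tsv(as.data.frame(curve), path)
}
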