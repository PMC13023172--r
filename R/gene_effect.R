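#' Per-construct log2 fold change between two RPM-normalized samples
#'
#' `log2((rpm_t + pseudocount) / (rpm_0 + pseudocount))`. The pseudocount
#' (default 1 RPM) keeps dropped-out constructs finite.
#'
#' @param rpm_t RPM counts at the later timepoint.
#' @param rpm_0 RPM counts at the reference timepoint (same construct index).
#' @param pseudocount positive real added to both numerator and denominator.
#' @return numeric vector of per-construct scores.
#' @export
log2_fold_change <- function(rpm_t, rpm_0, pseudocount = 1) {
  if (length(rpm_t) != length(rpm_0)) {
    stop("timepoint and reference vectors differ in length", call. = FALSE)
  }
  if (!is.null(names(rpm_t)) && !is.null(names(rpm_0)) &&
      !identical(names(rpm_t), names(rpm_0))) {
    stop("construct indices of the two vectors do not match", call. = FALSE)
  }
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  log2((rpm_t + pseudocount) / (rpm_0 + pseudocount))
}

#' Aggregate per-construct scores to per-gene scores
#'
#' Gene score = arithmetic mean of its constructs' scores; control constructs
#' are excluded. Works on a vector (one screen) or a constructs x screens
#' matrix.
#'
#' @param construct_scores named vector or matrix with rownames = construct
#'   ids present in `library`.
#' @param library a `guide_library`.
#' @param source_tag provenance tag for the resulting matrix.
#' @return a `gene_effect` matrix (genes x screens).
#' @export
aggregate_to_genes <- function(construct_scores, library,
                               source_tag = "log2fc") {
  if (is.null(dim(construct_scores))) {
    construct_scores <- matrix(construct_scores,
                               dimnames = list(names(construct_scores),
                                               "screen_1"))
  }
  ids <- rownames(construct_scores)
  if (is.null(ids) || !all(ids %in% library$construct_id)) {
    stop("construct scores must be named by library construct ids",
         call. = FALSE)
  }
  info <- library[match(ids, library$construct_id), ]
  keep <- !info$is_control & apply(is.finite(construct_scores), 1, all)
  n_dropped_na <- sum(!info$is_control & !keep)
  if (n_dropped_na > 0) {
    warning(n_dropped_na, " construct(s) with non-finite scores dropped",
            call. = FALSE)
  }
  if (!any(keep)) {
    warning("no non-control constructs with finite scores; empty matrix",
            call. = FALSE)
    return(gene_effect(matrix(numeric(0), nrow = 0,
                              ncol = ncol(construct_scores),
                              dimnames = list(character(0),
                                              colnames(construct_scores))),
                       source_tag))
  }
  sc <- construct_scores[keep, , drop = FALSE]
  gene <- info$gene[keep]
  sums <- rowsum(sc, gene)
  n <- as.vector(table(gene)[rownames(sums)])
  gene_effect(sums / n, source_tag)
}

#' Score screens from a count matrix by log2 fold change
#'
#' For each screen (grouped by `screen_id` in the sample metadata), computes
#' per-construct log2 fold change of a chosen later timepoint against the
#' screen's earliest timepoint, then aggregates to genes. The default
#' `timepoint = "final"` uses the last timepoint; `"best_recall"` evaluates
#' every later timepoint and keeps the one maximizing common-essential recall
#' against `reference` (requires `reference`).
#'
#' When `center = TRUE` (default) each screen's gene scores are shifted so
#' their median is zero. Without this, depletion of the essential fraction
#' inflates every neutral gene's relative abundance by the same factor
#' (counts are compositional), which the pseudocount then shrinks more at
#' low representation -- a spurious monotone trend with pDNA that has
#' nothing to do with sampling noise. Median-centering pins the typical
#' (neutral) gene at zero, the convention gene-effect scores follow.
#'
#' @param cm a `count_matrix` (raw or RPM; raw is normalized internally).
#' @param library a `guide_library`.
#' @param pseudocount pseudocount in RPM units (default 1).
#' @param timepoint `"final"` or `"best_recall"`.
#' @param reference common-essential gene list, needed for `"best_recall"`.
#' @param fraction essential-call fraction used by `"best_recall"`.
#' @param center median-center each screen's gene scores (default `TRUE`).
#' @return a `gene_effect` matrix with one column per screen.
#' @export
score_screens <- function(cm, library, pseudocount = 1,
                          timepoint = c("final", "best_recall"),
                          reference = NULL, fraction = 0.15,
                          center = TRUE) {
  timepoint <- match.arg(timepoint)
  if (timepoint == "best_recall" && is.null(reference)) {
    stop("timepoint = 'best_recall' needs a reference gene list",
         call. = FALSE)
  }
  if (!cm$normalized) cm <- normalize_rpm(cm)
  meta <- cm$samples
  if (is.null(meta$screen_id)) meta$screen_id <- meta$sample
  key <- if (!is.null(meta$doublings)) meta$doublings else meta$timepoint_day
  if (is.null(key)) stop("sample metadata needs doublings or timepoint_day",
                         call. = FALSE)
  screens <- unique(meta$screen_id)
  cols <- lapply(screens, function(s) {
    idx <- which(meta$screen_id == s)
    idx <- idx[order(key[idx])]
    if (length(idx) < 2) stop("screen '", s, "' has no later timepoint",
                              call. = FALSE)
    ref_rpm <- cm$counts[, idx[1]]
    later <- idx[-1]
    per_tp <- lapply(later, function(j) {
      lfc <- log2_fold_change(cm$counts[, j], ref_rpm, pseudocount)
      aggregate_to_genes(setNames(lfc, rownames(cm$counts)), library)[, 1]
    })
    if (timepoint == "final" || length(per_tp) == 1) {
      per_tp[[length(per_tp)]]
    } else {
      rec <- vapply(per_tp, function(g) {
        recall_common_essentials(call_essentials(g, fraction), reference,
                                 genes = names(g))
      }, numeric(1))
      per_tp[[which.max(rec)]]
    }
  })
  out <- do.call(cbind, cols)
  colnames(out) <- screens
  if (center) out <- sweep(out, 2, apply(out, 2, median))
  gene_effect(out, "log2fc")
}

#' Call essential genes by bottom rank
#'
#' The bottom `floor(fraction * n)` genes by ascending score are flagged
#' essential; boundary ties are broken by ascending gene label so the call is
#' deterministic across platforms.
#'
#' @param scores named numeric vector of one screen's gene scores.
#' @param fraction fraction of genes to call (default 0.15).
#' @return an `essential_call`: character vector of called genes, with
#'   attributes `fraction` and `universe` (all scored genes).
#' @export
call_essentials <- function(scores, fraction = 0.15) {
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  n <- length(scores)
  n_sel <- floor(fraction * n)
  if (n_sel < 1) {
    stop("too few genes to call at least one essential (n = ", n, ")",
         call. = FALSE)
  }
  if (is.null(names(scores))) stop("scores must be named by gene",
                                   call. = FALSE)
  ord <- stable_order(scores, names(scores))
  out <- names(scores)[ord][seq_len(n_sel)]
  structure(out, fraction = fraction, universe = names(scores),
            class = "essential_call")
}

#' Recall of a common-essential reference list
#'
#' `|call and reference| / |reference restricted to the scored genes|`.
#' Reference genes absent from the screen's gene universe are dropped from
#' the denominator so recall measures screen quality, not library content.
#'
#' @param call an `essential_call` (or character vector of called genes).
#' @param reference character vector of reference essential genes.
#' @param genes the scored gene universe (defaults to the call's universe).
#' @return recall in \[0, 1\].
#' @export
recall_common_essentials <- function(call, reference,
                                     genes = attr(call, "universe")) {
  if (is.null(genes)) stop("supply the scored gene universe", call. = FALSE)
  ref <- intersect(reference, genes)
  if (length(ref) == 0) {
    stop("no reference genes present in the scored universe", call. = FALSE)
  }
  length(intersect(as.character(call), ref)) / length(ref)
}

#' False-negative / false-positive rate curves over bottom-k calls
#'
#' Ranks all scored units (genes plus flagged negative-control units)
#' ascending and, for each k, computes FNR(k) = 1 - |bottom-k and
#' reference| / |reference| and FPR(k) = |bottom-k and controls| /
#' |controls|.
#'
#' @param scores named scores over genes and control units.
#' @param reference reference essential genes (restricted to scored units).
#' @param is_control named logical flag aligned with `scores`.
#' @param k_grid values of k (default every k from 1 to the number of units).
#' @return data.frame with columns `k`, `fnr`, `fpr` (fpr all `NA` with a
#'   warning when no controls are present).
#' @export
fnr_fpr_curves <- function(scores, reference, is_control = NULL,
                           k_grid = NULL) {
  n <- length(scores)
  if (is.null(is_control)) {
    is_control <- setNames(rep(FALSE, n), names(scores))
  }
  is_control <- is_control[names(scores)]
  ref <- intersect(reference, names(scores)[!is_control])
  if (length(ref) == 0) stop("no reference genes among scored units",
                             call. = FALSE)
  if (is.null(k_grid)) k_grid <- seq_len(n)
  ord <- stable_order(scores, names(scores))
  ranked <- names(scores)[ord]
  cum_ref <- cumsum(ranked %in% ref)
  n_ctrl <- sum(is_control)
  fnr <- 1 - c(0, cum_ref)[k_grid + 1] / length(ref)
  if (n_ctrl == 0) {
    warning("no control units present; FPR curve omitted", call. = FALSE)
    fpr <- rep(NA_real_, length(k_grid))
  } else {
    cum_ctrl <- cumsum(is_control[ord])
    fpr <- c(0, cum_ctrl)[k_grid + 1] / n_ctrl
  }
  data.frame(k = k_grid, fnr = fnr, fpr = fpr)
}

#' Overlap between two essential calls
#'
#' @param callA,callB essential calls over the same gene universe.
#' @return list with `overlap` (|A and B|) and `jaccard`
#'   (|A and B| / |A or B|).
#' @export
pairwise_overlap <- function(callA, callB) {
  a <- as.character(callA)
  b <- as.character(callB)
  inter <- length(intersect(a, b))
  uni <- length(union(a, b))
  list(overlap = inter, jaccard = if (uni == 0) NA_real_ else inter / uni)
}
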