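#' Per-bin z-score correction of gene effect scores
#'
#' Standardizes scores within each (representation bin, screen) group:
#' `z = (score - mean) / sd` with the sample SD. Zero-SD groups map to all
#' zeros with a warning; singleton bins are an error (SD undefined). With
#' `cross_screen = TRUE` the mean and SD are pooled over all screens of a
#' bin instead of per screen.
#'
#' @param scores genes x screens matrix.
#' @param partition a `bin_partition` covering all genes of `scores`.
#' @param cross_screen pool moments across screens (default `FALSE`).
#' @return corrected matrix of the same shape (class `gene_effect` kept).
#' @export
zscore_by_bin <- function(scores, partition, cross_screen = FALSE) {
  m <- unclass(scores)
  missing <- setdiff(rownames(m), partition$gene)
  if (length(missing) > 0) {
    stop("partition does not cover gene(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  bin_of <- setNames(partition$bin, partition$gene)[rownames(m)]
  out <- m
  zero_sd <- 0L
  for (b in unique(bin_of)) {
    rows <- which(bin_of == b)
    if (length(rows) < 2) {
      stop("bin ", b, " has a single gene; SD undefined", call. = FALSE)
    }
    if (cross_screen) {
      mu <- mean(m[rows, ])
      s <- sd(as.vector(m[rows, ]))
      if (s == 0) {
        out[rows, ] <- 0
        zero_sd <- zero_sd + 1L
      } else {
        out[rows, ] <- (m[rows, ] - mu) / s
      }
    } else {
      for (j in seq_len(ncol(m))) {
        mu <- mean(m[rows, j])
        s <- sd(m[rows, j])
        if (s == 0) {
          out[rows, j] <- 0
          zero_sd <- zero_sd + 1L
        } else {
          out[rows, j] <- (m[rows, j] - mu) / s
        }
      }
    }
  }
  if (zero_sd > 0) {
    warning(zero_sd, " zero-SD group(s) mapped to all-zero z-scores",
            call. = FALSE)
  }
  if (inherits(scores, "gene_effect")) {
    out <- gene_effect(out, attr(scores, "source_tag"))
  }
  out
}

#' Filter out low-representation units (or a matched random high set)
#'
#' `mode = "low"` drops units whose pDNA representation is below
#' `threshold_rpm` (default 50 RPM, the elbow-derived cut-off).
#' `mode = "matched_random_high"` is the negative control: it drops an equal
#' number of units sampled uniformly without replacement from those at or
#' above the threshold (seed the RNG before calling for reproducibility).
#'
#' @param x matrix with rownames, or named vector, indexed by unit (gene or
#'   construct).
#' @param pdna named per-unit representation (RPM), covering the units of
#'   `x`.
#' @param threshold_rpm representation cut-off (default 50).
#' @param mode `"low"` or `"matched_random_high"`.
#' @return `x` with the dropped units removed; attribute `dropped` holds
#'   their names.
#' @export
filter_low_representation <- function(x, pdna, threshold_rpm = 50,
                                      mode = c("low",
                                               "matched_random_high")) {
  mode <- match.arg(mode)
  if (threshold_rpm < 0) stop("threshold must be >= 0", call. = FALSE)
  units <- if (is.null(dim(x))) names(x) else rownames(x)
  if (is.null(units) || !all(units %in% names(pdna))) {
    stop("pdna must cover every unit of x", call. = FALSE)
  }
  p <- pdna[units]
  low <- units[p < threshold_rpm]
  drop <- if (mode == "low") {
    low
  } else {
    high <- units[p >= threshold_rpm]
    if (length(high) < length(low)) {
      stop("fewer high-representation units (", length(high),
           ") than needed (", length(low), ")", call. = FALSE)
    }
    if (length(low) == 0) character(0) else sample(high, length(low))
  }
  keep <- setdiff(units, drop)
  out <- if (is.null(dim(x))) x[keep] else x[keep, , drop = FALSE]
  attr(out, "dropped") <- drop
  out
}

#' PCA of screens with pairwise Euclidean distances
#'
#' Screens are the observations; genes with a missing value in any screen
#' are dropped, scores are centered per gene (no unit-variance scaling,
#' since gene effect scores share a scale), and screens are projected onto
#' the top `n_pc` principal components.
#'
#' @param scores genes x screens matrix with at least 3 screens.
#' @param n_pc number of components (must be < number of screens).
#' @return a `pca_distance_report` list: `coords` (screens x n_pc),
#'   `distances` (symmetric matrix, zero diagonal), `var_explained`
#'   (fraction per retained component).
#' @export
pca_distances <- function(scores, n_pc = 2) {
  m <- unclass(scores)
  n_screens <- ncol(m)
  if (n_screens < 3) stop("need at least 3 screens", call. = FALSE)
  if (n_pc >= n_screens) stop("n_pc must be < number of screens",
                              call. = FALSE)
  complete <- apply(is.finite(m), 1, all)
  m <- m[complete, , drop = FALSE]
  pca <- prcomp(t(m), center = TRUE, scale. = FALSE)
  coords <- pca$x[, seq_len(n_pc), drop = FALSE]
  d <- as.matrix(dist(coords))
  var_expl <- pca$sdev^2 / sum(pca$sdev^2)
  structure(list(coords = coords, distances = d,
                 var_explained = var_expl[seq_len(n_pc)]),
            class = "pca_distance_report")
}

#' Pairwise distances from a PCA report as a flat vector
#'
#' @param report a `pca_distance_report`.
#' @return numeric vector of the lower-triangle pairwise distances.
#' @export
pairwise_distances <- function(report) {
  d <- report$distances
  d[lower.tri(d)]
}

#' Screen-to-screen correlation groups
#'
#' Computes per-gene rank correlations for every admissible pair of screens
#' and groups them as (same cell line, different library) vs (different cell
#' line, same library) -- the comparison asking whether library choice or
#' cell-line model dominates screen outcome -- then contrasts the two groups
#' with a two-sided Wilcoxon rank-sum test. Self-pairs and pairs fitting
#' neither group are excluded.
#'
#' @param scores genes x screens matrix.
#' @param metadata data.frame with columns `screen` (matching the score
#'   columns), `cell_line`, `library`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list: `pairs` (data.frame `screen_a`, `screen_b`, `group`,
#'   `rho`), `wilcoxon` (from [wilcoxon_compare()], or `NULL` with a
#'   warning when a group has < 2 pairs).
#' @export
correlation_groups <- function(scores, metadata,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  m <- unclass(scores)
  meta <- metadata[match(colnames(m), metadata$screen), , drop = FALSE]
  if (anyNA(meta$screen)) {
    stop("metadata must describe every screen column", call. = FALSE)
  }
  combs <- utils::combn(ncol(m), 2)
  rows <- lapply(seq_len(ncol(combs)), function(k) {
    i <- combs[1, k]
    j <- combs[2, k]
    same_cell <- meta$cell_line[i] == meta$cell_line[j]
    same_lib <- meta$library[i] == meta$library[j]
    group <- if (same_cell && !same_lib) {
      "same_cell_diff_lib"
    } else if (!same_cell && same_lib) {
      "diff_cell_same_lib"
    } else {
      NA_character_
    }
    data.frame(screen_a = colnames(m)[i], screen_b = colnames(m)[j],
               group = group,
               rho = cor(m[, i], m[, j], method = method,
                         use = "pairwise.complete.obs"),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  pairs <- pairs[!is.na(pairs$group), , drop = FALSE]
  g1 <- pairs$rho[pairs$group == "same_cell_diff_lib"]
  g2 <- pairs$rho[pairs$group == "diff_cell_same_lib"]
  wx <- NULL
  if (length(g1) >= 2 && length(g2) >= 2) {
    wx <- wilcoxon_compare(g1, g2, paired = FALSE)
  } else {
    warning("a correlation group has fewer than 2 pairs; ",
            "rank-sum comparison skipped", call. = FALSE)
  }
  list(pairs = pairs, wilcoxon = wx)
}

#' Wilcoxon comparison of two value sets
#'
#' Signed-rank when `paired = TRUE` (equal lengths required), rank-sum
#' otherwise; always two-sided. All-zero paired differences yield the
#' degenerate result `p = 1` with a flag instead of an error.
#'
#' @param valuesA,valuesB numeric vectors.
#' @param paired logical.
#' @return list: `statistic`, `p`, `degenerate`.
#' @export
wilcoxon_compare <- function(valuesA, valuesB, paired = FALSE) {
  if (paired && length(valuesA) != length(valuesB)) {
    stop("paired mode requires equal lengths", call. = FALSE)
  }
  if (paired && all(valuesA == valuesB)) {
    return(list(statistic = 0, p = 1, degenerate = TRUE))
  }
  wt <- suppressWarnings(wilcox.test(valuesA, valuesB, paired = paired,
                                     alternative = "two.sided",
                                     exact = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value, degenerate = FALSE)
}

#' Before/after correction evaluation battery
#'
#' Compares an uncorrected and a corrected score matrix on: per-screen
#' common-essential recall (when a reference list is supplied), the
#' correlation-group contrast, and paired signed-rank tests on the per-pair
#' rhos of each group before vs after.
#'
#' @param before,after genes x screens matrices over the same screens.
#' @param metadata screen metadata as in [correlation_groups()].
#' @param reference optional common-essential gene list.
#' @param fraction essential-call fraction for recall (default 0.15).
#' @param method correlation flavor.
#' @return a `correction_report` list: `recall` (data.frame or `NULL`),
#'   `groups_before`, `groups_after`, `paired_tests` (per group).
#' @export
correction_report <- function(before, after, metadata, reference = NULL,
                              fraction = 0.15, method = "spearman") {
  stopifnot(identical(colnames(before), colnames(after)))
  recall <- NULL
  if (!is.null(reference)) {
    rec <- function(m) {
      vapply(seq_len(ncol(m)), function(j) {
        sc <- setNames(unclass(m)[, j], rownames(m))
        recall_common_essentials(call_essentials(sc, fraction), reference,
                                 genes = names(sc))
      }, numeric(1))
    }
    recall <- data.frame(screen = colnames(before),
                         recall_before = rec(before),
                         recall_after = rec(after),
                         stringsAsFactors = FALSE)
  }
  gb <- correlation_groups(before, metadata, method = method)
  ga <- correlation_groups(after, metadata, method = method)
  paired_tests <- lapply(c(same_cell_diff_lib = "same_cell_diff_lib",
                           diff_cell_same_lib = "diff_cell_same_lib"),
                         function(g) {
    b <- gb$pairs$rho[gb$pairs$group == g]
    a <- ga$pairs$rho[ga$pairs$group == g]
    if (length(b) < 2) return(NULL)
    wilcoxon_compare(a, b, paired = TRUE)
  })
  structure(list(recall = recall, groups_before = gb, groups_after = ga,
                 paired_tests = paired_tests),
            class = "correction_report")
}
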