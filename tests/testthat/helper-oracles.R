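# Independent oracle implementations, deliberately kept apart from the code
# paths they check.

# Average-rank assignment without base::rank's shortcuts for the Pearson
# step: explicit sums.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Perpendicular distance of every point to the chord through the first and
# last points, computed by projection (not the cross-product formula used in
# the package); returns the index of the max, first index on ties.
oracle_elbow_index <- function(x, y) {
  p1 <- c(x[1], y[1])
  p2 <- c(x[length(x)], y[length(y)])
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  d <- vapply(seq_along(x), function(i) {
    v <- c(x[i], y[i]) - p1
    proj <- sum(v * u) * u
    sqrt(sum((v - proj)^2))
  }, numeric(1))
  which.max(d)
}

# Two-sample KS statistic as an explicit sup over the pooled values.
oracle_ks_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}
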