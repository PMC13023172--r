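test_that("threshold_curve matches the worked fixture and is monotone", {
  pdna <- setNames(c(1, 2, 3, 4, 10, 20, 30, 40, 50, 60),
                   paste0("g", sprintf("%02d", 1:10)))
  ess <- paste0("g", sprintf("%02d", 1:4))   # the 4 lowest genes
  cur <- threshold_curve(pdna, ess, fraction = 0.15)
  at4 <- cur[cur$threshold == 4, ]
  expect_equal(at4$n_below, 4)
  expect_equal(at4$ratio, 1)
  expect_equal(at4$expected, 0.6)
  expect_equal(at4$predicted_fp, 3.4)
  expect_true(all(diff(cur$n_below) >= 0))
  expect_true(all(diff(cur$ess_below) >= 0))
  expect_equal(cur$predicted_fp, cur$ess_below - 0.15 * cur$n_below)

  # uniformly interleaved flags: |predicted_fp| < 1 everywhere
  pdna2 <- setNames(seq_len(40), paste0("h", sprintf("%02d", 1:40)))
  ess2 <- paste0("h", sprintf("%02d", seq(4, 40, by = 8)))  # every 8th
  cur2 <- threshold_curve(pdna2, ess2, fraction = 0.125)
  expect_true(all(abs(cur2$predicted_fp) < 1))

  # custom threshold below the observed minimum
  cur3 <- threshold_curve(pdna, ess, thresholds = c(0.5, 100))
  expect_equal(cur3$n_below[1], 0)
  expect_true(is.na(cur3$ratio[1]))

  # predicted_fp at the top threshold equals the floor() rounding slack
  set.seed(3)
  sc <- setNames(rnorm(123), paste0("z", sprintf("%03d", 1:123)))
  pd <- setNames(runif(123, 1, 100), names(sc))
  call <- call_essentials(sc, 0.15)
  cur4 <- threshold_curve(pd, call, fraction = 0.15)
  top <- cur4[nrow(cur4), ]
  expect_equal(top$predicted_fp, floor(0.15 * 123) - 0.15 * 123)

  expect_error(threshold_curve(pdna, character(0)), "no essential")
})

test_that("detect_elbow equals the brute-force oracle exactly", {
  fixture <- data.frame(threshold = c(0, 1, 2), n_below = c(1, 2, 3),
                        ess_below = 0, ratio = c(0, 0.9, 1.0),
                        expected = 0, predicted_fp = 0)
  class(fixture) <- c("threshold_curve", "data.frame")
  eb <- detect_elbow(fixture, min_genes_below = 0)
  expect_equal(eb$threshold, 1)
  expect_false(eb$degenerate)

  collinear <- fixture
  collinear$ratio <- c(0, 0.5, 1)
  ec <- detect_elbow(collinear, min_genes_below = 0)
  expect_equal(ec$threshold, 0)
  expect_true(ec$degenerate)

  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- sort(runif(n, 0, 100))
    y <- sort(runif(n))          # random monotone curve
    cur <- data.frame(threshold = x, n_below = seq_len(n), ess_below = 0,
                      ratio = y, expected = 0, predicted_fp = 0)
    class(cur) <- c("threshold_curve", "data.frame")
    got <- detect_elbow(cur, min_genes_below = 0)
    expect_identical(got$threshold, x[oracle_elbow_index(x, y)])
  }

  expect_error(detect_elbow(fixture[1:2, ], min_genes_below = 0),
               "fewer than 3")
})

test_that("per_bin_fp_fn reproduces fixtures and conserves totals", {
  mk_part <- function(n_per_bin, n_bins) {
    genes <- paste0("g", sprintf("%04d", seq_len(n_per_bin * n_bins)))
    equal_count_bins(setNames(seq_along(genes), genes), n_bins)
  }
  part <- mk_part(100, 3)
  # observed essentials per bin: 30, 15, 0 (bins ordered by key)
  ess <- c(part$gene[part$bin == 1][1:30], part$gene[part$bin == 2][1:15])
  pdna <- setNames(part$key, part$gene)
  est <- per_bin_fp_fn(pdna, ess, part, fraction = 0.15)
  expect_equal(est$bins$expected, c(15, 15, 15))
  expect_equal(est$bins$fp, c(15, 0, 0))
  expect_equal(est$bins$fn, c(0, 0, 15))
  expect_equal(est$total_fp, 15)
  expect_equal(est$total_fn, 15)
  expect_equal(est$total_misclassified, 30)

  # observed equal to expected everywhere -> all zero
  ess_even <- unlist(lapply(1:3, function(b) part$gene[part$bin == b][1:15]))
  even <- per_bin_fp_fn(pdna, ess_even, part, fraction = 0.15)
  expect_equal(even$total_misclassified, 0)

  # fractional expectations: 2 bins x 10 genes, observed [3, 0]
  part2 <- mk_part(10, 2)
  pd2 <- setNames(part2$key, part2$gene)
  est2 <- per_bin_fp_fn(pd2, part2$gene[part2$bin == 1][1:3], part2, 0.15)
  expect_equal(est2$bins$fp, c(1.5, 0))
  expect_equal(est2$bins$fn, c(0, 1.5))
  expect_equal(est2$total_fp, est2$total_fn)

  # conservation property: random worlds with exact-size calls
  set.seed(9)
  for (i in 1:10) {
    n <- sample(c(200, 500, 1000), 1)
    nb <- sample(c(4, 10, 20), 1)
    sc <- setNames(rnorm(n), paste0("r", sprintf("%04d", seq_len(n))))
    pd <- setNames(runif(n, 1, 1000), names(sc))
    call <- call_essentials(sc, 0.2)  # 0.2 * n is integral for these n
    est_i <- per_bin_fp_fn(pd, call, equal_count_bins(pd, nb), 0.2)
    expect_equal(est_i$total_fp, est_i$total_fn)
  }
  expect_error(per_bin_fp_fn(pd2, "g0001", part2, 1.5), "fraction")
})

test_that("ecdf_ks matches endpoints and the independent oracle", {
  same <- setNames(rep(c(1, 5, 9), 4), paste0("g", 1:12))
  flags <- setNames(rep(c(TRUE, FALSE), each = 6), names(same))
  # both groups hold the identical value multiset
  expect_equal(ecdf_ks(same, flags)$ks_stat, 0)

  sep <- setNames(c(1:5, 101:105), paste0("s", 1:10))
  fsep <- setNames(c(rep(TRUE, 5), rep(FALSE, 5)), names(sep))
  expect_equal(ecdf_ks(sep, fsep)$ks_stat, 1)

  set.seed(1)
  vals <- c(rlnorm(1000, 5, 1) / 2, rlnorm(1000, 5, 1))  # shifted essential
  pd <- setNames(vals, paste0("k", sprintf("%04d", 1:2000)))
  fl <- setNames(c(rep(TRUE, 1000), rep(FALSE, 1000)), names(pd))
  ks <- ecdf_ks(pd, fl)
  expect_gt(ks$ks_stat, 0)
  expect_lt(ks$ks_p, 0.05)
  expect_equal(ks$ks_stat, oracle_ks_stat(vals[1:1000], vals[1001:2000]),
               tolerance = 1e-12)
  expect_error(ecdf_ks(pd, setNames(rep(TRUE, 2000), names(pd))),
               "non-empty")
})

test_that("estimate_fp_fn assembles a coherent report", {
  w <- sim_world(1, n_genes = 1000)
  sc <- setNames(unclass(w$scores)[, 1], rownames(w$scores))
  rep1 <- estimate_fp_fn(sc, w$pdna, min_genes_below = 50)
  expect_s3_class(rep1, "fpfn_report")
  expect_length(rep1$call, floor(0.15 * 1000))
  expect_equal(rep1$total_misclassified, rep1$total_fp + rep1$total_fn)
  expect_equal(rep1$total_fp, rep1$total_fn, tolerance = 1e-8)
  expect_true(rep1$elbow_threshold %in% rep1$curve$threshold)
  # the reported D is exactly the two-sample ECDF sup over pDNA
  ess_pd <- w$pdna[as.character(rep1$call)]
  non_pd <- w$pdna[setdiff(names(w$pdna), as.character(rep1$call))]
  expect_equal(rep1$ks$D, oracle_ks_stat(ess_pd, non_pd),
               tolerance = 1e-12)
  # the uniform flavor is exposed behind a flag
  rep2 <- estimate_fp_fn(sc, w$pdna, min_genes_below = 50,
                         ks_flavor = "uniform")
  expect_equal(rep2$ks$flavor, "uniform")
  expect_true(rep2$ks$D >= 0 && rep2$ks$D <= 1)
})
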