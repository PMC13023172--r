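test_that("zscore_by_bin standardizes each (bin, screen) group", {
  genes <- paste0("g", sprintf("%02d", 1:9))
  part <- equal_count_bins(setNames(1:9, genes), 3)
  m <- matrix(c(-1, 0, 1, 5, 6, 7, 2, 2, 2, -3, 0, 3, 1, 2, 9, 4, 4, 4),
              nrow = 9, dimnames = list(genes, c("s1", "s2")))
  expect_warning(z <- zscore_by_bin(m, part), "zero-SD")
  # [-1, 0, 1] has sample SD 1: identity
  expect_equal(unname(z[1:3, 1]), c(-1, 0, 1))
  # constant groups map to zeros
  expect_equal(unname(z[7:9, 1]), c(0, 0, 0))
  # every non-degenerate group: mean 0, SD 1
  for (b in 1:3) {
    for (j in 1:2) {
      grp <- z[part$gene[part$bin == b], j]
      expect_lt(abs(mean(grp)), 1e-9)
      if (sd(m[part$gene[part$bin == b], j]) > 0) expect_equal(sd(grp), 1)
    }
  }
  # idempotence on non-degenerate input
  set.seed(2)
  m2 <- matrix(rnorm(90), nrow = 9, dimnames = list(genes, letters[1:10]))
  z1 <- zscore_by_bin(m2, part)
  expect_equal(zscore_by_bin(z1, part), z1, tolerance = 1e-9)
  # singleton bins are an error
  part1 <- equal_count_bins(setNames(1:3, genes[1:3]), 3)
  expect_error(zscore_by_bin(m2[1:3, ], part1), "single gene")
})

test_that("z-score correction flattens the simulated bias every time", {
  for (s in 1:5) {
    w <- sim_world(s, n_genes = 1000)
    before <- representation_bias(mean_abs_score(w$scores), w$partition)
    z <- zscore_by_bin(w$scores, w$partition)
    after <- representation_bias(mean_abs_score(z), w$partition)
    expect_lt(abs(after$rho), abs(before$rho))
  }
})

test_that("filter_low_representation drops the right units", {
  pd <- setNames(c(10, 60, 5, 200, 49, 51), paste0("u", 1:6))
  x <- setNames(rnorm(6), names(pd))
  low <- filter_low_representation(x, pd, 50, "low")
  expect_equal(sort(names(low)), sort(c("u2", "u4", "u6")))
  expect_equal(sort(attr(low, "dropped")), sort(c("u1", "u3", "u5")))
  # filtering everything leaves an empty vector
  all_low <- filter_low_representation(c(a = 1), c(a = 10), 50, "low")
  expect_length(all_low, 0)
  # threshold 0 is the identity
  ident <- filter_low_representation(x, pd, 0, "low")
  expect_equal(names(ident), names(x))
  # matched removal is seed-reproducible and size-matched
  set.seed(99)
  m1 <- filter_low_representation(x, pd, 50, "matched_random_high")
  set.seed(99)
  m2 <- filter_low_representation(x, pd, 50, "matched_random_high")
  expect_identical(names(m1), names(m2))
  expect_length(m1, 3)
  expect_true(all(pd[attr(m1, "dropped")] >= 50))
  # not enough high-representation units
  pd_low <- setNames(c(1, 2, 3, 100), paste0("v", 1:4))
  expect_error(filter_low_representation(setNames(rnorm(4), names(pd_low)),
                                         pd_low, 50,
                                         "matched_random_high"),
               "fewer high")
})

test_that("filtering low-representation genes removes the noisiest stratum", {
  # the rank-level rho barely moves under filtering (the gradient among the
  # survivors persists), so the meaningful check is on magnitude: the worst
  # surviving bin is quieter than the worst unfiltered bin
  # threshold taken at the 10th pDNA percentile so the cut bites at this
  # library size (the 50 RPM default is calibrated to genome-scale
  # libraries whose mean RPM sits near 50)
  for (s in 1:3) {
    w <- sim_world(s, n_genes = 1000)
    stat <- mean_abs_score(w$scores)
    full <- representation_bias(stat, w$partition)
    thr <- unname(quantile(w$pdna, 0.10))
    kept <- filter_low_representation(unclass(w$scores), w$pdna,
                                      threshold_rpm = thr, mode = "low")
    expect_true(all(w$pdna[rownames(kept)] >= thr))
    pd_kept <- w$pdna[rownames(kept)]
    part_kept <- equal_count_bins(pd_kept, 20)
    filt <- representation_bias(mean_abs_score(kept), part_kept)
    # the median is the robust summary here; the within-bin SD is dominated
    # by where the strongest essentials happen to land
    expect_lt(filt$bins$median[1], full$bins$median[1])
  }
})

test_that("pca_distances yields a valid geometry and separates libraries", {
  set.seed(8)
  base <- matrix(rnorm(600), nrow = 200,
                 dimnames = list(paste0("g", 1:200), paste0("s", 1:3)))
  dup <- cbind(base, s4 = base[, 2])
  rep4 <- pca_distances(dup, n_pc = 2)
  expect_equal(rep4$distances["s2", "s4"], 0, tolerance = 1e-9)
  expect_true(isSymmetric(rep4$distances))
  expect_equal(unname(diag(rep4$distances)), rep(0, 4))
  expect_error(pca_distances(base, n_pc = 3), "n_pc")
  expect_error(pca_distances(base[, 1:2, drop = FALSE]), "at least 3")

  # two library realizations sharing truth: library identity drives PC space
  cfg <- sim_config(seed = 21, n_genes = 600, n_libraries = 2)
  sim <- simulate_library(cfg)
  score_lib <- function(lib, ids) {
    cm <- simulate_screens(lib, sim$truth, cfg, screen_ids = ids)
    score_screens(cm, lib)
  }
  sa <- score_lib(sim$libraries[[1]], c("A1", "A2"))
  sb <- score_lib(sim$libraries[[2]], c("B1", "B2"))
  all4 <- cbind(sa, sb)
  colnames(all4) <- c("A1", "A2", "B1", "B2")
  pr <- pca_distances(all4, n_pc = 2)
  d <- pr$distances
  within <- c(d["A1", "A2"], d["B1", "B2"])
  between <- c(d["A1", "B1"], d["A1", "B2"], d["A2", "B1"], d["A2", "B2"])
  expect_lt(mean(within), mean(between))
})

test_that("correlation_groups assembles the right pairs and statistics", {
  set.seed(13)
  n <- 1000
  genes <- paste0("g", sprintf("%04d", 1:n))
  m <- matrix(rnorm(6 * n), nrow = n,
              dimnames = list(genes,
                              c("c1_L1", "c1_L2", "c2_L1", "c2_L2",
                                "c3_L1", "c3_L2")))
  m[, "c1_L2"] <- m[, "c1_L1"]          # an exact copy pair
  meta <- data.frame(screen = colnames(m),
                     cell_line = rep(c("c1", "c2", "c3"), each = 2),
                     library = rep(c("L1", "L2"), 3),
                     stringsAsFactors = FALSE)
  cg <- correlation_groups(m, meta)
  copy_row <- cg$pairs[cg$pairs$screen_a == "c1_L1" &
                         cg$pairs$screen_b == "c1_L2", ]
  expect_equal(copy_row$group, "same_cell_diff_lib")
  expect_equal(copy_row$rho, 1)
  # independent score vectors: near-zero rank correlation,
  # matching an independent implementation
  ind_row <- cg$pairs[cg$pairs$screen_a == "c2_L1" &
                        cg$pairs$screen_b == "c3_L1", ]
  expect_lt(abs(ind_row$rho), 0.1)
  expect_equal(ind_row$rho, oracle_spearman(m[, "c2_L1"], m[, "c3_L1"]),
               tolerance = 1e-10)
  # groups: 3 same-cell pairs; same-library pairs = 2 libraries x C(3,2)
  expect_equal(sum(cg$pairs$group == "same_cell_diff_lib"), 3)
  expect_equal(sum(cg$pairs$group == "diff_cell_same_lib"), 6)
  expect_false(is.null(cg$wilcoxon))
})

test_that("rank-sum comparison holds its level under the null", {
  set.seed(31)
  p_over <- replicate(20, {
    a <- rnorm(12)
    b <- rnorm(15)
    wilcoxon_compare(a, b)$p > 0.05
  })
  expect_gte(sum(p_over), 16)
})

test_that("wilcoxon_compare flags degeneracy and detects shifts", {
  v <- rnorm(10)
  deg <- wilcoxon_compare(v, v, paired = TRUE)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  set.seed(17)
  a <- rnorm(20)
  shifted <- wilcoxon_compare(a, a + 50)
  expect_lt(shifted$p, 0.01)
  # cross-check the rank-sum statistic: fully separated samples
  expect_equal(shifted$statistic, 0)
  # rank-sum is invariant under a common monotone transform
  b <- rnorm(20, mean = 1)
  raw <- wilcoxon_compare(a, b)
  tr <- wilcoxon_compare(exp(a), exp(b))
  expect_equal(raw$statistic, tr$statistic)
  expect_equal(raw$p, tr$p)
  expect_error(wilcoxon_compare(1:3, 1:4, paired = TRUE), "equal lengths")
})

test_that("correction_report tracks recall and group rhos before/after", {
  w <- sim_world(6, n_genes = 400, n_screens = 4)
  scores <- w$scores
  colnames(scores) <- c("c1_L1", "c1_L2", "c2_L1", "c2_L2")
  meta <- data.frame(screen = colnames(scores),
                     cell_line = rep(c("c1", "c2"), each = 2),
                     library = rep(c("L1", "L2"), 2))
  reference <- w$sim$truth$gene[w$sim$truth$is_essential][1:30]
  z <- zscore_by_bin(scores, w$partition)
  rep_ <- suppressWarnings(
    correction_report(scores, z, meta, reference = reference))
  expect_equal(nrow(rep_$recall), 4)
  expect_true(all(rep_$recall$recall_before >= 0 &
                    rep_$recall$recall_before <= 1))
  expect_equal(nrow(rep_$groups_before$pairs),
               nrow(rep_$groups_after$pairs))
})
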