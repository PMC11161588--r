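test_that("connectivity recovers hand-computed and degenerate correlations", {
  r <- attnconn:::node_area_cor(matrix(c(1, 2, 3, 4), 1),
                                matrix(c(2, 1, 4, 3), 1))
  expect_equal(as.numeric(r), 0.6, tolerance = 1e-12)
  # identical and anti-correlated series
  x <- matrix(rnorm(40), 1)
  expect_equal(as.numeric(attnconn:::node_area_cor(x, x)), 1,
               tolerance = 1e-12)
  expect_equal(as.numeric(attnconn:::node_area_cor(x, -x)), -1,
               tolerance = 1e-12)
  # zero-variance series give NA
  expect_true(is.na(attnconn:::node_area_cor(matrix(1, 1, 40), x)))
  # scale invariance
  y <- matrix(rnorm(40), 1)
  expect_equal(attnconn:::node_area_cor(3.7 * x, y),
               attnconn:::node_area_cor(x, y), tolerance = 1e-12)
})

test_that("per-run z averaging and concatenation both produce full maps", {
  ds <- quick_subject(seed = 51, n_vertices = 100)
  rs <- residualize_dataset(ds, runs = which(ds$run_type == "main"))
  m1 <- connectivity_map(rs, "per_run_z_mean")
  m2 <- connectivity_map(rs, "concatenated")
  expect_equal(dim(unclass(m1)), c(100, 3, 2))
  expect_false(anyNA(m1))
  expect_gt(cor(as.numeric(unclass(m1)), as.numeric(unclass(m2))), 0.9)
})

test_that("binned profiles are complete and permutation-invariant", {
  ds <- quick_subject(seed = 52, n_vertices = 120)
  loc <- localizer_contrast(
    residualize_dataset(ds, FALSE, runs = which(ds$run_type == "localizer")))
  rois <- assign_rois(ds$geometry, loc$p)
  rs <- residualize_dataset(ds, runs = which(ds$run_type == "main"))
  map <- connectivity_map(rs)
  prof <- profile_by_bin(map, rois)
  expect_equal(nrow(prof), 4 * 3 * 2)
  expect_false(anyNA(prof$z))
  expect_equal(prof$r, tanh(prof$z))

  # permuting node order leaves the profile unchanged
  perm <- sample(nrow(ds$geometry))
  map_p <- unclass(map)[perm, , , drop = FALSE]
  attr(map_p, "subject_id") <- attr(map, "subject_id")
  class(map_p) <- "connectivity_map"
  rois_p <- rois[perm, ]
  prof_p <- profile_by_bin(map_p, rois_p)
  expect_equal(prof_p$z, prof$z, tolerance = 1e-12)
})

test_that("repeated-measures ANOVA matches the brute-force SS oracle", {
  set.seed(7)
  for (rep in 1:5) {
    d <- expand.grid(subject = 1:3, bin = letters[1:4],
                     condition = c("c1", "c2"))
    d$z <- rnorm(nrow(d))
    out <- rm_anova_2way(d)
    oracle <- rm_anova_bruteforce(
      data.frame(subject = d$subject, A = d$bin, B = d$condition,
                 value = d$z))
    expect_equal(out$statistic,
                 c(oracle$F_A, oracle$F_B, oracle$F_AB), tolerance = 1e-8)
    expect_equal(out$df1, c(3, 1, 3))
    expect_equal(out$df2, c(6, 2, 6))
  }
  # 8 subjects x 4 bins x 2 conditions gives the (3, 21) interaction df
  d8 <- expand.grid(subject = 1:8, bin = letters[1:4],
                    condition = c("c1", "c2"))
  d8$z <- rnorm(nrow(d8))
  out8 <- rm_anova_2way(d8)
  expect_equal(out8$df1[3], 3)
  expect_equal(out8$df2[3], 21)
  # no condition effect when values identical across conditions
  d8$z <- rep(rnorm(32), 2)
  outc <- rm_anova_2way(d8)
  expect_equal(outc$statistic[2], 0, tolerance = 1e-10)
  expect_error(rm_anova_2way(d8[-1, ]), "balanced")
})

test_that("paired and one-sample t tests match hand formulas", {
  out <- paired_t(c(2, 3, 4), c(1, 1, 1))
  expect_equal(out$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(out$df, 2)
  x <- rnorm(8)
  expect_equal(paired_t(x, x)$statistic, 0)
  expect_equal(paired_t(x, x)$p, 1)
  expect_equal(paired_t(rnorm(8), rnorm(8))$df, 7)
  expect_error(paired_t(c(1, 2), c(0, 1)), "zero-variance")
  expect_equal(one_sample_t(c(2, 3, 4), mu = 3)$statistic, 0,
               tolerance = 1e-12)
})

test_that("Benjamini-Hochberg adjustment matches the step-up rule", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  # hand rule: p * m / rank with cumulative minimum from the largest rank
  p <- c(0.001, 0.2, 0.011, 0.04)
  m <- length(p)
  o <- order(p)
  q_hand <- rev(cummin(rev(p[o] * m / seq_len(m))))[order(o)]
  expect_equal(fdr_adjust(p), q_hand)
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})
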