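test_that("geometry stratification populates every analysis bin and is seeded", {
  g <- make_geometry(500, ecc_max = 12, seed = 1)
  counts <- attnconn:::geometry_bin_counts(g)
  expect_true(all(counts >= 10))
  expect_identical(g, make_geometry(500, ecc_max = 12, seed = 1))
  expect_false(identical(g, make_geometry(500, ecc_max = 12, seed = 2)))
  expect_true(all(g$eccentricity >= 0 & g$eccentricity <= 12))
  expect_true(all(g$polar_angle > -180 & g$polar_angle <= 180))
  expect_identical(g$node_id, seq_len(500) - 1L)
  # every 2-degree stratum populated
  strata <- table(cut(g$eccentricity, seq(0, 12, 2)))
  expect_true(all(strata > 0))
  expect_error(make_geometry(20, 12, 1), "n_vertices")
})

test_that("stimulated-truth flag is disc membership around 2.5 deg on the meridian", {
  g <- data.frame(node_id = 0:2,
                  eccentricity = c(2.5, 2.5, 7),
                  polar_angle = c(0, 90, 0),
                  is_stimulated_truth = NA)
  x <- g$eccentricity * cospi(g$polar_angle / 180)
  y <- g$eccentricity * sinpi(g$polar_angle / 180)
  inside <- sqrt((x - 2.5)^2 + y^2) <= 1.5
  expect_equal(inside, c(TRUE, FALSE, FALSE))
  gg <- make_geometry(200, 12, 3)
  xx <- gg$eccentricity * cospi(gg$polar_angle / 180)
  yy <- gg$eccentricity * sinpi(gg$polar_angle / 180)
  expect_equal(gg$is_stimulated_truth,
               sqrt((xx - 2.5)^2 + yy^2) <= 1.5)
})

test_that("simulated subjects are seed-deterministic and snr-accounted", {
  g <- make_geometry(150, 12, 5)
  d <- quick_design(n_cycles = 10, n_runs = 2)
  prof <- coupling_profile("weak_crowding")
  ds1 <- simulate_subject(g, d, prof, snr = 2, seed = 9)
  ds2 <- simulate_subject(g, d, prof, snr = 2, seed = 9)
  expect_identical(ds1$bold, ds2$bold)
  expect_identical(ds1$nuisance, ds2$nuisance)

  # variance accounting: pooled var(signal)/var(noise) within 20% of snr^2
  set.seed(1)
  ds_clean <- simulate_subject(g, d, prof, snr = 1e12, seed = 9)
  sig <- ds_clean$bold[[1]]
  noise <- ds1$bold[[1]] - sig
  ratio <- stats::var(as.numeric(sig)) / stats::var(as.numeric(noise))
  expect_gt(ratio, 0.8 * 4)
  expect_lt(ratio, 1.2 * 4)
  expect_error(simulate_subject(g, d, prof, snr = -1, seed = 1), "snr")
})

test_that("equal gains across conditions make a null generator", {
  prof <- coupling_profile("null")
  expect_equal(prof[, "focal"], prof[, "diffused"])
  profs <- coupling_profile("strong_crowding")
  expect_equal(profs[, "focal"], profs[, "diffused"])
  profw <- coupling_profile("weak_crowding")
  expect_equal(unname(profw[, "focal"] - profw[, "diffused"]),
               c(0.25, -0.2, -0.2, -0.05))
})

test_that("noise-free single-gain residual correlation approaches 1", {
  g <- make_geometry(120, 12, 4)
  d <- quick_design(n_cycles = 10, n_runs = 1)
  prof <- coupling_profile("null")
  prof[] <- 0
  prof["6-8", ] <- 1
  ds <- simulate_subject(g, d, prof, snr = 1e10, seed = 3,
                         nuisance_sd = 0, evoked_amp = 0)
  rs <- residualize_dataset(ds, runs = which(ds$run_type == "main"))
  node <- which(attnconn:::truth_bin(ds$geometry) == "6-8")[1]
  r <- stats::cor(rs$residuals[[1]][node, ], rs$downstream[[1]]["V2", ])
  expect_gt(r, 0.999)
})

test_that("cohorts are reproducible and scenarios control the gains", {
  c1 <- make_cohort(2, "null", seed = 11, n_vertices = 80)
  c2 <- make_cohort(2, "null", seed = 11, n_vertices = 80)
  expect_identical(c1[[1]]$bold, c2[[1]]$bold)
  expect_identical(c1[[2]]$ground_truth$coupling_gain,
                   coupling_profile("null"))
  expect_error(make_cohort(4, "something_else", seed = 1), "arg")
  expect_error(make_cohort(1, "null", seed = 1))
})
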