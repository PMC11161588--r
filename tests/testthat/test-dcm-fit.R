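# small session used by the inversion unit tests (the acceptance test runs
# the full-size cohort)
fit_design <- function() quick_design(n_cycles = 3, n_runs = 1)

test_that("variational Laplace recovers generating parameters at high snr", {
  d <- fit_design()
  m <- specify_model("recurrent", nodes = three_node, design = d)
  theta <- dcm_true_params(m)
  sim <- simulate_dcm_timeseries(m, theta, snr = 5, seed = 8)
  fit <- dcm_fit(m, sim$y, max_iter = 40)
  expect_s3_class(fit, "dcm_fit")
  expect_true(all(is.finite(fit$theta)))
  # free energy is non-decreasing over accepted steps
  expect_true(all(diff(fit$trace) >= 0))
  # posterior covariance is symmetric positive semidefinite
  ev <- eigen(fit$Sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  # coupling recovery: correlation between true and estimated A and B
  ab <- m$par_index$type %in% c("A", "B")
  expect_gt(cor(theta[ab], fit$theta[ab]), 0.8)
  # fit explains most of the variance at snr 5 (ceiling ~ 96%)
  Yd <- attnconn:::demean_runs(sim$y, m$run_lengths)
  r2 <- 1 - colSums((Yd - fitted(fit))^2) / colSums(Yd^2)
  expect_true(all(r2 > 0.85))
})

test_that("pure-noise data leave the posterior close to the prior", {
  d <- fit_design()
  m <- specify_model("feedforward", nodes = three_node, design = d)
  set.seed(10)
  Y <- matrix(rnorm(sum(m$run_lengths) * m$n, sd = 0.5),
              sum(m$run_lengths), m$n)
  fit <- suppressWarnings(dcm_fit(m, Y, max_iter = 24))
  # posterior means stay at the prior (no information to move them); the
  # posterior *variance* legitimately tightens for parameters the data
  # constrain toward zero, so the check is on the mean shift in units of
  # the prior standard deviation
  shift <- abs(fit$theta - m$pE) / sqrt(m$pV)
  expect_lt(max(shift), 3)
  expect_lt(stats::median(shift), 0.5)
})

test_that("unused modulatory parameters do not inflate model evidence", {
  d <- fit_design()
  m_ff <- specify_model("feedforward", nodes = three_node, design = d)
  theta_ff <- dcm_true_params(m_ff)
  sim <- simulate_dcm_timeseries(m_ff, theta_ff, snr = 10, seed = 12)
  f_small <- dcm_fit(m_ff, sim$y, max_iter = 40)$F
  m_rc <- specify_model("recurrent", nodes = three_node, design = d)
  f_big <- dcm_fit(m_rc, sim$y, max_iter = 40)$F
  # the larger model carries truly-zero feedback parameters; the Occam
  # penalty must keep its evidence from exceeding the generating model's
  expect_lt(f_big, f_small + 0.5)
})

test_that("group modulation statistics summarize pathway contrasts", {
  d <- fit_design()
  m <- specify_model("recurrent", nodes = three_node, design = d)
  # synthetic posteriors: clone one fit and overwrite the B estimates
  base <- list(model = m, Sigma = diag(length(m$pE)))
  set.seed(13)
  fits <- lapply(1:8, function(i) {
    th <- m$pE
    idx <- m$par_index
    for (k in which(idx$type == "B")) {
      from_s <- idx$j[k] == 1 || (idx$i[k] == 1 && idx$j[k] > 2)
      th[k] <- (if (from_s) 0.3 else -0.2) + rnorm(1, sd = 0.05)
    }
    f <- base
    f$theta <- th
    names(f$theta) <- names(m$pE)
    class(f) <- "dcm_fit"
    f
  })
  out <- modulation_group_stats(fits)
  expect_true(all(out$tests$df == 7))
  sv <- out$tests[out$tests$family == "EX feedforward S-vs-NS", ]
  expect_gt(sv$statistic, 0)
  expect_lt(sv$p, 0.05)
  expect_true(all(out$tests$q >= out$tests$p - 1e-12))
  # identical pathways give a zero paired t
  fits0 <- lapply(fits, function(f) {
    f$theta[m$par_index$type == "B"] <- 0.1 + rnorm(1, sd = 0.02)
    f
  })
  out0 <- modulation_group_stats(fits0)
  expect_equal(out0$tests$statistic[grep("S-vs-NS", out0$tests$family)],
               c(0, 0, 0))
  expect_error(modulation_group_stats(fits[1]), "length")
})
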