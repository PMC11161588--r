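test_that("candidate structures share A/C masks and differ only in B", {
  d <- quick_design()
  ff <- specify_model("feedforward", design = d)
  fb <- specify_model("feedback", design = d)
  rc <- specify_model("recurrent", design = d)
  expect_identical(ff$A_mask, fb$A_mask)
  expect_identical(ff$A_mask, rc$A_mask)
  expect_identical(ff$C_mask, rc$C_mask)
  expect_identical(rc$B_mask, ff$B_mask | fb$B_mask)
  # feedforward model has no feedback modulation open
  expect_false(ff$B_mask["V1_S", "V4"])
  expect_true(ff$B_mask["V4", "V1_S"])
  expect_true(fb$B_mask["V1_S", "V4"])
  # all structures include the lateral within-V1 modulation
  for (m in list(ff, fb, rc)) {
    expect_true(m$B_mask["V1_S", "V1_NS"])
    expect_true(m$B_mask["V1_NS", "V1_S"])
  }
  # no extrastriate-extrastriate intrinsic links
  expect_false(any(ff$A_mask[3:5, 3:5] & !diag(TRUE, 3)))
  # driving input reaches V1_S only
  expect_equal(unname(which(ff$C_mask[, 1])), 1)
  expect_error(specify_model("sideways"), "arg")
})

test_that("attention input is on only during focal stimulus blocks", {
  d <- quick_design(n_cycles = 2, n_runs = 1)
  m <- specify_model("recurrent", nodes = three_node, design = d)
  T <- d$run_vols
  box <- stimulus_boxcar(d)
  expect_equal(m$U["u1", ], rep(box, 2))
  expect_equal(m$U["u2", 1:T], box)             # focal run
  expect_equal(m$U["u2", (T + 1):(2 * T)], rep(0, T))  # diffused run
})

test_that("forward model is deterministic, quiescent without drive, and stable", {
  d <- quick_design(n_cycles = 2, n_runs = 1)
  m <- specify_model("recurrent", nodes = three_node, design = d)
  theta0 <- m$pE
  theta0[m$par_index$type == "C"] <- 0
  tr0 <- dcm_forward(m, theta0)
  expect_equal(max(abs(tr0$y)), 0, tolerance = 1e-12)
  expect_true(all(tr0$f > 0 & tr0$v > 0 & tr0$q > 0))

  theta <- dcm_true_params(m)
  tr1 <- dcm_forward(m, theta)
  tr2 <- dcm_forward(m, theta)
  expect_identical(tr1$y, tr2$y)

  # impulse response returns to baseline within 60 s
  d_imp <- design_spec(tr = 1, block_s = 1, fix_s = 95, n_cycles = 1,
                       n_runs_per_condition = 1)
  m_imp <- specify_model("recurrent", nodes = three_node, design = d_imp,
                         conditions = "diffused")
  tr_imp <- dcm_forward(m_imp, dcm_true_params(m_imp))
  expect_gt(max(abs(tr_imp$z)), 1e-3)
  expect_lt(max(abs(tr_imp$z[61:96, ])), 1e-4)

  # unstable A is refused before integration
  theta_bad <- dcm_true_params(m, a_ff = 1.2, a_fb = 1.2, a_lat = 1.2)
  expect_error(dcm_forward(m, theta_bad), "unstable")
})

test_that("linear-regime trajectories match the matrix-exponential oracle", {
  skip_if_not_installed("pracma")
  d <- quick_design(n_cycles = 4, n_runs = 1)
  m <- specify_model("recurrent", nodes = three_node, design = d)
  theta <- dcm_true_params(m, b_s = 0, b_ns = 0)
  tr <- dcm_forward(m, theta)
  mats <- attnconn:::dcm_matrices(m, theta)
  A <- mats$A
  C <- mats$C
  dt <- m$tr / m$nsub
  E <- pracma::expm(A * dt)
  G <- solve(A, (E - diag(m$n))) %*% C
  z <- matrix(0, m$n, sum(m$run_lengths))
  t0 <- 0
  for (L in m$run_lengths) {
    zc <- rep(0, m$n)
    for (t in (t0 + 1):(t0 + L)) {
      u <- m$U[, t]
      for (s in seq_len(m$nsub)) zc <- as.numeric(E %*% zc + G %*% u)
      z[, t] <- zc
    }
    t0 <- t0 + L
  }
  expect_lt(max(abs(t(tr$z) - z)), 1e-5)
})

test_that("simulated DCM data respect snr and the noise-free limit", {
  d <- quick_design(n_cycles = 2, n_runs = 1)
  m <- specify_model("recurrent", nodes = three_node, design = d)
  theta <- dcm_true_params(m)
  simc <- simulate_dcm_timeseries(m, theta, snr = 1e9, seed = 2)
  expect_equal(simc$y, simc$y_clean, tolerance = 1e-6)
  sim1 <- simulate_dcm_timeseries(m, theta, snr = 2, seed = 2)
  sim2 <- simulate_dcm_timeseries(m, theta, snr = 2, seed = 2)
  expect_identical(sim1$y, sim2$y)
  noise <- sim1$y - sim1$y_clean
  ratio <- stats::var(as.numeric(sim1$y_clean)) /
    stats::var(as.numeric(noise))
  expect_gt(ratio, 0.7 * 4)
  expect_lt(ratio, 1.3 * 4)
  expect_error(simulate_dcm_timeseries(m, theta, snr = 0), "snr")
})
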