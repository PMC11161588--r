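test_that("high-pass removes DC and slow drifts but passes fast components", {
  T <- 240
  t_s <- seq_len(T) - 1
  expect_equal(max(abs(highpass(rep(3, T), 100, 1))), 0, tolerance = 1e-10)

  # a 20 s-period cosine on the DCT grid (k = 24) is orthogonal to every
  # removed regressor and passes through exactly
  fast <- cos(pi * 24 * (t_s + 0.5) / T)
  out <- highpass(fast, 100, 1)
  expect_lt(max(abs(out - (fast - mean(fast)))), 1e-8)
  # an off-grid 20 s sinusoid passes up to small spectral leakage
  fast2 <- sin(2 * pi * t_s / 20)
  out2 <- highpass(fast2, 100, 1)
  expect_gt(sum(out2 * fast2) / sum(fast2^2), 0.95)

  # a 240 s-period basis cosine is annihilated; a generic 200 s sinusoid
  # keeps under 5% of its power (DCT projection, not a brick-wall filter)
  slow <- cos(pi * 2 * (t_s + 0.5) / T)
  expect_lt(sum(highpass(slow, 100, 1)^2) / sum(slow^2), 1e-16)
  slow2 <- sin(2 * pi * t_s / 200)
  expect_lt(sum(highpass(slow2, 100, 1)^2) / sum(slow2^2), 0.05)

  expect_error(highpass(fast, 1.5, 1), "cutoff")
})

test_that("regress_out matches closed-form OLS and enforces orthogonality", {
  # a line is perfectly fit by intercept + t
  res <- regress_out(matrix(c(1, 2, 3, 4, 5), 1), matrix(1:5, 5, 1))
  expect_lt(max(abs(res$residuals)), 1e-10)

  # series orthogonal to (centered) X: output = series - mean
  set.seed(2)
  X <- matrix(rnorm(50), 50, 1)
  X <- X - mean(X)
  ts <- matrix(rnorm(50), 1)
  ts <- ts - c(ts %*% X) / sum(X^2) * t(X)  # orthogonalize to X
  out <- regress_out(ts, X)$residuals
  expect_equal(as.numeric(out), as.numeric(ts - mean(ts)),
               tolerance = 1e-10)

  # perfect fit when ts is a multiple of a regressor
  out2 <- regress_out(matrix(2 * X[, 1], 1), X)$residuals
  expect_lt(max(abs(out2)), 1e-10)

  # residuals orthogonal to every regressor
  Xb <- cbind(rnorm(50), rnorm(50))
  tsb <- matrix(rnorm(3 * 50), 3)
  rb <- regress_out(tsb, Xb)$residuals
  expect_lt(max(abs(rb %*% Xb)) / max(abs(tsb)), 1e-8)

  expect_error(regress_out(matrix(rnorm(4), 1), matrix(rnorm(4 * 5), 4)),
               "regressors")
  expect_warning(regress_out(tsb, cbind(Xb, Xb[, 1])), "rank")
})

test_that("FIR design has one indicator per cycle phase", {
  d <- design_spec()
  X <- build_fir_design(d)
  expect_equal(dim(X), c(240, 24))
  expect_true(all(X %in% c(0, 1)))
  expect_true(all(rowSums(X) == 1))
  expect_equal(unname(colSums(X)), rep(10, 24))
  expect_equal(max(abs(crossprod(X) - diag(10, 24))), 0)
  expect_error(build_fir_design(d, n_vols = 250), "integer number")
})

test_that("FIR removal annihilates cycle-locked signal and accounts for df", {
  d <- design_spec()
  shape <- evoked_regressor(d)
  ts <- rbind(2 * shape, -0.5 * shape + 7)
  out <- remove_evoked(ts, d)
  expect_lt(max(abs(out$residuals)), 1e-10)
  expect_equal(out$fitted_evoked, ts, tolerance = 1e-10)

  # white noise: residual variance matches (1 - 24/T) * input variance
  set.seed(5)
  big <- design_spec(n_cycles = 50)
  noise <- matrix(rnorm(100 * big$run_vols), 100)
  outn <- remove_evoked(noise, big)
  ratio <- stats::var(as.numeric(outn$residuals)) /
    stats::var(as.numeric(noise))
  expect_equal(ratio, 1 - 24 / big$run_vols, tolerance = 0.02)

  # idempotence
  twice <- remove_evoked(out$residuals, d)$residuals
  expect_equal(twice, out$residuals, tolerance = 1e-12)
})

test_that("dataset residualization is orthogonal, variance-reducing and flagged", {
  ds <- quick_subject(seed = 21, n_vertices = 100)
  rs <- residualize_dataset(ds, remove_evoked_flag = TRUE, cutoff_s = 100)
  expect_true(rs$provenance$nuisance_removed)
  expect_true(rs$provenance$evoked_removed)

  # FIR removal is the last stage: exact orthogonality to its basis
  fir <- build_fir_design(ds$design)
  res1 <- rs$residuals[[1]]
  cos_fir <- abs(res1 %*% fir) /
    outer(sqrt(rowSums(res1^2)), sqrt(colSums(fir^2)))
  expect_lt(max(cos_fir), 1e-10)
  # earlier-stage regressors: the sequential fit (nuisance GLM, then FIR)
  # lets the evoked subtraction reintroduce modest components along the
  # nuisance directions, so only near-orthogonality can be demanded
  X <- ds$nuisance[[1]]
  cos_x <- abs(res1 %*% X) /
    outer(sqrt(rowSums(res1^2)), sqrt(colSums(X^2)))
  expect_lt(max(cos_x), 0.25)
  expect_lt(stats::median(cos_x), 0.05)

  # each removal step never increases per-node variance
  v_raw <- apply(ds$bold[[1]], 1, var)
  hp <- highpass(ds$bold[[1]], 100, 1)
  v_hp <- apply(hp, 1, var)
  nu <- regress_out(hp, X)$residuals
  v_nu <- apply(nu, 1, var)
  v_fir <- apply(remove_evoked(nu, ds$design)$residuals, 1, var)
  expect_true(all(v_hp <= v_raw + 1e-12))
  expect_true(all(v_nu <= v_hp + 1e-12))
  expect_true(all(v_fir <= v_nu + 1e-12))

  # evoked-free data: profiles with and without FIR removal agree closely
  g <- make_geometry(100, 12, 31)
  dsa <- simulate_subject(g, quick_design(), coupling_profile("null"),
                          snr = 1, seed = 32, evoked_amp = 0)
  main <- which(dsa$run_type == "main")
  z1 <- connectivity_map(residualize_dataset(dsa, TRUE, runs = main))
  z2 <- connectivity_map(residualize_dataset(dsa, FALSE, runs = main))
  expect_gt(cor(as.numeric(unclass(z1)), as.numeric(unclass(z2))), 0.9)
})
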