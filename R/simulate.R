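#' Built-in coupling profiles for the simulation scenarios
#'
#' A coupling profile gives, per eccentricity bin and attention condition,
#' the gain with which the shared background fluctuation enters V1 vertices.
#' `weak_crowding` encodes the center-enhancement / surround-suppression
#' gradient under focal attention against a flat diffused-state profile;
#' `strong_crowding` uses one graded profile (elevated at the stimulated
#' bin) for both conditions, so eccentricity structure survives but the
#' attention contrast is zero by construction; `null` is flat everywhere.
#'
#' @param scenario One of `"weak_crowding"`, `"strong_crowding"`, `"null"`.
#' @return A 4 x 2 numeric matrix, rows `stim, 4-6, 6-8, 8-10`, columns
#'   `focal, diffused`.
#' @export
coupling_profile <- function(scenario = c("weak_crowding", "strong_crowding",
                                          "null")) {
  scenario <- match.arg(scenario)
  bins <- c("stim", "4-6", "6-8", "8-10")
  prof <- switch(scenario,
    weak_crowding = cbind(focal = c(0.6, 0.15, 0.15, 0.3),
                          diffused = c(0.35, 0.35, 0.35, 0.35)),
    strong_crowding = {
      shared <- c(0.6, 0.35, 0.35, 0.35)
      cbind(focal = shared, diffused = shared)
    },
    null = cbind(focal = rep(0.35, 4), diffused = rep(0.35, 4)))
  rownames(prof) <- bins
  prof
}

row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums(m * m) - n * mu * mu, 0) / (n - 1))
}

# one latent background fluctuation per run: white noise low-passed below
# `cutoff_hz` by zeroing Fourier coefficients, standardized to unit sd
latent_fluctuation <- function(n, tr, cutoff_hz = 0.1) {
  w <- stats::rnorm(n)
  f <- stats::fft(w)
  freq <- seq_len(n) - 1
  freq <- pmin(freq, n - freq) / (n * tr)  # two-sided frequency axis
  f[freq > cutoff_hz] <- 0
  g <- Re(stats::fft(f, inverse = TRUE)) / n
  s <- stats::sd(g)
  if (s < 1e-12) g else (g - mean(g)) / s
}

# 8 nuisance series for one run: six motion-like smoothed random walks plus
# two slow sinusoids (white-matter, ventricle surrogates), each unit sd
make_nuisance <- function(n, tr) {
  ma9 <- function(x) {          # centered moving average, window 9
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - 5, 0)
    hi <- pmin(seq_len(n) + 4, n)
    (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
  }
  motion <- sapply(seq_len(6), function(k) ma9(cumsum(stats::rnorm(n))))
  t_s <- (seq_len(n) - 1) * tr
  slow <- cbind(sin(2 * pi * t_s / (97 + stats::runif(1, 0, 30))
                    + stats::runif(1, 0, 2 * pi)),
                sin(2 * pi * t_s / (61 + stats::runif(1, 0, 30))
                    + stats::runif(1, 0, 2 * pi)))
  X <- cbind(motion, slow)
  X <- sweep(X, 2, colMeans(X))
  X <- sweep(X, 2, apply(X, 2, stats::sd), `/`)
  colnames(X) <- c(paste0("motion", 1:6), "wm", "ventricle")
  X
}

#' Simulate one synthetic subject
#'
#' Generates per-run node x time BOLD for a model V1 patch plus downstream
#' area (V2, V3, V4) mean series, under the generative model
#' `bold = evoked + gain(bin, condition) * g(t) + nuisance + noise`, where
#' `g(t)` is one shared low-frequency latent fluctuation per run (the
#' background source, injected into each downstream area with unit gain),
#' the evoked component is the stimulus boxcar convolved with a double-gamma
#' HRF and confined to ground-truth stimulated vertices (and the downstream
#' areas, which are stimulus responsive), nuisance weights are drawn once
#' per node, and the iid Gaussian noise standard deviation is set per node
#' to `sd(signal)/snr`. Two extra localizer runs (reserved for ROI
#' definition) are generated alongside the main runs.
#'
#' @param geometry A [make_geometry()] table.
#' @param design A [design_spec()].
#' @param profile 4 x 2 gain matrix as returned by [coupling_profile()]
#'   (rows `stim, 4-6, 6-8, 8-10`; columns `focal, diffused`).
#' @param snr Amplitude signal-to-noise ratio (> 0); the per-node
#'   signal-to-noise variance ratio equals `snr^2`.
#' @param seed Integer seed.
#' @param evoked_amp Evoked-response amplitude at stimulated vertices.
#' @param nuisance_sd Standard deviation of the per-node nuisance weights
#'   (0 disables nuisance contamination).
#' @param n_localizer_runs Localizer runs reserved for ROI definition.
#' @param cutoff_hz Low-pass cutoff of the latent background source (Hz).
#' @param subject_id Identifier stored with the dataset.
#'
#' @return An object of class `bg_dataset`: list with `bold` (list of
#'   node x time matrices), `downstream` (list of 3 x time matrices, rows
#'   V2, V3, V4), `nuisance` (list of time x 8 matrices), `condition`
#'   (per-run factor), `run_type` (`"main"` or `"localizer"`), `geometry`,
#'   `design`, `subject_id` and `ground_truth` (gains, evoked amplitudes,
#'   nuisance weights; never consumed by analysis code).
#' @export
simulate_subject <- function(geometry, design, profile, snr = 1, seed = 1,
                             evoked_amp = 1, nuisance_sd = 0.5,
                             n_localizer_runs = 2,
                             cutoff_hz = 0.1, subject_id = "sub-01") {
  stopifnot(inherits(design, "design_spec"))
  if (!is.matrix(profile) ||
      !setequal(rownames(profile), c("stim", "4-6", "6-8", "8-10")) ||
      !setequal(colnames(profile), c("focal", "diffused"))) {
    stop("profile must be a matrix with rows stim, 4-6, 6-8, 8-10 and columns focal, diffused")
  }
  if (!is.numeric(snr) || snr <= 0) stop("snr must be positive")
  set.seed(as.integer(seed))

  n_nodes <- nrow(geometry)
  T <- design$run_vols
  areas <- c("V2", "V3", "V4")
  bin <- truth_bin(geometry)

  # per-node gain lookup under each condition (nodes outside all bins get 0)
  gain_for <- function(cond) {
    g <- rep(0, n_nodes)
    ok <- !is.na(bin)
    g[ok] <- profile[bin[ok], cond]
    g
  }

  evoked_shape <- evoked_regressor(design)
  amp <- ifelse(geometry$is_stimulated_truth, evoked_amp, 0)
  evoked_mat <- outer(amp, evoked_shape)          # node x time
  evoked_area <- evoked_amp * evoked_shape

  # nuisance weights: drawn once per node (and per downstream area)
  w_node <- matrix(stats::rnorm(n_nodes * 8), n_nodes, 8) * nuisance_sd
  w_area <- matrix(stats::rnorm(3 * 8), 3, 8) * nuisance_sd

  conds <- rep(c("focal", "diffused"), each = design$n_runs_per_condition)
  run_type <- c(rep("main", length(conds)), rep("localizer", n_localizer_runs))
  conds <- c(conds, rep("diffused", n_localizer_runs))

  bold <- downstream <- nuisance <- vector("list", length(conds))
  for (r in seq_along(conds)) {
    g_t <- latent_fluctuation(T, design$tr, cutoff_hz)
    X <- make_nuisance(T, design$tr)
    gains <- gain_for(conds[r])
    signal <- evoked_mat + outer(gains, g_t) + w_node %*% t(X)
    sig_sd <- row_sds(signal)
    fallback <- stats::median(sig_sd[sig_sd > 1e-12])
    if (!is.finite(fallback)) fallback <- 1
    sig_sd[sig_sd <= 1e-12] <- fallback
    noise <- matrix(stats::rnorm(n_nodes * T), n_nodes, T) * (sig_sd / snr)
    bold[[r]] <- signal + noise
    rownames(bold[[r]]) <- NULL

    a_signal <- matrix(rep(evoked_area + g_t, each = 3), 3, T) +
      w_area %*% t(X)
    a_sd <- row_sds(a_signal)
    a_sd[a_sd <= 1e-12] <- fallback
    downstream[[r]] <- a_signal +
      matrix(stats::rnorm(3 * T), 3, T) * (a_sd / snr)
    rownames(downstream[[r]]) <- areas
    nuisance[[r]] <- X
  }

  structure(list(
    bold = bold, downstream = downstream, nuisance = nuisance,
    condition = conds, run_type = run_type,
    geometry = geometry, design = design, subject_id = subject_id,
    ground_truth = list(coupling_gain = profile,
                        evoked_amplitude = amp,
                        nuisance_weights = w_node,
                        snr = snr, cutoff_hz = cutoff_hz)),
    class = "bg_dataset")
}

#' @export
print.bg_dataset <- function(x, ...) {
  cat(sprintf("Synthetic retinotopic BOLD dataset '%s': %d vertices, %d runs (%d main + %d localizer), %d volumes/run\n",
              x$subject_id, nrow(x$geometry), length(x$bold),
              sum(x$run_type == "main"), sum(x$run_type == "localizer"),
              ncol(x$bold[[1]])))
  invisible(x)
}

#' Simulate a cohort of subjects under a named scenario
#'
#' Per-subject seeds are derived deterministically from the master seed, so
#' the same call reproduces the cohort bit for bit.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param scenario Scenario name passed to [coupling_profile()].
#' @param seed Master integer seed.
#' @param n_vertices,ecc_max Geometry size passed to [make_geometry()].
#' @param design A [design_spec()].
#' @param snr Amplitude signal-to-noise ratio.
#' @param ... Further arguments passed to [simulate_subject()].
#' @return List of `bg_dataset` objects, one per subject.
#' @export
make_cohort <- function(n_subjects = 8,
                        scenario = c("weak_crowding", "strong_crowding",
                                     "null"),
                        seed = 1, n_vertices = 240, ecc_max = 12,
                        design = design_spec(), snr = 1, ...) {
  stopifnot(n_subjects >= 2)
  scenario <- match.arg(scenario)
  prof <- coupling_profile(scenario)
  lapply(seq_len(n_subjects), function(i) {
    s_i <- (as.integer(seed) %% 1000003L) * 1000L + i
    geom <- make_geometry(n_vertices, ecc_max, seed = s_i)
    simulate_subject(geom, design, prof, snr = snr, seed = s_i + 500L,
                     subject_id = sprintf("sub-%02d", i), ...)
  })
}
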