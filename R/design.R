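#' Block-design specification
#'
#' Describes the periodic block structure of a run: stimulus blocks of
#' `block_s` seconds interleaved with `fix_s` seconds of fixation, repeated
#' `n_cycles` times, sampled every `tr` seconds. The defaults reproduce the
#' acquisition this package emulates: 12 s stimulus blocks, 12 s fixation,
#' TR = 1 s, ten cycles per run and eight runs per attention condition.
#'
#' @param tr Repetition time in seconds per volume.
#' @param block_s Stimulus-block duration in seconds; must be an integer
#'   multiple of `tr`.
#' @param fix_s Fixation-block duration in seconds; must be an integer
#'   multiple of `tr`.
#' @param n_cycles Number of block+fixation cycles per run.
#' @param n_runs_per_condition Number of runs acquired under each attention
#'   condition (focal, diffused).
#'
#' @return An object of class `design_spec`: a list with the arguments plus
#'   `cycle_vols` (volumes per cycle) and `run_vols` (volumes per run).
#' @export
#' @examples
#' d <- design_spec()
#' d$run_vols  # 240 volumes
design_spec <- function(tr = 1, block_s = 12, fix_s = 12, n_cycles = 10,
                        n_runs_per_condition = 8) {
  stopifnot(tr > 0, block_s > 0, fix_s > 0, n_cycles >= 1,
            n_runs_per_condition >= 1)
  if (abs(block_s / tr - round(block_s / tr)) > 1e-9 ||
      abs(fix_s / tr - round(fix_s / tr)) > 1e-9) {
    stop("block_s and fix_s must be integer multiples of tr")
  }
  cycle_vols <- as.integer(round((block_s + fix_s) / tr))
  structure(list(tr = tr, block_s = block_s, fix_s = fix_s,
                 n_cycles = as.integer(n_cycles),
                 n_runs_per_condition = as.integer(n_runs_per_condition),
                 cycle_vols = cycle_vols,
                 run_vols = cycle_vols * as.integer(n_cycles)),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "Block design: %gs stimulus / %gs fixation x %d cycles, TR = %gs (%d volumes/run, %d runs/condition)\n",
    x$block_s, x$fix_s, x$n_cycles, x$tr, x$run_vols,
    x$n_runs_per_condition))
  invisible(x)
}

#' Stimulus boxcar for one run
#'
#' 1 during stimulus blocks, 0 during fixation, on the TR grid.
#'
#' @param design A [design_spec()].
#' @return Numeric vector of length `design$run_vols`.
#' @export
stimulus_boxcar <- function(design) {
  phase <- (seq_len(design$run_vols) - 1) %% design$cycle_vols
  as.numeric(phase < design$block_s / design$tr)
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style difference of two gamma densities (response peak near 6 s,
#' undershoot near 16 s), sampled at `tr` and normalized to peak 1.
#'
#' @param tr Sampling interval in seconds.
#' @param duration_s Length of the sampled kernel in seconds.
#' @return Numeric vector of the kernel on the TR grid.
#' @export
hrf_double_gamma <- function(tr = 1, duration_s = 32) {
  t <- seq(0, duration_s, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Convolve a stimulus time course with an HRF (causal, truncated)
#'
#' @param x Stimulus vector on the TR grid.
#' @param hrf Kernel from [hrf_double_gamma()].
#' @return Vector of `length(x)` convolved values.
#' @export
convolve_hrf <- function(x, hrf) {
  full <- stats::convolve(x, rev(hrf), type = "open")
  full[seq_along(x)]
}

#' Steady-state evoked-response regressor
#'
#' The hemodynamic response to the ongoing periodic block design: the
#' stimulus boxcar circularly convolved with the HRF over one cycle and
#' tiled across the run. Being exactly cycle-locked, it is the shape an
#' FIR basis reproduces perfectly; it serves both as the generator's
#' evoked component and as the GLM regressor for stimulus-vs-fixation
#' contrasts.
#'
#' @param design A [design_spec()].
#' @param hrf Kernel; defaults to [hrf_double_gamma()] at the design's TR.
#' @return Numeric vector of length `design$run_vols`.
#' @export
evoked_regressor <- function(design, hrf = hrf_double_gamma(design$tr)) {
  L <- design$cycle_vols
  box <- stimulus_boxcar(design)[seq_len(L)]
  shape <- sapply(seq_len(L) - 1, function(t) {
    sum(hrf * box[((t - seq_along(hrf) + 1) %% L) + 1])
  })
  rep(shape, design$n_cycles)
}
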