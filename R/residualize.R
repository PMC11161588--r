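#' High-pass filter by discrete-cosine projection
#'
#' Removes slow drifts by regressing out the DCT basis functions whose
#' period exceeds `cutoff_s`, together with the mean. This is the standard
#' fMRI high-pass used before nuisance regression.
#'
#' @param ts node x time matrix (a plain vector is treated as one node).
#' @param cutoff_s Cutoff period in seconds; must exceed `2 * tr`.
#' @param tr Sampling interval in seconds.
#' @return node x time matrix of filtered (mean-removed) series.
#' @export
highpass <- function(ts, cutoff_s = 100, tr = 1) {
  if (cutoff_s <= 2 * tr) stop("cutoff_s must exceed 2 * tr")
  if (is.null(dim(ts))) ts <- matrix(ts, nrow = 1)
  T <- ncol(ts)
  key <- sprintf("%d_%g_%g", T, cutoff_s, tr)
  Q <- .dct_cache[[key]]
  if (is.null(Q)) {
    n_dct <- floor(2 * T * tr / cutoff_s)
    X <- matrix(1, T, 1)
    if (n_dct >= 1) {
      k <- seq_len(n_dct)
      t_idx <- seq_len(T) - 0.5
      X <- cbind(X, sapply(k, function(kk) cos(pi * kk * t_idx / T)))
    }
    Q <- qr.Q(qr(X))
    .dct_cache[[key]] <- Q
  }
  ts - tcrossprod(ts %*% Q, Q)
}

.dct_cache <- new.env(parent = emptyenv())

#' Ordinary-least-squares removal of regressors
#'
#' Projects each node's time series onto the orthogonal complement of the
#' column space of `X`. An intercept column is appended unless one is
#' already present (or `intercept = FALSE`). Rank-deficient designs are
#' handled by the pivoted QR pseudoinverse with a warning.
#'
#' @param ts node x time matrix.
#' @param X time x k regressor matrix.
#' @param intercept Append an intercept column if none present?
#' @param want_betas Also return the OLS coefficients? (The residual
#'   projection itself does not need them.)
#' @return List with `residuals` (node x time) and `betas` (node x k, or
#'   `NULL` when `want_betas = FALSE`).
#' @export
regress_out <- function(ts, X, intercept = TRUE, want_betas = TRUE) {
  if (is.null(dim(ts))) ts <- matrix(ts, nrow = 1)
  X <- as.matrix(X)
  if (nrow(X) != ncol(ts)) stop("X rows must match time points")
  if (intercept) {
    mu <- colMeans(X)
    v <- colMeans(X * X) - mu * mu
    has_const <- any(v < 1e-24 & abs(mu) > 1e-12)
    if (!has_const) X <- cbind(`(Intercept)` = 1, X)
  }
  if (ncol(X) >= nrow(X)) stop("more regressors than time points")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient regressor matrix; using pseudoinverse")
  }
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  residuals <- ts - tcrossprod(ts %*% Q, Q)
  betas <- NULL
  if (want_betas) {
    beta <- qr.coef(qrX, t(ts))
    beta[is.na(beta)] <- 0
    betas <- t(beta)
  }
  list(residuals = residuals, betas = betas)
}

#' Finite-impulse-response design matrix for a periodic block design
#'
#' One indicator column per TR position within the block+fixation cycle (24
#' columns for the default 12 s + 12 s design at TR = 1 s), so the FIR fit
#' captures the mean evoked response of arbitrary shape across cycles.
#'
#' @param design A [design_spec()].
#' @param n_vols Number of volumes; defaults to one run. Must be an integer
#'   number of cycles.
#' @return n_vols x cycle_vols 0/1 matrix with mutually orthogonal columns.
#' @export
build_fir_design <- function(design, n_vols = design$run_vols) {
  L <- design$cycle_vols
  if (n_vols %% L != 0) stop("run length is not an integer number of cycles")
  phase <- (seq_len(n_vols) - 1) %% L
  X <- matrix(0, n_vols, L)
  X[cbind(seq_len(n_vols), phase + 1)] <- 1
  colnames(X) <- sprintf("fir%02d", seq_len(L) - 1)
  X
}

#' Remove the FIR-estimated evoked response
#'
#' Fits the per-cycle-phase indicator basis by OLS and subtracts the fitted
#' evoked response; because the FIR columns are orthogonal indicators the
#' fitted response per node equals the mean cycle-phase pattern, so any
#' deterministic cycle-locked signal is annihilated exactly.
#'
#' @param ts node x time matrix for one run.
#' @param design A [design_spec()].
#' @return List with `residuals` (node x time), `fir_betas` (node x
#'   cycle_vols) and `fitted_evoked` (node x time).
#' @export
remove_evoked <- function(ts, design) {
  if (is.null(dim(ts))) ts <- matrix(ts, nrow = 1)
  L <- design$cycle_vols
  T <- ncol(ts)
  if (T %% L != 0) stop("run length is not an integer number of cycles")
  phase <- (seq_len(T) - 1) %% L
  # orthogonal indicator basis: OLS fit = per-phase mean pattern
  X <- build_fir_design(design, T)
  fir_betas <- (ts %*% X) / (T / L)
  colnames(fir_betas) <- colnames(X)
  fitted_evoked <- fir_betas[, phase + 1, drop = FALSE]
  dimnames(fitted_evoked) <- NULL
  list(residuals = ts - fitted_evoked, fir_betas = fir_betas,
       fitted_evoked = fitted_evoked)
}

#' Residualize a dataset into background time series
#'
#' Applies, per run and identically to V1 vertices and downstream area
#' series: high-pass filtering, nuisance regression (six motion parameters
#' plus white-matter and ventricle series), and optionally FIR removal of
#' the evoked response. The result is the substrate of every connectivity
#' analysis in the package.
#'
#' @param ds A `bg_dataset`.
#' @param remove_evoked_flag Remove the FIR-estimated evoked response? Keep
#'   `FALSE` for analyses that need the evoked drive (localizer GLM, DCM).
#' @param cutoff_s High-pass cutoff in seconds (`NULL` to skip).
#' @param runs Which runs to process (indices); default all runs.
#' @return Object of class `residual_set`: list with `residuals` (list of
#'   node x time matrices), `downstream` (list of area x time matrices),
#'   `condition`, `run_type`, `geometry`, `design` and `provenance` flags.
#' @export
residualize_dataset <- function(ds, remove_evoked_flag = TRUE,
                                cutoff_s = 100, runs = seq_along(ds$bold)) {
  stopifnot(inherits(ds, "bg_dataset"))
  res <- dres <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    r <- runs[i]
    v1 <- ds$bold[[r]]
    dw <- ds$downstream[[r]]
    if (!is.null(cutoff_s)) {
      v1 <- highpass(v1, cutoff_s, ds$design$tr)
      dw <- highpass(dw, cutoff_s, ds$design$tr)
    }
    X <- ds$nuisance[[r]]
    v1 <- regress_out(v1, X, want_betas = FALSE)$residuals
    dw <- regress_out(dw, X, want_betas = FALSE)$residuals
    if (remove_evoked_flag) {
      v1 <- remove_evoked(v1, ds$design)$residuals
      dw <- remove_evoked(dw, ds$design)$residuals
    }
    rownames(dw) <- rownames(ds$downstream[[r]])
    res[[i]] <- v1
    dres[[i]] <- dw
  }
  structure(list(residuals = res, downstream = dres,
                 condition = ds$condition[runs],
                 run_type = ds$run_type[runs],
                 geometry = ds$geometry, design = ds$design,
                 subject_id = ds$subject_id,
                 provenance = list(nuisance_removed = TRUE,
                                   evoked_removed = remove_evoked_flag,
                                   highpass_s = cutoff_s)),
            class = "residual_set")
}

#' @export
print.residual_set <- function(x, ...) {
  cat(sprintf("Background residual set '%s': %d runs, evoked %s, high-pass %s\n",
              x$subject_id, length(x$residuals),
              if (isTRUE(x$provenance$evoked_removed)) "removed" else "retained",
              if (is.null(x$provenance$highpass_s)) "none"
              else paste0(x$provenance$highpass_s, "s")))
  invisible(x)
}
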