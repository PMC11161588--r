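#' Localizer contrast: stimulus > fixation
#'
#' Per-node GLM t statistic for a positive response to stimulus blocks,
#' computed on nuisance-regressed (but evoked-retained) localizer runs with
#' a boxcar-convolved-HRF regressor, pooled across runs by fixed-effects
#' (inverse-variance) combination of the betas. One-sided p values.
#'
#' @param rs A `residual_set` whose provenance says the evoked response was
#'   NOT removed; only its localizer runs are used (all runs if none are
#'   flagged as localizer).
#' @return data.frame with `node_id`, `beta`, `t`, `p` (one-sided), `df`.
#' @export
localizer_contrast <- function(rs) {
  stopifnot(inherits(rs, "residual_set"))
  if (isTRUE(rs$provenance$evoked_removed)) {
    stop("localizer contrast needs the evoked signal; run residualize_dataset with remove_evoked_flag = FALSE")
  }
  idx <- which(rs$run_type == "localizer")
  if (length(idx) == 0) idx <- seq_along(rs$residuals)
  reg <- evoked_regressor(rs$design)
  n_nodes <- nrow(rs$residuals[[1]])
  wsum <- bsum <- rep(0, n_nodes)
  df_tot <- 0
  for (r in idx) {
    ts <- rs$residuals[[r]]
    X <- cbind(1, reg)
    qrX <- qr(X)
    beta <- qr.coef(qrX, t(ts))[2, ]
    resid <- t(qr.resid(qrX, t(ts)))
    df <- ncol(ts) - 2
    sigma2 <- rowSums(resid^2) / df
    xtx_inv <- chol2inv(qr.R(qrX))[2, 2]
    var_b <- sigma2 * xtx_inv
    var_b[var_b < 1e-300] <- Inf      # constant series: no information
    wsum <- wsum + 1 / var_b
    bsum <- bsum + beta / var_b
    df_tot <- df_tot + df
  }
  beta_fe <- ifelse(wsum > 0, bsum / wsum, 0)
  t_fe <- ifelse(wsum > 0, beta_fe * sqrt(wsum), 0)
  p <- stats::pt(t_fe, df = df_tot, lower.tail = FALSE)
  data.frame(node_id = rs$geometry$node_id, beta = beta_fe, t = t_fe,
             p = p, df = df_tot)
}

#' Assign analysis ROIs to V1 vertices
#'
#' The stimulated region is defined statistically (localizer p below
#' `alpha`); the peripheral bins are defined by geometry alone: vertices
#' within +/-10 degrees of the horizontal meridian, binned by eccentricity
#' into 4-6, 6-8 and 8-10 degrees (half-open bins, last bin closed at 10).
#' Vertices meeting both criteria go to the stimulated region; everything
#' else is excluded.
#'
#' @param geometry A [make_geometry()] table.
#' @param localizer_p Per-node one-sided p values from [localizer_contrast()].
#' @param alpha Uncorrected selection threshold (default 0.01).
#' @return Object of class `roi_assignment`: data.frame with `node_id` and
#'   `label` in `stim, 4-6, 6-8, 8-10, excluded`.
#' @export
assign_rois <- function(geometry, localizer_p, alpha = 0.01) {
  stopifnot(nrow(geometry) == length(localizer_p))
  e <- geometry$eccentricity
  lab <- rep("excluded", nrow(geometry))
  in_window <- abs(geometry$polar_angle) <= 10
  lab[in_window & e >= 4 & e < 6] <- "4-6"
  lab[in_window & e >= 6 & e < 8] <- "6-8"
  lab[in_window & e >= 8 & e <= 10] <- "8-10"
  lab[!is.na(localizer_p) & localizer_p < alpha] <- "stim"
  for (b in c("stim", "4-6", "6-8", "8-10")) {
    if (!any(lab == b)) stop("ROI bin '", b, "' is empty")
  }
  structure(data.frame(node_id = geometry$node_id, label = lab),
            class = c("roi_assignment", "data.frame"))
}

#' Mean time series over ROI member nodes
#'
#' @param ts node x time matrix.
#' @param members Integer node ids (0-based, matching geometry) to average.
#' @return Numeric vector: the unweighted mean series.
#' @export
roi_mean_timeseries <- function(ts, members) {
  if (length(members) == 0) stop("empty ROI member list")
  rows <- members + 1L
  if (length(rows) == 1) return(ts[rows, ])
  colMeans(ts[rows, , drop = FALSE])
}
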