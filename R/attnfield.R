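#' Normalize a response distribution over eccentricity
#'
#' Negative responses are truncated to zero and the remainder rescaled to
#' sum to one, so the spatial distribution of the BOLD response can be
#' treated as a probability distribution over eccentricity.
#'
#' @param responses Per-bin response amplitudes (>= 2 bins, at least one
#'   positive).
#' @return Numeric vector `p` with `p >= 0`, `sum(p) = 1`.
#' @export
response_profile <- function(responses) {
  if (length(responses) < 2) stop("need >= 2 bins")
  p <- pmax(responses, 0)
  s <- sum(p)
  if (s <= 0) stop("all responses non-positive: distribution undefined")
  p / s
}

#' Center of the stimulus/attention field
#'
#' Probability-weighted mean eccentricity, `E(x) = sum x_i p(x_i)`, in
#' degrees of visual angle.
#'
#' @param x Bin-center eccentricities (degrees).
#' @param p Normalized responses from [response_profile()].
#' @return Field center in degrees.
#' @export
field_center <- function(x, p) {
  stopifnot(length(x) == length(p))
  sum(x * p)
}

#' Size of the stimulus/attention field
#'
#' Twice the probability-weighted standard deviation over eccentricity:
#' `2 * sqrt(sum (x_i - E(x))^2 p(x_i))`.
#'
#' @inheritParams field_center
#' @return Field size in degrees.
#' @export
field_size <- function(x, p) {
  stopifnot(length(x) == length(p))
  2 * sqrt(sum((x - field_center(x, p))^2 * p))
}

#' Estimate the stimulus field from a dataset
#'
#' Per condition: a stimulus-vs-fixation GLM beta is computed for every
#' vertex on nuisance-regressed (evoked-retained) main runs, pooled across
#' runs by fixed effects; betas are averaged within 1-degree eccentricity
#' bins from 0 to 10 degrees, truncated and normalized, and summarized by
#' the field center and size.
#'
#' @param ds A `bg_dataset`.
#' @param bin_width Eccentricity bin width in degrees.
#' @param ecc_range Eccentricity range covered by the bins.
#' @param cutoff_s High-pass cutoff (seconds).
#' @return data.frame of class `field_estimate` with one row per
#'   condition: `condition`, `center_deg`, `size_deg`.
#' @export
estimate_field <- function(ds, bin_width = 1, ecc_range = c(0, 10),
                           cutoff_s = 100) {
  stopifnot(inherits(ds, "bg_dataset"))
  reg <- evoked_regressor(ds$design)
  breaks <- seq(ecc_range[1], ecc_range[2], by = bin_width)
  mids <- breaks[-1] - bin_width / 2
  ecc <- ds$geometry$eccentricity
  bin_of <- findInterval(ecc, breaks, rightmost.closed = TRUE)
  bin_of[ecc < ecc_range[1] | ecc > ecc_range[2]] <- NA

  out <- do.call(rbind, lapply(c("focal", "diffused"), function(cond) {
    runs <- which(ds$run_type == "main" & ds$condition == cond)
    rs <- residualize_dataset(ds, remove_evoked_flag = FALSE,
                              cutoff_s = cutoff_s, runs = runs)
    X <- cbind(1, reg)
    qrX <- qr(X)
    wsum <- bsum <- rep(0, nrow(ds$geometry))
    for (i in seq_along(runs)) {
      ts <- rs$residuals[[i]]
      beta <- qr.coef(qrX, t(ts))[2, ]
      resid <- t(qr.resid(qrX, t(ts)))
      var_b <- (rowSums(resid^2) / (ncol(ts) - 2)) *
        chol2inv(qr.R(qrX))[2, 2]
      var_b[var_b < 1e-300] <- Inf
      wsum <- wsum + 1 / var_b
      bsum <- bsum + beta / var_b
    }
    beta_fe <- ifelse(wsum > 0, bsum / wsum, 0)
    bin_means <- tapply(beta_fe, factor(bin_of, levels = seq_along(mids)),
                        mean)
    keep <- !is.na(bin_means)
    p <- response_profile(as.numeric(bin_means[keep]))
    data.frame(condition = cond,
               center_deg = field_center(mids[keep], p),
               size_deg = field_size(mids[keep], p))
  }))
  out$subject <- ds$subject_id
  class(out) <- c("field_estimate", "data.frame")
  out
}

#' Compare field estimates between attention conditions
#'
#' Paired t tests of center and size between focal and diffused attention,
#' and one-sample t tests of the centers against the physical stimulus
#' eccentricity.
#'
#' @param estimates A `field_estimate` data.frame over subjects (complete
#'   subject x condition crossing).
#' @param stim_ecc Physical stimulus eccentricity in degrees.
#' @return `stat_result` data.frame with one row per test.
#' @export
compare_fields <- function(estimates, stim_ecc = 2.5) {
  wide_c <- stats::reshape(estimates[, c("subject", "condition", "center_deg")],
                           idvar = "subject", timevar = "condition",
                           direction = "wide")
  wide_s <- stats::reshape(estimates[, c("subject", "condition", "size_deg")],
                           idvar = "subject", timevar = "condition",
                           direction = "wide")
  res <- rbind(
    cbind(test = "center focal-vs-diffused",
          paired_t(wide_c$center_deg.focal, wide_c$center_deg.diffused)),
    cbind(test = "size focal-vs-diffused",
          paired_t(wide_s$size_deg.focal, wide_s$size_deg.diffused)),
    cbind(test = "center focal vs stimulus",
          one_sample_t(wide_c$center_deg.focal, mu = stim_ecc)),
    cbind(test = "center diffused vs stimulus",
          one_sample_t(wide_c$center_deg.diffused, mu = stim_ecc)))
  class(res) <- c("stat_result", "data.frame")
  res
}
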