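#' Synthetic retinotopic vertex geometry
#'
#' Samples vertex coordinates for a model V1 patch: eccentricity is
#' stratified-uniform over 2-degree strata covering `[0, ecc_max]` so that
#' every eccentricity bin the analysis uses is populated, and polar angle is
#' stratified between the +/-10 degree horizontal-meridian window (fraction
#' `meridian_frac` of each stratum) and the remainder of the circle. A
#' ground-truth stimulated flag marks vertices whose visual-field position
#' falls within the footprint of the stimulus array: a disc of radius 1.5
#' degrees centered at 2.5 degrees eccentricity on the horizontal meridian
#' (central element plus flankers at 0.75 degree spacing, element radius
#' 0.3125 degrees).
#'
#' @param n_vertices Number of vertices (>= 50).
#' @param ecc_max Maximum eccentricity in degrees (>= 10).
#' @param seed Integer seed; identical arguments give identical geometry.
#' @param meridian_frac Fraction of each eccentricity stratum sampled inside
#'   the +/-10 degree polar window used by the region-of-interest rule.
#' @param stim_center Eccentricity of the stimulus-array center (degrees).
#' @param stim_radius Radius of the stimulated disc (degrees).
#'
#' @return A `data.frame` of class `vertex_geometry` with columns `node_id`
#'   (0-based, contiguous), `eccentricity`, `polar_angle` (degrees in
#'   (-180, 180], 0 = horizontal meridian), `is_stimulated_truth`.
#' @export
#' @examples
#' g <- make_geometry(300, ecc_max = 12, seed = 1)
#' table(cut(g$eccentricity, seq(0, 12, 2)))
make_geometry <- function(n_vertices, ecc_max = 12, seed = 1,
                          meridian_frac = 0.25,
                          stim_center = 2.5, stim_radius = 1.5) {
  stopifnot(n_vertices >= 50, ecc_max >= 10)
  set.seed(as.integer(seed))
  n_strata <- as.integer(ceiling(ecc_max / 2))
  # near-equal allocation of vertices to 2-degree eccentricity strata
  alloc <- rep(n_vertices %/% n_strata, n_strata)
  extra <- n_vertices %% n_strata
  if (extra > 0) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L
  ecc <- polar <- numeric(0)
  for (s in seq_len(n_strata)) {
    lo <- (s - 1) * 2
    hi <- min(s * 2, ecc_max)
    m <- alloc[s]
    ecc <- c(ecc, stats::runif(m, lo, hi))
    n_in <- round(meridian_frac * m)
    pol_in <- stats::runif(n_in, -10, 10)
    # outside the window: uniform over the two remaining arcs
    u <- stats::runif(m - n_in, 0, 340)
    pol_out <- ifelse(u < 170, 10 + u, u - 350)
    polar <- c(polar, sample(c(pol_in, pol_out)))
  }
  x <- ecc * cospi(polar / 180)
  y <- ecc * sinpi(polar / 180)
  stim <- sqrt((x - stim_center)^2 + y^2) <= stim_radius
  geom <- data.frame(node_id = seq_len(n_vertices) - 1L,
                     eccentricity = ecc,
                     polar_angle = polar,
                     is_stimulated_truth = stim)
  class(geom) <- c("vertex_geometry", "data.frame")
  counts <- geometry_bin_counts(geom)
  empty <- names(counts)[counts == 0]
  if (length(empty) > 0) {
    stop("n_vertices too small: bin(s) ", paste(empty, collapse = ", "),
         " would be empty")
  }
  geom
}

# vertex counts in the analysis bins (stim disc; peripheral bins within the
# +/-10 degree polar window)
geometry_bin_counts <- function(geom) {
  in_window <- abs(geom$polar_angle) <= 10
  e <- geom$eccentricity
  c(stim = sum(geom$is_stimulated_truth),
    `4-6` = sum(in_window & e >= 4 & e < 6),
    `6-8` = sum(in_window & e >= 6 & e < 8),
    `8-10` = sum(in_window & e >= 8 & e <= 10))
}

# ground-truth coupling bin of each node, by geometry alone: the stimulated
# disc overrides; peripheral bins depend on eccentricity only (the latent
# coupling field varies over eccentricity, not polar angle)
truth_bin <- function(geom) {
  e <- geom$eccentricity
  bin <- rep(NA_character_, nrow(geom))
  bin[e >= 4 & e < 6] <- "4-6"
  bin[e >= 6 & e < 8] <- "6-8"
  bin[e >= 8 & e <= 10] <- "8-10"
  bin[geom$is_stimulated_truth] <- "stim"
  bin
}
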