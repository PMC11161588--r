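#' Specify a bilinear DCM candidate model
#'
#' Builds the connectivity masks, priors and exogenous inputs for one of
#' the three candidate architectures distinguishing where focal attention
#' acts. All candidates share the same intrinsic (A) and driving (C)
#' structure: bidirectional intrinsic connections between each V1
#' subregion (stimulated `V1_S`, non-stimulated `V1_NS`) and every
#' extrastriate node, plus the lateral `V1_S`/`V1_NS` pair and
#' self-connections; no extrastriate-extrastriate links; the stimulus
#' boxcar drives `V1_S` only. They differ only in the modulatory (B) mask
#' for the attention input: `feedforward` places modulation on the V1 ->
#' extrastriate directions, `feedback` on extrastriate -> V1, `recurrent`
#' on their union; all three include the lateral within-V1 modulation.
#'
#' The attention input is 1 during stimulus blocks of focal-condition runs
#' and 0 elsewhere; runs are concatenated in the given order.
#'
#' @param structure `"feedforward"`, `"feedback"` or `"recurrent"`.
#' @param nodes Node labels: `V1_S`, `V1_NS`, then extrastriate labels.
#'   Default is the five-node configuration; `c("V1_S","V1_NS","EX")`
#'   gives the three-node preset with a single extrastriate node.
#' @param design A [design_spec()].
#' @param conditions Per-run condition labels (`"focal"`/`"diffused"`);
#'   defaults to `n_runs_per_condition` of each.
#' @param nsub Integration sub-steps per TR (fixed step `tr/nsub`).
#'
#' @return Object of class `dcm_model`: masks, prior means/variances over
#'   the free-parameter vector, fixed hemodynamic constants
#'   (gamma = 0.41/s, alpha = 0.32, E0 = 0.34, V0 = 0.04; kappa and tau
#'   free on a log scale around 0.65/s and 0.98 s), inputs `U` and run
#'   lengths.
#' @export
specify_model <- function(structure = c("feedforward", "feedback",
                                        "recurrent"),
                          nodes = c("V1_S", "V1_NS", "V2", "V3", "V4"),
                          design = design_spec(),
                          conditions = NULL, nsub = 16) {
  structure <- match.arg(structure)
  stopifnot(all(c("V1_S", "V1_NS") %in% nodes[1:2]), length(nodes) >= 3)
  n <- length(nodes)
  ex <- nodes[-(1:2)]
  iS <- 1L; iNS <- 2L; iEx <- seq(3L, n)

  A_mask <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (k in iEx) {
    A_mask[k, c(iS, iNS)] <- TRUE   # V1 -> extrastriate
    A_mask[c(iS, iNS), k] <- TRUE   # extrastriate -> V1
  }
  A_mask[iS, iNS] <- A_mask[iNS, iS] <- TRUE

  ff <- fb <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (k in iEx) {
    ff[k, c(iS, iNS)] <- TRUE
    fb[c(iS, iNS), k] <- TRUE
  }
  lateral <- matrix(FALSE, n, n)
  lateral[iS, iNS] <- lateral[iNS, iS] <- TRUE
  B_mask <- switch(structure,
                   feedforward = ff | lateral,
                   feedback = fb | lateral,
                   recurrent = ff | fb | lateral)
  dimnames(B_mask) <- list(nodes, nodes)

  C_mask <- matrix(FALSE, n, 2, dimnames = list(nodes, c("u1", "u2")))
  C_mask[iS, 1] <- TRUE

  if (is.null(conditions)) {
    conditions <- rep(c("focal", "diffused"),
                      each = design$n_runs_per_condition)
  }
  box <- stimulus_boxcar(design)
  U <- rbind(u1 = rep(box, length(conditions)),
             u2 = unlist(lapply(conditions,
                                function(cc) box * (cc == "focal"))))
  run_lengths <- rep(design$run_vols, length(conditions))

  # free-parameter bookkeeping: one row per parameter
  idx <- data.frame(type = character(0), i = integer(0), j = integer(0),
                    name = character(0))
  add <- function(idx, type, i, j, name) {
    rbind(idx, data.frame(type = type, i = i, j = j, name = name))
  }
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (i != j && A_mask[i, j]) {
      idx <- add(idx, "A", i, j, sprintf("A.%s<-%s", nodes[i], nodes[j]))
    }
  }
  for (i in seq_len(n)) idx <- add(idx, "self", i, i,
                                   sprintf("self.%s", nodes[i]))
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (B_mask[i, j]) {
      idx <- add(idx, "B", i, j, sprintf("B.%s<-%s", nodes[i], nodes[j]))
    }
  }
  for (i in which(C_mask[, 1])) idx <- add(idx, "C", i, 1L,
                                           sprintf("C.%s", nodes[i]))
  for (i in seq_len(n)) idx <- add(idx, "kappa", i, i,
                                   sprintf("kappa.%s", nodes[i]))
  for (i in seq_len(n)) idx <- add(idx, "tau", i, i,
                                   sprintf("tau.%s", nodes[i]))

  pE <- rep(0, nrow(idx))
  pV <- c(A = 1 / 16, self = 1 / 256, B = 1 / 16, C = 1,
          kappa = 0.01, tau = 0.01)[idx$type]
  names(pE) <- names(pV) <- idx$name

  structure(list(structure = structure, nodes = nodes, n = n,
                 A_mask = A_mask, B_mask = B_mask, C_mask = C_mask,
                 U = U, run_lengths = run_lengths, tr = design$tr,
                 nsub = as.integer(nsub), conditions = conditions,
                 par_index = idx, pE = pE, pV = pV,
                 hemo = list(kappa0 = 0.65, gamma = 0.41, tau0 = 0.98,
                             alpha = 0.32, E0 = 0.34, V0 = 0.04)),
            class = "dcm_model")
}

#' @export
print.dcm_model <- function(x, ...) {
  cat(sprintf("Bilinear DCM (%s): %d nodes [%s], %d free parameters, %d volumes\n",
              x$structure, x$n, paste(x$nodes, collapse = ", "),
              nrow(x$par_index), sum(x$run_lengths)))
  invisible(x)
}

# expand a free-parameter vector into A, B, C and hemodynamic vectors
dcm_matrices <- function(model, theta) {
  n <- model$n
  idx <- model$par_index
  A <- matrix(0, n, n)
  Bm <- matrix(0, n, n)
  C <- matrix(0, n, 2)
  kap <- rep(model$hemo$kappa0, n)
  tau <- rep(model$hemo$tau0, n)
  for (k in seq_len(nrow(idx))) {
    v <- theta[k]
    switch(idx$type[k],
           A = { A[idx$i[k], idx$j[k]] <- v },
           self = { A[idx$i[k], idx$i[k]] <- -0.5 * exp(v) },
           B = { Bm[idx$i[k], idx$j[k]] <- v },
           C = { C[idx$i[k], idx$j[k]] <- v },
           kappa = { kap[idx$i[k]] <- model$hemo$kappa0 * exp(v) },
           tau = { tau[idx$i[k]] <- model$hemo$tau0 * exp(v) })
  }
  list(A = A, B = Bm, C = C, kappa = kap, tau = tau)
}

#' Integrate the DCM forward model
#'
#' Runs the bilinear neuronal equation `dz/dt = (A + u2 B) z + C u` and the
#' balloon hemodynamic model per node, at fixed step `tr/nsub` with RK4 on
#' the neuronal states and the hemodynamic states propagated in log space,
#' and samples the predicted BOLD at the TR grid. Runs are integrated
#' independently from rest.
#'
#' @param model A [specify_model()] object.
#' @param theta Free-parameter vector (defaults to the prior mean).
#' @return Object of class `dcm_trajectory`: list with `y` (time x node
#'   predicted BOLD, percent signal), `z`, `s`, `f`, `v`, `q` state
#'   matrices.
#' @export
dcm_forward <- function(model, theta = model$pE) {
  stopifnot(inherits(model, "dcm_model"),
            length(theta) == nrow(model$par_index))
  mat <- dcm_matrices(model, theta)
  ev <- eigen(mat$A, only.values = TRUE)$values
  if (any(Re(ev) > 1e-8)) stop("unstable A matrix (eigenvalue with positive real part)")
  Bcube <- array(0, dim = c(model$n, model$n, 2))
  Bcube[, , 2] <- mat$B
  out <- dcm_integrate_cpp(mat$A, as.numeric(Bcube), mat$C, model$U,
                           as.integer(model$run_lengths),
                           mat$kappa, rep(model$hemo$gamma, model$n),
                           mat$tau, model$hemo$alpha, model$hemo$E0,
                           model$hemo$V0, model$tr, model$nsub)
  colnames(out$y) <- model$nodes
  class(out) <- "dcm_trajectory"
  out
}

#' Simulate noisy BOLD from a DCM
#'
#' Integrates the forward model at the supplied parameters and adds iid
#' Gaussian observation noise with per-node standard deviation
#' `sd(signal)/snr`.
#'
#' @param model A [specify_model()] object.
#' @param theta True free-parameter values.
#' @param snr Amplitude signal-to-noise ratio (> 0).
#' @param seed Integer seed.
#' @return List with `y` (time x node noisy BOLD), `y_clean`, and
#'   `ground_truth` (theta and the expanded matrices).
#' @export
simulate_dcm_timeseries <- function(model, theta, snr = 2, seed = 1) {
  if (!is.numeric(snr) || snr <= 0) stop("snr must be positive")
  set.seed(as.integer(seed))
  traj <- dcm_forward(model, theta)
  y <- traj$y
  sds <- apply(y, 2, stats::sd)
  sds[sds < 1e-12] <- max(sds, 1e-12)
  noise <- matrix(stats::rnorm(length(y)), nrow(y), ncol(y))
  noise <- sweep(noise, 2, sds / snr, `*`)
  list(y = y + noise, y_clean = y,
       ground_truth = list(theta = theta,
                           matrices = dcm_matrices(model, theta),
                           snr = snr))
}

#' Generating parameter vector for simulation studies
#'
#' Fills the free-parameter vector with stable generating values: a
#' feedforward-dominant intrinsic hierarchy (`a_ff` on V1 -> extrastriate,
#' `a_fb` on the returns, `a_lat` between the V1 subregions — asymmetric so
#' extrastriate activity is vigorous while the system keeps a comfortable
#' stability margin), a driving gain on `C`, and attention modulation split
#' by pathway: connections linking `V1_S` with extrastriate nodes (either
#' direction) get `b_s`, connections linking `V1_NS` get `b_ns`; the
#' lateral pair gets `b_s` for `V1_S -> V1_NS` and `b_ns` for
#' `V1_NS -> V1_S`.
#'
#' @param model A [specify_model()] object.
#' @param b_s,b_ns Modulatory gains (Hz) for the stimulated and
#'   non-stimulated V1 pathways.
#' @param a_ff,a_fb,a_lat Intrinsic coupling (Hz) for the feedforward,
#'   feedback and lateral within-V1 connections.
#' @param c_gain Driving-input gain.
#' @return Named parameter vector aligned with `model$par_index`.
#' @export
dcm_true_params <- function(model, b_s = 0.3, b_ns = -0.2, a_ff = 0.4,
                            a_fb = 0.1, a_lat = 0.1, c_gain = 0.8) {
  idx <- model$par_index
  theta <- model$pE
  for (k in seq_len(nrow(idx))) {
    i <- idx$i[k]; j <- idx$j[k]
    if (idx$type[k] == "A") {
      theta[k] <- if (i <= 2 && j <= 2) a_lat else if (j <= 2) a_ff
      else a_fb
    }
    if (idx$type[k] == "C") theta[k] <- c_gain
    if (idx$type[k] == "B") {
      from_s <- (i == 1 || j == 1)
      theta[k] <- if (i <= 2 && j <= 2) {
        if (j == 1) b_s else b_ns       # lateral: keyed by source subregion
      } else if (from_s) b_s else b_ns
    }
  }
  theta
}
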