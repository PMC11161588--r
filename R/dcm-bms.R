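#' Random-effects Bayesian model selection
#'
#' Hierarchical Dirichlet-multinomial scheme over candidate models: the
#' generating model is treated as varying across subjects with unknown
#' population frequencies. Variational updates alternate subject-wise
#' model weights `u_nk` proportional to `exp(F_nk + digamma(alpha_k) -
#' digamma(sum alpha))` with the concentration update `alpha_k = alpha0 +
#' sum_n u_nk` until the alphas stabilize. Exceedance probabilities — the
#' posterior probability that each model is the most frequent in the
#' population — are computed by Monte Carlo sampling from the Dirichlet
#' posterior.
#'
#' @param F subject x model matrix of free energies (log evidences).
#' @param alpha0 Prior Dirichlet concentration (default 1).
#' @param n_samples Monte Carlo draws for the exceedance probability.
#' @param seed Seed for the Monte Carlo sampler.
#' @return Object of class `bms_result`: `alpha` (posterior
#'   concentrations), `expected_freq`, `exceedance`, `weights`
#'   (subject x model posterior assignments).
#' @export
rfx_bms <- function(F, alpha0 = 1, n_samples = 1e6, seed = 1) {
  F <- as.matrix(F)
  if (nrow(F) < 2 || ncol(F) < 2) stop("need >= 2 subjects and >= 2 models")
  if (any(!is.finite(F))) stop("free energies must be finite")
  n <- nrow(F)
  K <- ncol(F)
  alpha <- rep(alpha0, K)
  for (iter in 1:500) {
    lw <- sweep(F, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < 1e-8) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  xp <- exceedance_mc(alpha, n_samples, seed)
  names(alpha) <- names(xp) <- colnames(F)
  structure(list(alpha = alpha, expected_freq = alpha / sum(alpha),
                 exceedance = xp, weights = u, alpha0 = alpha0,
                 n_samples = n_samples),
            class = "bms_result")
}

# Monte Carlo exceedance probabilities for a Dirichlet(alpha) posterior
exceedance_mc <- function(alpha, n_samples = 1e6, seed = 1) {
  K <- length(alpha)
  set.seed(as.integer(seed))
  counts <- integer(K)
  block <- 250000L
  left <- as.integer(n_samples)
  while (left > 0) {
    b <- min(block, left)
    g <- matrix(stats::rgamma(b * K, shape = rep(alpha, each = b)), b, K)
    counts <- counts + tabulate(max.col(g), nbins = K)
    left <- left - b
  }
  counts / as.integer(n_samples)
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects Bayesian model selection\n")
  out <- data.frame(model = names(x$alpha), alpha = x$alpha,
                    expected_freq = x$expected_freq,
                    exceedance = x$exceedance)
  print(out, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Group statistics on attentional modulation parameters
#'
#' Summarizes per-subject posterior B estimates from a common candidate
#' structure: for each extrastriate area and modulated direction, a paired
#' t test between the `V1_S`-pathway and `V1_NS`-pathway estimates and
#' one-sample t tests of each estimate against zero; the same contrast for
#' the lateral within-V1 pair; a visual-field x cortical-area
#' repeated-measures ANOVA per direction when more than one area is
#' modeled; and Benjamini-Hochberg adjustment across the reported family
#' of t tests.
#'
#' @param fits List of `dcm_fit` objects (same structure for all
#'   subjects).
#' @return List with `tests` (a `stat_result` data.frame with `q` column),
#'   `anova` (per-direction data.frame or NULL), and `b_table` (the
#'   per-subject estimates in long format).
#' @export
modulation_group_stats <- function(fits) {
  stopifnot(length(fits) >= 2)
  structures <- vapply(fits, function(f) f$model$structure, "")
  if (length(unique(structures)) != 1) {
    stop("all subjects must be inverted under the same structure")
  }
  model <- fits[[1]]$model
  nodes <- model$nodes
  ex <- nodes[-(1:2)]
  nsub <- length(fits)

  rows <- list()
  for (a in ex) {
    for (dir in c("feedforward", "feedback")) {
      tgt_s <- if (dir == "feedforward") a else "V1_S"
      src_s <- if (dir == "feedforward") "V1_S" else a
      if (!model$B_mask[tgt_s, src_s]) next
      bs <- vapply(fits, b_entry, 0, target = tgt_s, source = src_s)
      tgt_n <- if (dir == "feedforward") a else "V1_NS"
      src_n <- if (dir == "feedforward") "V1_NS" else a
      bn <- vapply(fits, b_entry, 0, target = tgt_n, source = src_n)
      rows[[length(rows) + 1]] <-
        data.frame(area = a, direction = dir,
                   subject = rep(seq_len(nsub), 2),
                   pathway = rep(c("V1_S", "V1_NS"), each = nsub),
                   b = c(bs, bn))
    }
  }
  lat_sn <- vapply(fits, b_entry, 0, target = "V1_NS", source = "V1_S")
  lat_ns <- vapply(fits, b_entry, 0, target = "V1_S", source = "V1_NS")
  b_table <- do.call(rbind, rows)

  tests <- list()
  addt <- function(tests, family, res) {
    res$family <- family
    tests[[length(tests) + 1]] <- res
    tests
  }
  if (!is.null(b_table)) {
    for (key in unique(paste(b_table$area, b_table$direction))) {
      sub <- b_table[paste(b_table$area, b_table$direction) == key, ]
      bs <- sub$b[sub$pathway == "V1_S"]
      bn <- sub$b[sub$pathway == "V1_NS"]
      tests <- addt(tests, paste0(key, " S-vs-NS"), paired_t(bs, bn))
      tests <- addt(tests, paste0(key, " S vs 0"), one_sample_t(bs))
      tests <- addt(tests, paste0(key, " NS vs 0"), one_sample_t(bn))
    }
  }
  tests <- addt(tests, "within-V1 S-vs-NS", paired_t(lat_sn, lat_ns))
  tests <- addt(tests, "within-V1 NS->S vs 0", one_sample_t(lat_ns))
  tests <- do.call(rbind, tests)
  tests$q <- fdr_adjust(tests$p)

  anova <- NULL
  if (length(ex) >= 2 && !is.null(b_table)) {
    anova <- do.call(rbind, lapply(unique(b_table$direction), function(d) {
      sub <- b_table[b_table$direction == d, ]
      out <- rm_anova_2way(sub, a_col = "pathway", b_col = "area",
                           value_col = "b")
      out$direction <- d
      out
    }))
  }
  list(tests = tests, anova = anova, b_table = b_table)
}
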