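#' Vertexwise background-connectivity map
#'
#' Pearson correlation between every V1 vertex's background residuals and
#' each downstream area's residual series, Fisher z-transformed. With the
#' default aggregation the correlation is computed per run and the z values
#' averaged over runs of the same condition; `"concatenated"` computes one
#' correlation over the concatenated residuals per condition.
#'
#' @param rs A `residual_set` (main runs only are used).
#' @param method `"per_run_z_mean"` (default) or `"concatenated"`.
#' @return Object of class `connectivity_map`: node x area x condition
#'   array of Fisher z values (attribute `r` holds the back-transformed
#'   correlations), plus `subject_id`.
#' @export
connectivity_map <- function(rs, method = c("per_run_z_mean",
                                            "concatenated")) {
  stopifnot(inherits(rs, "residual_set"))
  method <- match.arg(method)
  idx <- which(rs$run_type == "main")
  if (length(idx) == 0) idx <- seq_along(rs$residuals)
  areas <- rownames(rs$downstream[[idx[1]]])
  if (is.null(areas)) areas <- paste0("area", seq_len(nrow(rs$downstream[[idx[1]]])))
  conds <- unique(rs$condition[idx])
  n_nodes <- nrow(rs$residuals[[idx[1]]])
  z <- array(NA_real_, dim = c(n_nodes, length(areas), length(conds)),
             dimnames = list(NULL, areas, conds))
  for (cond in conds) {
    runs <- idx[rs$condition[idx] == cond]
    if (method == "per_run_z_mean") {
      zsum <- matrix(0, n_nodes, length(areas))
      nsum <- matrix(0, n_nodes, length(areas))
      for (r in runs) {
        if (ncol(rs$residuals[[r]]) < 30) stop("need >= 30 time points per run")
        rr <- node_area_cor(rs$residuals[[r]], rs$downstream[[r]])
        zz <- fisher_z(rr)
        ok <- is.finite(zz)
        zsum[ok] <- zsum[ok] + zz[ok]
        nsum <- nsum + ok
      }
      zc <- zsum / nsum
      zc[nsum == 0] <- NA_real_
      z[, , cond] <- zc
    } else {
      v1 <- do.call(cbind, rs$residuals[runs])
      dw <- do.call(cbind, rs$downstream[runs])
      z[, , cond] <- fisher_z(node_area_cor(v1, dw))
    }
  }
  if (anyNA(z)) warning("undefined correlations (zero-variance series) recorded as missing")
  structure(z, class = "connectivity_map", subject_id = rs$subject_id)
}

# correlation of every row of `v1` (node x time) with every row of `dw`
# (area x time); zero-variance series give NA
node_area_cor <- function(v1, dw) {
  v1c <- v1 - rowMeans(v1)
  dwc <- dw - rowMeans(dw)
  sd1 <- sqrt(rowSums(v1c^2))
  sd2 <- sqrt(rowSums(dwc^2))
  num <- v1c %*% t(dwc)
  den <- outer(sd1, sd2)
  r <- num / den
  r[den < 1e-12] <- NA_real_
  r
}

# Fisher z with clipping so the transform stays finite
fisher_z <- function(r, eps = 1e-12) {
  r <- pmin(pmax(r, -1 + eps), 1 - eps)
  atanh(r)
}

#' Eccentricity-binned connectivity profile
#'
#' Averages the Fisher-z connectivity over ROI member vertices, producing
#' the subject x condition x area x bin table the group statistics consume.
#'
#' @param map A [connectivity_map()].
#' @param rois A [assign_rois()] table.
#' @return data.frame of class `connectivity_profile` with columns
#'   `subject`, `condition`, `area`, `bin`, `z`, `r`.
#' @export
profile_by_bin <- function(map, rois) {
  stopifnot(inherits(map, "connectivity_map"), inherits(rois, "roi_assignment"))
  bins <- c("stim", "4-6", "6-8", "8-10")
  areas <- dimnames(map)[[2]]
  conds <- dimnames(map)[[3]]
  out <- expand.grid(bin = bins, area = areas, condition = conds,
                     stringsAsFactors = FALSE)
  out$subject <- attr(map, "subject_id")
  lab <- factor(rois$label, levels = bins)
  keep <- !is.na(lab)
  M <- matrix(unclass(map)[keep, , ], nrow = sum(keep))  # node x (area*cond)
  ok <- !is.na(M)
  M[!ok] <- 0
  sums <- rowsum(M, lab[keep])
  cnts <- rowsum(ok + 0, lab[keep])
  out$z <- as.numeric(sums / cnts)
  out$r <- tanh(out$z)
  out <- out[, c("subject", "condition", "area", "bin", "z", "r")]
  class(out) <- c("connectivity_profile", "data.frame")
  out
}

#' Background-connectivity profiles for a whole cohort
#'
#' Runs residualization, localizer ROI definition and binned connectivity
#' for each subject and stacks the per-subject profiles.
#'
#' @param cohort List of `bg_dataset` objects.
#' @param cutoff_s High-pass cutoff (seconds).
#' @param alpha Localizer threshold for the stimulated region.
#' @param method Correlation aggregation, see [connectivity_map()].
#' @param remove_evoked_flag Remove the FIR evoked model before
#'   correlating (the standard background-connectivity definition).
#' @return A `connectivity_profile` data.frame over all subjects.
#' @export
cohort_profiles <- function(cohort, cutoff_s = 100, alpha = 0.01,
                            method = "per_run_z_mean",
                            remove_evoked_flag = TRUE) {
  out <- lapply(cohort, function(ds) {
    loc_runs <- which(ds$run_type == "localizer")
    rs_loc <- residualize_dataset(ds, remove_evoked_flag = FALSE,
                                  cutoff_s = cutoff_s, runs = loc_runs)
    loc <- localizer_contrast(rs_loc)
    rois <- assign_rois(ds$geometry, loc$p, alpha = alpha)
    main_runs <- which(ds$run_type == "main")
    rs <- residualize_dataset(ds, remove_evoked_flag = remove_evoked_flag,
                              cutoff_s = cutoff_s, runs = main_runs)
    profile_by_bin(connectivity_map(rs, method = method), rois)
  })
  out <- do.call(rbind, out)
  class(out) <- c("connectivity_profile", "data.frame")
  out
}

#' Two-way repeated-measures ANOVA
#'
#' Classical within-subject ANOVA for a complete balanced subject x A x B
#' table: each effect is tested against its own subject-interaction error
#' stratum (no sphericity correction; flagged in the output). Fitted with
#' `stats::aov` and `Error(subject/(A*B))` strata.
#'
#' @param table data.frame with columns `subject`, `A`, `B`, `value` (or
#'   supply `a_col`, `b_col`, `value_col` to rename).
#' @param a_col,b_col,value_col Column names for the two within factors and
#'   the response.
#' @return data.frame of class `stat_result` with one row per effect
#'   (`A`, `B`, `A:B`): `statistic` (F), `df1`, `df2`, `p`.
#' @export
rm_anova_2way <- function(table, a_col = "bin", b_col = "condition",
                          value_col = "z") {
  d <- data.frame(subject = factor(table$subject),
                  A = factor(table[[a_col]]),
                  B = factor(table[[b_col]]),
                  value = table[[value_col]])
  if (anyNA(d$value)) stop("missing cells in repeated-measures table")
  tab <- with(d, table(subject, A, B))
  if (any(tab != 1)) stop("table must be complete and balanced (one value per subject x A x B cell)")
  if (nlevels(d$subject) < 2) stop("need >= 2 subjects")
  fit <- stats::aov(value ~ A * B + Error(subject / (A * B)), data = d)
  s <- summary(fit)
  ss_tot <- sum((d$value - mean(d$value))^2)
  pick <- function(stratum, term) {
    tb <- as.data.frame(s[[stratum]][[1]])
    i <- grep(paste0("^", term, "\\s*$"), trimws(rownames(tb)))
    err <- grep("Residuals", rownames(tb))
    ss_eff <- tb[i, "Sum Sq"]
    ss_err <- tb[err, "Sum Sq"]
    eps <- 1e-12 * max(ss_tot, 1e-300)
    if (ss_eff < eps) {                      # numerically null effect
      return(data.frame(effect = term, statistic = 0,
                        df1 = tb[i, "Df"], df2 = tb[err, "Df"], p = 1))
    }
    if (!is.finite(ss_err) || ss_err < eps) {
      stop("zero error sum of squares in stratum ", stratum)
    }
    data.frame(effect = term, statistic = tb[i, "F value"],
               df1 = tb[i, "Df"], df2 = tb[err, "Df"],
               p = tb[i, "Pr(>F)"])
  }
  out <- rbind(pick("Error: subject:A", "A"),
               pick("Error: subject:B", "B"),
               pick("Error: subject:A:B", "A:B"))
  out$effect <- c(a_col, b_col, paste0(a_col, ":", b_col))
  attr(out, "sphericity_corrected") <- FALSE
  class(out) <- c("stat_result", "data.frame")
  out
}

#' Paired t test (two-sided)
#'
#' @param x,y Per-subject values under the two conditions (equal length,
#'   n >= 2).
#' @return One-row `stat_result` data.frame: `statistic` (t), `df`, `p`,
#'   `mean_diff`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) stop("need equal-length vectors, n >= 2")
  d <- x - y
  if (stats::sd(d) < 1e-14) {
    if (all(abs(d - 0) < 1e-14)) {
      out <- data.frame(effect = "paired", statistic = 0,
                        df = length(d) - 1, p = 1, mean_diff = 0)
      class(out) <- c("stat_result", "data.frame")
      return(out)
    }
    stop("zero-variance differences: paired t undefined")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  out <- data.frame(effect = "paired", statistic = unname(tt$statistic),
                    df = unname(tt$parameter), p = tt$p.value,
                    mean_diff = unname(tt$estimate))
  class(out) <- c("stat_result", "data.frame")
  out
}

#' One-sample t test (two-sided)
#'
#' @param x Per-subject values.
#' @param mu Null value.
#' @return One-row `stat_result` data.frame.
#' @export
one_sample_t <- function(x, mu = 0) {
  if (length(x) < 2) stop("need n >= 2")
  if (stats::sd(x) < 1e-14) {
    if (abs(mean(x) - mu) < 1e-12) {
      out <- data.frame(effect = "one-sample", statistic = 0,
                        df = length(x) - 1, p = 1, mean_diff = 0)
      class(out) <- c("stat_result", "data.frame")
      return(out)
    }
    stop("zero-variance sample: t undefined")
  }
  tt <- stats::t.test(x, mu = mu)
  out <- data.frame(effect = "one-sample", statistic = unname(tt$statistic),
                    df = unname(tt$parameter), p = tt$p.value,
                    mean_diff = unname(tt$estimate) - mu)
  class(out) <- c("stat_result", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvals Numeric p values in `[0, 1]`.
#' @return q values (same order as input).
#' @export
fdr_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Group statistics on binned connectivity profiles
#'
#' For each downstream area: the visual-field x attention repeated-measures
#' ANOVA on Fisher-z profiles, and per-bin paired t tests of the focal -
#' diffused contrast, FDR-adjusted across the per-bin family.
#'
#' @param profiles A `connectivity_profile` over subjects.
#' @return List with `anova` (per area) and `contrasts` (per area x bin,
#'   with `q` column), both `stat_result` data.frames.
#' @export
profile_group_stats <- function(profiles) {
  areas <- unique(profiles$area)
  bins <- unique(profiles$bin)
  anova_list <- lapply(areas, function(a) {
    out <- rm_anova_2way(profiles[profiles$area == a, ])
    out$area <- a
    out
  })
  contr <- do.call(rbind, lapply(areas, function(a) {
    do.call(rbind, lapply(bins, function(b) {
      sub <- profiles[profiles$area == a & profiles$bin == b, ]
      wide <- stats::reshape(sub[, c("subject", "condition", "z")],
                             idvar = "subject", timevar = "condition",
                             direction = "wide")
      tt <- paired_t(wide$z.focal, wide$z.diffused)
      data.frame(area = a, bin = b, statistic = tt$statistic, df = tt$df,
                 p = tt$p, mean_diff = tt$mean_diff)
    }))
  }))
  contr$q <- NA_real_
  for (a in areas) {
    i <- contr$area == a
    contr$q[i] <- fdr_adjust(contr$p[i])
  }
  list(anova = do.call(rbind, anova_list), contrasts = contr)
}
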