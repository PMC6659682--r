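# Empirical-Bayes moderated one-sample t-test, BH FDR, AP-MS bait
# enrichment. Implemented from the closed-form equations; not delegated to a
# statistics library (library implementations serve as cross-checks in the
# test suite only).

# Newton inversion of the trigamma function; x > 0.
.trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Fit the variance prior by moment matching on log-variances
#'
#' Fits a scaled inverse-chi-square prior (hyperparameters `d0`, prior
#' degrees of freedom, and `s0_squared`, prior variance) to per-site sample
#' variances, each on `df` residual degrees of freedom. Under the model
#' `s^2 | sigma^2 ~ sigma^2 chi^2_df / df` with
#' `1/sigma^2 ~ chi^2_d0 / (d0 s0^2)`, the log sample variances have mean and
#' variance expressible through digamma/trigamma functions; the fit inverts
#' those two equations (method of moments on the log scale). When the
#' observed spread of log-variances does not exceed the sampling floor
#' `trigamma(df/2)`, there is no evidence of variance heterogeneity and
#' `d0 = Inf` is returned with `s0_squared` equal to the mean variance.
#'
#' @param variances numeric vector of sample variances; non-finite and
#'   non-positive entries are ignored (at least 2 must remain).
#' @param df residual degrees of freedom of each variance (scalar).
#' @return list with `d0` (possibly `Inf`) and `s0_squared`.
#' @export
estimate_prior <- function(variances, df) {
  stopifnot(length(df) == 1L, df >= 1)
  if (length(variances) >= 2L && all(!is.na(variances) & variances == 0)) {
    .stop_phosfx("phosfx_degenerate_error",
                 "all variances are zero; prior is undefined")
  }
  v <- variances[is.finite(variances) & variances > 0]
  if (length(v) < 2L) {
    .stop_phosfx("phosfx_input_error",
                 "need at least 2 finite positive variances, got %d", length(v))
  }
  e <- log(v) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_squared <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no evidence of variance heterogeneity: point-mass prior at the mean
    d0 <- Inf
    s0_squared <- mean(v)
  }
  list(d0 = d0, s0_squared = s0_squared)
}

#' Moderated one-sample t-test on replicate log2 ratios
#'
#' Tests mean 0 with the empirical-Bayes shrunken variance
#' `s2_post = (d0 s0^2 + d s^2) / (d0 + d)` where `d = n - 1`;
#' `t = mean / sqrt(s2_post / n)` on `d0 + d` degrees of freedom, two-sided.
#' With `d0 = 0` this is the ordinary one-sample t-test; with `d0 = Inf` the
#' variance is fully pooled and the reference distribution is normal.
#'
#' @param values numeric vector of replicate log2 ratios (`NA` dropped).
#' @param d0 prior degrees of freedom (may be 0 or `Inf`).
#' @param s0_squared prior variance.
#' @return list: `n`, `mean_log2fc`, `s2`, `s2_post`, `t_mod`, `df_total`,
#'   `p`. All statistics are `NA` when fewer than 2 values are available.
#' @export
moderated_t <- function(values, d0, s0_squared) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 2L) {
    return(list(n = n, mean_log2fc = if (n) mean(v) else NA_real_,
                s2 = NA_real_, s2_post = NA_real_, t_mod = NA_real_,
                df_total = NA_real_, p = NA_real_))
  }
  d <- n - 1
  m <- mean(v)
  s2 <- stats::var(v)
  if (is.infinite(d0)) {
    s2_post <- s0_squared
  } else if (d0 == 0) {
    s2_post <- s2
  } else {
    s2_post <- (d0 * s0_squared + d * s2) / (d0 + d)
  }
  t_mod <- m / sqrt(s2_post / n)
  df_total <- d0 + d
  p <- if (is.infinite(df_total)) {
    2 * stats::pnorm(-abs(t_mod))
  } else {
    2 * stats::pt(-abs(t_mod), df = df_total)
  }
  p <- max(p, .Machine$double.xmin)  # guard underflow; p must stay in (0, 1]
  list(n = n, mean_log2fc = m, s2 = s2, s2_post = s2_post,
       t_mod = t_mod, df_total = df_total, p = p)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `fdr[i] = min_{j: p_j >= p_i} (n * p_j / rank_j)`, capped at 1; monotone
#' non-decreasing in p.
#'
#' @param pvalues numeric vector with all values in `(0, 1]`; `NA`s are
#'   propagated and excluded from the ranking.
#' @return adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p <= 0 | p > 1)) {
    .stop_phosfx("phosfx_input_error", "p-values must lie in (0, 1]")
  }
  n <- length(p)
  out <- rep(NA_real_, length(pvalues))
  if (n) {
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(n / seq(n, 1) * p[o]))[order(o)]
    out[ok] <- adj
  }
  out
}

#' AP-MS bait enrichment z-score
#'
#' Enrichment of a bait protein in its own pulldowns relative to control
#' pulldowns: `z = (mean(bait) - mean(control)) / sd(control)`. Missing
#' intensities are imputed with a floor value (default: half the smallest
#' observed non-zero intensity across both groups) before the statistic is
#' computed, mirroring how undetected proteins are handled in affinity
#' purification scoring.
#'
#' @param bait_intensities,control_intensities numeric vectors (`NA` =
#'   not detected).
#' @param floor imputation value for missing intensities; default half the
#'   smallest observed positive intensity.
#' @return z-score; `+Inf` (with a warning) when the controls have zero
#'   spread after imputation.
#' @export
bait_enrichment_z <- function(bait_intensities, control_intensities, floor = NULL) {
  if (all(is.na(control_intensities))) {
    .stop_phosfx("phosfx_input_error", "all control intensities missing")
  }
  if (length(control_intensities) < 2L) {
    .stop_phosfx("phosfx_input_error", "need at least 2 control intensities")
  }
  if (is.null(floor)) {
    obs <- c(bait_intensities, control_intensities)
    obs <- obs[!is.na(obs) & obs > 0]
    floor <- if (length(obs)) min(obs) / 2 else 0
  }
  bait <- ifelse(is.na(bait_intensities), floor, bait_intensities)
  ctrl <- ifelse(is.na(control_intensities), floor, control_intensities)
  s <- stats::sd(ctrl)
  num <- mean(bait) - mean(ctrl)
  if (s == 0) {
    if (num == 0) return(0)
    warning("control intensities have zero spread; z-score is infinite")
    return(sign(num) * Inf)
  }
  num / s
}

#' Moderated test over a normalized site table
#'
#' Runs the moderated one-sample t-test per site within each condition.
#' Sites with fewer than `min_reps` non-missing replicate log2 ratios are
#' reported with `NA` statistics. The variance prior is estimated per
#' condition by pooling the sample variances of all testable sites (using
#' the modal residual df when replicate counts are mixed) and applied with
#' each site's own residual df. FDR correction is Benjamini-Hochberg, by
#' default within each condition.
#'
#' @param normalized output of [normalize_sites()].
#' @param min_reps minimum non-missing replicates required to test a site
#'   (default 2).
#' @param prior optional list `(d0, s0_squared)` to reuse a fitted prior;
#'   default estimates it from the data per condition.
#' @param global_fdr if `TRUE`, apply BH across all conditions jointly
#'   instead of within condition.
#' @return data.frame with one row per site x condition: `site_id`,
#'   `condition`, `n_obs`, `mean_log2fc`, `summary_log2fc` (median),
#'   `s2`, `s2_post`, `t_mod`, `df_total`, `p`, `fdr`, `protein_normalized`.
#' @export
moderated_test <- function(normalized, min_reps = 2L, prior = NULL,
                           global_fdr = FALSE) {
  stopifnot(min_reps >= 2L)
  summ <- summarize_sites(normalized)
  conds <- unique(normalized$condition)
  res_list <- lapply(conds, function(cond) {
    nc <- normalized[normalized$condition == cond, ]
    vals <- split(nc$log2fc, nc$site_id)
    ids <- names(vals)
    n_obs <- vapply(vals, function(v) sum(!is.na(v)), 0L)
    means <- vapply(vals, function(v) mean(v, na.rm = TRUE), 0)
    s2 <- vapply(vals, function(v) stats::var(v[!is.na(v)]), 0)
    testable <- n_obs >= min_reps
    pr <- prior
    if (is.null(pr)) {
      dfs <- n_obs[testable] - 1L
      df_modal <- as.integer(names(which.max(table(dfs))))
      pr <- estimate_prior(s2[testable][dfs == df_modal], df_modal)
    }
    out <- data.frame(
      site_id = ids, condition = cond, n_obs = n_obs,
      mean_log2fc = ifelse(n_obs >= 1L, means, NA_real_),
      s2 = NA_real_, s2_post = NA_real_, t_mod = NA_real_,
      df_total = NA_real_, p = NA_real_, stringsAsFactors = FALSE
    )
    for (i in which(testable)) {
      mt <- moderated_t(vals[[i]], pr$d0, pr$s0_squared)
      out$s2[i] <- mt$s2; out$s2_post[i] <- mt$s2_post
      out$t_mod[i] <- mt$t_mod; out$df_total[i] <- mt$df_total
      out$p[i] <- mt$p
    }
    out
  })
  res <- do.call(rbind, res_list)
  if (global_fdr) {
    res$fdr <- bh_fdr(res$p)
  } else {
    res$fdr <- NA_real_
    for (cond in conds) {
      sel <- res$condition == cond
      res$fdr[sel] <- bh_fdr(res$p[sel])
    }
  }
  res <- merge(res, summ[, c("site_id", "condition", "summary_log2fc",
                             "protein_normalized")],
               by = c("site_id", "condition"), sort = FALSE)
  rownames(res) <- NULL
  res
}
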