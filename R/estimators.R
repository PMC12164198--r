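#' Single-method causal-effect result
#'
#' @param method one of `"wald_ratio"`, `"ivw"`, `"egger"`,
#'   `"weighted_median"`, `"presso_raw"`, `"presso_corrected"`.
#' @param estimate,se point estimate (log-odds-ratio scale for a binary
#'   outcome) and standard error.
#' @param pval two-sided p-value.
#' @param n_snps number of variants used.
#' @param ci_level confidence level for the normal-quantile display interval.
#' @return object of class `mr_result`.
#' @export
mr_result <- function(method, estimate, se, pval, n_snps, ci_level = 0.95) {
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(list(method = method,
                 estimate = estimate,
                 se = se,
                 ci_low = estimate - z * se,
                 ci_high = estimate + z * se,
                 pval = pval,
                 n_snps = as.integer(n_snps)),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  or <- to_odds_ratio(x)
  cat(sprintf("<mr_result> %s (k = %d): lnOR %.4f (95%% CI %.4f, %.4f), SE %.4f, p = %.4g\n         OR %.3f (95%% CI %.3f, %.3f)\n",
              x$method, x$n_snps, x$estimate, x$ci_low, x$ci_high, x$se,
              x$pval, or$or, or$ci_low, or$ci_high))
  invisible(x)
}

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

unpack_hs <- function(hs, min_k, what) {
  stopifnot(inherits(hs, "harmonized_set"))
  v <- hs$variants
  if (nrow(v) < min_k)
    abort_mr(sprintf("%s requires at least %d variants (got %d)",
                     what, min_k, nrow(v)), "mrscreen_too_few")
  v
}

# Core zero-intercept weighted fit shared by ivw, Q, leave-one-out, PRESSO.
ivw_fit <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxx <- sum(w * bx^2)
  est <- sum(w * bx * by) / sxx
  q <- sum(w * (by - est * bx)^2)
  list(estimate = est, se_fixed = 1 / sqrt(sxx), q = q, k = length(bx))
}

# Weighted least squares with intercept after orienting every variant to the
# exposure-increasing allele. Returns slope/intercept with SEs scaled by
# sqrt(max(1, Q/(k-2))) and t-based p-values (k-2 df).
egger_fit <- function(bx, by, sy) {
  flip <- bx < 0
  bx <- ifelse(flip, -bx, bx)
  by <- ifelse(flip, -by, by)
  w <- 1 / sy^2
  k <- length(bx)
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  q <- sum(w * (by - intercept - slope * bx)^2)
  scale <- sqrt(max(1, q / (k - 2)))
  se_slope <- sqrt(sw / det) * scale
  se_int <- sqrt(swxx / det) * scale
  list(slope = slope, se_slope = se_slope,
       p_slope = 2 * stats::pt(-abs(slope / se_slope), df = k - 2),
       intercept = intercept, se_intercept = se_int,
       p_intercept = 2 * stats::pt(-abs(intercept / se_int), df = k - 2),
       q = q, k = k)
}

#' Wald ratio estimate for a single variant
#'
#' @param v one-row data.frame (or list) with `beta_exp`, `beta_out`,
#'   `se_out`, or a [harmonized_set()] with exactly one variant.
#' @return an [mr_result()] with `estimate = beta_out / beta_exp` and
#'   first-order `se = |se_out / beta_exp|`.
#' @export
mr_wald_ratio <- function(v) {
  if (inherits(v, "harmonized_set")) {
    v <- unpack_hs(v, 1L, "wald ratio")
    if (nrow(v) != 1L)
      abort_mr("wald ratio is a single-variant estimator", "mrscreen_bad_input")
  }
  if (v$beta_exp == 0)
    abort_mr("wald ratio undefined for beta_exp = 0", "mrscreen_bad_input")
  est <- v$beta_out / v$beta_exp
  se <- abs(v$se_out / v$beta_exp)
  mr_result("wald_ratio", est, se, two_sided_p(est / se), 1L)
}

#' Inverse-variance weighted estimator
#'
#' Zero-intercept regression of outcome on exposure effects with weights
#' `1/se_out^2`; the primary causal estimator. With
#' `mode = "multiplicative_random"` (default) the fixed-effect SE is
#' inflated by `sqrt(max(1, Q/(k-1)))`, truncating underdispersion at 1.
#' A single-variant set delegates to [mr_wald_ratio()].
#'
#' @param hs a [harmonized_set()].
#' @param mode `"multiplicative_random"` or `"fixed"`.
#' @return an [mr_result()] (normal two-sided p).
#' @export
mr_ivw <- function(hs, mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  v <- unpack_hs(hs, 1L, "IVW")
  if (nrow(v) == 1L) return(mr_wald_ratio(v))
  fit <- ivw_fit(v$beta_exp, v$beta_out, v$se_out)
  se <- fit$se_fixed
  if (mode == "multiplicative_random")
    se <- se * sqrt(max(1, fit$q / (fit$k - 1)))
  mr_result("ivw", fit$estimate, se,
            two_sided_p(fit$estimate / se), fit$k)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects *with* intercept,
#' after orienting each variant to its exposure-increasing allele. A
#' non-zero intercept estimates the average directional pleiotropic effect;
#' the slope remains consistent under the InSIDE assumption. SEs use
#' multiplicative dispersion truncated at 1; p-values use the t
#' distribution with k-2 degrees of freedom.
#'
#' @param hs a [harmonized_set()] with at least 3 variants.
#' @return object of class `mr_egger_result`: `$slope` is an [mr_result()];
#'   `$intercept`, `$intercept_se`, `$intercept_pval` describe the
#'   pleiotropy test.
#' @export
mr_egger <- function(hs) {
  v <- unpack_hs(hs, 3L, "MR-Egger")
  fit <- egger_fit(v$beta_exp, v$beta_out, v$se_out)
  slope <- mr_result("egger", fit$slope, fit$se_slope, fit$p_slope, fit$k)
  structure(list(slope = slope,
                 intercept = fit$intercept,
                 intercept_se = fit$se_intercept,
                 intercept_pval = fit$p_intercept),
            class = "mr_egger_result")
}

#' @export
print.mr_egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept %.4f (SE %.4f), p = %.4g\n",
              x$intercept, x$intercept_se, x$intercept_pval))
  invisible(x)
}

# Weighted median of per-variant ratio estimates: linear interpolation of the
# sorted ratios at standardized cumulative weight 1/2.
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  ratio <- ratio[ord]
  weight <- weight[ord]
  p <- (cumsum(weight) - weight / 2) / sum(weight)
  if (p[1] >= 0.5) return(ratio[1])
  if (p[length(p)] <= 0.5) return(ratio[length(p)])
  stats::approx(p, ratio, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' Median of per-variant Wald ratios under inverse-variance weights
#' `beta_exp^2 / se_out^2`; consistent when variants carrying more than half
#' of the weight are valid instruments. The SE is a parametric bootstrap:
#' exposure and outcome effects are resampled from
#' `Normal(beta, se^2)` and the weighted median recomputed `n_boot` times.
#'
#' @param hs a [harmonized_set()] with at least 3 variants.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap; same seed gives identical SE.
#' @return an [mr_result()] (normal two-sided p).
#' @export
mr_weighted_median <- function(hs, n_boot = 1000, seed = NULL) {
  v <- unpack_hs(hs, 3L, "weighted median")
  if (any(v$beta_exp == 0))
    abort_mr("weighted median undefined with beta_exp = 0", "mrscreen_bad_input")
  ratio <- v$beta_out / v$beta_exp
  weight <- v$beta_exp^2 / v$se_out^2
  est <- weighted_median_point(ratio, weight)
  k <- nrow(v)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(k, v$beta_exp, v$se_exp)
      by <- stats::rnorm(k, v$beta_out, v$se_out)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / v$se_out[ok]^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_result("weighted_median", est, se, two_sided_p(est / se), k)
}

# Leave-one-out IVW estimates for every variant at once (fixed effect).
loo_ivw_estimates <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

presso_rss <- function(bx, by, sy) {
  est_loo <- loo_ivw_estimates(bx, by, sy)
  w <- 1 / sy^2
  resid2 <- w * (by - est_loo * bx)^2
  list(rss = sum(resid2), resid2 = resid2)
}

#' MR-PRESSO global, outlier, and distortion tests
#'
#' Residual-sum-of-squares resampling framework for horizontal pleiotropy.
#' The observed RSS sums, over variants, the weighted squared deviation of
#' each outcome effect from its leave-one-out IVW prediction. The null
#' distribution is built by `n_sim` parametric simulations (outcome effects
#' from `Normal(loo-prediction, se_out^2)`; exposure effects, when
#' `sim_exposure = TRUE`, from `Normal(beta_exp, se_exp^2)`). Per-variant
#' outlier p-values are the empirical tail of each variant's own simulated
#' residual; variants with Bonferroni-corrected p below `outlier_alpha` are
#' flagged, an outlier-corrected IVW estimate is computed, and a distortion
#' test compares the raw/corrected difference against differences obtained
#' by removing random variant subsets of the same size.
#'
#' @param hs a [harmonized_set()] with at least 4 variants; with fewer a
#'   `presso_not_testable` marker is returned instead of an error.
#' @param n_sim simulated datasets for the null distribution (default 1000).
#' @param outlier_alpha familywise outlier significance level (default 0.05;
#'   per-variant threshold is `outlier_alpha / k`).
#' @param seed RNG seed; same seed reproduces all p-values.
#' @param sim_exposure also resample exposure effects (default TRUE).
#' @return object of class `mr_presso_result` with elements `global_rss`,
#'   `global_pval`, `outlier_indices`, `outlier_pvals`, `raw`
#'   ([mr_result()]), `corrected` (present iff outliers were detected) and
#'   `distortion_pval`.
#' @export
mr_presso <- function(hs, n_sim = 1000, outlier_alpha = 0.05, seed = NULL,
                      sim_exposure = TRUE) {
  stopifnot(inherits(hs, "harmonized_set"))
  v <- hs$variants
  k <- nrow(v)
  raw <- mr_ivw(hs)
  if (k < 4L)
    return(structure(list(testable = FALSE, reason = "fewer than 4 variants",
                          raw = raw, n_snps = k),
                     class = c("presso_not_testable", "mr_presso_result")))
  bx <- v$beta_exp; by <- v$beta_out
  sx <- v$se_exp; sy <- v$se_out
  obs <- presso_rss(bx, by, sy)
  pred <- loo_ivw_estimates(bx, by, sy) * bx

  out <- with_seed(seed, {
    sim_rss <- numeric(n_sim)
    exceed <- numeric(k)    # per-variant count of simulated resid2 >= observed
    for (s in seq_len(n_sim)) {
      by_s <- stats::rnorm(k, pred, sy)
      bx_s <- if (sim_exposure) stats::rnorm(k, bx, sx) else bx
      sim <- presso_rss(bx_s, by_s, sy)
      sim_rss[s] <- sim$rss
      exceed <- exceed + (sim$resid2 >= obs$resid2)
    }
    global_pval <- (sum(sim_rss >= obs$rss) + 1) / (n_sim + 1)
    outlier_pvals <- (exceed + 1) / (n_sim + 1)
    flagged <- which(outlier_pvals * k < outlier_alpha)

    corrected <- NULL
    distortion_pval <- NA_real_
    if (length(flagged) > 0L && (k - length(flagged)) >= 2L) {
      keepv <- setdiff(seq_len(k), flagged)
      hs_cor <- hs
      hs_cor$variants <- v[keepv, , drop = FALSE]
      corrected <- mr_ivw(hs_cor)
      corrected$method <- "presso_corrected"
      d_obs <- raw$estimate - corrected$estimate
      d_sim <- vapply(seq_len(n_sim), function(s) {
        drop_idx <- sample(keepv, length(flagged), replace = length(flagged) > length(keepv))
        keep_s <- setdiff(seq_len(k), drop_idx)
        fit <- ivw_fit(bx[keep_s], by[keep_s], sy[keep_s])
        raw$estimate - fit$estimate
      }, numeric(1))
      distortion_pval <- (sum(abs(d_sim) >= abs(d_obs)) + 1) / (n_sim + 1)
    }
    list(global_pval = global_pval, outlier_pvals = outlier_pvals,
         flagged = flagged, corrected = corrected,
         distortion_pval = distortion_pval)
  })
  raw$method <- "presso_raw"
  structure(list(testable = TRUE,
                 global_rss = obs$rss,
                 global_pval = out$global_pval,
                 outlier_indices = out$flagged,
                 outlier_pvals = out$outlier_pvals,
                 raw = raw,
                 corrected = out$corrected,
                 distortion_pval = out$distortion_pval,
                 n_snps = k),
            class = "mr_presso_result")
}

#' @export
print.mr_presso_result <- function(x, ...) {
  if (isFALSE(x$testable)) {
    cat(sprintf("<mr_presso_result> not testable: %s\n", x$reason))
    return(invisible(x))
  }
  cat(sprintf("<mr_presso_result> RSSobs %.3f, global p = %.4g, %d outlier(s)\n",
              x$global_rss, x$global_pval, length(x$outlier_indices)))
  print(x$raw)
  if (!is.null(x$corrected)) {
    print(x$corrected)
    cat(sprintf("  distortion p = %.4g\n", x$distortion_pval))
  }
  invisible(x)
}

#' Convert a log-odds estimate to an odds-ratio display
#'
#' @param m an [mr_result()], or a numeric estimate with `ci_low`/`ci_high`.
#' @param digits rounding for display (default 3, as conventionally printed).
#' @return list with `or`, `ci_low`, `ci_high` (rounded).
#' @export
to_odds_ratio <- function(m, digits = 3) {
  if (inherits(m, "mr_result"))
    return(list(or = round(exp(m$estimate), digits),
                ci_low = round(exp(m$ci_low), digits),
                ci_high = round(exp(m$ci_high), digits)))
  list(or = round(exp(m), digits))
}
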