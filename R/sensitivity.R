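#' Cochran's Q heterogeneity test
#'
#' Weighted residual heterogeneity of the per-variant outcome effects around
#' the fitted IVW (zero-intercept) or Egger (with-intercept) regression,
#' with weights `1/se_out^2`. Under homogeneity Q is chi-square with k-1
#' (IVW) or k-2 (Egger) degrees of freedom; `pval` is the upper tail.
#'
#' @param hs a [harmonized_set()].
#' @param model `"ivw"` (k >= 2) or `"egger"` (k >= 3).
#' @return object of class `mr_q_result` with `model`, `q`, `df`, `pval`.
#' @export
mr_cochran_q <- function(hs, model = c("ivw", "egger")) {
  model <- match.arg(model)
  min_k <- if (model == "ivw") 2L else 3L
  v <- unpack_hs(hs, min_k, paste0("Cochran's Q (", model, ")"))
  if (model == "ivw") {
    fit <- ivw_fit(v$beta_exp, v$beta_out, v$se_out)
    q <- fit$q
    df <- fit$k - 1L
  } else {
    fit <- egger_fit(v$beta_exp, v$beta_out, v$se_out)
    q <- fit$q
    df <- fit$k - 2L
  }
  structure(list(model = model, q = q, df = as.integer(df),
                 pval = stats::pchisq(q, df = df, lower.tail = FALSE)),
            class = "mr_q_result")
}

#' @export
print.mr_q_result <- function(x, ...) {
  cat(sprintf("<mr_q_result> Cochran's Q via %s: Q = %.3f, df = %d, p = %.4g\n",
              toupper(x$model), x$q, x$df, x$pval))
  invisible(x)
}

#' Leave-one-out influence analysis
#'
#' Refits the IVW estimator k times, omitting each variant once. A variant
#' is flagged influential when its omission flips the sign of the estimate
#' or moves it outside the all-variant confidence interval.
#'
#' @param hs a [harmonized_set()] with at least 3 variants.
#' @param mode IVW mode, passed to [mr_ivw()].
#' @return object of class `mr_loo_series`: data.frame `$series` (one row per
#'   left-out variant: estimate, se, ci, p, influential flag) plus `$full`,
#'   the all-variant [mr_result()].
#' @export
mr_leave_one_out <- function(hs, mode = "multiplicative_random") {
  v <- unpack_hs(hs, 3L, "leave-one-out")
  full <- mr_ivw(hs, mode = mode)
  rows <- lapply(seq_len(nrow(v)), function(j) {
    hs_j <- hs
    hs_j$variants <- v[-j, , drop = FALSE]
    fit <- mr_ivw(hs_j, mode = mode)
    data.frame(left_out = v$variant_id[j],
               estimate = fit$estimate, se = fit$se,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               pval = fit$pval, n_snps = fit$n_snps,
               stringsAsFactors = FALSE)
  })
  series <- do.call(rbind, rows)
  series$influential <- sign(series$estimate) != sign(full$estimate) |
    series$estimate < full$ci_low | series$estimate > full$ci_high
  structure(list(series = series, full = full), class = "mr_loo_series")
}

#' @export
print.mr_loo_series <- function(x, ...) {
  cat(sprintf("<mr_loo_series> %d refits; full estimate %.4f (%.4f, %.4f); %d influential variant(s)\n",
              nrow(x$series), x$full$estimate, x$full$ci_low, x$full$ci_high,
              sum(x$series$influential)))
  invisible(x)
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure versus the
#' outcome. Per-variant variance explained uses the t-statistic
#' approximation `r2_j = t^2 / (t^2 + n - 2)` with `t = beta/se`, summed over
#' instruments for each trait (for a binary outcome this is on the observed
#' log-odds scale). `direction` is `TRUE` when the exposure r2 is strictly
#' larger; the p-value is a two-sided z test on the Fisher-transformed
#' correlations `r = sqrt(r2)` with variance `1/(n_exp-3) + 1/(n_out-3)`.
#'
#' @param hs a [harmonized_set()]; `n_exposure`/`n_outcome` are needed for
#'   the p-value (direction is still computed when they are missing).
#' @return object of class `mr_steiger_result` with `r2_exposure`,
#'   `r2_outcome`, `direction`, `pval`.
#' @export
mr_steiger <- function(hs) {
  v <- unpack_hs(hs, 1L, "Steiger test")
  n_exp <- hs$n_exposure
  n_out <- hs$n_outcome
  r2_one <- function(beta, se, n) {
    if (is.na(n)) return(NA_real_)
    t2 <- (beta / se)^2
    sum(t2 / (t2 + n - 2))
  }
  # direction itself only needs the ratio t^2/(t^2+n-2); when n is missing
  # fall back to a large-n comparison of summed squared z-scores.
  r2_exp <- r2_one(v$beta_exp, v$se_exp, n_exp)
  r2_out <- r2_one(v$beta_out, v$se_out, n_out)
  if (is.na(r2_exp) || is.na(r2_out)) {
    z2_exp <- sum((v$beta_exp / v$se_exp)^2)
    z2_out <- sum((v$beta_out / v$se_out)^2)
    direction <- z2_exp > z2_out
    pval <- NA_real_
  } else {
    direction <- r2_exp > r2_out
    r_exp <- sqrt(min(r2_exp, 1 - 1e-12))
    r_out <- sqrt(min(r2_out, 1 - 1e-12))
    z <- (atanh(r_exp) - atanh(r_out)) /
      sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
    pval <- two_sided_p(z)
  }
  structure(list(r2_exposure = r2_exp, r2_outcome = r2_out,
                 direction = direction, pval = pval),
            class = "mr_steiger_result")
}

#' @export
print.mr_steiger_result <- function(x, ...) {
  cat(sprintf("<mr_steiger_result> r2 exposure %.4g vs outcome %.4g: direction %s, p = %.3g\n",
              x$r2_exposure, x$r2_outcome, x$direction, x$pval))
  invisible(x)
}

#' Full sensitivity suite for one exposure-outcome pair
#'
#' Convenience wrapper returning both Q tests, the Egger intercept test,
#' the leave-one-out series and the Steiger test.
#'
#' @param hs a [harmonized_set()] with at least 3 variants.
#' @return list of class `mr_sensitivity_suite` with elements `q_ivw`,
#'   `q_egger`, `egger_intercept` (from [mr_egger()]), `loo`, `steiger`.
#' @export
mr_sensitivity <- function(hs) {
  egger <- mr_egger(hs)
  structure(list(q_ivw = mr_cochran_q(hs, "ivw"),
                 q_egger = mr_cochran_q(hs, "egger"),
                 egger_intercept = list(intercept = egger$intercept,
                                        se = egger$intercept_se,
                                        pval = egger$intercept_pval),
                 loo = mr_leave_one_out(hs),
                 steiger = mr_steiger(hs)),
            class = "mr_sensitivity_suite")
}
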