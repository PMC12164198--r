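#' Bonferroni-corrected significance threshold
#'
#' @param alpha familywise level (default 0.05).
#' @param m number of tests (e.g. number of exposures screened).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (length(m) != 1L || is.na(m) || m < 1)
    abort_mr("m must be a positive integer", "mrscreen_bad_input")
  alpha / m
}

#' Screen configuration
#'
#' Bundles every tunable of [mr_screen()]: instrument-selection thresholds,
#' estimator settings and seeds, and the multiple-testing setup.
#'
#' @param pval_threshold,r2_max,window_kb,f_min,outcome_pval,min_instruments
#'   instrument-selection thresholds, see [select_instruments()].
#' @param ivw_mode `"multiplicative_random"` or `"fixed"`.
#' @param n_boot weighted-median bootstrap replicates.
#' @param n_sim MR-PRESSO simulations.
#' @param seed master seed; each exposure gets a derived child seed so any
#'   single trait is independently reproducible.
#' @param alpha nominal significance level (default 0.05).
#' @param n_exposures_for_bonferroni divisor for the Bonferroni threshold;
#'   `NULL` (default) uses the number of exposures actually screened.
#' @param palindrome_policy passed to [harmonize()].
#' @return list of class `screen_config`.
#' @export
screen_config <- function(pval_threshold = 1e-5, r2_max = 0.1,
                          window_kb = 500, f_min = 10, outcome_pval = 1e-5,
                          min_instruments = 3,
                          ivw_mode = "multiplicative_random",
                          n_boot = 1000, n_sim = 1000, seed = 1L,
                          alpha = 0.05, n_exposures_for_bonferroni = NULL,
                          palindrome_policy = "drop_ambiguous") {
  stopifnot(pval_threshold > 0, pval_threshold <= 1,
            r2_max >= 0, r2_max <= 1, window_kb > 0, f_min >= 0,
            outcome_pval > 0, outcome_pval <= 1,
            min_instruments >= 1, n_boot >= 2, n_sim >= 2,
            alpha > 0, alpha < 1, !is.null(seed))
  structure(list(pval_threshold = pval_threshold, r2_max = r2_max,
                 window_kb = window_kb, f_min = f_min,
                 outcome_pval = outcome_pval,
                 min_instruments = min_instruments,
                 ivw_mode = ivw_mode, n_boot = n_boot, n_sim = n_sim,
                 seed = as.integer(seed), alpha = alpha,
                 n_exposures_for_bonferroni = n_exposures_for_bonferroni,
                 palindrome_policy = palindrome_policy),
            class = "screen_config")
}

#' Classify exposures as strong / robust / potential / not significant
#'
#' Vectorised classification rule of the screen:
#' \describe{
#'   \item{not_significant}{IVW p >= `alpha`.}
#'   \item{potential}{IVW p < `alpha` only.}
#'   \item{robust}{IVW p < `alpha`, at least two of the Egger /
#'     weighted-median / PRESSO p-values < `alpha`, and the IVW, Egger and
#'     weighted-median estimates share the same direction.}
#'   \item{strong}{IVW p below the Bonferroni-corrected threshold.}
#' }
#' Labels are mutually exclusive with precedence
#' strong > robust > potential > not_significant. All comparisons are
#' strict (`<`); missing supplementary results count as non-significant.
#'
#' @param ivw_p,egger_p,wm_p,presso_p per-method p-values (vectors).
#' @param ivw_sign,egger_sign,wm_sign signs of the respective estimates
#'   (+1/-1, or the estimates themselves).
#' @param bonferroni Bonferroni-corrected threshold, see
#'   [bonferroni_threshold()].
#' @param alpha nominal level (default 0.05).
#' @return data.frame with `flag` (character) and `direction_consistent`
#'   (logical; reported regardless of significance).
#' @export
classify_candidates <- function(ivw_p, ivw_sign, egger_p, egger_sign,
                                wm_p, wm_sign, presso_p,
                                bonferroni, alpha = 0.05) {
  n <- length(ivw_p)
  sig <- function(p) !is.na(p) & p < alpha
  dir_consistent <- !is.na(ivw_sign) & !is.na(egger_sign) & !is.na(wm_sign) &
    sign(ivw_sign) == sign(egger_sign) & sign(ivw_sign) == sign(wm_sign)
  n_supp <- sig(egger_p) + sig(wm_p) + sig(presso_p)
  ivw_sig <- sig(ivw_p)
  flag <- rep("not_significant", n)
  flag[ivw_sig] <- "potential"
  flag[ivw_sig & n_supp >= 2 & dir_consistent] <- "robust"
  flag[!is.na(ivw_p) & ivw_p < bonferroni] <- "strong"
  data.frame(flag = flag, direction_consistent = dir_consistent,
             stringsAsFactors = FALSE)
}

# Run estimators + sensitivity suite on one selected instrument set and
# flatten everything into a single results row.
screen_one <- function(hs, exposure, cfg, bonferroni, seed) {
  ivw <- mr_ivw(hs, mode = cfg$ivw_mode)
  egger <- mr_egger(hs)
  wm <- mr_weighted_median(hs, n_boot = cfg$n_boot, seed = seed)
  presso <- mr_presso(hs, n_sim = cfg$n_sim, seed = child_seed(seed, 1L))
  q_ivw <- mr_cochran_q(hs, "ivw")
  q_egger <- mr_cochran_q(hs, "egger")
  loo <- mr_leave_one_out(hs, mode = cfg$ivw_mode)
  steiger <- mr_steiger(hs)
  # reporting scale follows the usual presentation: PRESSO column shows the
  # outlier-corrected estimate when outliers were found, else the raw one
  presso_est <- if (!is.null(presso$corrected)) presso$corrected else presso$raw
  presso_p <- if (isTRUE(presso$testable)) presso_est$pval else NA_real_
  cls <- classify_candidates(ivw$pval, ivw$estimate,
                             egger$slope$pval, egger$slope$estimate,
                             wm$pval, wm$estimate, presso_p,
                             bonferroni = bonferroni, alpha = cfg$alpha)
  or <- to_odds_ratio(ivw)
  data.frame(
    trait_id = exposure$trait_id, trait_label = exposure$trait_label,
    category = exposure$category, status = "ok", n_iv = nrow(hs$variants),
    ivw_lnor = ivw$estimate, ivw_se = ivw$se,
    ivw_ci_low = ivw$ci_low, ivw_ci_high = ivw$ci_high, ivw_p = ivw$pval,
    ivw_or = or$or, ivw_or_low = or$ci_low, ivw_or_high = or$ci_high,
    egger_lnor = egger$slope$estimate, egger_se = egger$slope$se,
    egger_p = egger$slope$pval,
    wm_lnor = wm$estimate, wm_se = wm$se, wm_p = wm$pval,
    presso_lnor = presso_est$estimate, presso_se = presso_est$se,
    presso_p = presso_p,
    presso_rss = if (isTRUE(presso$testable)) presso$global_rss else NA_real_,
    presso_global_p = if (isTRUE(presso$testable)) presso$global_pval else NA_real_,
    presso_n_outliers = if (isTRUE(presso$testable)) length(presso$outlier_indices) else NA_integer_,
    q_ivw = q_ivw$q, q_ivw_df = q_ivw$df, q_ivw_p = q_ivw$pval,
    q_egger = q_egger$q, q_egger_df = q_egger$df, q_egger_p = q_egger$pval,
    no_heterogeneity = q_ivw$pval > cfg$alpha,
    egger_intercept = egger$intercept, egger_intercept_se = egger$intercept_se,
    egger_intercept_p = egger$intercept_pval,
    n_influential_loo = sum(loo$series$influential),
    steiger_r2_exposure = steiger$r2_exposure,
    steiger_r2_outcome = steiger$r2_outcome,
    steiger_direction = steiger$direction, steiger_p = steiger$pval,
    flag = cls$flag, direction_consistent = cls$direction_consistent,
    stringsAsFactors = FALSE)
}

empty_verdict_row <- function(exposure, log) {
  data.frame(trait_id = exposure$trait_id, trait_label = exposure$trait_label,
             category = exposure$category, status = "insufficient instruments",
             n_iv = unname(log["after_outcome_exclusion"]) %||% 0L,
             flag = "not_testable", stringsAsFactors = FALSE)
}

#' Screen many exposures against one outcome
#'
#' For each exposure runs the full chain: exposure p-value filter, LD
#' clumping, F filter, harmonization, outcome-association exclusion, the
#' four estimators, the sensitivity suite, and classification against the
#' Bonferroni threshold. Deterministic given `cfg$seed` (each exposure uses
#' a derived child seed).
#'
#' @param exposures list of [summary_dataset()] objects.
#' @param outcome a [summary_dataset()].
#' @param ld an [ld_source()].
#' @param cfg a [screen_config()].
#' @return data.frame of class `mr_screen_result`, one row per exposure;
#'   exposures with fewer than `cfg$min_instruments` selected instruments
#'   get `status = "insufficient instruments"`. Summary counts are attached
#'   as `attr(, "summary")`.
#' @export
mr_screen <- function(exposures, outcome, ld, cfg = screen_config()) {
  if (inherits(exposures, "summary_dataset")) exposures <- list(exposures)
  if (length(exposures) == 0L)
    abort_mr("no exposures supplied", "mrscreen_bad_input")
  stopifnot(inherits(cfg, "screen_config"))
  m <- cfg$n_exposures_for_bonferroni %||% length(exposures)
  bonf <- bonferroni_threshold(cfg$alpha, m)
  rows <- vector("list", length(exposures))
  for (i in seq_along(exposures)) {
    exposure <- exposures[[i]]
    seed_i <- child_seed(cfg$seed, i)
    hs <- select_instruments(exposure, outcome, ld,
                             pval_threshold = cfg$pval_threshold,
                             r2_max = cfg$r2_max, window_kb = cfg$window_kb,
                             f_min = cfg$f_min, outcome_pval = cfg$outcome_pval,
                             min_instruments = cfg$min_instruments,
                             palindrome_policy = cfg$palindrome_policy)
    rows[[i]] <- if (inherits(hs, "empty_instrument_set")) {
      empty_verdict_row(exposure, hs$selection_log)
    } else {
      screen_one(hs, exposure, cfg, bonf, seed_i)
    }
  }
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    for (col in setdiff(all_cols, names(r))) r[[col]] <- NA
    r[all_cols]
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  by_cat <- table(res$category[res$flag %in% c("potential", "robust", "strong")])
  attr(res, "summary") <- list(
    n_exposures = nrow(res),
    bonferroni = bonf,
    n_insufficient = sum(res$status != "ok"),
    n_significant = sum(res$flag %in% c("potential", "robust", "strong")),
    n_strong = sum(res$flag == "strong"),
    n_robust = sum(res$flag == "robust"),
    n_potential = sum(res$flag == "potential"),
    by_category = by_cat)
  class(res) <- c("mr_screen_result", class(res))
  res
}

#' Forest-plot-ready table from a screen result
#'
#' @param res an [mr_screen_result][mr_screen()] data.frame.
#' @return data.frame with `label`, `or`, `ci_low`, `ci_high` for the
#'   exposures with estimable effects.
#' @export
forest_table <- function(res) {
  ok <- res$status == "ok"
  data.frame(label = res$trait_label[ok],
             or = res$ivw_or[ok],
             ci_low = res$ivw_or_low[ok],
             ci_high = res$ivw_or_high[ok],
             stringsAsFactors = FALSE)
}
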