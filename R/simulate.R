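#' Ground-truth parameters for a simulated exposure-outcome pair
#'
#' @param theta true causal effect (log odds ratio per exposure SD).
#' @param pi_pleio fraction of instruments with a direct (pleiotropic)
#'   outcome effect.
#' @param mu_alpha,sigma_alpha mean and SD of the pleiotropic effects,
#'   expressed relative to the exposure-increasing allele (non-zero
#'   `mu_alpha` = directional pleiotropy).
#' @param inside_violated when `TRUE`, pleiotropic effects gain a component
#'   proportional to the instrument's exposure effect
#'   (`inside_coef * gamma`), violating the InSIDE assumption.
#' @param inside_coef proportionality constant for the InSIDE violation.
#' @param n_exp exposure GWAS sample size. The default 7000 is a synthetic
#'   stand-in of the order of published metabolite GWAS panels.
#' @param n_out,case_fraction outcome GWAS size and case fraction; defaults
#'   emulate a binary-outcome GWAS of 1028 cases and 196,986 controls.
#' @return list of class `truth_record`.
#' @export
truth_record <- function(theta = 0, pi_pleio = 0, mu_alpha = 0,
                         sigma_alpha = 0.05, inside_violated = FALSE,
                         inside_coef = 0.5,
                         n_exp = 7000, n_out = 198014,
                         case_fraction = 1028 / 198014) {
  stopifnot(pi_pleio >= 0, pi_pleio <= 1,
            case_fraction > 0, case_fraction < 1,
            n_exp > 3, n_out > 3, sigma_alpha >= 0)
  structure(list(theta = theta, pi_pleio = pi_pleio, mu_alpha = mu_alpha,
                 sigma_alpha = sigma_alpha,
                 inside_violated = inside_violated, inside_coef = inside_coef,
                 n_exp = n_exp, n_out = n_out,
                 case_fraction = case_fraction),
            class = "truth_record")
}

#' Simulation scenario: instrument panel layout
#'
#' Controls the genetic architecture of the simulated exposure. Instrument
#' strength can be given either as the total exposure variance explained
#' (`variance_explained`) or, by default, through the mean per-instrument
#' F statistic `f_mean` (default 50, the order observed for
#' significance-selected metabolite instruments), from which
#' `variance_explained = k * f_mean / n_exp` is derived.
#'
#' @param k number of instruments.
#' @param maf_range minor-allele-frequency range, default `c(0.05, 0.5)`.
#' @param variance_explained total exposure variance explained by the k
#'   instruments; `NULL` derives it from `f_mean`.
#' @param f_mean target mean per-instrument F statistic (used when
#'   `variance_explained` is `NULL`).
#' @param swap_fraction fraction of outcome records written with
#'   effect/other alleles exchanged (beta negated, eaf mirrored).
#' @param flip_fraction fraction of outcome records written on the opposite
#'   strand (alleles complemented).
#' @param ld_block_size decoy variants generated per instrument (0 = none);
#'   decoys share the instrument's locus and are correlated with it.
#' @param ld_block_r2 r-squared between an instrument and its decoys.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(k = 15, maf_range = c(0.05, 0.5),
                         variance_explained = NULL, f_mean = 50,
                         swap_fraction = 0.25, flip_fraction = 0.25,
                         ld_block_size = 0, ld_block_r2 = 0.5) {
  stopifnot(k >= 1, maf_range[1] > 0, maf_range[2] <= 0.5,
            swap_fraction >= 0, swap_fraction <= 1,
            flip_fraction >= 0, flip_fraction <= 1,
            ld_block_size >= 0, ld_block_r2 >= 0, ld_block_r2 <= 1)
  structure(list(k = as.integer(k), maf_range = maf_range,
                 variance_explained = variance_explained, f_mean = f_mean,
                 swap_fraction = swap_fraction, flip_fraction = flip_fraction,
                 ld_block_size = as.integer(ld_block_size),
                 ld_block_r2 = ld_block_r2),
            class = "sim_scenario")
}

# Non-palindromic allele pairs used for simulated variants.
.allele_pairs <- cbind(ea = c("A", "A", "T", "T", "G", "G", "C", "C"),
                       oa = c("G", "C", "G", "C", "A", "T", "A", "T"))

#' Simulate a two-sample GWAS summary-statistics pair with known truth
#'
#' Generates exposure and outcome summary statistics under a linear
#' instrumental-variable model: per-variant exposure effects `gamma_j`
#' scaled to the target variance explained; direct (pleiotropic) outcome
#' effects `alpha_j` for a `pi_pleio` fraction; true outcome effects
#' `theta * gamma_j + alpha_j`; standard errors
#' `se_X = 1/sqrt(2 maf (1-maf) n_exp)` and, for the binary outcome on the
#' log-odds scale, `se_Y = 1/sqrt(2 maf (1-maf) n_out cf (1-cf))`; observed
#' effects drawn from `Normal(true, se^2)` with exact two-sided normal
#' p-values. A configurable fraction of outcome records is written
#' allele-swapped and/or strand-flipped so harmonization is exercised, and
#' optional LD-correlated decoy variants exercise clumping.
#'
#' @param scn a [sim_scenario()].
#' @param truth a [truth_record()].
#' @param seed RNG seed (same seed, identical output).
#' @param exposure_id,outcome_id trait ids for the emitted datasets.
#' @return list with `exposure` and `outcome` ([summary_dataset()]s), `ld`
#'   (pairwise r2 data.frame: `snp_id_1`, `snp_id_2`, `r2`), and `truth`
#'   (the input record augmented with the realised `gamma`, `alpha`,
#'   `instrument_ids` and `seed`).
#' @export
simulate_pair <- function(scn, truth = truth_record(), seed = 1L,
                          exposure_id = "sim_exposure",
                          outcome_id = "sim_outcome") {
  stopifnot(inherits(scn, "sim_scenario"), inherits(truth, "truth_record"))
  k <- scn$k
  h2 <- scn$variance_explained %||% (k * scn$f_mean / truth$n_exp)
  with_seed(seed, {
    maf <- stats::runif(k, scn$maf_range[1], scn$maf_range[2])
    het <- 2 * maf * (1 - maf)
    g <- stats::rnorm(k)
    gamma <- g * sqrt(h2 / sum(het * g^2))
    pleio <- stats::runif(k) < truth$pi_pleio
    # pleiotropic effects are defined relative to the exposure-increasing
    # allele (the orientation MR-Egger works in), so a non-zero mu_alpha is
    # genuinely directional rather than cancelling across allele codings
    alpha <- ifelse(pleio,
                    stats::rnorm(k, truth$mu_alpha, truth$sigma_alpha), 0)
    if (truth$inside_violated)
      alpha <- alpha + ifelse(pleio, truth$inside_coef * abs(gamma), 0)
    Gamma <- truth$theta * gamma + sign(gamma) * alpha

    se_x <- 1 / sqrt(het * truth$n_exp)
    cf <- truth$case_fraction
    se_y <- 1 / sqrt(het * truth$n_out * cf * (1 - cf))
    bx <- stats::rnorm(k, gamma, se_x)
    by <- stats::rnorm(k, Gamma, se_y)

    ids <- sprintf("rs%06d", seq_len(k))
    chrom <- as.character(rep_len(1:22, k))
    pos <- 1e6 * seq_len(k) + sample.int(1e5, k, replace = TRUE)
    pair <- .allele_pairs[sample.int(nrow(.allele_pairs), k, replace = TRUE), ,
                          drop = FALSE]

    exp_rec <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                          effect_allele = pair[, "ea"],
                          other_allele = pair[, "oa"],
                          eaf = maf, beta = bx, se = se_x,
                          pval = two_sided_p(bx / se_x), n = truth$n_exp,
                          stringsAsFactors = FALSE)
    out_rec <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                          effect_allele = pair[, "ea"],
                          other_allele = pair[, "oa"],
                          eaf = maf, beta = by, se = se_y,
                          pval = two_sided_p(by / se_y), n = truth$n_out,
                          stringsAsFactors = FALSE)

    # scramble the outcome's allele representation: swaps and strand flips
    do_swap <- stats::runif(k) < scn$swap_fraction
    out_rec$effect_allele[do_swap] <- pair[do_swap, "oa"]
    out_rec$other_allele[do_swap] <- pair[do_swap, "ea"]
    out_rec$beta[do_swap] <- -out_rec$beta[do_swap]
    out_rec$eaf[do_swap] <- 1 - out_rec$eaf[do_swap]
    do_flip <- stats::runif(k) < scn$flip_fraction
    out_rec$effect_allele[do_flip] <- complement_allele(out_rec$effect_allele[do_flip])
    out_rec$other_allele[do_flip] <- complement_allele(out_rec$other_allele[do_flip])

    ld <- data.frame(snp_id_1 = character(0), snp_id_2 = character(0),
                     r2 = numeric(0), stringsAsFactors = FALSE)
    if (scn$ld_block_size > 0) {
      n_decoy <- k * scn$ld_block_size
      idx <- rep(seq_len(k), each = scn$ld_block_size)
      d_ids <- sprintf("rs9%05d", seq_len(n_decoy))
      d_pos <- pos[idx] + sample(c(-1, 1), n_decoy, replace = TRUE) *
        sample.int(2e5, n_decoy, replace = TRUE)
      r <- sqrt(scn$ld_block_r2)
      d_se_x <- se_x[idx]
      # LD-attenuated effect plus correlated noise keeps decoys weaker than
      # their index variant
      d_bx <- r * bx[idx] + sqrt(1 - r^2) * stats::rnorm(n_decoy, 0, d_se_x)
      d_by <- r * by[idx] + sqrt(1 - r^2) * stats::rnorm(n_decoy, 0, se_y[idx])
      d_pair <- .allele_pairs[sample.int(nrow(.allele_pairs), n_decoy,
                                         replace = TRUE), , drop = FALSE]
      decoy_exp <- data.frame(variant_id = d_ids, chrom = chrom[idx],
                              pos = d_pos,
                              effect_allele = d_pair[, "ea"],
                              other_allele = d_pair[, "oa"],
                              eaf = maf[idx], beta = d_bx, se = d_se_x,
                              pval = two_sided_p(d_bx / d_se_x),
                              n = truth$n_exp, stringsAsFactors = FALSE)
      decoy_out <- data.frame(variant_id = d_ids, chrom = chrom[idx],
                              pos = d_pos,
                              effect_allele = d_pair[, "ea"],
                              other_allele = d_pair[, "oa"],
                              eaf = maf[idx], beta = d_by, se = se_y[idx],
                              pval = two_sided_p(d_by / se_y[idx]),
                              n = truth$n_out, stringsAsFactors = FALSE)
      exp_rec <- rbind(exp_rec, decoy_exp)
      out_rec <- rbind(out_rec, decoy_out)
      ld <- data.frame(snp_id_1 = ids[idx], snp_id_2 = d_ids,
                       r2 = scn$ld_block_r2, stringsAsFactors = FALSE)
    }

    truth_out <- truth
    truth_out$gamma <- gamma
    truth_out$alpha <- alpha
    truth_out$pleio <- pleio
    truth_out$instrument_ids <- ids
    truth_out$variance_explained <- h2
    truth_out$seed <- seed
    list(exposure = summary_dataset(exp_rec, trait_id = exposure_id,
                                    sample_size = truth$n_exp),
         outcome = summary_dataset(out_rec, trait_id = outcome_id,
                                   sample_size = truth$n_out),
         ld = ld,
         truth = truth_out)
  })
}

#' Operating characteristics of the estimators over a scenario grid
#'
#' For each scenario row, simulates `n_reps` exposure-outcome pairs,
#' harmonizes and runs the estimators, and aggregates rejection rates
#' (type-I error or power), bias, CI coverage, Egger-intercept rejection
#' rate, PRESSO outlier sensitivity/specificity and Steiger direction
#' accuracy. Deterministic given `seed` (replicate r of scenario s uses a
#' derived child seed).
#'
#' @param scenarios data.frame; recognised columns (all optional):
#'   `k`, `theta`, `pi_pleio`, `mu_alpha`, `sigma_alpha`, `inside_violated`,
#'   `f_mean`, `variance_explained`. One row per scenario.
#' @param n_reps replicates per scenario (>= 50 recommended).
#' @param seed master seed.
#' @param n_boot,n_sim weighted-median / PRESSO settings (reduced defaults;
#'   point estimates, not their SEs, drive most summaries).
#' @param alpha nominal level for rejection rates.
#' @return data.frame, one row per scenario, with the aggregate columns.
#' @export
operating_characteristics <- function(scenarios, n_reps = 100, seed = 1L,
                                      n_boot = 100, n_sim = 200,
                                      alpha = 0.05) {
  stopifnot(is.data.frame(scenarios), n_reps >= 2)
  out <- vector("list", nrow(scenarios))
  for (s in seq_len(nrow(scenarios))) {
    row <- scenarios[s, , drop = FALSE]
    grab <- function(col, default) if (!is.null(row[[col]]) && !is.na(row[[col]])) row[[col]] else default
    scn <- sim_scenario(k = grab("k", 15),
                        variance_explained = if (!is.null(row$variance_explained) &&
                                                 !is.na(row$variance_explained))
                          row$variance_explained else NULL,
                        f_mean = grab("f_mean", 50))
    truth <- truth_record(theta = grab("theta", 0),
                          pi_pleio = grab("pi_pleio", 0),
                          mu_alpha = grab("mu_alpha", 0),
                          sigma_alpha = grab("sigma_alpha", 0.05),
                          inside_violated = isTRUE(row$inside_violated))
    reps <- lapply(seq_len(n_reps), function(r) {
      sd_r <- child_seed(seed, (s - 1L) * n_reps + r)
      sim <- simulate_pair(scn, truth, seed = sd_r)
      hs <- harmonize(sim$exposure, sim$outcome)
      ivw <- mr_ivw(hs)
      egger <- mr_egger(hs)
      wm <- mr_weighted_median(hs, n_boot = n_boot, seed = child_seed(sd_r, 1L))
      presso <- mr_presso(hs, n_sim = n_sim, seed = child_seed(sd_r, 2L))
      st <- mr_steiger(hs)
      truth_pleio <- sim$truth$pleio[match(hs$variants$variant_id,
                                           sim$truth$instrument_ids)]
      flagged <- seq_len(nrow(hs$variants)) %in%
        (if (isTRUE(presso$testable)) presso$outlier_indices else integer(0))
      c(ivw_est = ivw$estimate, ivw_rej = ivw$pval < alpha,
        cover = ivw$ci_low <= truth$theta & truth$theta <= ivw$ci_high,
        egger_est = egger$slope$estimate,
        egger_int_rej = egger$intercept_pval < alpha,
        wm_est = wm$estimate,
        presso_tp = sum(flagged & truth_pleio),
        presso_fp = sum(flagged & !truth_pleio),
        n_pleio = sum(truth_pleio), n_valid = sum(!truth_pleio),
        steiger_ok = st$direction)
    })
    m <- do.call(rbind, reps)
    out[[s]] <- data.frame(
      scenario = s, k = scn$k, theta = truth$theta,
      pi_pleio = truth$pi_pleio, mu_alpha = truth$mu_alpha,
      n_reps = n_reps,
      rejection_rate = mean(m[, "ivw_rej"]),
      ivw_bias = mean(m[, "ivw_est"]) - truth$theta,
      egger_bias = mean(m[, "egger_est"]) - truth$theta,
      wm_bias = mean(m[, "wm_est"]) - truth$theta,
      coverage = mean(m[, "cover"]),
      egger_intercept_rejection = mean(m[, "egger_int_rej"]),
      presso_sensitivity = if (sum(m[, "n_pleio"]) > 0)
        sum(m[, "presso_tp"]) / sum(m[, "n_pleio"]) else NA_real_,
      presso_specificity = 1 - sum(m[, "presso_fp"]) / sum(m[, "n_valid"]),
      steiger_accuracy = mean(m[, "steiger_ok"]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
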