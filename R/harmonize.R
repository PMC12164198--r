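#' Harmonized exposure-outcome variant set
#'
#' Constructor for the container every estimator consumes: per-variant
#' exposure and outcome effects expressed for the same effect allele.
#'
#' @param variants data.frame with columns `variant_id`, `beta_exp`,
#'   `se_exp`, `pval_exp`, `beta_out`, `se_out`, `pval_out`, and optionally
#'   `eaf_exp`, `eaf_out`.
#' @param exposure_id,outcome_id trait identifiers.
#' @param n_exposure,n_outcome GWAS sample sizes (may be `NA`).
#' @return object of class `harmonized_set`.
#' @export
harmonized_set <- function(variants, exposure_id = "exposure",
                           outcome_id = "outcome",
                           n_exposure = NA_real_, n_outcome = NA_real_) {
  required <- c("variant_id", "beta_exp", "se_exp", "pval_exp",
                "beta_out", "se_out", "pval_out")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0L)
    abort_mr(paste0("harmonized variants lack column(s): ",
                    paste(missing_cols, collapse = ", ")), "mrscreen_bad_input")
  if (nrow(variants) == 0L)
    abort_mr("harmonized set is empty", "mrscreen_empty")
  if (anyDuplicated(variants$variant_id))
    abort_mr("duplicated variant_id in harmonized set", "mrscreen_bad_input")
  if (any(!is.finite(variants$se_exp)) || any(variants$se_exp <= 0) ||
      any(!is.finite(variants$se_out)) || any(variants$se_out <= 0))
    abort_mr("harmonized SEs must be positive", "mrscreen_bad_input")
  for (col in c("eaf_exp", "eaf_out"))
    if (is.null(variants[[col]])) variants[[col]] <- NA_real_
  rownames(variants) <- NULL
  structure(list(exposure_id = as.character(exposure_id),
                 outcome_id = as.character(outcome_id),
                 variants = variants,
                 n_exposure = as.numeric(n_exposure),
                 n_outcome = as.numeric(n_outcome)),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d variant(s)\n",
              x$exposure_id, x$outcome_id, nrow(x$variants)))
  invisible(x)
}

#' @export
length.harmonized_set <- function(x) nrow(x$variants)

complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(ea, oa) complement_allele(ea) == oa

#' Harmonize outcome effects to the exposure's effect alleles
#'
#' Variants present in both datasets are aligned so that `beta_exp` and
#' `beta_out` refer to the same effect allele. When the outcome's alleles are
#' swapped relative to the exposure, `beta_out` is negated and `eaf_out`
#' replaced by `1 - eaf_out`; when they match only after strand
#' complementation (A<->T, C<->G), the complement is taken first. Palindromic
#' variants (A/T, G/C), for which strand cannot be resolved from alleles,
#' are handled by `palindrome_policy`:
#' \describe{
#'   \item{drop_ambiguous}{(default) always dropped.}
#'   \item{infer_by_eaf}{kept when both allele frequencies lie outside the
#'     ambiguity band; same side of 0.5 keeps the orientation, opposite
#'     sides flips it. Missing eaf or eaf inside the band drops the variant.}
#' }
#' Variants whose allele pairs cannot be reconciled are dropped; per-reason
#' counts are available in `attr(, "harmonization_log")`.
#'
#' @param exposure,outcome [summary_dataset()] objects.
#' @param palindrome_policy `"drop_ambiguous"` or `"infer_by_eaf"`.
#' @param eaf_ambiguity_band numeric length 2: allele-frequency band around
#'   0.5 within which a palindromic variant is considered unresolvable.
#' @return a [harmonized_set()].
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop_ambiguous", "infer_by_eaf"),
                      eaf_ambiguity_band = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"))
  ex <- exposure$records
  ot <- outcome$records
  shared <- intersect(ex$variant_id, ot$variant_id)
  if (length(shared) == 0L)
    abort_mr("no shared variants between exposure and outcome",
             "mrscreen_empty")
  ex <- ex[match(shared, ex$variant_id), , drop = FALSE]
  ot <- ot[match(shared, ot$variant_id), , drop = FALSE]

  ea_e <- ex$effect_allele; oa_e <- ex$other_allele
  ea_o <- ot$effect_allele; oa_o <- ot$other_allele
  pal <- is_palindromic(ea_e, oa_e)

  same  <- ea_o == ea_e & oa_o == oa_e
  swap  <- ea_o == oa_e & oa_o == ea_e
  csame <- complement_allele(ea_o) == ea_e & complement_allele(oa_o) == oa_e
  cswap <- complement_allele(ea_o) == oa_e & complement_allele(oa_o) == ea_e

  flip <- rep(NA, length(shared))   # NA = drop, FALSE = keep, TRUE = negate
  flip[(same | csame) & !pal] <- FALSE
  flip[(swap & !pal) | (cswap & !pal)] <- TRUE
  # for palindromic variants same==csame and swap==cswap: alleles alone
  # cannot orient the strand
  pal_matched <- pal & (same | swap)
  if (palindrome_policy == "infer_by_eaf") {
    lo <- eaf_ambiguity_band[1]; hi <- eaf_ambiguity_band[2]
    fe <- ex$eaf
    fo <- ifelse(swap, 1 - ot$eaf, ot$eaf)  # outcome eaf on exposure's EA label
    resolvable <- pal_matched & !is.na(fe) & !is.na(fo) &
      (fe < lo | fe > hi) & (fo < lo | fo > hi)
    same_side <- (fe > 0.5) == (fo > 0.5)
    flip[resolvable & same_side] <- xor(FALSE, swap[resolvable & same_side])
    flip[resolvable & !same_side] <- xor(TRUE, swap[resolvable & !same_side])
  }

  keep <- !is.na(flip)
  log <- c(shared = length(shared),
           incompatible_alleles = sum(!keep & !pal_matched),
           palindromic_dropped = sum(!keep & pal_matched),
           flipped = sum(flip[keep]))
  if (!any(keep))
    abort_mr("no variants could be harmonized", "mrscreen_empty")

  beta_out <- ifelse(flip, -ot$beta, ot$beta)
  eaf_out <- ifelse(flip, 1 - ot$eaf, ot$eaf)
  variants <- data.frame(
    variant_id = shared,
    beta_exp = ex$beta, se_exp = ex$se, pval_exp = ex$pval,
    beta_out = beta_out, se_out = ot$se, pval_out = ot$pval,
    eaf_exp = ex$eaf, eaf_out = eaf_out,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  hs <- harmonized_set(variants,
                       exposure_id = exposure$trait_id,
                       outcome_id = outcome$trait_id,
                       n_exposure = exposure$sample_size,
                       n_outcome = outcome$sample_size)
  attr(hs, "harmonization_log") <- log
  hs
}
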