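#' Linkage-disequilibrium source
#'
#' Wraps pairwise r-squared values for clumping. Accepts a square symmetric
#' matrix with variant ids as dimnames, a data.frame with columns
#' `snp_id_1`, `snp_id_2`, `r2`, or a path to a tab-delimited file in that
#' dialect. Pairs absent from the source are treated as r2 = 0 (the LD source
#' is taken as given; no reference panel is consulted).
#'
#' @param x matrix, data.frame, or file path.
#' @return object of class `ld_source`.
#' @export
ld_source <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.delim(x, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  }
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x)))
      abort_mr("LD matrix needs variant ids as dimnames", "mrscreen_bad_input")
    idx <- which(upper.tri(x) & x != 0, arr.ind = TRUE)
    x <- data.frame(snp_id_1 = rownames(x)[idx[, 1]],
                    snp_id_2 = colnames(x)[idx[, 2]],
                    r2 = x[idx],
                    stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x) ||
      !all(c("snp_id_1", "snp_id_2", "r2") %in% names(x)))
    abort_mr("LD source needs columns snp_id_1, snp_id_2, r2",
             "mrscreen_bad_input")
  if (nrow(x) > 0 && (any(x$r2 < 0) || any(x$r2 > 1)))
    abort_mr("r2 values must lie in [0, 1]", "mrscreen_bad_input")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  tbl <- if (nrow(x) == 0) numeric(0) else {
    v <- x$r2
    names(v) <- key(as.character(x$snp_id_1), as.character(x$snp_id_2))
    # keep the max when a pair is listed twice (symmetric input)
    v <- tapply(v, names(v), max)
    v
  }
  structure(list(table = tbl, key = key), class = "ld_source")
}

#' Pairwise r-squared lookup
#' @param ld an [ld_source()].
#' @param id1,id2 variant id vectors (recycled).
#' @return numeric vector of r2 values; absent pairs give 0, identical ids 1.
#' @export
ld_r2 <- function(ld, id1, id2) {
  stopifnot(inherits(ld, "ld_source"))
  k <- ld$key(as.character(id1), as.character(id2))
  out <- unname(ld$table[k])
  out[is.na(out)] <- 0
  out[as.character(id1) == as.character(id2)] <- 1
  out
}

#' Filter variants on exposure association p-value
#'
#' Retains records with `pval` strictly below `threshold` (equality keeps
#' the record).
#'
#' @param ds a [summary_dataset()].
#' @param threshold genome-wide-suggestive default `1e-5`.
#' @return filtered [summary_dataset()]; may be empty-marked, see
#'   [selection_log()].
#' @export
filter_pvalue <- function(ds, threshold = 1e-5) {
  stopifnot(inherits(ds, "summary_dataset"))
  keep <- ds$records$pval < threshold
  out <- ds
  out$records <- ds$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Single-variant instrument-strength F statistic
#'
#' Per-variant approximation `(beta / se)^2`; equals the square of the
#' association z score.
#'
#' @param beta,se effect size and its standard error (vectorised).
#' @return numeric F values.
#' @export
f_statistic <- function(beta, se) {
  stopifnot(all(is.finite(se)), all(se > 0))
  (beta / se)^2
}

#' Exclude weak instruments
#'
#' Removes records with F strictly below `f_min` (F equal to `f_min` is
#' retained). Computed F values are attached as `attr(, "f_statistics")`.
#'
#' @param ds a [summary_dataset()].
#' @param f_min conventional weak-instrument bound, default 10.
#' @return filtered [summary_dataset()].
#' @export
filter_weak <- function(ds, f_min = 10) {
  stopifnot(inherits(ds, "summary_dataset"))
  f <- f_statistic(ds$records$beta, ds$records$se)
  keep <- !(f < f_min)
  out <- ds
  out$records <- ds$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  attr(out, "f_statistics") <- stats::setNames(f[keep],
                                               out$records$variant_id)
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining record with the smallest p-value as index
#' (ties broken by lexicographic `variant_id`) and removes all remaining
#' records with r2 above `r2_max` with the index that also lie within
#' `window_kb` kilobases of it on the same chromosome. The retained set is
#' independent of input order; no retained pair within the window has
#' r2 > `r2_max`.
#'
#' @param ds a [summary_dataset()] with positions when the window is enforced.
#' @param ld an [ld_source()].
#' @param r2_max LD pruning threshold, default 0.1.
#' @param window_kb distance window around the index variant, default 500
#'   (i.e. +/- 500 kb). `Inf` disables the distance condition.
#' @return clumped [summary_dataset()].
#' @export
clump <- function(ds, ld, r2_max = 0.1, window_kb = 500) {
  stopifnot(inherits(ds, "summary_dataset"), inherits(ld, "ld_source"))
  rec <- ds$records
  if (nrow(rec) == 0L) return(ds)
  if (is.finite(window_kb) && any(is.na(rec$pos) | is.na(rec$chrom)))
    abort_mr("clump with a finite window needs chrom and pos on all records",
             "mrscreen_bad_input")
  ord <- order(rec$pval, rec$variant_id)
  rec <- rec[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(rec))
  keep <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive)
    if (length(cand) == 0L) break
    in_window <- if (is.finite(window_kb)) {
      rec$chrom[cand] == rec$chrom[i] &
        abs(rec$pos[cand] - rec$pos[i]) <= window_kb * 1000
    } else rep(TRUE, length(cand))
    high_ld <- ld_r2(ld, rec$variant_id[cand], rec$variant_id[i]) > r2_max
    alive[cand[in_window & high_ld]] <- FALSE
  }
  out <- ds
  out$records <- rec[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Remove variants associated with the outcome
#'
#' Drops harmonized variants whose outcome p-value is strictly below
#' `threshold`, enforcing the exclusion-restriction screen.
#'
#' @param hs a [harmonized_set()].
#' @param threshold default `1e-5`.
#' @return filtered [harmonized_set()], or `NULL`-like empty marker: when all
#'   variants are removed an object of class `empty_instrument_set` is
#'   returned instead of an error.
#' @export
exclude_outcome_associated <- function(hs, threshold = 1e-5) {
  stopifnot(inherits(hs, "harmonized_set"))
  keep <- !(hs$variants$pval_out < threshold)
  if (!any(keep))
    return(structure(list(exposure_id = hs$exposure_id,
                          outcome_id = hs$outcome_id,
                          n_removed = nrow(hs$variants)),
                     class = "empty_instrument_set"))
  out <- hs
  out$variants <- hs$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  out
}

#' Full instrument-selection chain
#'
#' Applies, in order: exposure p-value filter, LD clumping, weak-instrument
#' (F) filter, harmonization against the outcome, and exclusion of
#' outcome-associated variants. Stage-by-stage retention counts are recorded
#' in `attr(, "selection_log")`.
#'
#' @param exposure,outcome [summary_dataset()] objects.
#' @param ld an [ld_source()].
#' @param pval_threshold,r2_max,window_kb,f_min,outcome_pval selection
#'   thresholds (defaults 1e-5, 0.1, 500, 10, 1e-5).
#' @param min_instruments minimum instruments required to proceed to
#'   estimation (default 3); below it an `empty_instrument_set`-classed
#'   marker with the log is returned.
#' @param palindrome_policy passed to [harmonize()].
#' @return a [harmonized_set()] restricted to selected instruments, with
#'   `selection_log` and `f_statistics` attributes, or an
#'   `empty_instrument_set` marker.
#' @export
select_instruments <- function(exposure, outcome, ld,
                               pval_threshold = 1e-5, r2_max = 0.1,
                               window_kb = 500, f_min = 10,
                               outcome_pval = 1e-5, min_instruments = 3,
                               palindrome_policy = "drop_ambiguous") {
  log <- c(input = nrow(exposure$records))
  ds <- filter_pvalue(exposure, pval_threshold)
  log["after_pval_filter"] <- nrow(ds$records)
  if (nrow(ds$records) > 0L) {
    ds <- clump(ds, ld, r2_max = r2_max, window_kb = window_kb)
  }
  log["after_clump"] <- nrow(ds$records)
  f_all <- NULL
  if (nrow(ds$records) > 0L) {
    ds <- filter_weak(ds, f_min)
    f_all <- attr(ds, "f_statistics")
  }
  log["after_f_filter"] <- nrow(ds$records)
  hs <- NULL
  if (nrow(ds$records) > 0L) {
    hs <- tryCatch(harmonize(ds, outcome, palindrome_policy = palindrome_policy),
                   mrscreen_empty = function(e) NULL)
  }
  log["after_harmonize"] <- if (is.null(hs)) 0L else nrow(hs$variants)
  if (!is.null(hs)) {
    hs <- exclude_outcome_associated(hs, outcome_pval)
    if (inherits(hs, "empty_instrument_set")) hs <- NULL
  }
  log["after_outcome_exclusion"] <- if (is.null(hs)) 0L else nrow(hs$variants)
  if (is.null(hs) || nrow(hs$variants) < min_instruments) {
    return(structure(list(exposure_id = exposure$trait_id,
                          outcome_id = outcome$trait_id,
                          selection_log = log,
                          reason = "insufficient instruments"),
                     class = "empty_instrument_set"))
  }
  attr(hs, "selection_log") <- log
  attr(hs, "f_statistics") <- f_all[hs$variants$variant_id]
  hs
}

#' Stage-by-stage selection log
#' @param x result of [select_instruments()].
#' @return named integer vector of retention counts.
#' @export
selection_log <- function(x) {
  if (inherits(x, "empty_instrument_set")) x$selection_log
  else attr(x, "selection_log")
}
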