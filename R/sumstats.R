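#' GWAS summary-statistics container
#'
#' A `summary_dataset` bundles one trait's per-variant association summary
#' statistics with its identity and sample size. Effect sizes (`beta`) are
#' per-allele and, for binary traits, on the log-odds scale.
#'
#' @param records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   `eaf` and `n` may be `NA`; `chrom`/`pos` may be `NA` when no distance
#'   window is needed downstream.
#' @param trait_id short unique identifier.
#' @param trait_label human-readable name (defaults to `trait_id`).
#' @param category free-text annotation (e.g. "Lipid", "Unknown").
#' @param sample_size GWAS sample size; `NA` allowed (Steiger p then absent).
#' @param drop_invalid drop rows violating record invariants (with a count in
#'   `attr(,"n_dropped")`) instead of erroring.
#'
#' @return object of class `summary_dataset`.
#' @export
summary_dataset <- function(records, trait_id, trait_label = trait_id,
                            category = "Unknown", sample_size = NA_integer_,
                            drop_invalid = TRUE) {
  required <- c("variant_id", "effect_allele", "other_allele",
                "beta", "se", "pval")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L)
    abort_mr(paste0("records lack required column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "mrscreen_bad_input")
  for (col in c("chrom", "eaf", "n"))
    if (is.null(records[[col]])) records[[col]] <- NA
  if (is.null(records[["pos"]])) records[["pos"]] <- NA_real_
  records <- records[c("variant_id", "chrom", "pos", "effect_allele",
                       "other_allele", "eaf", "beta", "se", "pval", "n")]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.numeric(records$pos)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) records[[col]] <- as.numeric(records[[col]])
  records$n <- as.numeric(records$n)

  ok <- valid_gwas_record(records)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    if (!drop_invalid)
      abort_mr(sprintf("%d record(s) violate GWAS record invariants", n_dropped),
               "mrscreen_bad_input")
    records <- records[ok, , drop = FALSE]
  }
  if (nrow(records) == 0L)
    abort_mr(sprintf("no valid records for trait '%s'", trait_id),
             "mrscreen_empty")
  if (anyDuplicated(records$variant_id))
    abort_mr(sprintf("duplicated variant_id in trait '%s'", trait_id),
             "mrscreen_bad_input")
  rownames(records) <- NULL
  structure(
    list(trait_id = as.character(trait_id),
         trait_label = as.character(trait_label),
         category = as.character(category),
         records = records,
         sample_size = as.numeric(sample_size)),
    n_dropped = n_dropped,
    class = "summary_dataset")
}

# Row-wise invariant check; NA eaf / n / chrom / pos are permitted.
valid_gwas_record <- function(records) {
  bases <- c("A", "C", "G", "T")
  ok <- !is.na(records$variant_id) & nzchar(records$variant_id) &
    records$effect_allele %in% bases &
    records$other_allele %in% bases &
    records$effect_allele != records$other_allele &
    is.finite(records$beta) &
    is.finite(records$se) & records$se > 0 &
    is.finite(records$pval) & records$pval > 0 & records$pval <= 1
  eaf_ok <- is.na(records$eaf) | (records$eaf > 0 & records$eaf < 1)
  n_ok <- is.na(records$n) | records$n > 0
  ok & eaf_ok & n_ok
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s (%s, category %s): %d variant(s), n = %s\n",
              x$trait_id, x$trait_label, x$category, nrow(x$records),
              format(x$sample_size)))
  invisible(x)
}

#' @export
length.summary_dataset <- function(x) nrow(x$records)

# Replace the record table, keeping trait metadata.
replace_records <- function(ds, records, n_dropped = 0L) {
  ds$records <- records
  rownames(ds$records) <- NULL
  attr(ds, "n_dropped") <- n_dropped
  ds
}

default_column_map <- function() {
  c(variant_id = "snp_id", chrom = "chrom", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n")
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' The default dialect has headers
#' `snp_id chrom pos effect_allele other_allele eaf beta se pval n`;
#' `column_map` renames them (names are `summary_dataset` record fields,
#' values are file headers). Rows violating record invariants (non-ACGT or
#' equal alleles, `se <= 0`, p outside (0,1], `eaf` outside (0,1)) are
#' dropped; the count is kept in `attr(, "n_dropped")` and reported via a
#' message.
#'
#' @param path tab-delimited file with a header row.
#' @param trait_id,trait_label,category,sample_size trait metadata, see
#'   [summary_dataset()].
#' @param column_map named character vector mapping record fields to file
#'   headers; unspecified fields use the default dialect. `eaf`, `n`,
#'   `chrom`, `pos` are optional in the file.
#' @return a [summary_dataset()].
#' @export
read_sumstats <- function(path, trait_id, column_map = NULL,
                          trait_label = trait_id, category = "Unknown",
                          sample_size = NA_integer_) {
  if (!file.exists(path))
    abort_mr(paste0("file not found: ", path), "mrscreen_bad_input")
  map <- default_column_map()
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(map))
    if (length(bad) > 0L)
      abort_mr(paste0("unknown record field(s) in column_map: ",
                      paste(bad, collapse = ", ")), "mrscreen_bad_input")
    map[names(column_map)] <- column_map
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pval")
  for (field in required)
    if (!map[[field]] %in% names(tab))
      abort_mr(sprintf("mapped column for '%s' ('%s') not present in %s",
                       field, map[[field]], path), "mrscreen_bad_input")
  records <- data.frame(variant_id = tab[[map[["variant_id"]]]],
                        stringsAsFactors = FALSE)
  for (field in c("chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")) {
    col <- map[[field]]
    records[[field]] <- if (col %in% names(tab)) tab[[col]] else NA
  }
  ds <- summary_dataset(records, trait_id = trait_id, trait_label = trait_label,
                        category = category, sample_size = sample_size)
  if (attr(ds, "n_dropped") > 0L)
    message(sprintf("read_sumstats: dropped %d invalid row(s) from %s",
                    attr(ds, "n_dropped"), path))
  ds
}

#' Write a results table to TSV or JSON
#'
#' Output is bit-stable for identical input: fixed column order (as given),
#' numeric columns formatted with 6 significant digits, no scientific-notation
#' dependence on session options.
#'
#' @param report non-empty data.frame.
#' @param path output file path.
#' @param format `"tsv"` (one row per record) or `"json"` (array with one
#'   object per record).
#' @return `path`, invisibly.
#' @export
write_results <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(report) || nrow(report) == 0L)
    abort_mr("report must be a non-empty data.frame", "mrscreen_bad_input")
  out <- report
  num <- vapply(out, is.numeric, logical(1))
  if (format == "tsv") {
    for (j in which(num))
      out[[j]] <- ifelse(is.na(out[[j]]), "NA",
                         formatC(out[[j]], digits = 6, format = "g"))
    con <- tryCatch(suppressWarnings(file(path, open = "wt")),
                    error = function(e) abort_mr(
                      paste0("cannot open for writing: ", path),
                      "mrscreen_io_error"))
    on.exit(close(con))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    for (j in which(num)) out[[j]] <- signif(out[[j]], 6)
    txt <- jsonlite::toJSON(out, dataframe = "rows", na = "null",
                            auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ok <- tryCatch(suppressWarnings({ writeLines(txt, path); TRUE }),
                   error = function(e) FALSE)
    if (!ok) abort_mr(paste0("cannot write: ", path), "mrscreen_io_error")
  }
  invisible(path)
}

#' Read back a results table written by [write_results()]
#' @param path file path.
#' @param format `"tsv"` or `"json"`.
#' @return data.frame.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, na.strings = "NA",
                      check.names = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path))
  }
}
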