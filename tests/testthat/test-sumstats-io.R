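test_that("read_sumstats round-trips a well-formed file and enforces invariants", {
  tsv <- file.path(tempdir(), "exp.tsv")
  rec <- make_records(3)
  names(rec)[1] <- "snp_id"
  write.table(rec, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- read_sumstats(tsv, trait_id = "m1")
  expect_s3_class(ds, "summary_dataset")
  expect_equal(nrow(ds$records), 3)
  expect_equal(ds$records$beta, rec$beta)

  # one zero-se row is dropped, not fatal
  rec2 <- rec
  rec2$se[2] <- 0
  write.table(rec2, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(ds2 <- read_sumstats(tsv, trait_id = "m1"), "dropped 1")
  expect_equal(nrow(ds2$records), 2)
  expect_false("rs002" %in% ds2$records$variant_id)

  # column_map pointing at a missing header errors naming the field
  expect_error(read_sumstats(tsv, trait_id = "m1",
                             column_map = c(beta = "not_there")),
               "beta")
  # all rows invalid -> hard error
  rec3 <- rec
  rec3$pval <- 0
  write.table(rec3, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(tsv, trait_id = "m1"), class = "mrscreen_empty")
})

test_that("summary_dataset validates alleles, duplicates and emptiness", {
  expect_error(summary_dataset(make_records(2)[, -4], "x"), "effect_allele")
  rec <- make_records(2, effect_allele = c("A", "N"))
  expect_equal(nrow(summary_dataset(rec, "x")$records), 1)
  rec <- make_records(2, variant_id = c("rs1", "rs1"))
  expect_error(summary_dataset(rec, "x"), "duplicated")
  rec <- make_records(2, effect_allele = c("A", "A"), other_allele = c("A", "G"))
  ds <- summary_dataset(rec, "x")
  expect_equal(ds$records$variant_id, "rs002")
  expect_equal(attr(ds, "n_dropped"), 1L)
})

test_that("write_results round-trips tsv and json and rejects empty reports", {
  report <- data.frame(trait_id = c("a", "b"),
                       lnor = c(-0.7508, 1.121),
                       pval = c(0.001, 0.047),
                       stringsAsFactors = FALSE)
  tsv <- file.path(tempdir(), "res.tsv")
  write_results(report, tsv, "tsv")
  back <- read_results(tsv, "tsv")
  expect_equal(back$lnor, report$lnor, tolerance = 1e-6)
  expect_equal(back$trait_id, report$trait_id)
  # byte-stable on rewrite
  first <- readLines(tsv)
  write_results(report, tsv, "tsv")
  expect_identical(readLines(tsv), first)

  js <- file.path(tempdir(), "res.json")
  write_results(report, js, "json")
  parsed <- read_results(js, "json")
  expect_equal(nrow(parsed), 2)  # one object per row
  expect_equal(parsed$pval, report$pval, tolerance = 1e-6)

  expect_error(write_results(report[0, ], tsv), class = "mrscreen_bad_input")
  expect_error(write_results(report, "/nonexistent-dir/x/res.tsv"),
               class = "mrscreen_io_error")
})

test_that("harmonize aligns swapped and strand-complemented alleles", {
  exp <- summary_dataset(make_records(1, effect_allele = "A",
                                      other_allele = "G", beta = 0.10), "e")
  # outcome alleles swapped: sign must flip
  out <- summary_dataset(make_records(1, effect_allele = "G",
                                      other_allele = "A", beta = -0.05,
                                      eaf = 0.8), "o")
  hs <- harmonize(exp, out)
  expect_equal(hs$variants$beta_out, 0.05)
  expect_equal(hs$variants$eaf_out, 0.2)

  # strand complement, same orientation: beta unchanged
  out2 <- summary_dataset(make_records(1, effect_allele = "T",
                                       other_allele = "C", beta = -0.05), "o")
  hs2 <- harmonize(exp, out2)
  expect_equal(hs2$variants$beta_out, -0.05)

  # strand complement AND swap: sign flips
  out3 <- summary_dataset(make_records(1, effect_allele = "C",
                                       other_allele = "T", beta = -0.05), "o")
  expect_equal(harmonize(exp, out3)$variants$beta_out, 0.05)

  # incompatible alleles are dropped -> empty -> error
  out4 <- summary_dataset(make_records(1, effect_allele = "A",
                                       other_allele = "C"), "o")
  expect_error(harmonize(exp, out4), class = "mrscreen_empty")
})

test_that("palindromic variants follow the policy", {
  pal_exp <- function(eaf) summary_dataset(
    make_records(1, effect_allele = "A", other_allele = "T", eaf = eaf), "e")
  pal_out <- function(eaf, beta = 0.05) summary_dataset(
    make_records(1, effect_allele = "A", other_allele = "T",
                 eaf = eaf, beta = beta), "o")
  # ambiguous eaf under drop_ambiguous: gone (empty set errors)
  expect_error(harmonize(pal_exp(0.5), pal_out(0.5)), class = "mrscreen_empty")
  # infer_by_eaf, both well outside band, same side: kept, unflipped
  hs <- harmonize(pal_exp(0.2), pal_out(0.22), "infer_by_eaf")
  expect_equal(hs$variants$beta_out, 0.05)
  # opposite sides: strand flip inferred, sign negated
  hs2 <- harmonize(pal_exp(0.2), pal_out(0.78), "infer_by_eaf")
  expect_equal(hs2$variants$beta_out, -0.05)
  # inside the ambiguity band: dropped even under infer_by_eaf
  expect_error(harmonize(pal_exp(0.5), pal_out(0.5), "infer_by_eaf"),
               class = "mrscreen_empty")
  # missing eaf on a palindromic variant: dropped
  expect_error(harmonize(pal_exp(NA), pal_out(0.2), "infer_by_eaf"),
               class = "mrscreen_empty")
})

test_that("harmonize is idempotent and invariant to allele-flipped copies", {
  set.seed(42)
  for (rep in 1:5) {
    sim <- simulate_pair(sim_scenario(k = 12), truth_record(theta = 0.3),
                         seed = 100 + rep)
    hs <- harmonize(sim$exposure, sim$outcome)
    expect_lte(nrow(hs$variants), min(nrow(sim$exposure$records),
                                      nrow(sim$outcome$records)))
    # rebuild the outcome from the harmonized table: re-harmonizing is a no-op
    out_aligned <- sim$outcome
    idx <- match(hs$variants$variant_id, out_aligned$records$variant_id)
    exp_idx <- match(hs$variants$variant_id, sim$exposure$records$variant_id)
    out_aligned$records <- out_aligned$records[idx, ]
    out_aligned$records$effect_allele <- sim$exposure$records$effect_allele[exp_idx]
    out_aligned$records$other_allele <- sim$exposure$records$other_allele[exp_idx]
    out_aligned$records$beta <- hs$variants$beta_out
    out_aligned$records$eaf <- hs$variants$eaf_out
    hs2 <- harmonize(sim$exposure, out_aligned)
    expect_equal(hs2$variants, hs$variants)
    # flipping every outcome allele pair (swap + negate) changes nothing
    flipped <- sim$outcome
    tmp <- flipped$records$effect_allele
    flipped$records$effect_allele <- flipped$records$other_allele
    flipped$records$other_allele <- tmp
    flipped$records$beta <- -flipped$records$beta
    flipped$records$eaf <- 1 - flipped$records$eaf
    hs3 <- harmonize(sim$exposure, flipped)
    expect_equal(hs3$variants, hs$variants)
  }
})
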