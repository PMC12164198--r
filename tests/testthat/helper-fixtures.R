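# Shared in-code fixtures and independent oracles.

# minimal valid record table; override fields as needed
make_records <- function(n = 3, ...) {
  rec <- data.frame(
    variant_id = sprintf("rs%03d", seq_len(n)),
    chrom = rep("1", n),
    pos = 1e6 * seq_len(n),
    effect_allele = rep_len(c("A", "C", "G"), n),
    other_allele = rep_len(c("G", "T", "A"), n),
    eaf = rep_len(c(0.2, 0.3, 0.4), n),
    beta = seq(0.1, by = 0.05, length.out = n),
    se = rep(0.02, n),
    pval = rep(1e-8, n),
    n = rep(5000, n),
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

make_ds <- function(n = 3, trait_id = "exp", sample_size = 5000, ...) {
  summary_dataset(make_records(n, ...), trait_id = trait_id,
                  sample_size = sample_size)
}

# harmonized set straight from effect vectors (alignment already done)
make_hs <- function(bx, by, sy, sx = rep(0.02, length(bx)),
                    n_exposure = 7000, n_outcome = 198014) {
  k <- length(bx)
  harmonized_set(
    data.frame(variant_id = sprintf("rs%03d", seq_len(k)),
               beta_exp = bx, se_exp = sx, pval_exp = rep(1e-8, k),
               beta_out = by, se_out = sy,
               pval_out = 2 * pnorm(-abs(by / sy)),
               stringsAsFactors = FALSE),
    n_exposure = n_exposure, n_outcome = n_outcome)
}

# the 3-variant worked fixture with independently derived (closed-form /
# normal-equations) expected values, frozen
fixture3 <- function() make_hs(bx = c(0.1, 0.2, 0.3),
                               by = c(0.05, 0.12, 0.14),
                               sy = c(0.01, 0.02, 0.03))
fixture3_expect <- list(
  ivw_est = 0.5222222222, ivw_se_fixed = 0.0577350269, q_ivw = 0.9629629630,
  egger_slope = 0.526923076923077, egger_intercept = -0.000769230769231,
  q_egger = 0.9615384615)

# brute-force weighted-regression oracles (independent of the package path)
oracle_ivw <- function(bx, by, sy) {
  unname(coef(lm(by ~ 0 + bx, weights = 1 / sy^2)))
}
oracle_egger <- function(bx, by, sy) {
  flip <- bx < 0
  bx[flip] <- -bx[flip]; by[flip] <- -by[flip]
  unname(coef(lm(by ~ bx, weights = 1 / sy^2)))  # (intercept, slope)
}

empty_ld <- function() ld_source(data.frame(snp_id_1 = character(0),
                                            snp_id_2 = character(0),
                                            r2 = numeric(0)))

sim_harmonized <- function(k, theta = 0, seed = 1, f_mean = 50, ...) {
  sim <- simulate_pair(sim_scenario(k = k, f_mean = f_mean),
                       truth_record(theta = theta, ...), seed = seed)
  harmonize(sim$exposure, sim$outcome)
}
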