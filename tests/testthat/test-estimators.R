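test_that("wald ratio handles the basic, null and error cases", {
  v <- data.frame(beta_exp = 0.5, beta_out = 0.25, se_out = 0.1)
  res <- mr_wald_ratio(v)
  expect_equal(res$estimate, 0.5)
  expect_equal(res$se, 0.2)
  null <- mr_wald_ratio(data.frame(beta_exp = 0.5, beta_out = 0, se_out = 0.1))
  expect_equal(null$estimate, 0)
  expect_equal(null$pval, 1)
  expect_error(mr_wald_ratio(data.frame(beta_exp = 0, beta_out = 1,
                                        se_out = 0.1)),
               class = "mrscreen_bad_input")
})

test_that("IVW reproduces the frozen closed-form fixture", {
  hs <- fixture3()
  fixed <- mr_ivw(hs, mode = "fixed")
  expect_equal(fixed$estimate, fixture3_expect$ivw_est, tolerance = 1e-9)
  expect_equal(fixed$se, fixture3_expect$ivw_se_fixed, tolerance = 1e-9)
  # Q < k-1 here, so random-effects truncation leaves the SE unchanged
  rand <- mr_ivw(hs)
  expect_equal(rand$estimate, fixed$estimate)
  expect_equal(rand$se, fixed$se)
  expect_equal(rand$ci_low, rand$estimate - qnorm(0.975) * rand$se)
})

test_that("IVW degenerate and exact-ratio cases behave", {
  # all ratios equal b: estimate is exactly b, Q = 0, both modes agree
  hs <- make_hs(c(0.1, 0.2, 0.4), 0.3 * c(0.1, 0.2, 0.4), c(0.01, 0.02, 0.03))
  expect_equal(mr_ivw(hs, "fixed")$estimate, 0.3, tolerance = 1e-12)
  expect_equal(mr_cochran_q(hs, "ivw")$q, 0, tolerance = 1e-20)
  expect_equal(mr_ivw(hs)$se, mr_ivw(hs, "fixed")$se)
  # single variant delegates to the wald ratio
  one <- make_hs(0.5, 0.25, 0.1)
  res <- mr_ivw(one)
  expect_equal(res$method, "wald_ratio")
  expect_equal(res$estimate, 0.5)
})

test_that("Egger matches the normal-equations oracle and handles exact fits", {
  hs <- fixture3()
  eg <- mr_egger(hs)
  expect_equal(eg$slope$estimate, fixture3_expect$egger_slope, tolerance = 1e-9)
  expect_equal(eg$intercept, fixture3_expect$egger_intercept, tolerance = 1e-9)
  # zero pleiotropy, exact ratios: slope = b, intercept = 0
  exact <- make_hs(c(0.1, 0.2, 0.4), 0.3 * c(0.1, 0.2, 0.4),
                   c(0.01, 0.02, 0.03))
  eg2 <- mr_egger(exact)
  expect_equal(eg2$slope$estimate, 0.3, tolerance = 1e-10)
  expect_equal(eg2$intercept, 0, tolerance = 1e-12)
  # orientation symmetry: negating one variant's (bx, by) changes nothing
  hs_neg <- hs
  hs_neg$variants$beta_exp[2] <- -hs_neg$variants$beta_exp[2]
  hs_neg$variants$beta_out[2] <- -hs_neg$variants$beta_out[2]
  eg3 <- mr_egger(hs_neg)
  expect_equal(eg3$slope$estimate, eg$slope$estimate, tolerance = 1e-12)
  expect_equal(eg3$intercept, eg$intercept, tolerance = 1e-12)
  expect_equal(eg3$intercept_pval, eg$intercept_pval, tolerance = 1e-12)
  expect_error(mr_egger(make_hs(c(1, 2), c(1, 2), c(1, 1))),
               class = "mrscreen_too_few")
})

test_that("IVW and Egger match brute-force weighted regression on random instances", {
  set.seed(202)
  for (i in 1:100) {
    k <- sample(3:8, 1)
    bx <- rnorm(k, 0, 0.2); bx[abs(bx) < 0.01] <- 0.05
    by <- rnorm(k, 0.3 * bx, 0.05)
    sy <- runif(k, 0.01, 0.1)
    hs <- make_hs(bx, by, sy)
    expect_equal(mr_ivw(hs, "fixed")$estimate, oracle_ivw(bx, by, sy),
                 tolerance = 1e-10)
    coefs <- oracle_egger(bx, by, sy)
    eg <- mr_egger(hs)
    expect_equal(eg$intercept, coefs[1], tolerance = 1e-10)
    expect_equal(eg$slope$estimate, coefs[2], tolerance = 1e-10)
  }
})

test_that("weighted median interpolates the ratio distribution at weight 1/2", {
  # equal weights, ratios {0.5, 0.6, 0.4667}: p-grid {1/6, 1/2, 5/6} hits the
  # middle sorted ratio exactly
  hs <- make_hs(c(1, 1, 1), c(0.5, 0.6, 0.4667), c(1, 1, 1))
  wm <- mr_weighted_median(hs, n_boot = 50, seed = 1)
  expect_equal(wm$estimate, 0.5)
  # variants carrying >50% of the weight share ratio 0.8; the outlier cannot move it
  hs3 <- make_hs(c(1, 1, 1, 0.5), c(0.8, 0.8, 0.8, 5), c(1, 1, 1, 1))
  expect_equal(mr_weighted_median(hs3, n_boot = 50, seed = 1)$estimate, 0.8)
  # same seed, same SE; different seed, (almost surely) different SE
  a <- mr_weighted_median(fixture3(), n_boot = 200, seed = 9)
  b <- mr_weighted_median(fixture3(), n_boot = 200, seed = 9)
  expect_identical(a$se, b$se)
  # weighted median lies within the ratio range; equals the plain median for
  # equal weights and odd k
  set.seed(77)
  for (i in 1:20) {
    k <- sample(c(3, 5, 7), 1)
    bx <- runif(k, 0.05, 0.5); by <- rnorm(k, 0.2 * bx, 0.1)
    ratios <- by / bx
    hs_i <- make_hs(bx, by, bx)  # se_out = bx makes weights equal
    wm_i <- mr_weighted_median(hs_i, n_boot = 10, seed = 1)
    expect_gte(wm_i$estimate, min(ratios))
    expect_lte(wm_i$estimate, max(ratios))
    expect_equal(wm_i$estimate, median(ratios))
  }
  expect_error(mr_weighted_median(make_hs(c(1, 2), c(1, 2), c(1, 1))),
               class = "mrscreen_too_few")
})

test_that("estimators are scale-equivariant in the outcome", {
  hs <- sim_harmonized(k = 10, theta = 0.4, seed = 5)
  c_ <- 3.7
  hs_scaled <- hs
  hs_scaled$variants$beta_out <- c_ * hs$variants$beta_out
  hs_scaled$variants$se_out <- c_ * hs$variants$se_out
  for (f in list(function(h) mr_ivw(h),
                 function(h) mr_egger(h)$slope,
                 function(h) mr_weighted_median(h, n_boot = 100, seed = 2))) {
    a <- f(hs); b <- f(hs_scaled)
    expect_equal(b$estimate, c_ * a$estimate, tolerance = 1e-9)
    expect_equal(b$se, c_ * a$se, tolerance = 1e-9)
  }
})

test_that("all estimators converge to the same value as se -> 0", {
  k <- 8
  set.seed(31)
  bx <- runif(k, 0.1, 0.4)
  by <- 0.25 * bx
  hs <- make_hs(bx, by + rnorm(k, 0, 1e-7), rep(1e-6, k), sx = rep(1e-6, k))
  ests <- c(mr_ivw(hs)$estimate,
            mr_egger(hs)$slope$estimate,
            mr_weighted_median(hs, n_boot = 50, seed = 1)$estimate,
            mr_presso(hs, n_sim = 100, seed = 1)$raw$estimate)
  expect_true(all(abs(ests - 0.25) < 1e-3))
})

test_that("MR-PRESSO flags a planted outlier and reports the marker at k<4", {
  hs <- sim_harmonized(k = 10, theta = 0.3, seed = 12)
  j <- 4
  hs$variants$beta_out[j] <- hs$variants$beta_out[j] +
    10 * hs$variants$se_out[j]
  pr <- mr_presso(hs, n_sim = 500, seed = 99)
  expect_true(isTRUE(pr$testable))
  expect_true(j %in% pr$outlier_indices)
  expect_lt(pr$global_pval, 0.05)
  expect_false(is.null(pr$corrected))
  expect_lt(abs(pr$corrected$estimate - 0.3), abs(pr$raw$estimate - 0.3))
  expect_true(is.finite(pr$distortion_pval))
  # determinism
  pr2 <- mr_presso(hs, n_sim = 500, seed = 99)
  expect_identical(pr2$global_pval, pr$global_pval)
  expect_identical(pr2$outlier_pvals, pr$outlier_pvals)
  # homogeneous set: no outliers, corrected absent
  hs_null <- sim_harmonized(k = 10, theta = 0.3, seed = 13)
  pr_null <- mr_presso(hs_null, n_sim = 500, seed = 7)
  expect_gt(pr_null$global_pval, 0.05)
  expect_null(pr_null$corrected)
  # k = 3: not-testable marker, not a crash
  small <- mr_presso(make_hs(c(0.1, 0.2, 0.3), c(0.05, 0.1, 0.2),
                             c(0.02, 0.02, 0.02)), n_sim = 100, seed = 1)
  expect_s3_class(small, "presso_not_testable")
  expect_false(small$testable)
})

test_that("to_odds_ratio exponentiates the log-odds scale", {
  null <- mr_result("ivw", 0, 0.1, 1, 5)
  expect_equal(to_odds_ratio(null)$or, 1)
  # frozen: ln(0.472) = -0.750776, exp(1.121) = 3.068 at display rounding
  m <- mr_result("ivw", -0.750776, 0.233, 0.001, 13)
  expect_equal(to_odds_ratio(m)$or, 0.472)
  expect_equal(to_odds_ratio(mr_result("ivw", 1.121, 0.5, 0.02, 4))$or, 3.068)
})

test_that("PRESSO global test is calibrated under the null", {
  n_rep <- 200L
  rej <- vapply(seq_len(n_rep), function(r) {
    hs <- sim_harmonized(k = 10, theta = 0.3, seed = 700000 + r)
    mr_presso(hs, n_sim = 200, seed = 700000 + r)$global_pval < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.07)   # near-nominal, never anticonservative
})
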