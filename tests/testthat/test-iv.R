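test_that("IGA inversion follows covariance algebra and sample-regression duality", {
  # hand oracle: 0.2 * (4/5)^2 = 0.128, SE scaled identically
  inv <- invert_iga(0.2, 0.02, sd_parent = 4, sd_offspring = 5)
  expect_equal(inv$estimate, 0.128)
  expect_equal(inv$se, 0.02 * (4 / 5)^2)
  expect_identical(inv$kind, "denominator")
  # equal SDs: the identity
  expect_equal(invert_iga(0.2, 0.02, 3, 3)$estimate, 0.2)
  expect_error(invert_iga(0.2, 0.02, 0, 3), "positive")
  # duality on simulated trios: inverting the forward fit equals the reverse
  # fit exactly (same sample covariance, variances swap)
  fwd <- fit_iga(small_cohort, "mother", "daughter",
    adjustment = "unadjusted", direction = "offspring_on_parent"
  )
  rev <- fit_iga(small_cohort, "mother", "daughter", adjustment = "unadjusted")
  expect_equal(
    invert_iga(fwd$estimate, fwd$se, fwd$sd_parent, fwd$sd_offspring)$estimate,
    rev$estimate,
    tolerance = 1e-10
  )
})

test_that("GRS denominator applies the generation and sex-SD factors", {
  sds <- c(female = 5.03, male = 4.10)
  den_m <- grs_pgmr_denominator(0.02, 0.001, "mother", sds)
  expect_equal(den_m$estimate, 0.02 * 0.5 * 5.03)
  expect_equal(den_m$se, 0.001 * 0.5 * 5.03)
  expect_equal(grs_pgmr_denominator(0, 0.001, "father", sds)$estimate, 0)
  expect_error(grs_pgmr_denominator(0.02, 0.001, "uncle", sds), "parent_sex")
  expect_error(grs_pgmr_denominator(0.02, 0.001, "mother", c(male = 4.1)), "missing BMI SD")
})

test_that("per-SNP denominators scale panel weights; one-sample refit agrees", {
  sds <- c(female = 5.0, male = 4.1)
  dens <- snp_denominators(small_panel, "father", sds, source = "panel")
  expect_equal(dens$estimate, small_panel$weight * 0.5 * 4.1)
  expect_equal(dens$se, small_panel$weight_se * 0.5 * 4.1)
  # doubling the SD doubles every denominator (units contract)
  dens2 <- snp_denominators(small_panel, "father", 2 * sds, source = "panel")
  expect_equal(dens2$estimate, 2 * dens$estimate)
  # in-cohort refit reproduces the generative weights within MC error
  co <- small_cohort
  insample <- snp_denominators(small_panel, "mother", bmi_sd_by_sex(co),
    source = "cohort", cohort = co
  )
  truth <- small_panel$weight * 0.5 * 5.0
  z <- (insample$estimate - truth) / insample$se
  expect_lt(mean(abs(z) < 2.5), 1.01)
  expect_gt(mean(abs(z) < 2.5), 0.85)
})

test_that("Wald ratio arithmetic, SE conventions and guards", {
  num <- kinmr:::new_assoc("numerator", "grs", 0.001626, 0.0004)
  den <- kinmr:::new_assoc("denominator", "grs", 0.055, 0.0015)
  est <- wald_ratio(num, den, method = "grs_pgmr")
  expect_equal(est$estimate, 0.001626 / 0.055)
  expect_equal(exp(est$estimate), 1.030, tolerance = 1e-3)
  # delta SE by hand
  expect_equal(
    est$se,
    sqrt(0.0004^2 / 0.055^2 + 0.001626^2 * 0.0015^2 / 0.055^4)
  )
  # numerator-only convention drops the second term
  est2 <- wald_ratio(num, den, se_method = "numerator_only")
  expect_equal(est2$se, 0.0004 / 0.055)
  # null numerator: estimate 0, se = num.se / |d|
  nn <- kinmr:::new_assoc("numerator", "grs", 0, 0.0004)
  expect_equal(wald_ratio(nn, den)$estimate, 0)
  expect_equal(wald_ratio(nn, den)$se, 0.0004 / 0.055)
  # known-denominator limit
  dk <- kinmr:::new_assoc("denominator", "grs", 0.055, 0)
  expect_equal(wald_ratio(num, dk)$se, 0.0004 / 0.055)
  # guards
  expect_error(wald_ratio(den, num), "kind mismatch|numerator and one denominator")
  numx <- kinmr:::new_assoc("numerator", "offspring_bmi", 0.01, 0.001)
  expect_error(wald_ratio(numx, den), "labels differ")
  weak <- kinmr:::new_assoc("denominator", "grs", 0.001, 0.01)
  expect_error(wald_ratio(num, weak), "weak instrument")
  expect_s3_class(wald_ratio(num, weak, override_weak = TRUE), "iv_estimate")
  expect_equal(est$ci_upper, est$estimate + 1.96 * est$se)
})

test_that("IVW pooling: symmetric case, dominant-weight limit, WLS equivalence", {
  expect_equal(ivw_combine(make_per_snp(c(0.1, 0.3), c(0.1, 0.1)))$estimate, 0.2)
  expect_equal(ivw_combine(make_per_snp(c(0.1, 0.3), c(0.1, 0.1)))$se, 0.1 / sqrt(2))
  dom <- ivw_combine(make_per_snp(c(0.1, 0.9), c(1e-6, 10)))
  expect_equal(dom$estimate, 0.1, tolerance = 1e-6)
  # algebraic equivalence: IVW with numerator-only ratio SEs equals weighted
  # least squares of numerators on denominators through the origin
  withr::with_seed(3, {
    den <- runif(10, 0.02, 0.1)
    num <- 0.05 * den + rnorm(10, sd = 0.004)
    num_se <- runif(10, 0.002, 0.006)
  })
  per_snp <- make_per_snp(num / den, num_se / den)
  wls <- coef(lm(num ~ 0 + den, weights = 1 / num_se^2))[[1]]
  expect_equal(ivw_combine(per_snp)$estimate, wls, tolerance = 1e-12)
  expect_error(ivw_combine(make_per_snp(0.1, 0.1)), "at least 2")
})

test_that("Egger regression: closed form, pleiotropy shift, guards", {
  tbl <- make_assoc_tbl(den_est = 1:3, num_est = c(0.6, 1.1, 1.6))
  fit <- egger_regression(tbl)
  expect_equal(fit$egger_intercept, 0.1)
  expect_equal(fit$estimate, 0.5)
  # constant pleiotropy c moves the intercept by c, slope unchanged (exact
  # OLS algebra, the InSIDE-satisfying case)
  tblc <- tbl
  tblc$num_est <- tbl$num_est + 0.25
  fitc <- egger_regression(tblc)
  expect_equal(fitc$egger_intercept, 0.35, tolerance = 1e-12)
  expect_equal(fitc$estimate, fit$estimate, tolerance = 1e-12)
  expect_error(egger_regression(tbl[1:2, ]), "at least 3")
  expect_error(egger_regression(make_assoc_tbl(c(1, 1, 1), c(0.5, 0.6, 0.7))), "unidentified")
})

test_that("weighted median: plain median, worked interpolation, breakdown robustness", {
  expect_equal(weighted_median_mr(make_per_snp(c(1, 2, 3), rep(1, 3)), n_boot = 50)$estimate, 2)
  # hand-worked interpolation with normalized weights (0.25, 0.30, 0.45)
  w <- c(0.25, 0.30, 0.45)
  per <- make_per_snp(c(1, 2, 10), 1 / sqrt(w))
  expect_equal(weighted_median_mr(per, n_boot = 50)$estimate, 4.1333, tolerance = 1e-4)
  # 60% valid at the truth, 40% strongly pleiotropic: median stays near the
  # truth while the IVW mean is dragged away
  withr::with_seed(9, {
    k <- 40
    truth <- 0.05
    ratios <- truth + rnorm(k, sd = 0.005)
    ratios[1:16] <- ratios[1:16] + 0.3
    per2 <- make_per_snp(ratios, rep(0.01, k))
  })
  wm <- weighted_median_mr(per2, n_boot = 200, seed = 2)
  ivw <- ivw_combine(per2)
  expect_lt(abs(wm$estimate - truth), 0.02)
  expect_gt(abs(ivw$estimate - truth), 0.08)
  expect_error(weighted_median_mr(make_per_snp(c(1, 2), c(1, 1))), "at least 3")
})

test_that("weighted mode: degenerate spike, plurality cluster, smoothing limit", {
  same <- make_per_snp(rep(0.07, 4), rep(0.01, 4))
  expect_equal(weighted_mode_mr(same, n_boot = 20)$estimate, 0.07)
  withr::with_seed(10, {
    ratios <- c(rnorm(30, 0.05, 0.004), rnorm(12, 0.30, 0.004))
    per <- make_per_snp(ratios, rep(0.01, 42))
  })
  wm <- weighted_mode_mr(per, n_boot = 100, seed = 3)
  expect_lt(abs(wm$estimate - 0.05), 0.02)
  expect_gt(mean(per$estimate), 0.1) # the mean is pulled toward the minority
  # bandwidth -> infinity recovers the weighted mean
  big <- weighted_mode_mr(per, bandwidth_factor = 5e3, n_boot = 20, seed = 3)
  wmean <- weighted.mean(per$estimate, 1 / per$se^2)
  expect_equal(big$estimate, wmean, tolerance = 1e-2)
  expect_error(weighted_mode_mr(per, bandwidth_factor = 0), "positive")
})

test_that("combiners are invariant to flipping SNP orientation", {
  withr::with_seed(12, {
    den <- runif(20, 0.02, 0.1)
    num <- 0.05 * den + rnorm(20, sd = 0.003)
    tbl <- make_assoc_tbl(den, num, num_se = 0.003, den_se = 0.002)
  })
  flip <- rep(1, 20)
  flip[c(2, 5, 11)] <- -1
  tbl_f <- tbl
  tbl_f$num_est <- tbl$num_est * flip
  tbl_f$den_est <- tbl$den_est * flip
  nums <- function(t) kinmr:::new_assoc("numerator", t$instrument_label, t$num_est, t$num_se)
  dens <- function(t) kinmr:::new_assoc("denominator", t$instrument_label, t$den_est, t$den_se)
  a <- summary_pgmr(nums(tbl), dens(tbl), n_boot = 100, seed = 4)
  b <- summary_pgmr(nums(tbl_f), dens(tbl_f), n_boot = 100, seed = 4)
  expect_equal(a$per_snp$estimate, b$per_snp$estimate, tolerance = 1e-12)
  expect_equal(a$estimates$estimate, b$estimates$estimate, tolerance = 1e-12)
  expect_equal(
    a$estimates$egger_intercept[a$estimates$method == "egger_slope"],
    b$estimates$egger_intercept[b$estimates$method == "egger_slope"],
    tolerance = 1e-12
  )
})

test_that("multiplying all denominators by c divides every causal estimate by c", {
  withr::with_seed(13, {
    den <- runif(15, 0.02, 0.1)
    num <- 0.05 * den + rnorm(15, sd = 0.003)
    tbl <- make_assoc_tbl(den, num, num_se = 0.003, den_se = 0.001)
  })
  cc <- 2.5
  tbl_c <- tbl
  tbl_c$den_est <- tbl$den_est * cc
  tbl_c$den_se <- tbl$den_se * cc
  nums <- function(t) kinmr:::new_assoc("numerator", t$instrument_label, t$num_est, t$num_se)
  dens <- function(t) kinmr:::new_assoc("denominator", t$instrument_label, t$den_est, t$den_se)
  a <- summary_pgmr(nums(tbl), dens(tbl), n_boot = 100, seed = 5)
  b <- summary_pgmr(nums(tbl_c), dens(tbl_c), n_boot = 100, seed = 5)
  expect_equal(b$estimates$estimate, a$estimates$estimate / cc, tolerance = 1e-9)
})

test_that("fixed-effect meta-analysis: degenerate, closed-form and external checks", {
  two <- make_per_snp(c(0.1, 0.1), c(0.05, 0.05))
  m0 <- meta_fixed(two)
  expect_equal(m0$Q, 0)
  expect_equal(m0$i2, 0)
  expect_equal(m0$estimate, 0.1)
  # k = 2: Q equals the squared two-sample z statistic
  pair <- make_per_snp(c(0.12, 0.03), c(0.04, 0.02))
  z <- (0.12 - 0.03) / sqrt(0.04^2 + 0.02^2)
  expect_equal(meta_fixed(pair)$Q, z^2, tolerance = 1e-12)
  expect_identical(meta_fixed(pair)$df, 1)
  expect_error(meta_fixed(two[1, ]), "at least 2")
  # independent implementation cross-check
  skip_if_not_installed("metafor")
  withr::with_seed(14, {
    est <- make_per_snp(rnorm(6, 0.1, 0.05), runif(6, 0.02, 0.08))
  })
  ours <- meta_fixed(est)
  rma <- metafor::rma(yi = est$estimate, sei = est$se, method = "FE")
  expect_equal(ours$estimate, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(ours$se, rma$se, tolerance = 1e-10)
  expect_equal(ours$Q, rma$QE, tolerance = 1e-10)
  expect_equal(ours$i2, max(0, (rma$QE - 5) / rma$QE) * 100, tolerance = 1e-8)
})
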