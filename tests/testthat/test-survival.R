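test_that("entry-age imputation fills deceased parents from living ones by stratum", {
  co <- tibble::tibble(
    offspring_id = paste0("o", 1:6),
    parent_sex = rep(c("mother", "father"), each = 3),
    parent_alive_at_assessment = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    parent_entry_age = c(25, 35, NA, 20, 40, NA),
    parent_age_obs = 80
  )
  out <- impute_entry_age(co, "mean")
  expect_equal(out$parent_entry_age[3], 30) # mean of 25, 35
  expect_equal(out$parent_entry_age[6], 30) # mean of 20, 40, own stratum
  expect_equal(out$parent_entry_age[1:2], c(25, 35)) # observed values untouched
  # median equals mean on symmetric ages
  expect_equal(
    impute_entry_age(co, "percentile:50")$parent_entry_age[3],
    out$parent_entry_age[3]
  )
  expect_error(impute_entry_age(co, "percentile:101"), "percentile")
  co_dead <- co
  co_dead$parent_alive_at_assessment[1:2] <- FALSE
  co_dead$parent_entry_age[1:2] <- NA
  expect_error(impute_entry_age(co_dead, "mean"), "no living parents")
})

test_that("entry-age percentile choice barely moves the hazard ratio", {
  co <- simulate_trios(small_panel, 8000, trio_params(), seed = 37) |>
    add_grs(small_panel)
  est <- vapply(c("percentile:5", "percentile:95"), function(rule) {
    fit_ph_numerator(impute_entry_age(co, rule), "offspring_bmi",
      parent_sex = "mother", adjustment = "unadjusted"
    )$estimate
  }, numeric(1))
  # entry ages lie far below the first deaths, so risk sets barely change
  expect_lt(abs(est[1] - est[2]), 0.005)
})

test_that("toy Cox fit matches brute-force maximization of the partial likelihood", {
  oracle <- stats::optimize(toy_logpl, c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum
  fit <- fit_ph_numerator(toy_cohort, "offspring_bmi", adjustment = "unadjusted")
  expect_equal(fit$estimate, oracle, tolerance = 1e-6)
  expect_identical(fit$n_events, 3L)
})

test_that("delayed entry removes subjects from risk sets before their entry age", {
  # Three subjects; subject B enters between the two event times under
  # entry_late, before both under entry_early. Brute-force partial
  # likelihoods differ, and the fitted coefficient tracks the correct one.
  base <- tibble::tibble(
    offspring_id = c("a", "b", "c"),
    offspring_dob = 1950, offspring_bmi = c(0, 1, 0.5),
    parent_sex = "mother",
    parent_alive_at_assessment = c(FALSE, FALSE, TRUE),
    parent_age_obs = c(2, 3, 4)
  )
  x <- base$offspring_bmi
  pl_all_in <- function(b) {
    (b * x[1] - log(sum(exp(b * x)))) + (b * x[2] - log(sum(exp(b * x[2:3]))))
  }
  pl_b_late <- function(b) {
    (b * x[1] - log(exp(b * x[1]) + exp(b * x[3]))) +
      (b * x[2] - log(sum(exp(b * x[2:3]))))
  }
  for (case in list(
    list(entry = c(0, 1.5, 0), oracle = pl_all_in),
    list(entry = c(0, 2.5, 0), oracle = pl_b_late)
  )) {
    co <- dplyr::mutate(base, parent_entry_age = case$entry)
    fit <- fit_ph_numerator(co, "offspring_bmi", adjustment = "unadjusted")
    oracle <- stats::optimize(case$oracle, c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
    expect_equal(fit$estimate, oracle, tolerance = 1e-6)
  }
})

test_that("numerator is scale-equivariant in the instrument", {
  co <- small_cohort
  f1 <- fit_ph_numerator(co, "grs", parent_sex = "mother", adjustment = "unadjusted")
  co$grs <- co$grs / 10
  f2 <- fit_ph_numerator(co, "grs", parent_sex = "mother", adjustment = "unadjusted")
  expect_equal(f2$estimate, 10 * f1$estimate, tolerance = 1e-6)
  expect_equal(f2$estimate / f2$se, f1$estimate / f1$se, tolerance = 1e-6)
})

test_that("numerator guards degenerate inputs", {
  co <- small_cohort
  co$flat <- 1
  expect_error(
    fit_ph_numerator(co, "flat", parent_sex = "mother"),
    "zero variance"
  )
  co_na <- simulate_trios(tiny_panel, 100, trio_params(), seed = 41)
  expect_error(
    fit_ph_numerator(co_na, "offspring_bmi", parent_sex = "mother"),
    "impute_entry_age"
  )
})

test_that("proportional simulations pass diagnostics; split beyond range errors", {
  num <- fit_ph_numerator(small_cohort, "offspring_bmi",
    parent_sex = "mother", adjustment = "unadjusted"
  )
  d <- ph_diagnostics(num, small_cohort, split_age = 70)
  # proportional generator: pre/post log-HRs agree within a joint interval
  z <- (d$loghr_pre - d$loghr_post) / sqrt(d$se_pre^2 + d$se_post^2)
  expect_lt(abs(z), 3)
  expect_true(abs(d$schoenfeld_corr) <= 1)
  expect_error(ph_diagnostics(num, small_cohort, split_age = 200), "fewer than 3 events")
})

test_that("a hazard effect that vanishes after the split age shows as attenuation", {
  # Designed non-proportional oracle: piecewise-constant hazard with the
  # covariate acting only before age 70; built directly, not via the trio
  # generator.
  n <- 6000
  withr::with_seed(47, {
    x <- rnorm(n)
    h0 <- 0.04
    b <- 0.5
    # draw death ages from the piecewise-exponential starting at age 50
    u <- runif(n)
    rate1 <- h0 * exp(b * x)
    t1 <- 50 + (-log(u) / rate1)
    t <- ifelse(t1 <= 70, t1, 70 + (t1 - 70) * rate1 / h0)
  })
  co <- tibble::tibble(
    offspring_id = paste0("o", seq_len(n)),
    offspring_dob = 1950, offspring_bmi = x,
    parent_sex = "mother",
    parent_entry_age = 50,
    parent_age_obs = pmin(t, 95),
    parent_alive_at_assessment = t > 95
  )
  num <- fit_ph_numerator(co, "offspring_bmi", adjustment = "unadjusted")
  d <- ph_diagnostics(num, co, split_age = 70)
  expect_equal(d$loghr_pre, 0.5, tolerance = 0.1)
  expect_lt(d$loghr_post, d$loghr_pre - 2 * sqrt(d$se_pre^2 + d$se_post^2))
  expect_lt(d$p_value, 0.01) # Schoenfeld correlation flags the violation
})

test_that("covariate scans recover generator loadings with the right asymmetry", {
  ce <- tibble::tribble(
    ~name,    ~beta_bmi_o, ~beta_bmi_p, ~beta_loghr,
    "cov_a",  0.5,         0.3,         0,
    "cov_b",  0,           0,           0.3
  )
  pars <- trio_params(covariate_effects = ce, rho_mate = 0.25)
  co <- simulate_trios(small_panel, 8000, pars, seed = 53) |>
    add_grs(small_panel) |>
    impute_entry_age()

  bmi_scan <- covariate_scan(co, "bmi")
  off <- dplyr::distinct(tibble::as_tibble(co), offspring_id, .keep_all = TRUE)
  sd_mix <- mean(ifelse(off$offspring_sex == "daughter", 5.0, 4.1))
  a_row <- bmi_scan[bmi_scan$covariate == "cov_a", ]
  expect_lt(abs(a_row$estimate - 0.5 * sd_mix), 4 * a_row$se)
  b_row <- bmi_scan[bmi_scan$covariate == "cov_b", ]
  expect_lt(abs(b_row$estimate), 3 * b_row$se)

  grs_scan <- covariate_scan(co, "grs")
  expect_true(all(abs(grs_scan$estimate) < 4 * grs_scan$se))

  surv_scan <- covariate_scan(co, "parent_survival")
  b_surv <- surv_scan[surv_scan$covariate == "cov_b" & surv_scan$parent_sex == "mother", ]
  expect_gt(b_surv$estimate / b_surv$se, 4) # E2-style covariate hits mortality...
  expect_equal(b_surv$estimate, 0.3, tolerance = 0.1)
  g_b <- grs_scan[grs_scan$covariate == "cov_b", ]
  expect_lt(abs(g_b$estimate), 3 * g_b$se) # ...but not the genetic instrument

  co$constant <- 2
  expect_warning(covariate_scan(co, "bmi", covariates = c("cov_a", "constant")), "constant")
})
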