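# Shared small fixtures, built once per test run.

tiny_panel <- simulate_snp_panel(10, total_h2 = 0.02, seed = 42)

# Moderate cohort under default (valid-instrument) conditions.
small_panel <- simulate_snp_panel(30, total_h2 = 0.02, seed = 42)
small_cohort <- simulate_trios(small_panel, 3000, trio_params(), seed = 43) |>
  add_grs(small_panel) |>
  impute_entry_age()

# Four-subject survival toy with an analytic partial likelihood (no ties,
# no delayed entry): exits 1..4, events on the first three, binary covariate.
toy_cohort <- tibble::tibble(
  family_id = 1:4,
  offspring_id = paste0("o", 1:4),
  offspring_sex = "daughter",
  offspring_dob = 1950,
  offspring_bmi = c(1, 0, 1, 0),
  parent_sex = "mother",
  parent_alive_at_assessment = c(FALSE, FALSE, FALSE, TRUE),
  parent_age_obs = c(1, 2, 3, 4),
  parent_entry_age = 0
)

# Explicit log partial likelihood for toy_cohort with covariate offspring_bmi.
toy_logpl <- function(b) {
  x <- c(1, 0, 1, 0)
  (b * x[1] - log(sum(exp(b * x)))) +
    (b * x[2] - log(sum(exp(b * x[2:4])))) +
    (b * x[3] - log(sum(exp(b * x[3:4]))))
}

# Build a minimal per-SNP summary table for the combiners.
make_assoc_tbl <- function(den_est, num_est, num_se = 1, den_se = 0) {
  k <- length(den_est)
  tibble::tibble(
    instrument_label = sprintf("snp_%03d", seq_len(k)),
    num_est = num_est, num_se = rep_len(num_se, k),
    den_est = den_est, den_se = rep_len(den_se, k)
  )
}

make_per_snp <- function(estimate, se) {
  tibble::tibble(
    estimate = estimate, se = se,
    parent_sex = "both", offspring_sex = "both", adjustment = "unadjusted"
  )
}
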