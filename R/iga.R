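#' Fit an intergenerational BMI association in a reference cohort
#'
#' Estimates the OAI denominator — the difference in parental BMI (kg/m2)
#' per kg/m2 of offspring BMI — by linear regression in a cohort where both
#' generations' BMI are measured (emulating an external birth-cohort study;
#' on simulated data the parental BMI column is the simulator's
#' `true_parent_bmi`, which such a study would observe directly). Fit
#' separately by parent/offspring sex pairing; `adjustment = "adjusted"` adds
#' the covariate columns.
#'
#' `fit_iga(direction = "offspring_on_parent")` gives the published-style
#' forward regression instead, for use with [invert_iga()].
#'
#' @param cohort A cohort tibble with `offspring_bmi` and a parental BMI
#'   column.
#' @param parent_sex,offspring_sex Stratum selectors.
#' @param adjustment `"unadjusted"` or `"adjusted"`.
#' @param covariates Covariates for the adjusted fit.
#' @param direction `"parent_on_offspring"` (denominator-ready) or
#'   `"offspring_on_parent"` (published convention).
#' @param parent_bmi_col Name of the parental BMI column.
#' @return A one-row `instrument_assoc` denominator (for
#'   `"parent_on_offspring"`), or a plain tibble with `estimate`, `se`,
#'   `sd_parent`, `sd_offspring`, `n` (for the forward direction).
#' @export
fit_iga <- function(cohort, parent_sex, offspring_sex = "both",
                    adjustment = c("unadjusted", "adjusted"),
                    covariates = covariate_cols(cohort),
                    direction = c("parent_on_offspring", "offspring_on_parent"),
                    parent_bmi_col = "true_parent_bmi") {
  adjustment <- match.arg(adjustment)
  direction <- match.arg(direction)
  assert_cols(cohort, c("offspring_bmi", parent_bmi_col), "cohort")
  d <- cohort
  if (parent_sex != "both") d <- dplyr::filter(d, .data$parent_sex == !!parent_sex)
  if (offspring_sex != "both") d <- dplyr::filter(d, .data$offspring_sex == !!offspring_sex)
  if (nrow(d) < 10) stop("too few pairs to estimate an IGA", call. = FALSE)
  yx <- if (direction == "parent_on_offspring") {
    c(parent_bmi_col, "offspring_bmi")
  } else {
    c("offspring_bmi", parent_bmi_col)
  }
  terms <- yx[2]
  if (adjustment == "adjusted") terms <- c(terms, covariates)
  fit <- lm(as.formula(paste(yx[1], "~", paste(terms, collapse = " + "))), data = d)
  s <- summary(fit)$coefficients
  if (direction == "parent_on_offspring") {
    new_assoc(
      "denominator", "offspring_bmi",
      unname(s[yx[2], 1]), unname(s[yx[2], 2]),
      parent_sex = parent_sex, offspring_sex = offspring_sex,
      adjustment = adjustment, n = nrow(d), source = "external"
    )
  } else {
    tibble::tibble(
      estimate = unname(s[yx[2], 1]), se = unname(s[yx[2], 2]),
      sd_parent = sd(d[[parent_bmi_col]]), sd_offspring = sd(d$offspring_bmi),
      parent_sex = parent_sex, offspring_sex = offspring_sex,
      adjustment = adjustment, n = nrow(d)
    )
  }
}
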