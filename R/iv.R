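# Instrument-exposure and instrument-outcome associations are carried as
# `instrument_assoc` rows; causal estimates as `iv_estimate` rows. The two
# kinds never mix: numerators are log-HR per instrument unit, denominators
# kg/m2 per instrument unit.

new_assoc <- function(kind, instrument_label, estimate, se,
                      parent_sex = "both", offspring_sex = "both",
                      adjustment = "unadjusted", n = NA_integer_,
                      n_events = NA_integer_, source = "external") {
  if (any(se < 0, na.rm = TRUE)) stop("standard errors must be non-negative", call. = FALSE)
  tibble::new_tibble(
    tibble::tibble(
      kind = kind, instrument_label = instrument_label,
      estimate = estimate, se = se,
      parent_sex = parent_sex, offspring_sex = offspring_sex,
      adjustment = adjustment, n = n, n_events = n_events, source = source
    ),
    class = "instrument_assoc"
  )
}

new_iv_estimate <- function(method, estimate, se, parent_sex = "both",
                            offspring_sex = "both", adjustment = "unadjusted",
                            n_snps = NA_integer_,
                            egger_intercept = NA_real_, egger_intercept_se = NA_real_) {
  ci <- ci95(estimate, se)
  tibble::new_tibble(
    tibble::tibble(
      method = method, estimate = estimate, se = se,
      ci_lower = ci$ci_lower, ci_upper = ci$ci_upper,
      hr = exp(estimate), hr_lower = exp(ci$ci_lower), hr_upper = exp(ci$ci_upper),
      parent_sex = parent_sex, offspring_sex = offspring_sex,
      adjustment = adjustment, n_snps = n_snps,
      egger_intercept = egger_intercept, egger_intercept_se = egger_intercept_se
    ),
    class = "iv_estimate"
  )
}

#' Sex-specific BMI standard deviations and Z-scores
#'
#' `bmi_sd_by_sex()` returns the in-cohort SD of offspring BMI by sex (named
#' `female`/`male`); `add_bmi_zscore()` adds a `bmi_z` column holding the
#' sex-specific Z-score of offspring BMI, the exposure scale on which
#' genotype-BMI slopes are estimated before conversion to kg/m2.
#'
#' @param cohort A `kin_cohort` tibble.
#' @return A named numeric vector, or the cohort with a `bmi_z` column.
#' @export
bmi_sd_by_sex <- function(cohort) {
  d <- dplyr::distinct(tibble::as_tibble(cohort), .data$offspring_id, .keep_all = TRUE)
  c(
    female = sd(d$offspring_bmi[d$offspring_sex == "daughter"]),
    male = sd(d$offspring_bmi[d$offspring_sex == "son"])
  )
}

#' @rdname bmi_sd_by_sex
#' @export
add_bmi_zscore <- function(cohort) {
  out <- cohort |>
    dplyr::group_by(.data$offspring_sex) |>
    dplyr::mutate(bmi_z = as.numeric(scale(.data$offspring_bmi))) |>
    dplyr::ungroup()
  atts <- attributes(cohort)
  attr(out, "true_params") <- atts$true_params
  attr(out, "seed") <- atts$seed
  tibble::new_tibble(out, class = "kin_cohort")
}

parent_sd <- function(parent_sex, sd_by_sex) {
  key <- switch(parent_sex,
    mother = "female", father = "male",
    stop("parent_sex must be \"mother\" or \"father\"", call. = FALSE)
  )
  if (is.na(sd_by_sex[key] %||% NA)) stop("missing BMI SD for parent sex ", parent_sex, call. = FALSE)
  unname(sd_by_sex[key])
}

#' Invert a published intergenerational BMI association
#'
#' External intergenerational associations (IGAs) are usually reported as
#' offspring BMI per kg/m2 of parental BMI; the OAI denominator needs the
#' reverse regression. By covariance algebra the reverse slope is
#' `b * (sd_parent / sd_offspring)^2`, with the SE scaled by the same factor.
#'
#' @param b_offspring_on_parent Published slope (kg/m2 per kg/m2).
#' @param se Its standard error.
#' @param sd_parent,sd_offspring BMI SDs (kg/m2) in the source sample.
#' @param parent_sex,offspring_sex,adjustment,source Metadata carried on the
#'   resulting denominator.
#' @return A one-row `instrument_assoc` (`kind = "denominator"`,
#'   `instrument_label = "offspring_bmi"`).
#' @examples
#' invert_iga(0.2, 0.02, sd_parent = 4, sd_offspring = 5)$estimate # 0.128
#' @export
invert_iga <- function(b_offspring_on_parent, se, sd_parent, sd_offspring,
                       parent_sex = "both", offspring_sex = "both",
                       adjustment = "unadjusted", source = "external") {
  if (sd_parent <= 0 || sd_offspring <= 0) stop("BMI SDs must be positive", call. = FALSE)
  f <- (sd_parent / sd_offspring)^2
  new_assoc(
    "denominator", "offspring_bmi", b_offspring_on_parent * f, se * f,
    parent_sex, offspring_sex, adjustment,
    source = source
  )
}

#' GRS-PGMR denominator from a genotype-phenotype Z-score slope
#'
#' Converts the effect of the GRS on offspring sex-specific BMI Z-scores
#' (`b`, in SD units per GRS unit) into the instrument-exposure association
#' for *parental* BMI: multiplied by 0.5 for the one generation separating
#' instrument and exposure, and by the BMI SD of the sex corresponding to the
#' parent. The SE is scaled identically.
#'
#' @param b_zscore_per_grs Slope of sex-specific BMI Z-score on GRS.
#' @param se Its standard error.
#' @param parent_sex `"mother"` or `"father"`.
#' @param sd_by_sex Named numeric vector with `female` and `male` BMI SDs
#'   (kg/m2), e.g. from [bmi_sd_by_sex()].
#' @param adjustment,source Metadata.
#' @return A one-row `instrument_assoc` denominator for instrument `"grs"`
#'   (kg/m2 per GRS unit).
#' @export
grs_pgmr_denominator <- function(b_zscore_per_grs, se, parent_sex, sd_by_sex,
                                 adjustment = "unadjusted", source = "cohort") {
  s <- parent_sd(parent_sex, sd_by_sex)
  new_assoc(
    "denominator", "grs",
    b_zscore_per_grs * 0.5 * s, se * 0.5 * s,
    parent_sex = parent_sex, adjustment = adjustment, source = source
  )
}

#' Fit the GRS-to-BMI Z-score slope in a cohort
#'
#' Linear regression of sex-specific BMI Z-scores on the GRS, adjusted for
#' offspring date of birth and any `pc_*` columns ("unadjusted" convention),
#' plus the supplied covariates when `adjustment = "adjusted"`. One row per
#' offspring is used.
#'
#' @inheritParams fit_ph_numerator
#' @return A list with `b`, `se`, `n`.
#' @export
fit_grs_zscore_slope <- function(cohort, adjustment = c("unadjusted", "adjusted"),
                                 covariates = covariate_cols(cohort)) {
  adjustment <- match.arg(adjustment)
  assert_cols(cohort, "grs", "cohort")
  d <- dplyr::distinct(tibble::as_tibble(add_bmi_zscore(cohort)),
    .data$offspring_id,
    .keep_all = TRUE
  )
  terms <- c("grs", "offspring_dob", pc_cols(cohort))
  if (adjustment == "adjusted") terms <- c(terms, covariates)
  fit <- lm(as.formula(paste("bmi_z ~", paste(unique(terms), collapse = " + "))), data = d)
  s <- summary(fit)$coefficients
  list(b = unname(s["grs", 1]), se = unname(s["grs", 2]), n = nrow(d))
}

#' Per-SNP instrument-exposure denominators
#'
#' For each SNP the denominator is the per-allele effect on *parental* BMI in
#' kg/m2: the SD-unit weight times the BMI SD of the parent's sex, halved for
#' the generation gap. `source = "panel"` takes the weights from external
#' summary statistics (two-sample design); `source = "cohort"` refits each
#' per-allele slope on sex-specific BMI Z-scores in the cohort itself
#' (one-sample design), adjusted for offspring date of birth and `pc_*`
#' columns (plus covariates when `adjustment = "adjusted"`).
#'
#' @param panel An `snp_panel`; only rows with `include_flag = TRUE` are used.
#' @param parent_sex `"mother"` or `"father"`.
#' @param sd_by_sex Named `female`/`male` BMI SD vector.
#' @param source `"panel"` or `"cohort"`.
#' @param cohort Required when `source = "cohort"`.
#' @param adjustment,covariates Adjustment set for the in-cohort refit.
#' @return An `instrument_assoc` tibble, one denominator row per SNP
#'   (`instrument_label = snp_id`).
#' @export
snp_denominators <- function(panel, parent_sex, sd_by_sex,
                             source = c("panel", "cohort"), cohort = NULL,
                             adjustment = c("unadjusted", "adjusted"),
                             covariates = if (!is.null(cohort)) covariate_cols(cohort) else character()) {
  source <- match.arg(source)
  adjustment <- match.arg(adjustment)
  use <- panel[panel$include_flag %||% TRUE, , drop = FALSE]
  s <- parent_sd(parent_sex, sd_by_sex)
  if (source == "panel") {
    if (any(use$weight_se <= 0)) stop("panel weight SEs must be positive", call. = FALSE)
    return(new_assoc(
      "denominator", use$snp_id, use$weight * 0.5 * s, use$weight_se * 0.5 * s,
      parent_sex = parent_sex, adjustment = adjustment, source = "panel"
    ))
  }
  if (is.null(cohort)) stop("source = \"cohort\" requires a cohort", call. = FALSE)
  d <- dplyr::distinct(tibble::as_tibble(add_bmi_zscore(cohort)),
    .data$offspring_id,
    .keep_all = TRUE
  )
  adj <- c("offspring_dob", pc_cols(cohort))
  if (adjustment == "adjusted") adj <- c(adj, covariates)
  # Frisch-Waugh-Lovell: residualize the outcome and every dosage column on
  # the adjustment set once, then per-SNP slopes are simple regressions.
  X <- cbind(1, as.matrix(d[, unique(adj), drop = FALSE]))
  qr_x <- qr(X)
  y_res <- qr.resid(qr_x, d$bmi_z)
  D_res <- qr.resid(qr_x, as.matrix(d[, use$snp_id, drop = FALSE]))
  sxx <- colSums(D_res^2)
  b <- colSums(D_res * y_res) / sxx
  df <- nrow(d) - ncol(X) - 1
  resid_var <- (sum(y_res^2) - b^2 * sxx) / df
  se <- sqrt(resid_var / sxx)
  new_assoc(
    "denominator", use$snp_id, unname(b) * 0.5 * s, unname(se) * 0.5 * s,
    parent_sex = parent_sex, adjustment = adjustment, source = "cohort",
    n = nrow(d)
  )
}

#' Per-SNP mortality numerators
#'
#' Fits one Cox numerator per panel SNP via [fit_ph_numerator()] (log-HR per
#' effect allele, parental age axis, delayed entry).
#'
#' @inheritParams fit_ph_numerator
#' @param panel An `snp_panel`; rows with `include_flag = FALSE` are skipped.
#' @return An `instrument_assoc` tibble, one numerator row per SNP.
#' @export
snp_numerators <- function(cohort, panel, parent_sex = "both",
                           adjustment = c("unadjusted", "adjusted"),
                           covariates = covariate_cols(cohort)) {
  adjustment <- match.arg(adjustment)
  use <- panel[panel$include_flag %||% TRUE, , drop = FALSE]
  dplyr::bind_rows(purrr::map(use$snp_id, function(id) {
    fit_ph_numerator(cohort, id,
      parent_sex = parent_sex,
      adjustment = adjustment, covariates = covariates
    )
  }))
}

#' Wald ratio: causal log hazard ratio from a numerator/denominator pair
#'
#' `estimate = numerator / denominator` (log-HR per kg/m2). The default SE
#' is the first-order two-sample delta method assuming independent samples,
#' `se^2 = num_se^2 / d^2 + num^2 den_se^2 / d^4`; `se_method =
#' "numerator_only"` keeps only the first term (the convention under which
#' IVW equals a weighted regression through the origin). A weak-instrument
#' guard refuses denominators with `|estimate| / se` below `weak_threshold`
#' unless `override_weak = TRUE`.
#'
#' @param num,den One-row `instrument_assoc` objects of matching
#'   `instrument_label`, kinds `numerator` and `denominator`.
#' @param method Label for the resulting estimate (e.g. `"oai"`,
#'   `"grs_pgmr"`, `"wald"`).
#' @param se_method `"delta"` or `"numerator_only"`.
#' @param weak_threshold Minimum denominator `|estimate|/se`.
#' @param override_weak Proceed despite a weak denominator.
#' @return A one-row `iv_estimate` tibble.
#' @export
wald_ratio <- function(num, den, method = "wald",
                       se_method = c("delta", "numerator_only"),
                       weak_threshold = 2, override_weak = FALSE) {
  se_method <- match.arg(se_method)
  if (!identical(num$kind, "numerator") || !identical(den$kind, "denominator")) {
    stop("wald_ratio() needs one numerator and one denominator (kind mismatch)", call. = FALSE)
  }
  if (!identical(num$instrument_label, den$instrument_label)) {
    stop(sprintf(
      "instrument labels differ: numerator %s vs denominator %s",
      num$instrument_label, den$instrument_label
    ), call. = FALSE)
  }
  d <- den$estimate
  if (d == 0) stop("denominator is exactly zero: instrument carries no exposure signal", call. = FALSE)
  if (den$se > 0 && abs(d) / den$se < weak_threshold && !override_weak) {
    stop(sprintf(
      "weak instrument: |denominator|/SE = %.2f < %g (set override_weak = TRUE to proceed)",
      abs(d) / den$se, weak_threshold
    ), call. = FALSE)
  }
  est <- num$estimate / d
  se2 <- num$se^2 / d^2
  if (se_method == "delta") se2 <- se2 + num$estimate^2 * den$se^2 / d^4
  new_iv_estimate(
    method, est, sqrt(se2),
    parent_sex = num$parent_sex, offspring_sex = num$offspring_sex,
    adjustment = num$adjustment
  )
}

# Join per-SNP numerators and denominators on instrument label.
snp_assoc_table <- function(numerators, denominators) {
  stopifnot(all(numerators$kind == "numerator"), all(denominators$kind == "denominator"))
  tbl <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(numerators),
      "instrument_label",
      num_est = "estimate", num_se = "se",
      "parent_sex", "offspring_sex", "adjustment"
    ),
    dplyr::select(tibble::as_tibble(denominators),
      "instrument_label",
      den_est = "estimate", den_se = "se"
    ),
    by = "instrument_label"
  )
  if (nrow(tbl) < 2) stop("fewer than 2 SNPs shared between numerators and denominators", call. = FALSE)
  tbl
}

#' Inverse-variance-weighted mean of per-SNP Wald ratios
#'
#' `estimate = sum(w_j b_j) / sum(w_j)` with `w_j = 1 / se_j^2` and
#' `se = (sum w_j)^{-1/2}`.
#'
#' @param per_snp An `iv_estimate` tibble with >= 2 rows (one per SNP).
#' @return A one-row `iv_estimate` with `method = "ivw"`.
#' @export
ivw_combine <- function(per_snp) {
  if (nrow(per_snp) < 2) stop("IVW needs at least 2 instruments", call. = FALSE)
  w <- 1 / per_snp$se^2
  new_iv_estimate(
    "ivw", sum(w * per_snp$estimate) / sum(w), 1 / sqrt(sum(w)),
    parent_sex = per_snp$parent_sex[1], offspring_sex = per_snp$offspring_sex[1],
    adjustment = per_snp$adjustment[1], n_snps = nrow(per_snp)
  )
}

#' MR-Egger regression on per-SNP summary associations
#'
#' Weighted linear regression of per-SNP outcome associations (numerators) on
#' exposure associations (denominators) with a free intercept, weights
#' `1 / num_se^2`. Denominators are first oriented positive (numerators
#' re-signed accordingly). The slope is the causal log-HR per kg/m2; the
#' intercept estimates directional pleiotropy.
#'
#' @param assoc_tbl Output of joining per-SNP numerators and denominators
#'   (columns `num_est`, `num_se`, `den_est`, `den_se`), >= 3 rows.
#' @return A one-row `iv_estimate` with `method = "egger_slope"` and the
#'   intercept in `egger_intercept` / `egger_intercept_se`.
#' @export
egger_regression <- function(assoc_tbl) {
  if (nrow(assoc_tbl) < 3) stop("MR-Egger needs at least 3 instruments", call. = FALSE)
  flip <- sign(assoc_tbl$den_est)
  flip[flip == 0] <- 1
  x <- assoc_tbl$den_est * flip
  y <- assoc_tbl$num_est * flip
  if (var(x) == 0) stop("all denominators equal: Egger slope unidentified", call. = FALSE)
  fit <- lm(y ~ x, weights = 1 / assoc_tbl$num_se^2)
  s <- suppressWarnings(summary(fit))$coefficients
  col_or <- function(col, default) {
    if (col %in% names(assoc_tbl)) assoc_tbl[[col]][1] else default
  }
  new_iv_estimate(
    "egger_slope", unname(s["x", 1]), unname(s["x", 2]),
    parent_sex = col_or("parent_sex", "both"),
    offspring_sex = col_or("offspring_sex", "both"),
    adjustment = col_or("adjustment", "unadjusted"),
    n_snps = nrow(assoc_tbl),
    egger_intercept = unname(s["(Intercept)", 1]),
    egger_intercept_se = unname(s["(Intercept)", 2])
  )
}

weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(b[1])
  if (0.5 >= p[length(p)]) return(b[length(b)])
  stats::approx(p, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted median of per-SNP Wald ratios
#'
#' Orders the per-SNP ratio estimates, forms cumulative normalized
#' inverse-variance weights at interval midpoints, and linearly interpolates
#' the estimate at cumulative weight 0.5. Consistent when instruments
#' carrying at least half the weight are valid. The SE comes from a seeded
#' parametric bootstrap (ratios perturbed by their SEs).
#'
#' @param per_snp An `iv_estimate` tibble (>= 3 rows).
#' @param n_boot Bootstrap draws for the SE.
#' @param seed Seed for the bootstrap.
#' @return A one-row `iv_estimate` with `method = "weighted_median"`.
#' @export
weighted_median_mr <- function(per_snp, n_boot = 2000, seed = 1) {
  if (nrow(per_snp) < 3) stop("weighted median needs at least 3 instruments", call. = FALSE)
  b <- per_snp$estimate
  w <- 1 / per_snp$se^2
  est <- weighted_median_point(b, w)
  se <- with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      weighted_median_point(rnorm(length(b), b, per_snp$se), w)
    }, numeric(1))
    sd(reps)
  })
  new_iv_estimate(
    "weighted_median", est, se,
    parent_sex = per_snp$parent_sex[1], offspring_sex = per_snp$offspring_sex[1],
    adjustment = per_snp$adjustment[1], n_snps = nrow(per_snp)
  )
}

weighted_mode_point <- function(b, w, bandwidth_factor = 1) {
  if (length(unique(b)) == 1L) return(b[1])
  s <- 0.9 * min(sd(b), stats::mad(b)) * length(b)^(-1 / 5)
  if (s <= 0) s <- 0.9 * sd(b) * length(b)^(-1 / 5)
  h <- bandwidth_factor * s
  w <- w / sum(w)
  dens <- function(x) {
    vapply(x, function(xi) sum(w * stats::dnorm((xi - b) / h)), numeric(1))
  }
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 512)
  x0 <- grid[which.max(dens(grid))]
  step <- diff(grid[1:2])
  stats::optimize(dens, c(x0 - step, x0 + step), maximum = TRUE)$maximum
}

#' Weighted mode of per-SNP Wald ratios
#'
#' Mode of the inverse-variance-weighted Gaussian-kernel-smoothed density of
#' the ratio estimates; consistent when the largest weighted group of
#' instruments sharing the same causal estimate is valid. Bandwidth is
#' `bandwidth_factor` times a normal-reference rule on the ratio spread
#' (`0.9 min(sd, mad) n^{-1/5}`); as the factor grows the estimate tends to
#' the weighted mean. SE by seeded parametric bootstrap.
#'
#' @inheritParams weighted_median_mr
#' @param bandwidth_factor Positive multiplier on the reference bandwidth.
#' @return A one-row `iv_estimate` with `method = "weighted_mode"`.
#' @export
weighted_mode_mr <- function(per_snp, bandwidth_factor = 1, n_boot = 2000, seed = 1) {
  if (nrow(per_snp) < 3) stop("weighted mode needs at least 3 instruments", call. = FALSE)
  if (bandwidth_factor <= 0) stop("bandwidth_factor must be positive", call. = FALSE)
  b <- per_snp$estimate
  w <- 1 / per_snp$se^2
  est <- weighted_mode_point(b, w, bandwidth_factor)
  se <- with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      weighted_mode_point(rnorm(length(b), b, per_snp$se), w, bandwidth_factor)
    }, numeric(1))
    sd(reps)
  })
  new_iv_estimate(
    "weighted_mode", est, se,
    parent_sex = per_snp$parent_sex[1], offspring_sex = per_snp$offspring_sex[1],
    adjustment = per_snp$adjustment[1], n_snps = nrow(per_snp)
  )
}

#' Summary-level PGMR: per-SNP ratios and their combiners
#'
#' Joins per-SNP numerators and denominators on SNP id, forms Wald ratios,
#' and applies the requested combiners. The IVW mean is the headline
#' summary-PGMR estimate; MR-Egger, weighted median and weighted mode are
#' pleiotropy-robust sensitivity estimators.
#'
#' @param numerators,denominators `instrument_assoc` tibbles with one row per
#'   SNP.
#' @param methods Any of `"ivw"`, `"egger"`, `"weighted_median"`,
#'   `"weighted_mode"`.
#' @param se_method Ratio SE convention, see [wald_ratio()].
#' @param bandwidth_factor Passed to [weighted_mode_mr()].
#' @param n_boot,seed Bootstrap controls for median/mode SEs.
#' @return A list with `per_snp` (one `iv_estimate` row per SNP, method
#'   `"wald"`) and `estimates` (one row per combiner).
#' @export
summary_pgmr <- function(numerators, denominators,
                         methods = c("ivw", "egger", "weighted_median", "weighted_mode"),
                         se_method = c("delta", "numerator_only"),
                         bandwidth_factor = 1, n_boot = 2000, seed = 1) {
  se_method <- match.arg(se_method)
  methods <- match.arg(methods, several.ok = TRUE)
  tbl <- snp_assoc_table(numerators, denominators)
  per_snp <- dplyr::bind_rows(purrr::map(seq_len(nrow(tbl)), function(j) {
    wald_ratio(
      new_assoc("numerator", tbl$instrument_label[j], tbl$num_est[j], tbl$num_se[j],
        parent_sex = tbl$parent_sex[j], offspring_sex = tbl$offspring_sex[j],
        adjustment = tbl$adjustment[j]
      ),
      new_assoc("denominator", tbl$instrument_label[j], tbl$den_est[j], tbl$den_se[j]),
      method = "wald", se_method = se_method,
      override_weak = TRUE # single SNPs are individually weak by design
    )
  }))
  ests <- list()
  if ("ivw" %in% methods) ests$ivw <- ivw_combine(per_snp)
  if ("egger" %in% methods) ests$egger <- egger_regression(tbl)
  if ("weighted_median" %in% methods) {
    ests$weighted_median <- weighted_median_mr(per_snp, n_boot, derive_seed(seed, "median"))
  }
  if ("weighted_mode" %in% methods) {
    ests$weighted_mode <- weighted_mode_mr(
      per_snp, bandwidth_factor, n_boot, derive_seed(seed, "mode")
    )
  }
  list(per_snp = per_snp, estimates = dplyr::bind_rows(ests))
}

#' Fixed-effect meta-analysis with heterogeneity statistics
#'
#' Pools log-hazard-ratio estimates by inverse-variance weighting and reports
#' Cochran's `Q`, its degrees of freedom, `I^2 = max(0, (Q - df) / Q) * 100`
#' and the chi-squared heterogeneity p-value. A DerSimonian-Laird
#' random-effects pooled estimate is available for sensitivity.
#'
#' @param estimates An `iv_estimate` tibble (>= 2 rows on the log-HR scale).
#' @param method `"fixed"` (default) or `"dl"` (DerSimonian-Laird).
#' @return A one-row `meta_result` tibble: pooled `estimate`, `se`,
#'   `ci_lower`, `ci_upper`, `hr`, `Q`, `df`, `i2`, `p_het`, `k`.
#' @export
meta_fixed <- function(estimates, method = c("fixed", "dl")) {
  method <- match.arg(method)
  if (nrow(estimates) < 2) stop("meta-analysis needs at least 2 estimates", call. = FALSE)
  b <- estimates$estimate
  w <- 1 / estimates$se^2
  pooled_f <- sum(w * b) / sum(w)
  Q <- sum(w * (b - pooled_f)^2)
  df <- length(b) - 1
  i2 <- max(0, (Q - df) / Q) * 100
  p_het <- pchisq(Q, df, lower.tail = FALSE)
  if (method == "fixed") {
    pooled <- pooled_f
    se <- 1 / sqrt(sum(w))
  } else {
    tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
    w_dl <- 1 / (estimates$se^2 + tau2)
    pooled <- sum(w_dl * b) / sum(w_dl)
    se <- 1 / sqrt(sum(w_dl))
  }
  ci <- ci95(pooled, se)
  tibble::new_tibble(
    tibble::tibble(
      method = paste0("meta_", method),
      estimate = pooled, se = se,
      ci_lower = ci$ci_lower, ci_upper = ci$ci_upper,
      hr = exp(pooled),
      Q = Q, df = df, i2 = i2, p_het = p_het, k = length(b)
    ),
    class = "meta_result"
  )
}
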