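#' Instrument strength: partial R-squared and partial F
#'
#' Incremental variance of the exposure explained by the instrument beyond a
#' covariate set, from nested ordinary-least-squares fits:
#' `partial_r2 = (RSS0 - RSS1) / RSS0` and
#' `partial_f = (RSS0 - RSS1) / (RSS1 / df1)` with one numerator degree of
#' freedom. With no covariates this reduces to the simple-regression identity
#' `F = (n - 2) r^2 / (1 - r^2)`.
#'
#' @param cohort A cohort tibble (deduplicated to one row per offspring
#'   internally).
#' @param instrument Instrument column (`"offspring_bmi"` is its own
#'   exposure proxy; `"grs"` for the genetic score).
#' @param exposure Exposure column, default `"offspring_bmi"`.
#' @param covariates Covariate columns to partial out; defaults to
#'   `offspring_dob` plus, for genetic instruments, the `pc_*` columns.
#' @return A one-row tibble: `partial_r2`, `partial_f`, `n`.
#' @export
instrument_strength <- function(cohort, instrument, exposure = "offspring_bmi",
                                covariates = NULL) {
  assert_cols(cohort, c(instrument, exposure), "cohort")
  d <- dplyr::distinct(tibble::as_tibble(cohort), .data$offspring_id, .keep_all = TRUE)
  if (is.null(covariates)) {
    genetic <- identical(instrument, "grs") || startsWith(instrument, "snp_")
    covariates <- c("offspring_dob", if (genetic) pc_cols(cohort))
    covariates <- intersect(covariates, names(d))
  }
  if (nrow(d) <= length(covariates) + 2) stop("too few rows for the nested fits", call. = FALSE)
  rhs0 <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  fit0 <- lm(as.formula(paste(exposure, "~", rhs0)), data = d)
  fit1 <- lm(as.formula(paste(exposure, "~", paste(c(instrument, covariates), collapse = " + "))),
    data = d
  )
  if (anyNA(coef(fit1))) stop("instrument collinear with covariates", call. = FALSE)
  rss0 <- sum(residuals(fit0)^2)
  rss1 <- sum(residuals(fit1)^2)
  df1 <- fit1$df.residual
  tibble::tibble(
    instrument_label = instrument,
    partial_r2 = (rss0 - rss1) / rss0,
    partial_f = (rss0 - rss1) / (rss1 / df1),
    n = nrow(d)
  )
}

bias_raw_components <- function(d, covariates, instruments) {
  out <- matrix(NA_real_,
    nrow = length(covariates), ncol = length(instruments),
    dimnames = list(covariates, names(instruments))
  )
  for (k in seq_along(instruments)) {
    zc <- d[[instruments[k]]] - mean(d[[instruments[k]]])
    den <- sum(zc * d$offspring_bmi)
    if (den == 0) stop("zero instrument-exposure association for ", instruments[k], call. = FALSE)
    out[, k] <- vapply(covariates, function(v) sum(zc * d[[v]]) / den, numeric(1))
  }
  out
}

#' Relative bias components of the OAI and GRS-PGMR instruments
#'
#' For each measured covariate and each instrument, the raw bias component is
#' the ratio of two slopes: (covariate per instrument unit) divided by
#' (offspring BMI per instrument unit). These components are on an arbitrary
#' scale but comparable *between the two instruments for the same covariate*,
#' so each covariate's pair is scaled by the larger absolute member (the
#' scaled pair always has max |value| = 1). A covariate whose component is
#' large for offspring BMI but near zero for the GRS indicates confounding
#' that invalidates the OAI but not the PGMR instrument. Confidence
#' intervals on the raw components come from a seeded nonparametric bootstrap
#' over individuals; rows are ordered by absolute relative bias
#' `|raw_oai / raw_grs|`, largest first.
#'
#' @param cohort A cohort tibble with both instruments present.
#' @param covariates Covariate columns; default every `cov_*` column.
#' @param instruments Named character vector mapping method labels to
#'   instrument columns.
#' @param n_boot Bootstrap resamples (percentile CIs).
#' @param seed Bootstrap seed.
#' @return A `bias_components` tibble: `covariate`, `method`, `raw`,
#'   `ci_lower`, `ci_upper`, `scaled`, `rel_bias`.
#' @export
bias_components <- function(cohort, covariates = covariate_cols(cohort),
                            instruments = c(oai = "offspring_bmi", grs_pgmr = "grs"),
                            n_boot = 1000, seed = 1) {
  assert_cols(cohort, unname(instruments), "cohort")
  if (!length(covariates)) stop("no covariates supplied", call. = FALSE)
  d <- dplyr::distinct(tibble::as_tibble(cohort), .data$offspring_id, .keep_all = TRUE)
  d <- d[, unique(c("offspring_bmi", unname(instruments), covariates)), drop = FALSE]
  d$offspring_bmi_centred <- d$offspring_bmi - mean(d$offspring_bmi)
  for (v in covariates) d[[v]] <- d[[v]] - mean(d[[v]])
  d$offspring_bmi <- d$offspring_bmi_centred

  raw <- bias_raw_components(d, covariates, instruments) # covariates x instruments
  boot <- with_seed(seed, {
    replicate(n_boot, {
      idx <- sample.int(nrow(d), replace = TRUE)
      bias_raw_components(d[idx, , drop = FALSE], covariates, instruments)
    })
  })
  dim(boot) <- c(length(covariates), length(instruments), n_boot)
  dimnames(boot) <- list(covariates, names(instruments), NULL)
  lo <- apply(boot, c(1, 2), quantile, 0.025)
  hi <- apply(boot, c(1, 2), quantile, 0.975)

  pair_max <- apply(abs(raw), 1, max)
  out <- tidyr::expand_grid(covariate = covariates, method = names(instruments)) |>
    dplyr::mutate(
      raw = purrr::map2_dbl(.data$covariate, .data$method, ~ raw[.x, .y]),
      ci_lower = purrr::map2_dbl(.data$covariate, .data$method, ~ lo[.x, .y]),
      ci_upper = purrr::map2_dbl(.data$covariate, .data$method, ~ hi[.x, .y]),
      scaled = unname(.data$raw / pair_max[.data$covariate])
    )
  rel <- if (ncol(raw) == 2) abs(raw[, 1] / raw[, 2]) else pair_max
  out$rel_bias <- unname(rel[out$covariate])
  out <- dplyr::arrange(out, dplyr::desc(.data$rel_bias))
  tibble::new_tibble(out, class = "bias_components")
}
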