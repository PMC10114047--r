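#' Impute parental age at offspring birth for deceased parents
#'
#' Entry to follow-up is the parent's age at the offspring's birth. This age
#' is observable for parents alive at assessment (assessment age minus
#' offspring age) but not for deceased parents; following standard practice
#' the missing entries are set to a statistic of the observed entry ages
#' among *living* parents of the same parent sex: the mean (`rule = "mean"`,
#' the main-analysis choice) or a percentile (`rule = "percentile:5"`,
#' `"percentile:95"`, ... for sensitivity analyses).
#'
#' @param cohort A `kin_cohort` tibble with `parent_entry_age` missing for
#'   deceased parents.
#' @param rule `"mean"` or `"percentile:p"` with `p` in (0, 100).
#' @return The cohort with complete `parent_entry_age`.
#' @export
impute_entry_age <- function(cohort, rule = "mean") {
  assert_cols(cohort, c("parent_sex", "parent_alive_at_assessment", "parent_entry_age"), "cohort")
  stat_fun <- if (identical(rule, "mean")) {
    function(x) mean(x)
  } else if (grepl("^percentile:", rule)) {
    p <- as.numeric(sub("^percentile:", "", rule))
    if (is.na(p) || p <= 0 || p >= 100) stop("percentile must be in (0, 100)", call. = FALSE)
    function(x) unname(quantile(x, p / 100, type = 7))
  } else {
    stop("rule must be \"mean\" or \"percentile:p\"", call. = FALSE)
  }
  fills <- cohort |>
    dplyr::filter(.data$parent_alive_at_assessment, !is.na(.data$parent_entry_age)) |>
    dplyr::group_by(.data$parent_sex) |>
    dplyr::summarise(fill = stat_fun(.data$parent_entry_age), .groups = "drop")
  strata_needed <- unique(cohort$parent_sex[is.na(cohort$parent_entry_age)])
  missing_strata <- setdiff(strata_needed, fills$parent_sex)
  if (length(missing_strata)) {
    stop(
      "no living parents with observed entry age in stratum: ",
      paste(missing_strata, collapse = ", "),
      call. = FALSE
    )
  }
  out <- cohort |>
    dplyr::left_join(fills, by = "parent_sex") |>
    dplyr::mutate(parent_entry_age = dplyr::coalesce(.data$parent_entry_age, .data$fill)) |>
    dplyr::select(-"fill")
  atts <- attributes(cohort)
  attr(out, "true_params") <- atts$true_params
  attr(out, "seed") <- atts$seed
  tibble::new_tibble(out, class = "kin_cohort")
}

# Subset a cohort to an analysis stratum and attach survival columns.
cox_data <- function(cohort, parent_sex = NULL, offspring_sex = NULL) {
  assert_cols(
    cohort,
    c("parent_entry_age", "parent_age_obs", "parent_alive_at_assessment"), "cohort"
  )
  d <- cohort
  if (!is.null(parent_sex) && parent_sex != "both") {
    d <- dplyr::filter(d, .data$parent_sex == !!parent_sex)
  }
  if (!is.null(offspring_sex) && offspring_sex != "both") {
    d <- dplyr::filter(d, .data$offspring_sex == !!offspring_sex)
  }
  if (anyNA(d$parent_entry_age)) {
    stop("parent_entry_age contains missing values; run impute_entry_age() first",
      call. = FALSE
    )
  }
  d$entry <- d$parent_entry_age
  d$exit <- d$parent_age_obs
  d$event <- as.integer(!d$parent_alive_at_assessment)
  bad <- d$exit <= d$entry
  if (any(bad)) {
    # Imputed entry ages can exceed an early death age; such pairs contribute
    # no valid risk interval and are dropped (kept rare by design).
    d <- d[!bad, , drop = FALSE]
  }
  d
}

# Assemble the right-hand side of a numerator model.
numerator_terms <- function(instrument, adjustment, cohort, covariates) {
  terms <- c(instrument, "offspring_dob")
  genetic <- identical(instrument, "grs") || startsWith(instrument, "snp_")
  if (genetic) terms <- c(terms, pc_cols(cohort))
  if (identical(adjustment, "adjusted")) terms <- c(terms, covariates)
  unique(terms)
}

#' Fit a proportional-hazards numerator for an instrument
#'
#' Fits a Cox proportional-hazards model of parental mortality on an
#' instrument measured in the offspring, with *parental age* as the time
#' axis: follow-up is left-truncated at the parent's age at the offspring's
#' birth and right-censored at the parent's age when the offspring was
#' assessed. Ties are handled by the Efron approximation by default (whole-
#' year death ages make ties certain in questionnaire data). The offspring's
#' date of birth always enters as a linear term to absorb secular trends;
#' genetic instruments (`grs`, `snp_*`) are additionally adjusted for any
#' `pc_*` columns; `adjustment = "adjusted"` adds the supplied covariates.
#'
#' @param cohort A `kin_cohort` tibble with complete `parent_entry_age`.
#' @param instrument Column name of the instrument (`"offspring_bmi"`,
#'   `"grs"`, or a `snp_*` dosage column).
#' @param parent_sex,offspring_sex Stratum selectors (`"mother"`, `"father"`,
#'   `"daughter"`, `"son"`, or `"both"`).
#' @param adjustment `"unadjusted"` or `"adjusted"`.
#' @param covariates Covariate columns added under `"adjusted"`; defaults to
#'   every `cov_*` column.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A one-row `instrument_assoc` tibble (`kind = "numerator"`,
#'   log-HR per instrument unit) with the `coxph` fit in attribute `"fit"`.
#' @export
fit_ph_numerator <- function(cohort, instrument,
                             parent_sex = "both", offspring_sex = "both",
                             adjustment = c("unadjusted", "adjusted"),
                             covariates = covariate_cols(cohort),
                             ties = c("efron", "breslow")) {
  adjustment <- match.arg(adjustment)
  ties <- match.arg(ties)
  assert_cols(cohort, instrument, "cohort")
  d <- cox_data(cohort, parent_sex, offspring_sex)
  if (sum(d$event) < 2) stop("fewer than 2 events in stratum", call. = FALSE)
  if (var(d[[instrument]], na.rm = TRUE) == 0) {
    stop("instrument has zero variance in stratum", call. = FALSE)
  }
  terms <- numerator_terms(instrument, adjustment, cohort, covariates)
  # Constant adjustment columns (e.g. a single assessment date) carry no
  # information and would make the model matrix singular.
  keep <- vapply(
    terms,
    function(v) v == instrument || var(d[[v]], na.rm = TRUE) > 0,
    logical(1)
  )
  terms <- terms[keep]
  fml <- as.formula(paste("survival::Surv(entry, exit, event) ~", paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = ties)
  if (anyNA(coef(fit)[instrument])) {
    stop("Cox model failed to estimate the instrument coefficient", call. = FALSE)
  }
  out <- tibble::new_tibble(
    tibble::tibble(
      kind = "numerator",
      instrument_label = instrument,
      estimate = unname(coef(fit)[instrument]),
      se = unname(sqrt(diag(vcov(fit))[instrument])),
      parent_sex = parent_sex %||% "both",
      offspring_sex = offspring_sex %||% "both",
      adjustment = adjustment,
      n = nrow(d),
      n_events = sum(d$event),
      source = "cohort"
    ),
    class = "instrument_assoc"
  )
  attr(out, "fit") <- fit
  out
}

#' Proportional-hazards diagnostics for a numerator model
#'
#' Two complementary checks on the instrument's hazard ratio: (i) the
#' correlation of the instrument's Schoenfeld residuals with the natural
#' logarithm of analysis time (parental age at event), with a two-sided
#' p-value; (ii) an episode-split fit with the age axis cut at `split_age`,
#' giving separate log hazard ratios before and after the split (each parent
#' contributes person-time to every segment their follow-up traverses).
#'
#' @param assoc An `instrument_assoc` numerator from [fit_ph_numerator()].
#' @param cohort The cohort the numerator was fitted on.
#' @param split_age Age (years) at which to cut the time axis.
#' @return A one-row `ph_diagnostics` tibble: `schoenfeld_corr`, `p_value`,
#'   `loghr_pre`, `se_pre`, `loghr_post`, `se_post`, `n_events_pre`,
#'   `n_events_post`, `split_age`.
#' @export
ph_diagnostics <- function(assoc, cohort, split_age = 70) {
  stopifnot(inherits(assoc, "instrument_assoc"), assoc$kind == "numerator")
  fit <- attr(assoc, "fit")
  if (is.null(fit)) stop("assoc carries no fitted model; refit with fit_ph_numerator()", call. = FALSE)
  instrument <- assoc$instrument_label
  sr <- residuals(fit, type = "schoenfeld")
  if (is.null(dim(sr))) sr <- matrix(sr, dimnames = list(names(sr), instrument))
  times <- as.numeric(rownames(sr))
  ct <- cor.test(sr[, instrument], log(times))

  d <- cox_data(cohort, assoc$parent_sex, assoc$offspring_sex)
  ev_pre <- sum(d$event == 1 & d$exit <= split_age)
  ev_post <- sum(d$event == 1 & d$exit > split_age)
  if (ev_pre < 3 || ev_post < 3) {
    stop(sprintf(
      "fewer than 3 events on one side of split_age = %g (pre: %d, post: %d)",
      split_age, ev_pre, ev_post
    ), call. = FALSE)
  }
  terms <- setdiff(attr(fit$terms, "term.labels"), instrument)
  keep_terms <- intersect(terms, names(d))
  sp <- survival::survSplit(
    as.formula(paste(
      "Surv(entry, exit, event) ~",
      paste(c(instrument, keep_terms), collapse = " + ")
    )),
    data = d[, unique(c("entry", "exit", "event", instrument, keep_terms)), drop = FALSE],
    cut = split_age, episode = "segment"
  )
  sp$instr_pre <- sp[[instrument]] * (sp$segment == 1)
  sp$instr_post <- sp[[instrument]] * (sp$segment == 2)
  fml <- as.formula(paste(
    "survival::Surv(entry, exit, event) ~ instr_pre + instr_post",
    if (length(terms)) paste("+", paste(terms, collapse = " + ")) else ""
  ))
  sfit <- survival::coxph(fml, data = sp, ties = fit$method %||% "efron")
  cf <- coef(sfit)
  se <- sqrt(diag(vcov(sfit)))
  tibble::new_tibble(
    tibble::tibble(
      instrument_label = instrument,
      schoenfeld_corr = unname(ct$estimate),
      p_value = ct$p.value,
      loghr_pre = unname(cf["instr_pre"]),
      se_pre = unname(se["instr_pre"]),
      loghr_post = unname(cf["instr_post"]),
      se_post = unname(se["instr_post"]),
      n_events_pre = ev_pre,
      n_events_post = ev_post,
      split_age = split_age
    ),
    class = "ph_diagnostics"
  )
}

#' Scan covariate associations with BMI, the GRS, or parental survival
#'
#' One regression per covariate, following the usual reporting conventions
#' for cohort description tables: linear regression for offspring BMI
#' (unadjusted) and for the GRS (adjusted for `pc_*` columns); Cox
#' proportional-hazards regression for parental survival (adjusted for
#' offspring date of birth), run separately by parent sex. Offspring-level
#' scans deduplicate to one row per offspring. Constant covariates are
#' skipped with a warning.
#'
#' @param cohort A `kin_cohort` tibble (with `grs` present for the GRS scan,
#'   complete entry ages for the survival scan).
#' @param target `"bmi"`, `"grs"`, or `"parent_survival"`.
#' @param covariates Covariate columns; defaults to every `cov_*` column.
#' @return A tibble with one row per covariate (and per parent sex for the
#'   survival scan): `covariate`, `target`, `parent_sex`, `estimate`, `se`,
#'   `ci_lower`, `ci_upper`, `p_value`, `n`.
#' @export
covariate_scan <- function(cohort, target = c("bmi", "grs", "parent_survival"),
                           covariates = covariate_cols(cohort)) {
  target <- match.arg(target)
  if (!length(covariates)) stop("no covariates to scan", call. = FALSE)
  keep <- vapply(covariates, function(v) var(cohort[[v]], na.rm = TRUE) > 0, logical(1))
  if (any(!keep)) {
    warning("skipping constant covariate(s): ", paste(covariates[!keep], collapse = ", "),
      call. = FALSE
    )
  }
  covariates <- covariates[keep]

  if (target %in% c("bmi", "grs")) {
    d <- dplyr::distinct(tibble::as_tibble(cohort), .data$offspring_id, .keep_all = TRUE)
    outcome <- if (target == "bmi") "offspring_bmi" else "grs"
    assert_cols(d, outcome, "cohort")
    adj <- if (target == "grs") pc_cols(cohort) else character()
    rows <- purrr::map(covariates, function(v) {
      fml <- as.formula(paste(outcome, "~", paste(c(v, adj), collapse = " + ")))
      fit <- lm(fml, data = d)
      s <- summary(fit)$coefficients
      tibble::tibble(
        covariate = v, target = target, parent_sex = NA_character_,
        estimate = s[v, 1], se = s[v, 2], p_value = s[v, 4], n = nrow(d)
      )
    })
  } else {
    grid <- expand.grid(
      v = covariates, ps = unique(cohort$parent_sex),
      stringsAsFactors = FALSE
    )
    rows <- purrr::pmap(
      grid,
      function(v, ps) {
        d <- cox_data(cohort, parent_sex = ps)
        fml <- as.formula(paste("survival::Surv(entry, exit, event) ~", v, "+ offspring_dob"))
        fit <- survival::coxph(fml, data = d)
        tibble::tibble(
          covariate = v, target = target, parent_sex = ps,
          estimate = unname(coef(fit)[v]),
          se = unname(sqrt(diag(vcov(fit))[v])),
          p_value = unname(summary(fit)$coefficients[v, "Pr(>|z|)"]),
          n = nrow(d)
        )
      }
    )
  }
  out <- dplyr::bind_rows(rows)
  dplyr::bind_cols(out, ci95(out$estimate, out$se))[
    ,
    c("covariate", "target", "parent_sex", "estimate", "se", "ci_lower", "ci_upper", "p_value", "n")
  ]
}
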