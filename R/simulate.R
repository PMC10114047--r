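#' Ground-truth parameters for the parent-offspring cohort simulator
#'
#' Collects every generative parameter of [simulate_trios()] with defaults
#' chosen to emulate a UK-style middle-aged cohort reporting parental
#' longevity. The causal structure is: parental genotype and a family-level
#' shared environment `E1` jointly cause parental and offspring BMI (there is
#' no direct parental-BMI -> offspring-BMI arrow); parental mortality follows
#' a Weibull proportional-hazards model log-linear in parental BMI and in a
#' parental environment `E2` that may be correlated with `E1`. A non-zero
#' `rho_e1e2` together with a non-zero `delta_e2` is exactly the condition
#' that invalidates offspring BMI as an instrument while leaving offspring
#' genotype valid.
#'
#' @param gamma True log hazard ratio of parental mortality per kg/m2 of
#'   parental BMI.
#' @param h2_snp Fraction of (standardized) BMI variance explained by the SNP
#'   panel, in `[0, 1)`. Overridden by the panel actually supplied to
#'   [simulate_trios()]; kept here as the echo of ground truth.
#' @param mu_bmi_f,mu_bmi_m,sigma_bmi_f,sigma_bmi_m Mean and SD of BMI
#'   (kg/m2) for females and males; applied to both generations by sex.
#' @param var_e1 Variance share of standardized BMI contributed by the shared
#'   family environment `E1` (same loading for mother, father and offspring).
#' @param rho_e1e2 Correlation between `E1` and each parent's mortality
#'   environment `E2`, in `[-1, 1]`.
#' @param delta_e2 Log hazard ratio per SD of `E2`.
#' @param rho_mate Target spousal (phenotypic) BMI correlation, in `[-1, 1]`.
#'   Must be at least the variance share already forced by family-shared BMI
#'   causes (`var_e1` plus squared parental covariate loadings).
#' @param weibull_shape,weibull_scale Baseline mortality hazard parameters
#'   (shape > 0, scale in years); the baseline applies at sex-mean BMI.
#' @param entry_age_mean_f,entry_age_mean_m,entry_age_sd Parental age at the
#'   offspring's birth: sex-specific means and a common SD (years).
#' @param assess_age_mean,assess_age_sd Offspring age at assessment (years),
#'   truncated to `[40, 70]`.
#' @param assess_year Calendar year of assessment, used only to derive
#'   `offspring_dob`.
#' @param covariate_effects Tibble with columns `name`, `beta_bmi_o`,
#'   `beta_bmi_p`, `beta_loghr`: per-covariate loadings (per covariate SD) on
#'   standardized offspring BMI, standardized parental BMI, and parental log
#'   hazard. Covariates are family-level standard normals measured in the
#'   offspring.
#' @param n_pcs Number of pure-noise principal-component columns to emit
#'   (generic ancestry-adjustment covariates).
#'
#' @return A list of class `trio_params`.
#' @export
trio_params <- function(gamma = log(1.05),
                        h2_snp = 0.02,
                        mu_bmi_f = 26.7, sigma_bmi_f = 5.0,
                        mu_bmi_m = 27.6, sigma_bmi_m = 4.1,
                        var_e1 = 0.15,
                        rho_e1e2 = 0, delta_e2 = 0,
                        rho_mate = 0.2,
                        weibull_shape = 9, weibull_scale = 85,
                        entry_age_mean_f = 27, entry_age_mean_m = 30,
                        entry_age_sd = 4,
                        assess_age_mean = 56, assess_age_sd = 8,
                        assess_year = 2008,
                        covariate_effects = default_covariate_effects(),
                        n_pcs = 10) {
  stopifnot(
    h2_snp >= 0, h2_snp < 1,
    abs(rho_e1e2) <= 1, abs(rho_mate) <= 1,
    weibull_shape > 0, weibull_scale > 0,
    sigma_bmi_f > 0, sigma_bmi_m > 0,
    var_e1 >= 0, var_e1 < 1,
    entry_age_sd > 0, assess_age_sd > 0, n_pcs >= 0
  )
  covariate_effects <- tibble::as_tibble(covariate_effects)
  if (nrow(covariate_effects)) {
    assert_cols(covariate_effects, c("name", "beta_bmi_o", "beta_bmi_p", "beta_loghr"),
      "covariate_effects"
    )
  }
  b2_o <- sum(covariate_effects$beta_bmi_o^2)
  b2_p <- sum(covariate_effects$beta_bmi_p^2)
  if (h2_snp + var_e1 + b2_o >= 1 || h2_snp + var_e1 + b2_p >= 1) {
    stop("variance components (h2 + var_e1 + covariate loadings) exceed total BMI variance",
      call. = FALSE
    )
  }
  shared <- var_e1 + b2_p
  if (rho_mate < shared - 1e-12) {
    stop(sprintf(
      "rho_mate (%.3f) below the spousal correlation already forced by shared BMI causes (%.3f)",
      rho_mate, shared
    ), call. = FALSE)
  }
  keep <- names(formals(trio_params))
  structure(mget(keep, envir = environment()), class = "trio_params")
}

#' @rdname trio_params
#' @export
default_covariate_effects <- function() {
  tibble::tribble(
    ~name,         ~beta_bmi_o, ~beta_bmi_p, ~beta_loghr,
    "cov_income",  0.15,        0.15,        0.05,
    "cov_smoking", 0.10,        0.10,        0.10
  )
}

#' Draw a death age from a Weibull hazard conditional on survival to entry
#'
#' Inverse-transform sampling from the left-truncated proportional-hazards
#' Weibull: solves \eqn{S(t)^{e^{\mathrm{loghr}}} / S(a)^{e^{\mathrm{loghr}}} = 1 - u}
#' for `t`, with `a = entry_age` and Weibull survival
#' \eqn{S(t) = \exp(-(t/\lambda)^k)}. The draw always exceeds `entry_age`,
#' which is how the simulator encodes the selection that a parent must have
#' survived to the offspring's birth.
#'
#' @param shape,scale Weibull shape `k` > 0 and scale `lambda` > 0 (years).
#' @param log_hr Log hazard-ratio multiplier applied to the baseline hazard.
#' @param entry_age Age (years, >= 0) the subject is known to have survived.
#' @param u Uniform(0, 1) variate(s).
#' @return Death age(s) in years, strictly greater than `entry_age`.
#' @examples
#' draw_conditional_death_age(9, 85, log_hr = 0, entry_age = 30, u = 0.5)
#' @export
draw_conditional_death_age <- function(shape, scale, log_hr, entry_age, u) {
  if (any(shape <= 0) || any(scale <= 0)) stop("shape and scale must be positive", call. = FALSE)
  if (any(entry_age < 0)) stop("entry_age must be >= 0", call. = FALSE)
  # cumulative hazard at t: H(t) = (t/scale)^shape; conditional draw adds the
  # exponential increment -log(1-u)/exp(log_hr) to H(entry).
  scale * ((entry_age / scale)^shape - log1p(-u) / exp(log_hr))^(1 / shape)
}

#' Simulate parent-offspring pairs with genotypes, BMI and parental survival
#'
#' Generates `n_families` trios (mother, father, one offspring) and returns a
#' long cohort table with one row per offspring-parent pair (two rows per
#' family). The generative steps are:
#'
#' 1. Parental genotypes drawn from Hardy-Weinberg proportions at the panel's
#'    effect-allele frequencies; genetic values are centred weighted dosage
#'    sums in phenotype-SD units.
#' 2. Spouses paired by rank-matching on the parent-specific BMI component
#'    (genetic value + residual) with Gaussian noise calibrated analytically
#'    so the realized total spousal BMI correlation approximates
#'    `params$rho_mate`. Genotypic spousal correlation emerges from the
#'    phenotypic matching; genotypes are never matched directly.
#' 3. Offspring dosages built by Mendelian transmission: one allele from each
#'    parent with probability dosage/2 per SNP.
#' 4. Standardized BMI = genetic value + `sqrt(var_e1) * E1` + covariate
#'    loadings + residual, scaled to the sex-specific mean/SD; `E1` is a
#'    single family draw shared by mother, father and offspring. Parental BMI
#'    has no direct effect on offspring BMI.
#' 5. Each parent's mortality environment `E2` is drawn with correlation
#'    `rho_e1e2` to `E1`; death ages come from the truncated Weibull
#'    proportional-hazards draw with log hazard
#'    `gamma * (BMI - sex mean) + delta_e2 * E2 + covariate terms`,
#'    conditional on surviving to the parent's age at the offspring's birth.
#' 6. The observed record is censored at the parent's age when the offspring
#'    is assessed; `parent_entry_age` is reported only for parents alive at
#'    assessment (as in questionnaire data, where a dead parent's age at the
#'    respondent's birth is unknown), the truth being kept in
#'    `true_entry_age`.
#'
#' Columns prefixed `true_` (`true_parent_bmi`, `true_entry_age`,
#' `true_parent_grs`, `true_e1`, `true_e2`, `true_death_age`) are simulator
#' ground truth for validation only and must never be read by estimators.
#'
#' @param panel An `snp_panel` (see [simulate_snp_panel()]).
#' @param n_families Number of trios (>= 1).
#' @param params A [trio_params()] object.
#' @param seed Integer seed; required, refused if missing.
#' @return A tibble of class `kin_cohort` with attributes `true_params` and
#'   `seed`; two rows (mother, father) per family.
#' @export
simulate_trios <- function(panel, n_families, params = trio_params(), seed = NULL) {
  stopifnot(inherits(params, "trio_params"), n_families >= 1)
  assert_cols(panel, c("snp_id", "eaf", "weight"), "panel")
  if (is.null(seed)) stop("simulate_trios() requires an explicit seed", call. = FALSE)

  n <- as.integer(n_families)
  m <- nrow(panel)
  p <- panel$eaf
  w <- panel$weight
  h2 <- sum(2 * p * (1 - p) * w^2)
  ce <- params$covariate_effects
  k <- nrow(ce)
  b2_o <- sum(ce$beta_bmi_o^2)
  b2_p <- sum(ce$beta_bmi_p^2)
  var_res_p <- 1 - h2 - params$var_e1 - b2_p
  var_res_o <- 1 - h2 - params$var_e1 - b2_o
  if (var_res_p <= 0 || var_res_o <= 0) {
    stop("panel heritability plus shared components exceed total BMI variance", call. = FALSE)
  }

  with_seed(seed, {
    probs <- rep(p, each = n)
    d_m <- matrix(rbinom(n * m, 2L, probs), n, m)
    d_f <- matrix(rbinom(n * m, 2L, probs), n, m)
    g_m <- drop((d_m - matrix(2 * p, n, m, byrow = TRUE)) %*% w)
    g_f <- drop((d_f - matrix(2 * p, n, m, byrow = TRUE)) %*% w)

    # Parent-specific BMI component used for mate matching.
    core_m <- g_m + rnorm(n, sd = sqrt(var_res_p))
    core_f <- g_f + rnorm(n, sd = sqrt(var_res_p))
    var_core <- h2 + var_res_p
    shared <- params$var_e1 + b2_p
    rho_core <- (params$rho_mate - shared) / var_core
    if (rho_core > 1e-8) {
      # Sorting both sexes on noisy cores makes the sorted scores comonotone;
      # each core correlates var_core/(var_core + tau^2) with its score, so the
      # achieved core-core correlation is that attenuation factor.
      tau <- sqrt(var_core * (1 - rho_core) / rho_core)
      ord_m <- order(core_m + rnorm(n, sd = tau))
      ord_f <- order(core_f + rnorm(n, sd = tau))
      d_m <- d_m[ord_m, , drop = FALSE]; g_m <- g_m[ord_m]; core_m <- core_m[ord_m]
      d_f <- d_f[ord_f, , drop = FALSE]; g_f <- g_f[ord_f]; core_f <- core_f[ord_f]
    }

    # Mendelian transmission: one allele from each parent, P(transmit) = dosage/2.
    a_m <- matrix(rbinom(n * m, 1L, as.vector(d_m) / 2), n, m)
    a_f <- matrix(rbinom(n * m, 1L, as.vector(d_f) / 2), n, m)
    d_o <- a_m + a_f
    g_o <- drop((d_o - matrix(2 * p, n, m, byrow = TRUE)) %*% w)

    # Family-level variables.
    e1 <- rnorm(n)
    C <- if (k) matrix(rnorm(n * k), n, k, dimnames = list(NULL, ce$name)) else
      matrix(0, n, 0)
    c_bmi_p <- if (k) drop(C %*% ce$beta_bmi_p) else 0
    c_bmi_o <- if (k) drop(C %*% ce$beta_bmi_o) else 0
    c_loghr <- if (k) drop(C %*% ce$beta_loghr) else 0
    l_e1 <- sqrt(params$var_e1)

    z_m <- core_m + l_e1 * e1 + c_bmi_p
    z_f <- core_f + l_e1 * e1 + c_bmi_p
    z_o <- g_o + l_e1 * e1 + c_bmi_o + rnorm(n, sd = sqrt(var_res_o))

    off_sex <- sample(c("daughter", "son"), n, replace = TRUE)
    mu_o <- ifelse(off_sex == "daughter", params$mu_bmi_f, params$mu_bmi_m)
    sd_o <- ifelse(off_sex == "daughter", params$sigma_bmi_f, params$sigma_bmi_m)
    bmi_mother <- params$mu_bmi_f + params$sigma_bmi_f * z_m
    bmi_father <- params$mu_bmi_m + params$sigma_bmi_m * z_f
    bmi_o <- mu_o + sd_o * z_o

    # Parental mortality environments and log hazards.
    rho <- params$rho_e1e2
    e2_mother <- rho * e1 + sqrt(1 - rho^2) * rnorm(n)
    e2_father <- rho * e1 + sqrt(1 - rho^2) * rnorm(n)
    lhr_mother <- params$gamma * (bmi_mother - params$mu_bmi_f) +
      params$delta_e2 * e2_mother + c_loghr
    lhr_father <- params$gamma * (bmi_father - params$mu_bmi_m) +
      params$delta_e2 * e2_father + c_loghr

    entry_mother <- pmax(15, rnorm(n, params$entry_age_mean_f, params$entry_age_sd))
    entry_father <- pmax(15, rnorm(n, params$entry_age_mean_m, params$entry_age_sd))
    # Offspring age at assessment, truncated normal on [40, 70].
    lo <- pnorm(40, params$assess_age_mean, params$assess_age_sd)
    hi <- pnorm(70, params$assess_age_mean, params$assess_age_sd)
    assess_age <- qnorm(runif(n, lo, hi), params$assess_age_mean, params$assess_age_sd)
    dob <- params$assess_year - assess_age

    death_mother <- draw_conditional_death_age(
      params$weibull_shape, params$weibull_scale, lhr_mother, entry_mother, runif(n)
    )
    death_father <- draw_conditional_death_age(
      params$weibull_shape, params$weibull_scale, lhr_father, entry_father, runif(n)
    )
    exit_mother <- entry_mother + assess_age
    exit_father <- entry_father + assess_age

    grs_m <- if (sum(w) > 0) m * drop(d_m %*% w) / sum(w) else rep(NA_real_, n)
    grs_f <- if (sum(w) > 0) m * drop(d_f %*% w) / sum(w) else rep(NA_real_, n)

    pcs <- if (params$n_pcs > 0) {
      matrix(rnorm(n * params$n_pcs), n, params$n_pcs,
        dimnames = list(NULL, sprintf("pc_%02d", seq_len(params$n_pcs)))
      )
    } else {
      matrix(0, n, 0)
    }

    off <- tibble::tibble(
      family_id = seq_len(n),
      offspring_id = sprintf("off_%06d", seq_len(n)),
      offspring_sex = off_sex,
      offspring_dob = dob,
      offspring_bmi = bmi_o
    )
    off <- dplyr::bind_cols(
      off,
      tibble::as_tibble(C, .name_repair = "minimal"),
      tibble::as_tibble(pcs, .name_repair = "minimal"),
      tibble::as_tibble(d_o, .name_repair = "minimal") |>
        setNames(panel$snp_id)
    )

    one_parent <- function(sex, alive, age_obs, entry, bmi, grs, e2, death) {
      dplyr::bind_cols(
        off,
        tibble::tibble(
          parent_sex = sex,
          parent_alive_at_assessment = alive,
          parent_age_obs = age_obs,
          parent_entry_age = ifelse(alive, entry, NA_real_),
          true_parent_bmi = bmi,
          true_entry_age = entry,
          true_parent_grs = grs,
          true_e1 = e1,
          true_e2 = e2,
          true_death_age = death
        )
      )
    }
    dead_m <- death_mother <= exit_mother
    dead_f <- death_father <= exit_father
    cohort <- dplyr::bind_rows(
      one_parent(
        "mother", !dead_m, pmin(death_mother, exit_mother), entry_mother,
        bmi_mother, grs_m, e2_mother, death_mother
      ),
      one_parent(
        "father", !dead_f, pmin(death_father, exit_father), entry_father,
        bmi_father, grs_f, e2_father, death_father
      )
    )
    cohort$pair_id <- seq_len(nrow(cohort))
    out <- tibble::new_tibble(cohort, class = "kin_cohort")
    attr(out, "true_params") <- params
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Ground-truth parameters attached to a simulated cohort
#'
#' @param cohort A `kin_cohort` tibble from [simulate_trios()].
#' @return The `trio_params` object the cohort was generated from (or `NULL`
#'   for cohorts read from disk without a manifest).
#' @export
true_params <- function(cohort) attr(cohort, "true_params")

#' Read/write cohort tables as tab-delimited text
#'
#' `write_cohort()` writes the cohort as TSV (`NA` for missing) plus a sidecar
#' YAML manifest (`<path>.manifest.yaml`) echoing the generator parameters and
#' seed, which suffices to regenerate the table. `read_cohort()` reads the TSV
#' back and re-attaches the manifest when present.
#'
#' @param cohort A `kin_cohort` tibble.
#' @param path Output TSV path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   `kin_cohort` tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path, na = "NA")
  pars <- true_params(cohort)
  manifest <- list(
    seed = attr(cohort, "seed"),
    n_rows = nrow(cohort),
    true_params = if (!is.null(pars)) {
      pl <- unclass(pars)
      pl$covariate_effects <- as.list(as.data.frame(pl$covariate_effects))
      pl
    }
  )
  yaml::write_yaml(manifest, paste0(path, ".manifest.yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, na = "NA")
  out <- tibble::new_tibble(out, class = "kin_cohort")
  mpath <- paste0(path, ".manifest.yaml")
  if (file.exists(mpath)) {
    manifest <- yaml::read_yaml(mpath)
    if (!is.null(manifest$true_params)) {
      pl <- manifest$true_params
      pl$covariate_effects <- tibble::as_tibble(pl$covariate_effects)
      attr(out, "true_params") <- do.call(trio_params, pl[names(pl) %in% names(formals(trio_params))])
    }
    attr(out, "seed") <- manifest$seed
  }
  out
}
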