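#' Configuration for the end-to-end demo pipeline
#'
#' Collects every knob of [run_pipeline()] in one validated list so a run is
#' fully described by its config (echoed into the output manifest). All
#' randomness derives deterministically from `seed`.
#'
#' @param n_families Families in the analysis cohort.
#' @param n_aux Families in the auxiliary cohort used to estimate the
#'   external intergenerational associations (the OAI denominators), kept
#'   independent of the analysis cohort as in a two-sample design.
#' @param panel Optional pre-built `snp_panel`; if `NULL`, one is simulated
#'   with `n_snps`/`total_h2`.
#' @param n_snps,total_h2 Panel size and variance explained when simulating
#'   the panel.
#' @param params A [trio_params()] object (generator ground truth).
#' @param adjustment `"unadjusted"` or `"adjusted"` covariate convention for
#'   every model.
#' @param entry_rule Entry-age imputation rule, see [impute_entry_age()].
#' @param summary_parent_sex Parent sexes for the per-SNP summary-PGMR stage
#'   (each costs one Cox fit per SNP).
#' @param summary_source `"cohort"` (one-sample per-SNP denominators) or
#'   `"panel"` (external weights, two-sample).
#' @param summary_methods Combiners for the summary stage.
#' @param run_bias_components Whether to compute bias components.
#' @param n_boot Bootstrap resamples for median/mode SEs and bias CIs.
#' @param seed Master seed (required).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_families = 2000, n_aux = 2000,
                            panel = NULL, n_snps = 50, total_h2 = 0.02,
                            params = trio_params(),
                            adjustment = c("adjusted", "unadjusted"),
                            entry_rule = "mean",
                            summary_parent_sex = "mother",
                            summary_source = c("cohort", "panel"),
                            summary_methods = c("ivw", "egger", "weighted_median", "weighted_mode"),
                            run_bias_components = TRUE,
                            n_boot = 500,
                            seed = NULL) {
  if (is.null(seed)) stop("pipeline_config() requires a seed", call. = FALSE)
  structure(
    list(
      n_families = n_families, n_aux = n_aux, panel = panel,
      n_snps = n_snps, total_h2 = total_h2, params = params,
      adjustment = match.arg(adjustment), entry_rule = entry_rule,
      summary_parent_sex = summary_parent_sex,
      summary_source = match.arg(summary_source),
      summary_methods = summary_methods,
      run_bias_components = run_bias_components,
      n_boot = n_boot, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full intergenerational-IV pipeline on synthetic data
#'
#' Executes the paper-shaped analysis end to end: simulate a SNP panel and a
#' parent-offspring cohort, build the GRS, impute entry ages, fit Cox
#' numerators (OAI per parent/offspring sex pairing; GRS per parent sex),
#' estimate denominators (intergenerational BMI associations from an
#' independent auxiliary cohort for OAI; the halved sex-rescaled Z-score
#' slope for GRS-PGMR), form Wald ratios, meta-analyse the OAI son/daughter
#' estimates per parent, run per-SNP summary-PGMR with the requested
#' combiners, and compute instrument-strength and bias-component
#' diagnostics. Deterministic given the config seed.
#'
#' @param config A [pipeline_config()] object.
#' @param out_dir Optional directory: results, associations and diagnostics
#'   are written as TSV plus a YAML manifest echoing the config.
#' @return A list of class `kinmr_results`: `results` (one `iv_estimate` row
#'   per method/stratum), `meta` (per-parent OAI meta rows), `numerators`,
#'   `denominators`, `per_snp`, `strength`, `ph` (proportional-hazards
#'   diagnostics), `bias` (or `NULL`), `cohort`, `panel`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  adj <- config$adjustment

  panel <- config$panel %||% simulate_snp_panel(
    config$n_snps,
    total_h2 = config$total_h2, seed = derive_seed(seed, "panel")
  )
  cohort <- simulate_trios(panel, config$n_families, config$params,
    seed = derive_seed(seed, "cohort")
  ) |>
    add_grs(panel) |>
    impute_entry_age(config$entry_rule)
  aux <- simulate_trios(panel, config$n_aux, config$params,
    seed = derive_seed(seed, "aux")
  )

  strata <- tidyr::expand_grid(
    parent_sex = c("mother", "father"),
    offspring_sex = c("daughter", "son")
  )
  oai_num <- dplyr::bind_rows(purrr::pmap(strata, function(parent_sex, offspring_sex) {
    fit_ph_numerator(cohort, "offspring_bmi",
      parent_sex = parent_sex,
      offspring_sex = offspring_sex, adjustment = adj
    )
  }))
  grs_num_fits <- purrr::map(
    stats::setNames(c("mother", "father"), c("mother", "father")),
    function(ps) fit_ph_numerator(cohort, "grs", parent_sex = ps, adjustment = adj)
  )
  grs_num <- dplyr::bind_rows(grs_num_fits)

  iga_den <- dplyr::bind_rows(purrr::pmap(strata, function(parent_sex, offspring_sex) {
    fit_iga(aux, parent_sex, offspring_sex, adjustment = adj)
  }))
  sds <- bmi_sd_by_sex(cohort)
  zslope <- fit_grs_zscore_slope(cohort, adjustment = adj)
  grs_den <- dplyr::bind_rows(purrr::map(c("mother", "father"), function(ps) {
    grs_pgmr_denominator(zslope$b, zslope$se, ps, sds, adjustment = adj)
  }))

  pick <- function(tbl, ps, os = NULL) {
    r <- tbl[tbl$parent_sex == ps & (is.null(os) | tbl$offspring_sex == (os %||% "")), ]
    tibble::new_tibble(r[1, ], class = "instrument_assoc")
  }
  oai <- dplyr::bind_rows(purrr::pmap(strata, function(parent_sex, offspring_sex) {
    wald_ratio(
      pick(oai_num, parent_sex, offspring_sex),
      pick(iga_den, parent_sex, offspring_sex),
      method = "oai"
    )
  }))
  meta <- dplyr::bind_rows(purrr::map(c("mother", "father"), function(ps) {
    m <- meta_fixed(oai[oai$parent_sex == ps, ])
    m$parent_sex <- ps
    m
  }))
  oai_pooled <- dplyr::bind_rows(purrr::map(c("mother", "father"), function(ps) {
    m <- meta[meta$parent_sex == ps, ]
    new_iv_estimate("oai_meta", m$estimate, m$se,
      parent_sex = ps,
      offspring_sex = "both", adjustment = adj
    )
  }))
  grs_pgmr <- dplyr::bind_rows(purrr::map(c("mother", "father"), function(ps) {
    wald_ratio(pick(grs_num, ps), pick(grs_den, ps), method = "grs_pgmr")
  }))

  snp_num <- list(); snp_den <- list(); summaries <- list(); per_snp <- list()
  for (ps in config$summary_parent_sex) {
    nn <- snp_numerators(cohort, panel, parent_sex = ps, adjustment = adj)
    dd <- snp_denominators(panel, ps, sds,
      source = config$summary_source,
      cohort = cohort, adjustment = adj
    )
    sm <- summary_pgmr(nn, dd,
      methods = config$summary_methods,
      n_boot = config$n_boot, seed = derive_seed(seed, paste0("summary_", ps))
    )
    sm$estimates$parent_sex <- ps
    sm$per_snp$parent_sex <- ps
    snp_num[[ps]] <- nn; snp_den[[ps]] <- dd
    summaries[[ps]] <- sm$estimates; per_snp[[ps]] <- sm$per_snp
  }

  # OAI strength lives in the external (auxiliary) sample, where parental BMI
  # is observed; GRS strength is the in-cohort partial R2 against own BMI.
  strength <- dplyr::bind_rows(
    instrument_strength(aux, "offspring_bmi", exposure = "true_parent_bmi"),
    instrument_strength(cohort, "grs")
  )
  ph <- dplyr::bind_rows(
    ph_diagnostics(grs_num_fits$mother, cohort),
    ph_diagnostics(grs_num_fits$father, cohort)
  )
  bias <- if (isTRUE(config$run_bias_components)) {
    bias_components(cohort,
      n_boot = min(config$n_boot, 500),
      seed = derive_seed(seed, "bias")
    )
  }

  results <- dplyr::bind_rows(oai, oai_pooled, grs_pgmr, dplyr::bind_rows(summaries))
  out <- structure(
    list(
      results = results, meta = meta,
      numerators = dplyr::bind_rows(oai_num, grs_num, dplyr::bind_rows(snp_num)),
      denominators = dplyr::bind_rows(iga_den, grs_den, dplyr::bind_rows(snp_den)),
      per_snp = dplyr::bind_rows(per_snp),
      strength = strength, ph = ph, bias = bias,
      cohort = cohort, panel = panel, config = config
    ),
    class = "kinmr_results"
  )
  if (!is.null(out_dir)) write_results(out, out_dir)
  out
}

#' Write a pipeline results bundle as delimited text plus a manifest
#'
#' @param x A `kinmr_results` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tbl, name) {
    if (!is.null(tbl) && nrow(tbl)) {
      readr::write_tsv(tibble::as_tibble(tbl), file.path(out_dir, name), na = "NA")
    }
  }
  w(x$results, "results.tsv")
  w(x$meta, "meta.tsv")
  w(dplyr::select(x$numerators, -dplyr::any_of("fit")), "numerators.tsv")
  w(x$denominators, "denominators.tsv")
  w(x$per_snp, "per_snp.tsv")
  w(x$strength, "strength.tsv")
  w(x$ph, "ph_diagnostics.tsv")
  w(x$bias, "bias_components.tsv")
  cfg <- x$config
  manifest <- list(
    seed = cfg$seed, n_families = cfg$n_families, n_aux = cfg$n_aux,
    n_snps = cfg$n_snps, total_h2 = cfg$total_h2,
    adjustment = cfg$adjustment, entry_rule = cfg$entry_rule,
    summary_parent_sex = cfg$summary_parent_sex,
    summary_source = cfg$summary_source,
    summary_methods = cfg$summary_methods,
    n_boot = cfg$n_boot,
    true_params = {
      pl <- unclass(cfg$params)
      pl$covariate_effects <- as.list(as.data.frame(pl$covariate_effects))
      pl
    }
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"), precision = 15)
  invisible(out_dir)
}

#' @export
print.kinmr_results <- function(x, ...) {
  cat("kinmr pipeline results\n")
  cat(sprintf(
    "  cohort: %d pairs (%d families), adjustment: %s\n",
    nrow(x$cohort), x$config$n_families, x$config$adjustment
  ))
  cat("  estimates (HR per kg/m2):\n")
  tbl <- dplyr::mutate(
    dplyr::select(
      tibble::as_tibble(x$results),
      "method", "parent_sex", "offspring_sex", "hr", "hr_lower", "hr_upper"
    ),
    dplyr::across(dplyr::where(is.numeric), ~ round(.x, 3))
  )
  print(tbl, n = nrow(tbl))
  invisible(x)
}
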