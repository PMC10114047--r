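#' Bundled published input values
#'
#' Small tables of externally published quantities that the estimators take
#' as inputs, shipped as plain TSV under `inst/extdata/`:
#'
#' * `grs_denominators` — published GRS-PGMR denominators (kg/m2 of parental
#'   BMI per GRS unit) by parent sex and adjustment, from a large UK cohort
#'   analysis, with 95% CIs.
#' * `bmi_summary` — the corresponding sex-specific offspring BMI means and
#'   SDs (kg/m2), used to rescale denominators between parent sexes.
#' * `oai_loghr` — published OAI hazard ratios and SE(ln HR) by
#'   parent/offspring sex pairing and adjustment, usable as meta-analysis
#'   inputs.
#' * `iga_1958` — intergenerational BMI associations (parental BMI per kg/m2
#'   of offspring BMI) estimated in the 1958 British birth cohort, the
#'   classic external OAI denominator source.
#'
#' `se` columns are derived from the printed 95% CIs (`(upper - lower) /
#' (2 * 1.96)`) where an SE was not printed directly.
#'
#' @param name One of `"grs_denominators"`, `"bmi_summary"`, `"oai_loghr"`,
#'   `"iga_1958"`.
#' @return A tibble.
#' @export
published_inputs <- function(name = c("grs_denominators", "bmi_summary", "oai_loghr", "iga_1958")) {
  name <- match.arg(name)
  file <- system.file(
    "extdata",
    paste0(
      switch(name,
        grs_denominators = "grs_denominators_published",
        bmi_summary = "bmi_summary_published",
        oai_loghr = "oai_loghr_published",
        iga_1958 = "iga_1958_published"
      ),
      ".tsv"
    ),
    package = "kinmr", mustWork = TRUE
  )
  out <- readr::read_tsv(file, show_col_types = FALSE)
  if (all(c("ci_lower", "ci_upper") %in% names(out))) {
    out$se <- (out$ci_upper - out$ci_lower) / (2 * 1.96)
  }
  if ("hr" %in% names(out)) out$loghr <- log(out$hr)
  out
}
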