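#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for kinmr result objects
#'
#' `tidy()` returns one row per estimate with `term`, `estimate` (log-HR per
#' kg/m2), `std.error`, `conf.low`, `conf.high`; `glance()` returns one-row
#' model-level summaries (for meta-analyses: heterogeneity statistics).
#'
#' @param x An `iv_estimate`, `instrument_assoc` or `meta_result` object.
#' @param ... Unused.
#' @return A tibble.
#' @name kinmr-tidiers
NULL

#' @rdname kinmr-tidiers
#' @export
tidy.iv_estimate <- function(x, ...) {
  tibble::tibble(
    term = paste(x$method, x$parent_sex, x$offspring_sex, x$adjustment, sep = "/"),
    estimate = x$estimate,
    std.error = x$se,
    conf.low = x$ci_lower,
    conf.high = x$ci_upper
  )
}

#' @rdname kinmr-tidiers
#' @export
tidy.instrument_assoc <- function(x, ...) {
  tibble::tibble(
    term = paste(x$kind, x$instrument_label, x$parent_sex, x$offspring_sex, sep = "/"),
    estimate = x$estimate,
    std.error = x$se
  )
}

#' @rdname kinmr-tidiers
#' @export
tidy.meta_result <- function(x, ...) {
  tibble::tibble(
    term = x$method,
    estimate = x$estimate,
    std.error = x$se,
    conf.low = x$ci_lower,
    conf.high = x$ci_upper
  )
}

#' @rdname kinmr-tidiers
#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(Q = x$Q, df = x$df, i.squared = x$i2, p.heterogeneity = x$p_het, k = x$k)
}

#' @rdname kinmr-tidiers
#' @export
glance.kinmr_results <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$cohort),
    n_families = x$config$n_families,
    n_snps = nrow(x$panel),
    adjustment = x$config$adjustment,
    n_estimates = nrow(x$results),
    seed = x$config$seed
  )
}
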