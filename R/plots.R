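#' Forest plot of IV hazard-ratio estimates
#'
#' One point per (method, parent sex, offspring sex) with 95% CI whiskers on
#' the hazard-ratio scale (log-spaced axis), the null at HR = 1 dashed.
#'
#' @param object An `iv_estimate` tibble (or the `results` element of a
#'   `kinmr_results` bundle).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iv_estimate <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(
      label = paste(.data$method, .data$parent_sex, .data$offspring_sex, sep = " / ")
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hr, y = stats::reorder(.data$label, .data$hr))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$hr_lower, xmax = .data$hr_upper),
      height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = expression("Hazard ratio per kg/m"^2 * " of BMI"), y = NULL,
      title = "Intergenerational IV estimates"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.iv_estimate
#' @export
autoplot.kinmr_results <- function(object, ...) autoplot.iv_estimate(object$results, ...)

#' Paired dot-plot of bias components
#'
#' Shows, for each covariate, the scaled bias component of each instrument
#' with bootstrap 95% CIs (scaled by the same pair factor), ordered by
#' absolute relative bias as returned by [bias_components()]. Pairs where the
#' offspring-BMI component is large and the GRS component near zero indicate
#' confounding specific to the OAI instrument.
#'
#' @param object A `bias_components` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bias_components <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(
      covariate = factor(.data$covariate, levels = rev(unique(.data$covariate))),
      scale_factor = .data$scaled / .data$raw,
      lo = .data$ci_lower * .data$scale_factor,
      hi = .data$ci_upper * .data$scale_factor
    )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$scaled, y = .data$covariate,
    colour = .data$method, shape = .data$method
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
      height = 0.15, position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::geom_point(size = 2, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(
      x = "Bias component (scaled within covariate pair)", y = NULL,
      colour = "Instrument", shape = "Instrument",
      title = "Relative bias components: offspring BMI vs GRS instrument"
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.iv_estimate <- function(x, ...) print(autoplot.iv_estimate(x, ...))

#' @export
plot.bias_components <- function(x, ...) print(autoplot.bias_components(x, ...))
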