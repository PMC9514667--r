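#' Plot a MARY curve
#'
#' Singlet scavenging yield versus applied field on a log field axis,
#' with the reference field marked.
#'
#' @param object a `mary_curve` from [field_sweep()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mary_curve <- function(object, ...) {
  df <- dplyr::filter(object, .data$B_uT > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$B_uT, y = .data$phi_X)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "reference_uT"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(B ~ (mu * T)),
                  y = expression(Phi[X]),
                  title = "Magnetic field dependence of the scavenging yield") +
    ggplot2::theme_minimal()
}

#' Plot a rate map
#'
#' Signed percentage effect 100 (chi - 1) over the (k_X, k_Sigma) plane.
#'
#' @param object a `rate_map` from [rate_map()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rate_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k_X, y = .data$k_Sigma,
                                       fill = .data$effect_pct)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "effect (%)") +
    ggplot2::labs(x = expression(k[X] ~ (mu * s^-1)),
                  y = expression(k[Sigma] ~ (mu * s^-1)),
                  title = sprintf("Yield ratio: %.3g uT vs %.3g uT",
                                  attr(object, "B_uT"),
                                  attr(object, "B_ref_uT"))) +
    ggplot2::theme_minimal()
}

#' Plot a reduction-convergence report
#'
#' @param object a `reduction_report` from [reduction_convergence()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.reduction_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$gamma2,
                                       y = .data$discrepancy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(gamma[2] ~ (mu * s^-1)),
                  y = expression("|" * Phi[full] - Phi[reduced] * "|"),
                  title = "Convergence of the triad to the reduced model") +
    ggplot2::theme_minimal()
}
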