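# ggplot2 views of the result types

#' Plot wall shear stress along the vessel
#'
#' Per-face WSS against centerline arclength, coloured by quartile when the
#' map has been stratified.
#'
#' @param wss A [compute_wss()] tibble or `quartile_map`.
#' @return A ggplot object.
#' @export
plot_wss_profile <- function(wss) {
  p <- ggplot2::ggplot(wss, ggplot2::aes(x = .data$s_mm, y = .data$tau))
  p <- if ("quartile" %in% names(wss)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$quartile)),
                            size = 0.6, alpha = 0.7) +
      ggplot2::labs(colour = "ESS quartile")
  } else {
    p + ggplot2::geom_point(size = 0.6, alpha = 0.7)
  }
  p + ggplot2::labs(x = "arclength s (mm)", y = expression(tau ~ "(Pa)")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.quartile_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$quartile), y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = "ESS quartile", y = "mean ESS (Pa)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.prevalence_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$quartile), y = .data$pct_plaque)) +
    ggplot2::geom_col(fill = "firebrick", width = 0.7) +
    ggplot2::geom_hline(yintercept = attr(object, "overall_pct"),
                        linetype = "dashed") +
    ggplot2::labs(x = "ESS quartile", y = "plaque prevalence (%)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.anova_duncan <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(g, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters),
                       vjust = -1, size = 4) +
    ggplot2::labs(x = "group", y = "mean",
                  subtitle = "groups sharing a letter are homogeneous (Duncan)") +
    ggplot2::theme_minimal()
}

#' Residual convergence history of a flow solve
#'
#' @param flow A `flow_fields` object.
#' @return A ggplot object (log-scale residuals per Picard iteration).
#' @export
plot_residuals <- function(flow) {
  h <- tidyr::pivot_longer(flow$residual_history, -"iter",
                           names_to = "residual", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$iter, y = .data$value,
                                  colour = .data$residual)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Picard iteration", y = "scaled residual") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
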