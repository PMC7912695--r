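#' Plot rarefaction curves
#'
#' @param rar Rarefaction tibble from [rarefaction_curve()].
#' @return A ggplot object: expected richness against sampling depth, one
#'   curve per site.
#' @export
plot_rarefaction <- function(rar) {
  assert_cols(rar, c("site", "depth", "expected_richness"))
  ggplot2::ggplot(rar, ggplot2::aes(.data$depth, .data$expected_richness,
                                    colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Reads sampled", y = "Expected VT richness",
                  colour = "Site") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Ordination biplot
#'
#' Sample scores on the first two axes, optionally with environmental
#' vectors from [fit_environment()] drawn as arrows scaled by `sqrt(r2)`.
#'
#' @param object An `amf_ordination`.
#' @param envfit Optional envfit tibble.
#' @param arrow_scale Arrow length multiplier.
#' @param ... Ignored.
#' @export
autoplot.amf_ordination <- function(object, envfit = NULL, arrow_scale = NULL,
                                    ...) {
  sc <- tidy(object)
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data$axis1, .data$axis2)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample), vjust = -0.8,
                       size = 3) +
    ggplot2::labs(
      x = "Axis 1", y = "Axis 2",
      title = sprintf("%s ordination%s", toupper(object$method),
                      if (object$method == "nmds")
                        sprintf(" (stress %.3f)", object$stress) else "")) +
    ggplot2::theme_minimal()
  if (!is.null(envfit) && nrow(envfit) > 0 &&
      all(c("axis1", "axis2", "r2") %in% names(envfit))) {
    scale <- arrow_scale %||% (0.8 * max(abs(sc$axis1), abs(sc$axis2)))
    arrows <- dplyr::mutate(
      dplyr::filter(envfit, !is.na(.data$axis1)),
      x = .data$axis1 * sqrt(.data$r2) * scale,
      y = .data$axis2 * sqrt(.data$r2) * scale)
    p <- p +
      ggplot2::geom_segment(
        data = arrows,
        ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
        colour = "steelblue") +
      ggplot2::geom_text(
        data = arrows,
        ggplot2::aes(.data$x, .data$y, label = .data$variable),
        colour = "steelblue", vjust = -0.6, size = 3)
  }
  p
}

#' Z-value plot for null-test results
#'
#' One point per sample and pool scale with the +/- z_crit band marked.
#'
#' @param object An `amf_null_tests` tibble.
#' @param z_crit Significance threshold drawn as dashed lines.
#' @param ... Ignored.
#' @export
autoplot.amf_null_tests <- function(object, z_crit = 1.96, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$sample, .data$z,
                                       colour = .data$pool_scale)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = c(-z_crit, z_crit), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::labs(x = "Sample", y = "Z value", colour = "Pool scale") +
    ggplot2::theme_minimal()
}
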