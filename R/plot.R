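#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Size-concentration scatter for a stability series
#'
#' The diagnostic plot of the method: particle size (DLS-type mean) against
#' particle concentration per condition. Destabilising series fall on a
#' strongly negative trend.
#'
#' @param data A series tibble, or a `"stability_report"` (its conditions
#'   are used and the correlation shown in the subtitle).
#' @param label Column used to label points (default `condition`).
#' @return A ggplot object.
#' @export
plot_size_concentration <- function(data, label = "condition") {
  subtitle <- NULL
  if (inherits(data, "stability_report")) {
    if (!is.na(data$correlation$r)) {
      subtitle <- sprintf("Pearson r = %.2f (n = %d)",
                          data$correlation$r, data$correlation$n)
    }
    data <- data$conditions
  }
  assert_series(data)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$size_nm,
                                          y = .data$particles_per_ml)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Particle size (nm)",
                  y = "Particle concentration (/mL)",
                  subtitle = subtitle)
  if (!is.null(label) && label %in% names(data)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data[[label]]),
                                vjust = -0.8, size = 3)
  }
  p
}

#' @export
autoplot.stability_report <- function(object, ...) {
  plot_size_concentration(object)
}

#' @export
autoplot.particle_population <- function(object,
                                         weighting = c("number", "intensity"),
                                         bins = 50, ...) {
  weighting <- match.arg(weighting)
  d <- object$diameters
  w <- if (weighting == "intensity") intensity_weights(d) else
    rep(1 / length(d), length(d))
  ggplot2::ggplot(tibble(diameter_nm = d, weight = w),
                  ggplot2::aes(x = .data$diameter_nm,
                               weight = .data$weight)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::labs(x = "Diameter (nm)",
                  y = sprintf("%s-weighted fraction", weighting))
}
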