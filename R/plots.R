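#' Plot normalised toxicity ratios
#'
#' Bar chart of mean CFU survival ratio by concentration, grouped by
#' incubation time, with +/- 1 SD error bars.
#'
#' @param ratios Output of [normalized_cfu()].
#' @return A ggplot object.
#' @export
plot_toxicity <- function(ratios) {
  stopifnot(all(c("concentration", "time_h", "ratio") %in% names(ratios)))
  ggplot2::ggplot(ratios,
                  ggplot2::aes(x = factor(.data$concentration),
                               y = .data$ratio,
                               fill = factor(.data$time_h))) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$ratio - .data$sd, 0),
                   ymax = .data$ratio + .data$sd),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::labs(x = "Concentration", y = "CFU ratio (treated / control)",
                  fill = "Incubation (h)")
}

#' Plot a growth curve with its fitted exponential window
#'
#' OD600 on a log2 axis against time; when a doubling time is supplied (the
#' result of [doubling_time()]) the window it used is shaded.
#'
#' @param curve Data frame with `time_min`, `od600`.
#' @param dt Optional result of [doubling_time()].
#' @return A ggplot object.
#' @export
plot_growth <- function(curve, dt = NULL) {
  p <- ggplot2::ggplot(curve,
                       ggplot2::aes(x = .data$time_min, y = .data$od600)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = "Time (min)", y = "OD600")
  if (!is.null(dt)) {
    w <- attr(dt, "window")
    p <- p +
      ggplot2::annotate("rect", xmin = w[1], xmax = w[2],
                        ymin = -Inf, ymax = Inf, alpha = 0.12,
                        fill = "steelblue") +
      ggplot2::labs(subtitle = sprintf("doubling time %.0f min", dt))
  }
  p
}
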