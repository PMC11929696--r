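#' Plot a load-displacement curve with its extracted features
#'
#' Draws the raw curve, shades the chosen stiffness kernel window, and marks
#' the yield and ultimate loads -- the standard per-specimen audit figure
#' used alongside the plausibility flags.
#'
#' @param curve An [ld_curve()].
#' @param outcomes Optional [mech_outcomes()] for the same curve; computed
#'   with `config` when omitted.
#' @param config A [pipeline_config()].
#' @return A ggplot object.
#' @export
plot_curve <- function(curve, outcomes = NULL, config = pipeline_config()) {
  stopifnot(inherits(curve, "ld_curve"))
  if (is.null(outcomes)) outcomes <- extract_outcomes(curve, config)
  df <- tibble::tibble(displacement = curve$displacement, load = curve$load)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$displacement, .data$load)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "Displacement (mm)", y = "Load (N)",
      title = sprintf("%s [%s]", curve$specimen_id, curve$state),
      subtitle = if (length(outcomes$flags))
        paste("flags:", paste(outcomes$flags, collapse = ", ")) else NULL) +
    ggplot2::theme_minimal()
  if (!is.null(outcomes$stiffness_window))
    p <- p + ggplot2::annotate("rect",
      xmin = outcomes$stiffness_window[1], xmax = outcomes$stiffness_window[2],
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue")
  marks <- tibble::tibble(
    displacement = c(outcomes$yield_displacement,
                     outcomes$ultimate_displacement),
    load = c(outcomes$yield_load, outcomes$ultimate_load),
    what = c("yield load", "ultimate load"))
  marks <- marks[!is.na(marks$load), ]
  if (nrow(marks))
    p <- p + ggplot2::geom_point(
      data = marks, ggplot2::aes(colour = .data$what), size = 2) +
      ggplot2::labs(colour = NULL)
  p
}
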