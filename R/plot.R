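# ggplot2 views of the result containers.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a chromatogram
#' @param object A [chromatogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chromatogram
#' @export
autoplot.chromatogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "retention time (min)", y = "detector signal",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Plot a baseline-corrected chromatogram
#'
#' Original signal, estimated SNIP baseline (dashed) and corrected signal in
#' stacked panels.
#'
#' @param object A `baseline_tbl` from [correct_baseline()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot baseline_tbl
#' @export
autoplot.baseline_tbl <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("signal", "baseline", "corrected"),
    names_to = "trace", values_to = "value"
  )
  long$trace <- factor(long$trace, levels = c("signal", "baseline", "corrected"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     linetype = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trace, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "retention time (min)", y = "detector signal",
                  title = sprintf("SNIP baseline correction (%d iterations)",
                                  attr(object, "iterations"))) +
    ggplot2::guides(linetype = "none") +
    ggplot2::theme_minimal()
}

#' Plot extracted ion chromatograms
#' @param object An `xic_tbl` from [extract_xics()].
#' @param ... Unused.
#' @return A ggplot faceted by window centre m/z.
#' @method autoplot xic_tbl
#' @export
autoplot.xic_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$panel <- sprintf("m/z %.4f", df$center)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "retention time (min)", y = "summed ion intensity",
                  title = attr(object, "source")) +
    ggplot2::theme_minimal()
}

#' Plot a calibration curve
#'
#' Calibrant points and the fitted line, drawn on log10 axes for log-log
#' curves.
#'
#' @param object A `calibration_curve` from [fit_calibration()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  pts <- object$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$concentration, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "concentration", y = sprintf("integrated %s response", object$response_source),
      title = sprintf("%s (R² = %.4f, %s)", object$compound,
                      object$r_squared, object$scale)
    ) +
    ggplot2::theme_minimal()
  if (object$scale == "loglog") {
    grid <- exp(seq(log(min(pts$concentration)), log(max(pts$concentration)),
                    length.out = 100))
    line <- tibble::tibble(
      concentration = grid,
      response = 10^(object$intercept + object$slope * log10(grid))
    )
    p + ggplot2::geom_line(data = line) +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  } else {
    p + ggplot2::geom_abline(slope = object$slope, intercept = object$intercept)
  }
}
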