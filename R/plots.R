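#' Time-series and summary plots
#'
#' @name plots
NULL

#' @describeIn plots Displacement time series per pillar, with valley frames
#'   marked when beat segments are supplied.
#' @param object A `pt_displacement`.
#' @param segments Optional `pt_beats` whose valley frames are marked.
#' @param ... Unused.
#' @method autoplot pt_displacement
#' @export
autoplot.pt_displacement <- function(object, segments = NULL, ...) {
  fps <- attr(object, "fps")
  df <- as_tibble(object)
  if (!is.null(fps) && !"time_s" %in% names(df)) {
    df$time_s <- (df$frame - 1) / fps
  }
  xvar <- if ("time_s" %in% names(df)) "time_s" else "frame"
  xlab <- if (xvar == "time_s") "time (s)" else "frame"
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[xvar]], .data$abs_px,
                                        colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "mean absolute displacement (px)",
                  colour = "pillar") +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    vx <- segments$valley_frames
    if (xvar == "time_s") vx <- (vx - 1) / fps
    p <- p + ggplot2::geom_vline(xintercept = vx, linetype = "dotted",
                                 colour = "grey40")
  }
  p
}

#' @describeIn plots Per-beat peak force with the across-beat mean.
#' @method autoplot pt_report
#' @export
autoplot.pt_report <- function(object, ...) {
  df <- object$beats
  yvar <- if ("peak_force_un" %in% names(df)) "peak_force_un" else "peak_um"
  ylab <- if (yvar == "peak_force_un") "peak twitch force (uN)"
          else "peak displacement (um)"
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$beat), .data[[yvar]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = mean(df[[yvar]]), linetype = "dashed") +
    ggplot2::labs(x = "beat", y = ylab) +
    ggplot2::theme_minimal()
}

#' @describeIn plots Force (and stress, when present) time series.
#' @param force Force tibble from [twitch_force()]/[tissue_stress()].
#' @export
plot_force <- function(force, ...) {
  xvar <- if ("time_s" %in% names(force)) "time_s" else "frame"
  ggplot2::ggplot(force, ggplot2::aes(.data[[xvar]], .data$force_un)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = if (xvar == "time_s") "time (s)" else "frame",
                  y = "twitch force (uN)") +
    ggplot2::theme_minimal()
}
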