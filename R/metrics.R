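#' Contractility metrics
#'
#' Per-beat metrics are computed on the re-baselined displacement of each
#' beat: peak displacement (and force/stress when mechanics are supplied),
#' beat durations above 50% and 80% of the peak (FWHM, FW80M; linear
#' interpolation of the flank crossings), and contraction/relaxation
#' velocities (extrema of the central-difference derivative before/after the
#' peak). Whole-movie summaries are means and standard deviations across
#' beats, plus the beating rate.
#'
#' @name metrics
NULL

#' Beating rate
#'
#' `rate = n_complete_beats / (time between first and last valley)`.
#'
#' @param segments A `pt_beats`.
#' @param fps Frames per second.
#' @return Rate in Hz.
#' @export
beating_rate <- function(segments, fps) {
  v <- segments$valley_frames
  if (length(v) < 2) {
    abort("Beating rate needs at least one complete beat (two valleys).",
          class = "pillartrack_beat_error")
  }
  (length(v) - 1) / ((v[length(v)] - v[1]) / fps)
}

beat_signal <- function(beat) {
  if (is.numeric(beat)) return(beat)
  s <- beat |>
    dplyr::summarise(v = mean(.data$abs_px), .by = "frame") |>
    dplyr::arrange(.data$frame)
  s$v
}

#' Duration of a beat above a fraction of its peak
#'
#' The two crossings of `fraction * peak` on the rising and falling flanks
#' of the (unimodal) beat are located by linear interpolation; the width is
#' their separation in seconds. `fraction = 0.5` gives FWHM, `0.8` FW80M.
#'
#' @param beat Per-beat displacement: numeric vector or `pt_displacement`.
#' @param fraction Level as a fraction of the peak, in (0, 1).
#' @param fps Frames per second.
#' @return Width in seconds.
#' @export
width_at_fraction <- function(beat, fraction, fps) {
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  y <- beat_signal(beat)
  y <- y - min(y)
  ip <- which.max(y)
  peak <- y[ip]
  if (peak <= .Machine$double.eps^0.5) {
    abort("Beat peak is below resolution.", class = "pillartrack_metric_error")
  }
  lev <- fraction * peak
  rise <- which(y[seq_len(ip)] < lev)
  if (length(rise) == 0) {
    t_rise <- 1
  } else {
    i <- max(rise)
    t_rise <- i + (lev - y[i]) / (y[i + 1] - y[i])
  }
  after <- which(y[ip:length(y)] < lev)
  if (length(after) == 0) {
    abort("No falling crossing within the beat.",
          class = "pillartrack_metric_error")
  }
  j <- ip + min(after) - 1
  t_fall <- (j - 1) + (y[j - 1] - lev) / (y[j - 1] - y[j])
  (t_fall - t_rise) / fps
}

#' Contraction and relaxation velocities of a beat
#'
#' Central finite differences of displacement (um) against time; the
#' contraction velocity is the largest positive derivative before the peak
#' and the relaxation velocity the magnitude of the most negative derivative
#' after it.
#'
#' @param beat Per-beat displacement: numeric vector (pixels unless
#'   `length_scale = 1` and values already in um) or `pt_displacement`.
#' @param fps Frames per second.
#' @param length_scale um per pixel.
#' @return Named numeric: `contraction_um_s`, `relaxation_um_s`.
#' @export
beat_velocities <- function(beat, fps, length_scale = 1) {
  y <- beat_signal(beat) * length_scale
  n <- length(y)
  if (n < 5) abort("A beat needs at least 5 frames for velocity estimation.")
  if (diff(range(y)) <= .Machine$double.eps^0.5) {
    abort("Degenerate flat beat.", class = "pillartrack_metric_error")
  }
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / 2
  d[1] <- y[2] - y[1]
  d[n] <- y[n] - y[n - 1]
  v <- d * fps
  ip <- which.max(y)
  contraction <- max(v[seq_len(ip)])
  relaxation <- abs(min(v[ip:n]))
  c(contraction_um_s = contraction, relaxation_um_s = relaxation)
}

#' Compute the metric set of one beat
#'
#' @param beat Per-beat displacement (numeric vector in px, or
#'   `pt_displacement`).
#' @param fps Frames per second.
#' @param length_scale um per pixel.
#' @param k Optional stiffness (uN/um or `pt_stiffness`) to add peak force.
#' @param tissue Optional [tissue_geometry()] to add peak stress.
#' @return One-row tibble of beat metrics.
#' @export
beat_metrics <- function(beat, fps, length_scale = 1, k = NULL,
                         tissue = NULL) {
  y <- beat_signal(beat)
  y <- y - min(y)
  peak_um <- max(y) * length_scale
  vel <- beat_velocities(y, fps, length_scale)
  out <- tibble(
    peak_um = peak_um,
    fwhm_s = width_at_fraction(y, 0.5, fps),
    fw80m_s = width_at_fraction(y, 0.8, fps),
    contraction_um_s = vel[["contraction_um_s"]],
    relaxation_um_s = vel[["relaxation_um_s"]]
  )
  if (!is.null(k)) {
    if (inherits(k, "pt_stiffness")) k <- k$k
    # per-pillar-mean force: each pillar deflects ~peak_um at the twitch peak
    out$peak_force_un <- k * peak_um
    if (!is.null(tissue)) {
      out$peak_stress_kpa <- out$peak_force_un / tissue$area * 1000
    }
  }
  out
}

#' Summarise per-beat metrics into a contractility report
#'
#' @param per_beat Tibble of per-beat metrics (one row per beat, e.g. rows
#'   of [beat_metrics()] bound together).
#' @param segments Optional `pt_beats` used for the beating rate.
#' @param fps Frames per second (required with `segments`).
#' @param irregular Optional irregularity flag carried into the report.
#' @return A `pt_report`: `beats` (per-beat tibble), `summary` (long tibble
#'   of mean/sd per metric), `beating_rate_hz`, `n_beats`, flags.
#' @export
summarize_beats <- function(per_beat, segments = NULL, fps = NULL,
                            irregular = NA) {
  if (is.null(per_beat) || nrow(per_beat) == 0) {
    abort("No per-beat metrics to summarise.")
  }
  per_beat <- dplyr::mutate(per_beat, beat = dplyr::row_number(),
                            .before = 1)
  single <- nrow(per_beat) == 1
  summ <- per_beat |>
    dplyr::select(-"beat") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) sd(.data$value) else 0,
      .by = "metric"
    )
  rate <- if (!is.null(segments) && !is.null(fps)) {
    beating_rate(segments, fps)
  } else {
    NA_real_
  }
  structure(
    list(beats = per_beat, summary = summ, beating_rate_hz = rate,
         n_beats = nrow(per_beat), irregular = irregular,
         single_beat_sd_undefined = single),
    class = "pt_report"
  )
}

#' @export
print.pt_report <- function(x, ...) {
  cat(sprintf("<pt_report> %d beat(s)", x$n_beats))
  if (is.finite(x$beating_rate_hz)) {
    cat(sprintf(", beating rate %.3f Hz", x$beating_rate_hz))
  }
  if (isTRUE(x$irregular)) cat(" [irregular]")
  cat("\n")
  print(x$summary)
  invisible(x)
}

#' @describeIn summarize_beats Per-beat metrics, one row per beat.
#' @param x A `pt_report`.
#' @param ... Unused.
#' @method tidy pt_report
#' @export
tidy.pt_report <- function(x, ...) x$beats

#' @describeIn summarize_beats One-row summary: beating rate plus
#'   `<metric>_mean` / `<metric>_sd` columns.
#' @method glance pt_report
#' @export
glance.pt_report <- function(x, ...) {
  wide <- x$summary |>
    tidyr::pivot_longer(c("mean", "sd"), names_to = "stat") |>
    tidyr::unite("name", "metric", "stat") |>
    tidyr::pivot_wider()
  dplyr::bind_cols(
    tibble(beating_rate_hz = x$beating_rate_hz, n_beats = x$n_beats,
           irregular = x$irregular),
    wide
  )
}
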