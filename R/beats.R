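#' Displacement series, valley detection and beat segmentation
#'
#' Tracked marker positions are reduced to per-pillar mean directional and
#' absolute displacements relative to a baseline (valley) frame. Valleys of
#' the contraction signal delimit individual beats; the contraction signal is
#' the inter-pillar separation deficit when both pillars are available
#' (baseline-free, maximal separation = fully relaxed tissue), otherwise the
#' mean absolute displacement.
#'
#' @name beat-analysis
NULL

#' Per-pillar mean displacement series
#'
#' For each frame, the directional displacements are the mean over markers of
#' `position - position(baseline_frame)` and the absolute displacement is the
#' mean over markers of the per-marker Euclidean displacement norm. Only
#' markers that survive through the whole movie contribute.
#'
#' @param tracks A `pt_tracks` tibble from [track_markers()].
#' @param baseline_frame Frame index used as rest configuration (default 1).
#' @param fps,length_scale Optional acquisition metadata; when supplied,
#'   `time_s` and `abs_um` columns are added.
#' @return A `pt_displacement` tibble with columns `frame`, `side`, `d_row`,
#'   `d_col`, `abs_px` (and `time_s`, `abs_um` when metadata is known), with
#'   attributes `separation_px` (per-frame inter-pillar distance, if both
#'   sides present), `fps`, `length_scale`, `baseline_frame`, `n_markers`.
#' @export
mean_displacement <- function(tracks, baseline_frame = 1L, fps = NULL,
                              length_scale = NULL) {
  nf <- attr(tracks, "n_frames") %||% max(tracks$frame)
  # markers alive in every frame
  full <- tracks |>
    dplyr::summarise(n = dplyr::n(), .by = c("side", "marker")) |>
    dplyr::filter(.data$n == nf)
  if (nrow(full) == 0) abort("No markers survive the whole movie.")
  tr <- dplyr::inner_join(tracks, full[, c("side", "marker")],
                          by = c("side", "marker"))
  base <- tr |>
    dplyr::filter(.data$frame == baseline_frame) |>
    dplyr::select("side", "marker", row0 = "row", col0 = "col")
  if (nrow(base) == 0) abort("`baseline_frame` is out of range.")
  tr <- dplyr::inner_join(tr, base, by = c("side", "marker"))
  out <- tr |>
    dplyr::summarise(
      d_row = mean(.data$row - .data$row0),
      d_col = mean(.data$col - .data$col0),
      abs_px = mean(sqrt((.data$row - .data$row0)^2 +
                           (.data$col - .data$col0)^2)),
      .by = c("frame", "side")
    ) |>
    dplyr::arrange(.data$side, .data$frame)
  if (!is.null(fps)) out$time_s <- (out$frame - 1) / fps
  if (!is.null(length_scale)) out$abs_um <- out$abs_px * length_scale
  sep <- NULL
  if (all(c("left", "right") %in% out$side)) {
    centers <- tr |>
      dplyr::summarise(mr = mean(.data$row), mc = mean(.data$col),
                       .by = c("frame", "side")) |>
      tidyr::pivot_wider(names_from = "side", values_from = c("mr", "mc"))
    sep <- sqrt((centers$mr_left - centers$mr_right)^2 +
                  (centers$mc_left - centers$mc_right)^2)[order(centers$frame)]
  }
  n_markers <- setNames(full$n > 0, paste(full$side, full$marker))
  structure(
    out,
    class = c("pt_displacement", class(out)),
    separation_px = sep,
    fps = fps, length_scale = length_scale,
    baseline_frame = baseline_frame,
    n_markers = table(full$side)
  )
}

# contraction signal used for valley finding: separation deficit if
# available, else mean absolute displacement across sides
contraction_signal <- function(series) {
  sep <- attr(series, "separation_px")
  if (!is.null(sep)) return(max(sep) - sep)
  s <- series |>
    dplyr::summarise(v = mean(.data$abs_px), .by = "frame") |>
    dplyr::arrange(.data$frame)
  s$v
}

moving_average <- function(x, window) {
  window <- max(3L, as.integer(window))
  if (window %% 2 == 0) window <- window + 1L
  h <- (window - 1L) / 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[
    (h + 1):(h + length(x))]
}

#' Find valley frames and beat segments in a displacement series
#'
#' The contraction signal is smoothed with a centred moving average
#' (`max(3, round(fps/10))` frames), then valley frames are local minima with
#' prominence at least `prominence_frac` of the smoothed signal range and
#' mutual separation of at least `min_separation` frames (default `fps / 3`).
#' The movie start counts as a valley when its level is within the prominence
#' band of the global minimum. Beats are half-open frame ranges between
#' consecutive valleys; the terminal partial beat is discarded.
#'
#' @param series A `pt_displacement` (or a bare numeric contraction signal).
#' @param fps Frames per second.
#' @param prominence_frac Minimum valley prominence as a fraction of the
#'   smoothed signal range.
#' @param min_separation Minimum frames between valleys; `NULL` for `fps/3`.
#' @param smooth_window Moving-average window; `NULL` for `max(3, fps/10)`.
#' @return A `pt_beats` list: `valley_frames` (1-based), `beats` tibble
#'   (`beat`, `start`, `end`), `n_beats`, plus the smoothed signal.
#' @export
find_valleys <- function(series, fps, prominence_frac = 0.25,
                         min_separation = NULL, smooth_window = NULL) {
  s <- if (is.numeric(series)) series else contraction_signal(series)
  nfr <- length(s)
  if (is.null(min_separation)) min_separation <- fps / 3
  if (is.null(smooth_window)) smooth_window <- max(3, round(fps / 10))
  sm <- moving_average(s, smooth_window)
  rng <- diff(range(sm))
  if (rng <= 0) {
    abort("Displacement signal is constant; no beats to segment.",
          class = "pillartrack_beat_error")
  }
  # interior local minima (plateau bottoms keep their first frame)
  i <- 2:(nfr - 1)
  cand <- i[sm[i] < sm[i + 1] & sm[i] <= sm[i - 1]]
  if (length(cand) > 1) {
    cand <- cand[c(TRUE, diff(cand) > 1 | diff(sm[cand]) != 0)]
  }
  # prominence: lowest barrier between the valley and its neighbours
  valley_prom <- function(cand) {
    vapply(seq_along(cand), function(k) {
      i <- cand[k]
      lo <- if (k == 1) 1L else cand[k - 1]
      hi <- if (k == length(cand)) nfr else cand[k + 1]
      min(max(sm[lo:i]), max(sm[i:hi])) - sm[i]
    }, numeric(1))
  }
  prom <- valley_prom(cand)
  # reference scale: the deepest candidate's prominence tracks the beat
  # amplitude even when baseline drift inflates the raw signal range
  scale <- if (length(prom)) max(prom) else rng
  # movie start: a valley when it sits at the bottom of the signal band
  if (sm[1] <= min(sm) + prominence_frac * scale) {
    cand <- c(1L, cand)
    prom <- c(scale, prom)
  }
  if (length(cand) == 0) {
    abort("No valley frames found.", class = "pillartrack_beat_error")
  }
  keep <- prom >= prominence_frac * scale | cand == 1L
  cand <- cand[keep]
  # enforce minimum separation, keeping the deepest valleys first
  ordv <- cand[order(sm[cand])]
  sel <- integer(0)
  for (i in ordv) {
    if (all(abs(sel - i) >= min_separation)) sel <- c(sel, i)
  }
  valleys <- sort(sel)
  beats <- tibble(
    beat = seq_len(max(length(valleys) - 1, 0)),
    start = head(valleys, -1),
    end = tail(valleys, -1)
  )
  beats <- dplyr::filter(beats, .data$end - .data$start >= 3)
  if (nrow(beats) < 2) {
    abort(sprintf(paste0(
      "Only %d complete beat(s) detected; a minimum of 2 complete beats ",
      "must be present in any movie to be analyzed."), nrow(beats)),
      class = "pillartrack_beat_error")
  }
  structure(
    list(valley_frames = valleys, beats = beats, n_beats = nrow(beats),
         smoothed = sm, fps = fps,
         prominence_frac = prominence_frac,
         min_separation = min_separation),
    class = "pt_beats"
  )
}

#' @export
print.pt_beats <- function(x, ...) {
  cat(sprintf("<pt_beats> %d complete beats, valleys at frames %s\n",
              x$n_beats, paste(x$valley_frames, collapse = ", ")))
  invisible(x)
}

#' Re-anchor a movie to start at its first valley frame
#'
#' If the first detected valley is not frame 1, frames before it are dropped
#' and the caller must re-run feature detection and tracking on the adjusted
#' movie (`retrack_needed = TRUE`), so that the tracking baseline is a fully
#' relaxed configuration.
#'
#' @param movie A `pt_movie`.
#' @param segments A `pt_beats` from [find_valleys()].
#' @return A list with `movie` (possibly truncated) and `retrack_needed`.
#' @export
adjust_start <- function(movie, segments) {
  v1 <- segments$valley_frames[1]
  if (v1 <= 1L) {
    return(list(movie = movie, retrack_needed = FALSE))
  }
  trimmed <- pt_movie(movie$frames[, , v1:n_frames(movie), drop = FALSE],
                      bit_depth = movie$bit_depth, fps = movie$fps,
                      length_scale = movie$length_scale,
                      source = movie$source)
  list(movie = trimmed, retrack_needed = TRUE)
}

#' Detect baseline drift at valley frames
#'
#' Drift is flagged when the mean absolute displacement at any valley frame
#' other than the baseline exceeds `tol_px`: a relaxed tissue should return
#' to zero displacement, so a non-zero valley baseline indicates tracked
#' feature drift (imaging noise, out-of-plane motion).
#'
#' @param series A `pt_displacement`.
#' @param segments A `pt_beats`.
#' @param tol_px Tolerance in pixels at valleys (default 0.5 px).
#' @return A `pt_drift` list: `detected`, `valley_baselines_px`, `tol_px`.
#' @export
detect_drift <- function(series, segments, tol_px = 0.5) {
  if (length(segments$valley_frames) < 2) {
    abort("Drift detection needs at least 2 valleys.")
  }
  absbar <- series |>
    dplyr::summarise(v = mean(.data$abs_px), .by = "frame") |>
    dplyr::arrange(.data$frame)
  base <- attr(series, "baseline_frame") %||% 1L
  vf <- setdiff(segments$valley_frames, base)
  baselines <- absbar$v[match(segments$valley_frames, absbar$frame)]
  detected <- any(absbar$v[match(vf, absbar$frame)] > tol_px)
  if (isTRUE(detected)) {
    warn(sprintf(paste0(
      "Drift detected: displacement at valley frame(s) %s exceeds %.2f px. ",
      "Consider per-beat splitting (split = TRUE)."),
      paste(vf[absbar$v[match(vf, absbar$frame)] > tol_px], collapse = ", "),
      tol_px), class = "pillartrack_drift_warning")
  }
  structure(list(detected = detected,
                 valley_baselines_px = setNames(baselines,
                                                segments$valley_frames),
                 tol_px = tol_px),
            class = "pt_drift")
}

#' Split trajectories into per-beat displacement series
#'
#' Each beat is re-baselined to the fiducial marker positions at its own
#' start valley, which removes accumulated drift from per-beat outputs. The
#' split is only meaningful with at least 3 complete beats and is never
#' applied automatically.
#'
#' @param tracks A `pt_tracks`.
#' @param segments A `pt_beats`.
#' @param fps,length_scale Optional metadata forwarded to each series.
#' @return A list of `pt_displacement`, one per beat (frames renumbered from
#'   the beat's start valley; original frame kept in `movie_frame`).
#' @export
split_beats <- function(tracks, segments, fps = NULL, length_scale = NULL) {
  if (segments$n_beats < 3) {
    abort(sprintf(paste0(
      "Per-beat splitting requires at least 3 complete beats; found %d."),
      segments$n_beats), class = "pillartrack_beat_error")
  }
  purrr::pmap(segments$beats, function(beat, start, end) {
    sub <- dplyr::filter(tracks, .data$frame >= start, .data$frame < end)
    sub$movie_frame <- sub$frame
    sub$frame <- sub$frame - start + 1L
    attr(sub, "n_frames") <- end - start
    ser <- mean_displacement(sub, baseline_frame = 1L, fps = fps,
                             length_scale = length_scale)
    ser$movie_frame <- ser$frame + start - 1L
    attr(ser, "beat") <- beat
    ser
  })
}

#' Flag irregular beating
#'
#' A warning flag is raised when the beat-period coefficient of variation
#' exceeds `period_cv_max`, or when any beat's peak amplitude deviates from
#' the median peak by more than `amplitude_dev_max`. Detection only: no
#' further action is taken on flagged movies.
#'
#' @param segments A `pt_beats`.
#' @param series A `pt_displacement` for the same movie.
#' @param period_cv_max Maximum allowed period CV (default 0.20).
#' @param amplitude_dev_max Maximum allowed relative deviation of any beat
#'   peak from the median peak (default 0.30).
#' @return Logical flag (with a warning when `TRUE`); attributes carry the
#'   per-beat periods and peaks.
#' @export
detect_irregular <- function(segments, series, period_cv_max = 0.20,
                             amplitude_dev_max = 0.30) {
  if (segments$n_beats < 2) abort("Irregularity check needs >= 2 beats.")
  periods <- segments$beats$end - segments$beats$start
  absbar <- series |>
    dplyr::summarise(v = mean(.data$abs_px), .by = "frame") |>
    dplyr::arrange(.data$frame)
  peaks <- purrr::pmap_dbl(segments$beats, function(beat, start, end) {
    win <- absbar$v[absbar$frame >= start & absbar$frame < end]
    max(win) - min(win)
  })
  cv <- sd(periods) / mean(periods)
  amp_dev <- abs(peaks - stats::median(peaks)) / stats::median(peaks)
  flag <- cv > period_cv_max || any(amp_dev > amplitude_dev_max)
  if (flag) {
    warn(sprintf(paste0(
      "Irregular beating detected (period CV %.1f%%, max amplitude ",
      "deviation %.1f%%). No further action is taken."),
      100 * cv, 100 * max(amp_dev)),
      class = "pillartrack_irregular_warning")
  }
  structure(flag, period_cv = cv, amplitude_dev = amp_dev,
            periods = periods, peaks_px = peaks)
}
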