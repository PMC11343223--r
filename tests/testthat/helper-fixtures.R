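# Shared fixtures and independent oracles.

# Small fast movie spec used wherever full-size movies are not needed.
small_spec <- function(...) {
  synthetic_movie_spec(period = 20, beats = 2, ...)
}

jaccard <- function(a, b) sum(a == 1 & b == 1) / sum(a == 1 | b == 1)

# Track both pillars of a movie with automatically adjusted parameters and
# return the combined pt_tracks.
track_movie <- function(movie, masks) {
  fr <- get_frame(movie, 1)
  tracks <- dplyr::bind_rows(lapply(masks, function(m) {
    p <- auto_adjust(fr, m, bit_depth = movie$bit_depth)
    mk <- detect_features(fr, m, p$feature, bit_depth = movie$bit_depth)
    suppressWarnings(track_markers(movie, mk, p$flow))
  }))
  attr(tracks, "n_frames") <- n_frames(movie)
  tracks
}

# Peak of the mean absolute displacement (both pillars averaged).
peak_mean_abs <- function(series) {
  s <- dplyr::summarise(series, v = mean(abs_px), .by = "frame")
  max(s$v)
}

track_peak <- function(movie, masks) {
  peak_mean_abs(mean_displacement(track_movie(movie, masks)))
}

# Independent renderer oracle: brute-force SSD template matching of the
# frame-1 cap crop against each frame over a nested sub-pixel shift grid
# (bilinear image resampling; no optical flow involved).
oracle_col_shift <- function(movie, bbox, frames) {
  tpl <- get_frame(movie, 1)[bbox["rmin"]:bbox["rmax"],
                             bbox["cmin"]:bbox["cmax"]]
  tpl <- matrix(as.numeric(tpl), nrow(tpl))
  rr0 <- matrix(bbox["rmin"]:bbox["rmax"], nrow(tpl), ncol(tpl))
  cc0 <- matrix(bbox["cmin"]:bbox["cmax"], nrow(tpl), ncol(tpl), byrow = TRUE)
  bilin <- getFromNamespace("bilinear_at", "pillartrack")
  vapply(frames, function(f) {
    fr <- get_frame(movie, f)
    img <- matrix(as.numeric(fr), nrow(fr))
    ssd <- function(dc) sum((bilin(img, rr0, cc0 + dc) - tpl)^2)
    best <- 0
    for (step in c(1, 0.1, 0.01)) {
      grid <- best + seq(-5 * step, 5 * step, by = step)
      best <- grid[which.min(vapply(grid, ssd, numeric(1)))]
    }
    best
  }, numeric(1))
}

# Fabricate a pt_beats object from valley frames (for unit tests that do not
# need detection).
make_beats <- function(valley_frames, fps = 30) {
  beats <- tibble::tibble(
    beat = seq_len(length(valley_frames) - 1),
    start = utils::head(valley_frames, -1),
    end = utils::tail(valley_frames, -1)
  )
  structure(list(valley_frames = valley_frames, beats = beats,
                 n_beats = nrow(beats), smoothed = NULL, fps = fps,
                 prominence_frac = 0.25, min_separation = fps / 3),
            class = "pt_beats")
}

# Fabricate trajectories: markers rigidly displaced in the column direction
# by a prescribed per-frame signal (left +, right -), for beat-analysis tests
# that do not need rendering or tracking.
make_tracks <- function(disp, n_markers = 6) {
  nf <- length(disp)
  rows <- seq(40, 56, length.out = n_markers)
  build <- function(side, col0, sign) {
    tidyr::expand_grid(marker = seq_len(n_markers), frame = seq_len(nf)) |>
      dplyr::mutate(side = side,
                    row = rows[marker],
                    col = col0 + sign * disp[frame])
  }
  out <- dplyr::bind_rows(build("left", 50, +1), build("right", 150, -1))
  attr(out, "n_frames") <- nf
  out
}

raised_cosine <- function(t0, amplitude, period) {
  amplitude * (1 - cos(2 * pi * t0 / period)) / 2
}
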