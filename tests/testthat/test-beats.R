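test_that("mean displacement reduces markers correctly", {
  # two markers displaced identically by (3, 4): 3-4-5 triangle
  tr <- tibble::tibble(
    marker = rep(1:2, each = 2), side = "left",
    frame = rep(1:2, 2),
    row = c(10, 13, 20, 23), col = c(10, 14, 20, 24)
  )
  attr(tr, "n_frames") <- 2L
  ser <- mean_displacement(tr)
  at2 <- dplyr::filter(ser, frame == 2)
  expect_equal(at2$d_row, 3)
  expect_equal(at2$d_col, 4)
  expect_equal(at2$abs_px, 5)
  expect_equal(dplyr::filter(ser, frame == 1)$abs_px, 0)

  # opposite displacements cancel directionally but not in magnitude
  tr2 <- tibble::tibble(
    marker = rep(1:2, each = 2), side = "left", frame = rep(1:2, 2),
    row = c(10, 10, 20, 20), col = c(10, 12, 20, 18)
  )
  attr(tr2, "n_frames") <- 2L
  at2 <- dplyr::filter(mean_displacement(tr2), frame == 2)
  expect_equal(at2$d_col, 0)
  expect_equal(at2$abs_px, 2)

  # baselining at a frame zeroes that frame
  ser3 <- mean_displacement(tr, baseline_frame = 2L)
  expect_equal(dplyr::filter(ser3, frame == 2)$abs_px, 0)

  # permutation invariance: relabelling markers changes nothing
  tr4 <- dplyr::mutate(tr, marker = 3 - marker)
  attr(tr4, "n_frames") <- 2L
  expect_equal(mean_displacement(tr4)$abs_px, ser$abs_px)
})

test_that("valleys of a raised-cosine signal are found at its minima", {
  t0 <- 0:119
  y <- raised_cosine(t0, amplitude = 4, period = 30)
  seg <- find_valleys(y, fps = 30)
  expect_equal(seg$n_beats, 3)
  expect_true(all(abs(seg$valley_frames - c(1, 31, 61, 91)) <= 1))

  # with mild noise the valley frames move by at most one frame
  withr::with_seed(7, {
    noisy <- y + stats::rnorm(length(y), sd = 0.02 * 4)
  })
  segn <- find_valleys(noisy, fps = 30)
  expect_equal(segn$n_beats, 3)
  expect_true(all(abs(segn$valley_frames - seg$valley_frames) <= 1))
})

test_that("fewer than 2 complete beats is a hard error", {
  y <- raised_cosine(0:39, amplitude = 4, period = 30)
  expect_error(find_valleys(y, fps = 30), "minimum of 2 complete beats",
               class = "pillartrack_beat_error")
})

test_that("valley recovery matches generator ground truth across waveforms", {
  for (wf in c("raised_cosine", "triangular")) {
    gen <- generate_movie(synthetic_movie_spec(amplitude = 3, period = 20,
                                               beats = 3, waveform = wf,
                                               noise_sd = 0, seed = 31L))
    ser <- mean_displacement(track_movie(gen$movie, gen$truth$masks))
    seg <- find_valleys(ser, fps = 30)
    for (v in seg$valley_frames) {
      expect_lte(min(abs(gen$truth$valley_frames - v)), 1)
    }
    expect_gte(seg$n_beats, 3)
  }
})

test_that("movies are re-anchored to their first valley", {
  gen <- generate_movie(small_spec(seed = 32L))
  ser <- mean_displacement(track_movie(gen$movie, gen$truth$masks))
  seg <- find_valleys(ser, fps = 30)
  adj <- adjust_start(gen$movie, seg)
  expect_false(adj$retrack_needed)
  expect_identical(adj$movie$frames, gen$movie$frames)

  shifted <- make_beats(c(16, 46, 76))
  adj2 <- adjust_start(gen$movie, shifted)
  expect_true(adj2$retrack_needed)
  expect_equal(n_frames(adj2$movie), n_frames(gen$movie) - 15L)
  expect_identical(adj2$movie$frames[, , 1], gen$movie$frames[, , 16])
})

test_that("drift is detected from valley baselines", {
  t0 <- 0:119
  y <- raised_cosine(t0, 3, 30) + 0.05 * t0
  tr <- make_tracks(y)
  ser <- mean_displacement(tr)
  seg <- make_beats(c(1, 31, 61, 91))
  expect_warning(rep <- detect_drift(ser, seg, tol_px = 0.5),
                 class = "pillartrack_drift_warning")
  expect_true(rep$detected)
  expect_equal(unname(rep$valley_baselines_px), c(0, 1.5, 3.0, 4.5))

  # drift-free series: no detection
  ser0 <- mean_displacement(make_tracks(raised_cosine(t0, 3, 30)))
  expect_false(detect_drift(ser0, seg, tol_px = 0.5)$detected)
  # a vacuous tolerance never fires
  expect_false(detect_drift(ser, seg, tol_px = Inf)$detected)
})

test_that("per-beat splitting removes linear drift from beat amplitudes", {
  t0 <- 0:119
  amp <- 3; ramp <- 0.05
  y <- raised_cosine(t0, amp, 30) + ramp * t0
  tr <- make_tracks(y)
  seg <- make_beats(c(1, 31, 61, 91))
  beats <- split_beats(tr, seg)
  expect_length(beats, 3)
  true_peak <- amp + ramp * 15  # within-beat ramp accumulates to the peak
  for (b in beats) {
    expect_equal(dplyr::filter(b, frame == 1)$abs_px, c(0, 0))
    expect_lt(abs(peak_mean_abs(b) - true_peak) / true_peak, 0.05)
  }
  # whole-movie baselining inflates the last beat by the accumulated ramp
  whole <- peak_mean_abs(mean_displacement(tr))
  expect_gt(whole, true_peak * 1.5)

  # without drift, per-beat peaks equal the whole-movie peak
  tr0 <- make_tracks(raised_cosine(t0, amp, 30))
  beats0 <- split_beats(tr0, seg)
  whole0 <- peak_mean_abs(mean_displacement(tr0))
  for (b in beats0) {
    expect_equal(peak_mean_abs(b), whole0, tolerance = 0.01)
  }
})

test_that("splitting requires at least 3 complete beats", {
  tr <- make_tracks(raised_cosine(0:69, 3, 30))
  expect_error(split_beats(tr, make_beats(c(1, 31, 61))),
               "at least 3 complete beats", class = "pillartrack_beat_error")
})

test_that("irregular beating is flagged on period or amplitude deviations", {
  t0 <- 0:179
  y <- raised_cosine(t0, 3, 30)
  ser <- mean_displacement(make_tracks(y))
  regular <- make_beats(c(1, 31, 61, 91, 121, 151))
  expect_false(as.logical(detect_irregular(regular, ser)))

  # alternating 30/60-frame periods: period CV well above 20%
  alternating <- make_beats(c(1, 31, 91, 121, 181))
  expect_warning(flag <- detect_irregular(alternating, ser),
                 class = "pillartrack_irregular_warning")
  expect_true(as.logical(flag))
  expect_gt(attr(flag, "period_cv"), 0.2)

  # one beat at half amplitude among normal ones
  y2 <- raised_cosine(t0, 3, 30)
  dip <- t0 >= 60 & t0 < 90
  y2[dip] <- raised_cosine(t0[dip], 1.5, 30)
  ser2 <- mean_displacement(make_tracks(y2))
  expect_warning(flag2 <- detect_irregular(regular, ser2),
                 class = "pillartrack_irregular_warning")
  expect_true(as.logical(flag2))
})
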