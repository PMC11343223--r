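test_that("feature detection fails cleanly on textureless regions", {
  frame <- matrix(128L, 64, 64)
  mask_grid <- matrix(0L, 64, 64); mask_grid[20:44, 20:44] <- 1L
  mask <- pt_mask(mask_grid, "left")
  expect_error(detect_features(frame, mask),
               class = "pillartrack_tracking_error")
  # auto adjustment bottoms out at the quality floor without erroring
  p <- auto_adjust(frame, mask)
  expect_equal(p$feature$quality_level, 0.005)
})

test_that("checkerboard corners are found inside the mask", {
  sq <- 8
  frame <- 255L * outer(1:64, 1:64, function(r, c) {
    (floor((r - 1) / sq) + floor((c - 1) / sq)) %% 2
  })
  storage.mode(frame) <- "integer"
  mask_grid <- matrix(0L, 64, 64); mask_grid[13:52, 13:52] <- 1L
  mask <- pt_mask(mask_grid, "left")
  mk <- detect_features(frame, mask,
                        feature_params(min_distance = 5, max_corners = 200))
  # interior checker corners under the mask: a 40 px window over 8 px squares
  # holds a 4x4 corner lattice either way the phase falls; suppression radius
  # 5 < 8 keeps all of them
  expect_gte(nrow(mk), 9)
  expect_true(all(mask[cbind(round(mk$row), round(mk$col))] == 1))
})

test_that("lowering quality_level never decreases the feature count", {
  gen <- generate_movie(small_spec(seed = 22L))
  frame <- get_frame(gen$movie, 1)
  mask <- gen$truth$masks$left
  counts <- vapply(c(0.4, 0.2, 0.1, 0.05, 0.01), function(q) {
    nrow(detect_features(frame, mask, feature_params(quality_level = q,
                                                     max_corners = 500)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("static movies track to identically zero displacement", {
  gen <- generate_movie(small_spec(amplitude = 0, noise_sd = 0, seed = 23L))
  expect_identical(gen$movie$frames[, , 1], gen$movie$frames[, , 5])
  tracks <- track_movie(gen$movie, gen$truth$masks)
  series <- mean_displacement(tracks)
  expect_lt(max(series$abs_px), 0.05)
})

test_that("integer shifts are recovered within 0.2 px over 10 frames", {
  gen <- generate_movie(small_spec(amplitude = 0, noise_sd = 0, seed = 24L))
  base <- get_frame(gen$movie, 1)
  nc <- ncol(base)
  frames <- lapply(0:9, function(t) {
    shift <- 2L * t
    if (shift == 0) base
    else base[, c(seq(nc - shift + 1, nc), seq_len(nc - shift))]  # roll right
  })
  mv <- pt_movie(frames, bit_depth = 8L)
  mk <- detect_features(base, gen$truth$masks$left, feature_params())
  tracks <- track_markers(mv, mk, flow_params())
  last <- dplyr::filter(tracks, frame == 10)
  first <- dplyr::filter(tracks, frame == 1)
  shift_est <- mean(last$col) - mean(first$col[first$marker %in% last$marker])
  expect_equal(shift_est, 18, tolerance = 0.2 / 18)
})

test_that("sub-pixel sinusoidal motion is recovered within 10%", {
  gen <- generate_movie(small_spec(amplitude = 3, noise_sd = 0.02, seed = 25L))
  peak <- track_peak(gen$movie, gen$truth$masks)
  expect_lt(abs(peak - 3) / 3, 0.10)
})

test_that("auto adjustment follows its documented schedule", {
  # a corner-rich frame keeps the defaults untouched
  sq <- 8
  frame <- 255L * outer(1:96, 1:96, function(r, c) {
    (floor((r - 1) / sq) + floor((c - 1) / sq)) %% 2
  })
  storage.mode(frame) <- "integer"
  grid <- matrix(0L, 96, 96); grid[30:65, 30:65] <- 1L
  p <- auto_adjust(frame, pt_mask(grid, "left"))
  expect_equal(p$feature$quality_level, 0.1)
  expect_equal(p$flow$window_size, 15L)
  # low-contrast pillar: quality relaxed below the default
  lo <- generate_movie(small_spec(speckle_contrast = 0.02, noise_sd = 0.015,
                                  seed = 27L))
  p_lo <- auto_adjust(get_frame(lo$movie, 1), lo$truth$masks$left)
  expect_lt(p_lo$feature$quality_level, 0.1)
  # large mask: window scales with the bounding box and stays odd
  big <- matrix(0L, 400, 400); big[100:260, 100:260] <- 1L
  p_big <- auto_adjust(matrix(0L, 400, 400), pt_mask(big, "left"))
  expect_gt(p_big$flow$window_size, 15)
  expect_equal(p_big$flow$window_size %% 2, 1)
})
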