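test_that("beating rate is beats over valley span", {
  expect_equal(beating_rate(make_beats(c(1, 31, 61)), fps = 30), 1)
  expect_equal(beating_rate(make_beats(c(1, 66)), fps = 65), 1)
  expect_equal(beating_rate(make_beats(c(1, 31, 61, 91)), fps = 60), 2)
  expect_error(beating_rate(make_beats(c(1)), fps = 30),
               class = "pillartrack_beat_error")
})

test_that("beat widths follow closed forms on analytic pulses", {
  fps <- 30
  # symmetric triangle: rise over T frames, fall over T
  T <- 10; A <- 5
  tri <- c(seq(0, A, length.out = T + 1), seq(A, 0, length.out = T + 1)[-1])
  expect_equal(width_at_fraction(tri, 0.5, fps), T / fps)
  expect_equal(width_at_fraction(tri, 0.8, fps), 0.4 * T / fps)
  # raised cosine of period P: crossings at P/4 and 3P/4
  P <- 30
  beat <- raised_cosine(0:P, A, P)
  expect_equal(width_at_fraction(beat, 0.5, fps), P / 2 / fps,
               tolerance = 1 / (P / 2))
  # FW80M nests inside FWHM for any unimodal beat, asymmetric included
  for (t_fall in c(6, 10, 17)) {
    y <- c(seq(0, A, length.out = 11), seq(A, 0, length.out = t_fall + 1)[-1])
    expect_lte(width_at_fraction(y, 0.8, fps), width_at_fraction(y, 0.5, fps))
  }
  expect_error(width_at_fraction(rep(0, 30), 0.5, fps),
               class = "pillartrack_metric_error")
})

test_that("width estimates converge to the closed form as fps grows", {
  A <- 4
  for (fps in c(30, 60, 120)) {
    P <- fps  # 1 s beat
    beat <- raised_cosine(0:P, A, P)
    expect_lt(abs(width_at_fraction(beat, 0.5, fps) - 0.5), 1 / fps)
  }
})

test_that("velocities match analytic derivatives", {
  A <- 4; P <- 30; fps <- 30
  beat <- raised_cosine(0:P, A, P)
  v <- beat_velocities(beat, fps, length_scale = 1)
  expect_equal(unname(v["contraction_um_s"]), A * pi / P * fps,
               tolerance = 0.02)
  expect_equal(unname(v["relaxation_um_s"]), A * pi / P * fps,
               tolerance = 0.02)
  # linear ramps give the slopes exactly
  ramp <- c(seq(0, 5, by = 0.5), seq(4.75, 1, by = -0.25))
  vr <- beat_velocities(ramp, fps = 10, length_scale = 1)
  expect_equal(unname(vr["contraction_um_s"]), 5)
  expect_equal(unname(vr["relaxation_um_s"]), 2.5)
  # time reversal swaps contraction and relaxation
  vrev <- beat_velocities(rev(ramp), fps = 10, length_scale = 1)
  expect_equal(unname(vrev["contraction_um_s"]),
               unname(vr["relaxation_um_s"]))
  expect_equal(unname(vrev["relaxation_um_s"]),
               unname(vr["contraction_um_s"]))
})

test_that("metrics are invariant to constant displacement offsets", {
  beat <- raised_cosine(0:30, 3, 30)
  m0 <- beat_metrics(beat, fps = 30)
  for (off in c(1, 10)) {
    expect_equal(beat_metrics(beat + off, fps = 30), m0)
  }
})

test_that("summaries aggregate per-beat metrics", {
  b <- beat_metrics(raised_cosine(0:30, 3, 30), fps = 30, length_scale = 4,
                    k = 2.677)
  rep3 <- summarize_beats(dplyr::bind_rows(b, b, b),
                          make_beats(c(1, 31, 61, 91)), fps = 30)
  expect_equal(rep3$n_beats, 3)
  expect_equal(rep3$beating_rate_hz, 1)
  expect_true(all(rep3$summary$sd == 0))
  # mean of two distinct peaks
  b2 <- b; b2$peak_force_un <- 4; b$peak_force_un <- 2
  repm <- summarize_beats(dplyr::bind_rows(b, b2))
  expect_equal(dplyr::filter(repm$summary,
                             metric == "peak_force_un")$mean, 3)
  # single beat: sd reported as 0 with an explicit flag
  rep1 <- summarize_beats(b)
  expect_true(rep1$single_beat_sd_undefined)
  expect_true(all(rep1$summary$sd == 0))
  expect_error(summarize_beats(b[0, ]), "No per-beat")
})

test_that("tidy and glance expose the report in broom style", {
  b <- beat_metrics(raised_cosine(0:30, 3, 30), fps = 30, length_scale = 4,
                    k = 2.677, tissue = tissue_geometry(120, 350))
  rep2 <- summarize_beats(dplyr::bind_rows(b, b), make_beats(c(1, 31, 61)),
                          fps = 30, irregular = FALSE)
  td <- tidy(rep2)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_true(all(c("beat", "peak_um", "fwhm_s", "peak_force_un",
                    "peak_stress_kpa") %in% names(td)))
  gl <- glance(rep2)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$beating_rate_hz, 1)
  expect_equal(gl$peak_um_mean, b$peak_um)
  expect_equal(gl$peak_um_sd, 0)
})
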