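test_that("moments of inertia match closed forms", {
  rect <- pillar_geometry(E = 1, L = 10, a = 5, width = 2, thickness = 3)
  expect_equal(moment_of_inertia(rect), 4.5)
  circ <- pillar_geometry(E = 1, L = 10, a = 5, diameter = 2)
  expect_equal(moment_of_inertia(circ), pi / 4)
  expect_error(pillar_geometry(E = 1, L = 10, a = 5, width = 0, thickness = 3),
               "positive")
  expect_error(pillar_geometry(E = 1, L = 1, a = 2, diameter = 1),
               "cannot exceed")
})

test_that("cantilever stiffness follows beam theory", {
  # I = 1 um^4 via w = 12, t = 1; consistent units (E in uN/um^2)
  g <- function(a) pillar_geometry(E = 1, L = 1, a = a, width = 12,
                                   thickness = 1, E_unit = "uN_um2")
  # a = L: classical tip-load stiffness 3EI/L^3
  expect_equal(pillar_stiffness(g(1))$k, 3)
  expect_equal(pillar_stiffness(g(0.5))$k, 9.6)
  # monotone decreasing in a on (0, L]
  ks <- vapply(seq(0.1, 1, by = 0.1),
               function(a) pillar_stiffness(g(a))$k, numeric(1))
  expect_true(all(diff(ks) < 0))
  expect_identical(pillar_stiffness(g(1))$source, "derived")
  # kPa input is converted (1 kPa = 1e-3 uN/um^2)
  g_kpa <- pillar_geometry(E = 1, L = 1, a = 1, width = 12, thickness = 1)
  expect_equal(pillar_stiffness(g_kpa)$k, 3e-3)
})

test_that("Hooke's law gives force linear in deflection", {
  t0 <- 0:59
  ser <- mean_displacement(make_tracks(raised_cosine(t0, 2, 30)))
  # length_scale chosen so the peak deflection is exactly 1 um
  f <- twitch_force(ser, measured_stiffness(2.677), length_scale = 0.5)
  expect_equal(max(f$force_un), 2.677, tolerance = 1e-12)
  expect_equal(f$force_un[1], 0)
  f2 <- twitch_force(ser, measured_stiffness(2.677), length_scale = 1)
  expect_equal(f2$force_un, 2 * f$force_un)
})

test_that("the inter-pillar-distance convention doubles the force", {
  t0 <- 0:59
  ser <- mean_displacement(make_tracks(raised_cosine(t0, 3, 30)))
  f_mean <- twitch_force(ser, 1, length_scale = 1)
  f_dist <- twitch_force(ser, 1, length_scale = 1,
                         convention = "pillar_distance")
  sel <- f_mean$force_un > 0
  expect_equal(f_dist$force_un[sel] / f_mean$force_un[sel],
               rep(2, sum(sel)), tolerance = 1e-9)
})

test_that("tissue stress is force over cross-sectional area in kPa", {
  t0 <- 0:59
  ser <- mean_displacement(make_tracks(raised_cosine(t0, 10, 30)))
  f <- twitch_force(ser, 1, length_scale = 1)  # peak force 10 uN
  s <- tissue_stress(f, tissue_geometry(width = 100, depth = 10))
  expect_equal(max(s$stress_kpa), 10)  # 10 uN / 1000 um^2 = 10 kPa
  expect_equal(s$stress_kpa[1], 0)
  s2 <- tissue_stress(f, tissue_geometry(width = 100, depth = 20))
  expect_equal(s2$stress_kpa, s$stress_kpa / 2)
  expect_error(tissue_geometry(width = 0, depth = 10), "positive")
})

test_that("tissue width is measured from the inter-pillar band", {
  gen <- generate_movie(small_spec(tissue_width = 30, noise_sd = 0.01,
                                   seed = 41L))
  frame <- get_frame(gen$movie, 1)
  w <- measure_tissue_width(frame, gen$truth$masks, length_scale = 1)
  expect_lt(abs(as.numeric(w) - 30) / 30, 0.10)
  # invariant to global intensity rescaling (threshold is scale-free)
  w2 <- measure_tissue_width(round(frame * 0.6), gen$truth$masks,
                             length_scale = 1)
  expect_lte(abs(as.numeric(w2) - as.numeric(w)), 1)
  # length scale converts to um
  w4 <- measure_tissue_width(frame, gen$truth$masks, length_scale = 4)
  expect_equal(as.numeric(w4), 4 * as.numeric(w))
  # no band: constant gap between the pillars
  flat <- matrix(38L, nrow(frame), ncol(frame))
  flat[unclass(gen$truth$masks$left) == 1L] <- 200L
  flat[unclass(gen$truth$masks$right) == 1L] <- 200L
  expect_error(measure_tissue_width(flat, gen$truth$masks),
               class = "pillartrack_width_error")
})
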