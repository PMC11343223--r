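#' Synthetic brightfield-like microbundle movies with ground truth
#'
#' The generator renders two speckle-textured pillar caps joined by a dimmer
#' tissue band on a dark background, undergoing periodic equal-and-opposite
#' deflections (the pillars move toward each other during contraction), with
#' optional symmetric baseline drift, additive Gaussian noise and 8- or
#' 16-bit quantisation. Sub-pixel motion is realised by resampling smooth
#' continuous textures at shifted coordinates (never integer rolls), so the
#' optical-flow tracker faces realistic inputs. Every movie comes with a
#' ground-truth manifest: true per-pillar displacement per frame, valley
#' frames, cap masks and tissue width.
#'
#' @name synthetic-data
NULL

#' Specification of a synthetic microbundle movie
#'
#' @param nrow,ncol Frame size in pixels.
#' @param cap_size Side of the square pillar caps (px).
#' @param cap_cols Column centres of the left and right caps.
#' @param cap_row Row centre of both caps.
#' @param amplitude Peak per-pillar deflection (px, >= 0).
#' @param period Beat period in frames (>= 4).
#' @param beats Number of beats (>= 1); the movie spans `beats * period + 1`
#'   frames.
#' @param phase Phase offset in frames (0 starts at a valley; `period / 2`
#'   starts at peak contraction).
#' @param waveform `"raised_cosine"` or `"triangular"`.
#' @param noise_sd Additive Gaussian noise, as a fraction of dynamic range.
#' @param drift Symmetric baseline drift rate (px/frame); both pillars drift
#'   apart at this rate so the valley baseline ramps.
#' @param tissue_width Vertical extent of the tissue band (px).
#' @param speckle_contrast Cap texture contrast as a fraction of dynamic
#'   range (>= 0.2 keeps corner detection well supported).
#' @param bit_depth 8 or 16.
#' @param fps,length_scale Acquisition metadata recorded on the movie.
#' @param seed Integer seed; fixed seed implies bit-identical movies.
#' @param amplitudes Optional per-beat amplitude multipliers (length
#'   `beats`), used to render irregular beating.
#' @return A `pt_movie_spec` list.
#' @export
synthetic_movie_spec <- function(nrow = 96, ncol = 200, cap_size = 28,
                                 cap_cols = c(50, 150), cap_row = nrow / 2,
                                 amplitude = 3, period = 30, beats = 3,
                                 phase = 0, waveform = c("raised_cosine",
                                                         "triangular"),
                                 noise_sd = 0.02, drift = 0,
                                 tissue_width = 30, speckle_contrast = 0.22,
                                 bit_depth = 8L, fps = 30, length_scale = 4,
                                 seed = 0L, amplitudes = NULL) {
  waveform <- match.arg(waveform)
  if (amplitude < 0) abort("`amplitude` must be >= 0.")
  if (period < 4) abort("`period` must be at least 4 frames.")
  if (beats < 1) abort("`beats` must be >= 1.")
  gap <- diff(cap_cols) - cap_size
  if (gap - 2 * (amplitude + abs(drift) * beats * period) <= 2) {
    abort("Caps would overlap at peak deflection; reduce `amplitude`/`drift`.")
  }
  if (!is.null(amplitudes) && length(amplitudes) != beats) {
    abort("`amplitudes` must have one multiplier per beat.")
  }
  structure(
    list(nrow = nrow, ncol = ncol, cap_size = cap_size, cap_cols = cap_cols,
         cap_row = cap_row, amplitude = amplitude, period = period,
         beats = beats, phase = phase, waveform = waveform,
         noise_sd = noise_sd, drift = drift, tissue_width = tissue_width,
         speckle_contrast = speckle_contrast, bit_depth = as.integer(bit_depth),
         fps = fps, length_scale = length_scale, seed = as.integer(seed),
         amplitudes = amplitudes),
    class = "pt_movie_spec"
  )
}

# smooth band-limited texture: seeded white noise blurred and renormalised
# to [-1, 1]; sampled continuously via bilinear interpolation
make_texture <- function(nr, nc) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- c(1, 4, 6, 4, 1) / 16
  z <- conv_sep(conv_sep(z, k), k)
  2 * (z - min(z)) / diff(range(z)) - 1
}

soft_box <- function(x, lo, hi, edge = 1.2) {
  pmin(pmax((x - lo) / edge, 0), 1) * pmin(pmax((hi - x) / edge, 0), 1)
}

wave_value <- function(t0, spec) {
  # t0: 0-based time in frames; returns deflection in px >= 0
  ph <- (t0 + spec$phase) %% spec$period
  beat_idx <- pmin(floor((t0 + spec$phase) / spec$period) + 1, spec$beats)
  amp <- spec$amplitude *
    if (is.null(spec$amplitudes)) 1 else spec$amplitudes[beat_idx]
  if (spec$waveform == "raised_cosine") {
    amp * (1 - cos(2 * pi * ph / spec$period)) / 2
  } else {
    amp * (1 - abs(2 * ph / spec$period - 1))
  }
}

#' Render a synthetic movie and its ground truth
#'
#' @param spec A [synthetic_movie_spec()].
#' @return A list with `movie` (a `pt_movie`) and `truth`: a list holding
#'   `displacement` (tibble `frame`, `side`, `d_col`, `abs_px`),
#'   `valley_frames` (1-based), `masks` (a `pt_mask_pair` of the frame-1 cap
#'   footprints), `tissue_width_px`, `amplitude`, `period`, and the spec.
#' @export
generate_movie <- function(spec) {
  stopifnot(inherits(spec, "pt_movie_spec"))
  # half a cycle beyond the last valley keeps it an interior minimum, so a
  # movie rendered with B beats yields B complete analyzable beats
  nf <- spec$beats * spec$period + floor(spec$period / 2) + 1
  R <- spec$nrow; C <- spec$ncol
  half <- spec$cap_size / 2
  margin <- ceiling(spec$amplitude + abs(spec$drift) * nf) + 6
  withr::with_seed(spec$seed, {
    tex_l <- make_texture(spec$cap_size + 8, spec$cap_size + 8)
    tex_r <- make_texture(spec$cap_size + 8, spec$cap_size + 8)
    tex_band <- make_texture(spec$tissue_width + 8, 64)
    bg_tex <- make_texture(R, C)
    t0 <- seq_len(nf) - 1
    d <- wave_value(t0, spec)
    drift_t <- spec$drift * t0
    # left cap moves +col (toward centre) by d; drift pulls both pillars
    # slowly inward (tissue compaction), ramping the valley baseline
    shift_l <- d + drift_t
    shift_r <- -d - drift_t
    rows <- matrix(seq_len(R), R, C)
    cols <- matrix(seq_len(C), R, C, byrow = TRUE)
    bg <- 0.15 + 0.015 * bg_tex
    frames <- array(0L, dim = c(R, C, nf))
    maxval <- 2^spec$bit_depth - 1
    render_cap <- function(tex, c_center, s) {
      a <- soft_box(rows, spec$cap_row - half, spec$cap_row + half) *
        soft_box(cols, c_center + s - half, c_center + s + half)
      # sample the cap texture in the cap's own (moving) coordinates
      tr <- rows - (spec$cap_row - half) + 4
      tc <- cols - (c_center + s - half) + 4
      intensity <- 0.72 + spec$speckle_contrast * bilinear_at(tex, tr, tc)
      list(alpha = a, val = intensity)
    }
    alpha0 <- NULL
    for (f in seq_len(nf)) {
      img <- bg
      # tissue band stretches linearly between the inner cap edges
      xl <- spec$cap_cols[1] + shift_l[f] + half
      xr <- spec$cap_cols[2] + shift_r[f] - half
      band_a <- soft_box(rows, spec$cap_row - spec$tissue_width / 2,
                         spec$cap_row + spec$tissue_width / 2) *
        soft_box(cols, xl - 2, xr + 2)
      u <- (cols - xl) / (xr - xl)
      br <- rows - (spec$cap_row - spec$tissue_width / 2) + 4
      bc <- 1 + pmin(pmax(u, 0), 1) * 63
      band_v <- 0.32 + 0.05 * bilinear_at(tex_band, br, bc)
      img <- img * (1 - band_a) + band_v * band_a
      capl <- render_cap(tex_l, spec$cap_cols[1], shift_l[f])
      capr <- render_cap(tex_r, spec$cap_cols[2], shift_r[f])
      img <- img * (1 - capl$alpha) + capl$val * capl$alpha
      img <- img * (1 - capr$alpha) + capr$val * capr$alpha
      if (f == 1) alpha0 <- list(l = capl$alpha, r = capr$alpha)
      if (spec$noise_sd > 0) {
        img <- img + stats::rnorm(R * C, sd = spec$noise_sd)
      }
      frames[, , f] <- as.integer(round(pmin(pmax(img, 0), 1) * maxval))
    }
  })
  movie <- pt_movie(frames, bit_depth = spec$bit_depth, fps = spec$fps,
                    length_scale = spec$length_scale, source = "synthetic")
  disp <- dplyr::bind_rows(
    tibble(frame = seq_len(nf), side = "left",
           d_col = shift_l - shift_l[1],
           abs_px = abs(shift_l - shift_l[1])),
    tibble(frame = seq_len(nf), side = "right",
           d_col = shift_r - shift_r[1],
           abs_px = abs(shift_r - shift_r[1]))
  )
  ph <- (t0 + spec$phase) %% spec$period
  valley_t0 <- t0[ph < 1e-9 | spec$period - ph < 1e-9]
  masks <- mask_pair(
    pt_mask(matrix(as.integer(alpha0$l > 0.5), R, C), check_connected = FALSE),
    pt_mask(matrix(as.integer(alpha0$r > 0.5), R, C), check_connected = FALSE)
  )
  truth <- list(
    displacement = disp,
    valley_frames = valley_t0 + 1L,
    masks = masks,
    tissue_width_px = spec$tissue_width,
    amplitude = spec$amplitude,
    period = spec$period,
    spec = spec
  )
  list(movie = movie, truth = truth)
}

#' Write the canonical synthetic fixture suite
#'
#' Renders a set of small reference movies (static, integer-amplitude,
#' sub-pixel with noise, drifting, irregular-beat, low-contrast, type-1-like
#' and type-2-like styling) as TIFF frame folders, each with a ground-truth
#' manifest written through [write_timeseries()]. Idempotent for fixed seeds.
#'
#' @param out_dir Output directory (created if needed).
#' @return Named list of the specs used, invisibly.
#' @export
render_fixture_suite <- function(out_dir) {
  specs <- list(
    static = synthetic_movie_spec(amplitude = 0, beats = 2, noise_sd = 0,
                                  seed = 11L),
    subpixel_noisy = synthetic_movie_spec(amplitude = 3, beats = 3,
                                          noise_sd = 0.02, seed = 12L),
    drifting = synthetic_movie_spec(amplitude = 3, beats = 4, drift = 0.05,
                                    noise_sd = 0.01, seed = 13L),
    irregular = synthetic_movie_spec(amplitude = 3, beats = 5,
                                     amplitudes = c(1, 1, 0.5, 1, 1),
                                     noise_sd = 0.01, seed = 14L),
    low_contrast = synthetic_movie_spec(amplitude = 2, beats = 2,
                                        speckle_contrast = 0.06,
                                        noise_sd = 0.01, seed = 15L),
    type1_like = synthetic_movie_spec(amplitude = 3, beats = 3,
                                      noise_sd = 0.02, seed = 16L),
    type2_like = synthetic_movie_spec(amplitude = 2, beats = 3, cap_size = 20,
                                      tissue_width = 16, noise_sd = 0.02,
                                      seed = 17L)
  )
  for (name in names(specs)) {
    gen <- generate_movie(specs[[name]])
    folder <- file.path(out_dir, name)
    write_movie(gen$movie, folder)
    manifest <- dplyr::mutate(gen$truth$displacement,
                              amplitude_px = gen$truth$amplitude,
                              period_frames = gen$truth$period,
                              seed = specs[[name]]$seed)
    write_timeseries(manifest, file.path(folder, "ground_truth.txt"))
  }
  invisible(specs)
}
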