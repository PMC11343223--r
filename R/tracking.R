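#' Fiducial-marker detection and sparse optical-flow tracking
#'
#' Trackable fiducial points are detected inside each pillar mask on the
#' first frame by the Shi-Tomasi criterion (minimum eigenvalue of the local
#' image structure tensor) and followed through the movie with a pyramidal
#' Lucas-Kanade sparse optical-flow solver: each marker's inter-frame motion
#' is estimated by iterative local least squares on spatial and temporal
#' intensity gradients within a square window, refined coarse-to-fine over an
#' image pyramid so multi-pixel motion stays inside the linearisation range.
#'
#' @name tracking
NULL

#' Feature-detection parameters
#'
#' @param max_corners Maximum number of markers kept per mask.
#' @param quality_level Fraction of the maximal corner response below which
#'   candidates are rejected (in (0, 1)).
#' @param min_distance Minimum marker spacing in pixels (greedy non-maximum
#'   suppression radius).
#' @param block_size Side of the square neighbourhood over which the
#'   structure tensor is accumulated.
#' @return A `pt_feature_params` list.
#' @export
feature_params <- function(max_corners = 100L, quality_level = 0.1,
                           min_distance = 3, block_size = 5L) {
  if (quality_level <= 0 || quality_level >= 1) {
    abort("`quality_level` must be in (0, 1).")
  }
  if (min_distance < 1) abort("`min_distance` must be >= 1.")
  structure(list(max_corners = as.integer(max_corners),
                 quality_level = quality_level,
                 min_distance = min_distance,
                 block_size = as.integer(block_size)),
            class = "pt_feature_params")
}

#' Optical-flow parameters
#'
#' @param window_size Odd side length of the matching window in pixels.
#' @param pyramid_levels Number of pyramid levels (>= 1); capped so the
#'   coarsest level is at least 16 px in each dimension.
#' @param max_iterations Newton iterations per level.
#' @param epsilon Convergence tolerance on the update magnitude (pixels).
#' @return A `pt_flow_params` list.
#' @export
flow_params <- function(window_size = 15L, pyramid_levels = 3L,
                        max_iterations = 20L, epsilon = 0.01) {
  if (window_size < 3 || window_size %% 2 == 0) {
    abort("`window_size` must be odd and >= 3.")
  }
  if (pyramid_levels < 1) abort("`pyramid_levels` must be >= 1.")
  structure(list(window_size = as.integer(window_size),
                 pyramid_levels = as.integer(pyramid_levels),
                 max_iterations = as.integer(max_iterations),
                 epsilon = epsilon),
            class = "pt_flow_params")
}

# ---- low-level image helpers (replicate-padded, vectorised) ----

shift_mat <- function(m, dr, dc) {
  R <- nrow(m); C <- ncol(m)
  ri <- pmin(pmax(seq_len(R) + dr, 1L), R)
  ci <- pmin(pmax(seq_len(C) + dc, 1L), C)
  m[ri, ci, drop = FALSE]
}

# separable convolution with a symmetric odd kernel, replicated edges
conv_sep <- function(m, k) {
  h <- (length(k) - 1L) / 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(m, i - 1L - h, 0L)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(m2, 0L, i - 1L - h)
  out
}

gradient_rc <- function(m) {
  list(gr = (shift_mat(m, 1L, 0L) - shift_mat(m, -1L, 0L)) / 2,
       gc = (shift_mat(m, 0L, 1L) - shift_mat(m, 0L, -1L)) / 2)
}

# Gaussian-ish 5-tap antialiasing then 2x decimation
downsample2 <- function(m) {
  s <- conv_sep(m, c(1, 4, 6, 4, 1) / 16)
  s[seq(1, nrow(m), by = 2), seq(1, ncol(m), by = 2), drop = FALSE]
}

build_pyramid <- function(img, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- img
  for (l in seq_len(levels - 1)) pyr[[l + 1]] <- downsample2(pyr[[l]])
  pyr
}

cap_pyramid_levels <- function(levels, dim, min_size = 16L) {
  l <- 1L
  d <- dim
  while (l < levels && all(floor((d + 1) / 2) >= min_size)) {
    d <- floor((d + 1) / 2)
    l <- l + 1L
  }
  l
}

# bilinear sample of img at fractional (rr, cc), clamped to the valid domain
bilinear_at <- function(img, rr, cc) {
  R <- nrow(img); C <- ncol(img)
  rr <- pmin(pmax(rr, 1), R - 1e-9)
  cc <- pmin(pmax(cc, 1), C - 1e-9)
  r0 <- pmin(floor(rr), R - 1L); c0 <- pmin(floor(cc), C - 1L)
  fr <- rr - r0; fc <- cc - c0
  i00 <- (c0 - 1) * R + r0
  v00 <- img[i00];     v10 <- img[i00 + 1]
  v01 <- img[i00 + R]; v11 <- img[i00 + R + 1]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

normalize_frame <- function(frame, bit_depth) {
  matrix(as.numeric(frame), nrow(frame), ncol(frame)) / (2^bit_depth - 1)
}

#' Detect Shi-Tomasi features inside a pillar mask
#'
#' Corner response is the minimum eigenvalue of the structure tensor
#' accumulated over `block_size`; candidates below
#' `quality_level * max(response)` (maximum taken inside the mask) are
#' rejected, and survivors are thinned by greedy non-maximum suppression at
#' `min_distance`. All returned points lie on mask pixels.
#'
#' @param frame Grayscale matrix.
#' @param mask A `pt_mask` on the same grid.
#' @param params A [feature_params()] set.
#' @param bit_depth Bit depth used to normalise intensities (default guessed
#'   from the frame maximum).
#' @return A tibble with columns `marker`, `row`, `col`, `response`, `side`.
#' @export
detect_features <- function(frame, mask, params = feature_params(),
                            bit_depth = NULL) {
  if (sum(mask) == 0) abort("Mask is empty.")
  if (is.null(bit_depth)) bit_depth <- if (max(frame) > 255) 16L else 8L
  img <- normalize_frame(frame, bit_depth)
  g <- gradient_rc(img)
  box <- rep(1, params$block_size)
  s_rr <- conv_sep(g$gr * g$gr, box)
  s_cc <- conv_sep(g$gc * g$gc, box)
  s_rc <- conv_sep(g$gr * g$gc, box)
  tr <- s_rr + s_cc
  det_d <- sqrt(pmax((s_rr - s_cc)^2 + 4 * s_rc^2, 0))
  lambda_min <- (tr - det_d) / 2
  inside <- which(mask == 1, arr.ind = TRUE)
  resp <- lambda_min[inside]
  rmax <- max(resp)
  if (rmax <= 0) {
    abort("No trackable features: the pillar region has no intensity texture.",
          class = "pillartrack_tracking_error")
  }
  keep <- resp >= params$quality_level * rmax
  cand <- tibble(row = inside[keep, 1], col = inside[keep, 2],
                 response = resp[keep])
  cand <- dplyr::arrange(cand, dplyr::desc(.data$response))
  # greedy non-maximum suppression
  sel_r <- numeric(0); sel_c <- numeric(0); sel <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(sel) == 0 ||
        min((sel_r - cand$row[i])^2 + (sel_c - cand$col[i])^2) >=
          params$min_distance^2) {
      sel <- c(sel, i)
      sel_r <- c(sel_r, cand$row[i]); sel_c <- c(sel_c, cand$col[i])
      if (length(sel) >= params$max_corners) break
    }
  }
  out <- cand[sel, ]
  out$marker <- seq_len(nrow(out))
  out$side <- attr(mask, "side") %||% NA_character_
  dplyr::select(out, "marker", "row", "col", "response", "side")
}

# One pyramidal LK solve for all markers between two pyramids.
# pts: M x 2 matrix of (row, col) in the previous frame; returns list with
# M x 2 new positions and a logical `ok` flag per marker.
lk_step <- function(pyr_prev, pyr_next, pts, params) {
  M <- nrow(pts)
  levels <- length(pyr_prev)
  h <- (params$window_size - 1) / 2
  off <- expand.grid(dr = -h:h, dc = -h:h)
  n_win <- nrow(off)
  g <- matrix(0, M, 2)  # accumulated flow at current level scale
  ok <- rep(TRUE, M)
  for (L in levels:1) {
    scale <- 2^(L - 1)
    I <- pyr_prev[[L]]; J <- pyr_next[[L]]
    gI <- gradient_rc(I)
    # decimation keeps fine-grid pixels 1,3,5,... so coarse = (fine + 1) / 2,
    # i.e. fine / s + (1 - 1/s) after (L-1) applications
    p <- pts / scale + (1 - 1 / scale)
    rr <- rep(p[, 1], each = n_win) + rep(off$dr, M)
    cc <- rep(p[, 2], each = n_win) + rep(off$dc, M)
    Ip <- bilinear_at(I, rr, cc)
    Ir <- bilinear_at(gI$gr, rr, cc)
    Ic <- bilinear_at(gI$gc, rr, cc)
    dim(Ip) <- dim(Ir) <- dim(Ic) <- c(n_win, M)
    G11 <- colSums(Ir * Ir); G22 <- colSums(Ic * Ic); G12 <- colSums(Ir * Ic)
    detG <- G11 * G22 - G12^2
    solvable <- ok & detG > 1e-12
    v <- matrix(0, M, 2)
    active <- solvable
    for (it in seq_len(params$max_iterations)) {
      if (!any(active)) break
      ai <- which(active)
      sel <- rep((ai - 1) * n_win, each = n_win) + rep(seq_len(n_win), length(ai))
      rr2 <- rr[sel] + rep(g[ai, 1] + v[ai, 1], each = n_win)
      cc2 <- cc[sel] + rep(g[ai, 2] + v[ai, 2], each = n_win)
      Jp <- bilinear_at(J, rr2, cc2)
      dim(Jp) <- c(n_win, length(ai))
      dI <- Ip[, ai, drop = FALSE] - Jp
      b1 <- colSums(dI * Ir[, ai, drop = FALSE])
      b2 <- colSums(dI * Ic[, ai, drop = FALSE])
      d1 <- (G22[ai] * b1 - G12[ai] * b2) / detG[ai]
      d2 <- (G11[ai] * b2 - G12[ai] * b1) / detG[ai]
      v[ai, 1] <- v[ai, 1] + d1
      v[ai, 2] <- v[ai, 2] + d2
      active[ai] <- sqrt(d1^2 + d2^2) >= params$epsilon
    }
    flow <- g + v
    # a marker has diverged if its flow exceeds the window extent at this level
    diverged <- solvable & (abs(flow[, 1]) > params$window_size |
                              abs(flow[, 2]) > params$window_size)
    ok <- solvable & !diverged
    g <- if (L > 1) 2 * flow else flow
  }
  list(pts = pts + g, ok = ok & is.finite(g[, 1]) & is.finite(g[, 2]))
}

#' Track markers through a movie by pyramidal Lucas-Kanade optical flow
#'
#' Markers are carried frame to frame; a marker whose local system is
#' degenerate, whose flow diverges beyond the window extent, or whose
#' position leaves the image is dropped with a warning. Trajectories are
#' cumulative sub-pixel positions.
#'
#' @param movie A `pt_movie`.
#' @param markers Marker tibble from [detect_features()] (optionally from
#'   both pillars bound together; the `side` column is carried through).
#' @param params A [flow_params()] set.
#' @return A `pt_tracks` tibble with columns `marker`, `side`, `frame`,
#'   `row`, `col` (only frames where the marker is valid).
#' @export
track_markers <- function(movie, markers, params = flow_params()) {
  if (nrow(markers) == 0) {
    abort("No markers to track.", class = "pillartrack_tracking_error")
  }
  d <- dim(movie$frames)
  levels <- cap_pyramid_levels(params$pyramid_levels, d[1:2])
  nf <- d[3]
  pts <- cbind(markers$row, markers$col)
  M <- nrow(pts)
  alive <- rep(TRUE, M)
  coords <- array(NA_real_, dim = c(M, nf, 2))
  coords[, 1, ] <- pts
  pyr_prev <- build_pyramid(normalize_frame(movie$frames[, , 1],
                                            movie$bit_depth), levels)
  for (f in 2:nf) {
    pyr_next <- build_pyramid(normalize_frame(movie$frames[, , f],
                                              movie$bit_depth), levels)
    idx <- which(alive)
    st <- lk_step(pyr_prev, pyr_next, matrix(coords[idx, f - 1, ], ncol = 2),
                  params)
    inb <- st$pts[, 1] >= 1 & st$pts[, 1] <= d[1] &
      st$pts[, 2] >= 1 & st$pts[, 2] <= d[2]
    good <- st$ok & inb
    coords[idx[good], f, ] <- st$pts[good, , drop = FALSE]
    if (any(!good)) {
      warn(sprintf("Dropped %d marker(s) at frame %d (lost or out of bounds).",
                   sum(!good), f))
      alive[idx[!good]] <- FALSE
    }
    if (!any(alive)) {
      abort(sprintf("All markers lost by frame %d.", f),
            class = "pillartrack_tracking_error")
    }
    pyr_prev <- pyr_next
  }
  # long form: one row per (marker, frame), frames after loss dropped
  out <- tidyr::expand_grid(
    marker_i = seq_len(M), frame = seq_len(nf)
  )
  out$marker <- markers$marker[out$marker_i]
  out$side <- markers$side[out$marker_i]
  out$row <- coords[cbind(out$marker_i, out$frame, 1)]
  out$col <- coords[cbind(out$marker_i, out$frame, 2)]
  out <- dplyr::filter(out, is.finite(.data$row))
  out <- dplyr::select(out, "marker", "side", "frame", "row", "col")
  class(out) <- c("pt_tracks", class(out))
  attr(out, "n_frames") <- nf
  out
}

#' Automatically adjust detection and flow parameters to an input
#'
#' Deterministic schedule: start from the defaults; if fewer than
#' `min_features` Shi-Tomasi features are found, halve `quality_level`
#' repeatedly down to a floor of 0.005; scale the flow window up with the
#' mask bounding box for large pillars (reference box 40 px for the default
#' 15 px window, capped at 4x).
#'
#' @param frame Grayscale matrix (first frame).
#' @param mask A `pt_mask`.
#' @param min_features Target minimum marker count per pillar.
#' @param bit_depth Optional bit depth for intensity normalisation.
#' @return A list with elements `feature` ([feature_params()]) and `flow`
#'   ([flow_params()]).
#' @export
auto_adjust <- function(frame, mask, min_features = 10L, bit_depth = NULL) {
  fp <- feature_params()
  repeat {
    n <- tryCatch(
      nrow(detect_features(frame, mask, fp, bit_depth = bit_depth)),
      pillartrack_tracking_error = function(e) 0L
    )
    if (n >= min_features || fp$quality_level <= 0.005) break
    fp$quality_level <- max(fp$quality_level * 0.5, 0.005)
  }
  bb <- mask_bbox(mask)
  extent <- max(bb["rmax"] - bb["rmin"], bb["cmax"] - bb["cmin"]) + 1
  fl <- flow_params()
  scale <- min(max(extent / 40, 1), 4)
  w <- round(fl$window_size * scale)
  fl$window_size <- as.integer(w + (w + 1) %% 2)  # keep odd
  list(feature = fp, flow = fl)
}
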