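#' Pillar mechanics: from deflection to force and stress
#'
#' The pillars are elastomeric cantilevers: the tissue pulls each pillar tip
#' toward the centre, and the twitch force follows Hooke's law `F = k * delta`
#' where `delta` is the mean tracked pillar deflection (in micrometres) and
#' `k` the pillar stiffness in uN/um. When `k` has not been measured it is
#' derived from cantilever beam theory,
#' `k = 6 E I / (a^2 (3 L - a))`,
#' with `E` the elastic modulus, `I` the cross-section's second moment of
#' area (`w t^3 / 12` rectangular, `pi D^4 / 64` circular), `L` the cantilever
#' length and `a` the height at which the tissue applies its load.
#'
#' @name mechanics
NULL

#' Cantilever pillar geometry
#'
#' @param E Elastic modulus, by default in kPa (see `E_unit`).
#' @param L Cantilever length (um).
#' @param a Location of force application along the cantilever (um),
#'   `0 < a <= L`.
#' @param width,thickness Rectangular cross-section dimensions (um); supply
#'   these *or* `diameter`.
#' @param diameter Circular cross-section diameter (um).
#' @param E_unit `"kPa"` (default) or `"uN_um2"` for values already in
#'   consistent micro-units (1 kPa = 1e-3 uN/um^2).
#' @return A `pt_pillar_geometry` list.
#' @export
pillar_geometry <- function(E, L, a, width = NULL, thickness = NULL,
                            diameter = NULL, E_unit = c("kPa", "uN_um2")) {
  E_unit <- match.arg(E_unit)
  has_rect <- !is.null(width) && !is.null(thickness)
  has_circ <- !is.null(diameter)
  if (has_rect == has_circ) {
    abort("Supply either `width` and `thickness`, or `diameter`.")
  }
  dims <- c(E = E, L = L, a = a,
            if (has_rect) c(width = width, thickness = thickness)
            else c(diameter = diameter))
  if (any(dims <= 0)) {
    abort(sprintf("All geometry values must be positive; got %s = %g.",
                  names(dims)[dims <= 0][1], dims[dims <= 0][1]))
  }
  if (a > L) abort("Force application point `a` cannot exceed the length `L`.")
  structure(list(E = E, L = L, a = a, width = width, thickness = thickness,
                 diameter = diameter,
                 cross_section = if (has_rect) "rectangular" else "circular",
                 E_unit = E_unit),
            class = "pt_pillar_geometry")
}

#' Second moment of area of the pillar cross section
#'
#' `I = w t^3 / 12` for rectangular beams, `I = pi D^4 / 64` for circular.
#'
#' @param geom A [pillar_geometry()].
#' @return Moment of inertia in um^4.
#' @export
moment_of_inertia <- function(geom) {
  if (geom$cross_section == "rectangular") {
    geom$width * geom$thickness^3 / 12
  } else {
    pi * geom$diameter^4 / 64
  }
}

#' Pillar stiffness from cantilever beam theory
#'
#' `k = 6 E I / (a^2 (3 L - a))`; at `a = L` this reduces to the classical
#' tip-load stiffness `3 E I / L^3`.
#'
#' @param geom A [pillar_geometry()].
#' @return A `pt_stiffness` list with `k` (uN/um) and `source = "derived"`.
#' @export
pillar_stiffness <- function(geom) {
  E <- geom$E * if (geom$E_unit == "kPa") 1e-3 else 1  # -> uN/um^2
  I <- moment_of_inertia(geom)
  k <- 6 * E * I / (geom$a^2 * (3 * geom$L - geom$a))
  structure(list(k = k, source = "derived"), class = "pt_stiffness")
}

#' Declare an experimentally measured pillar stiffness
#'
#' @param k Stiffness in uN/um (e.g. 2.677 uN/um for the standard Type-1
#'   strain-gauge devices).
#' @return A `pt_stiffness` with `source = "measured"`.
#' @export
measured_stiffness <- function(k) {
  if (k <= 0) abort("Stiffness must be positive.")
  structure(list(k = k, source = "measured"), class = "pt_stiffness")
}

#' Tissue cross-section geometry
#'
#' @param width Tissue width in um (typically auto-measured on the first
#'   valley frame, see [measure_tissue_width()]).
#' @param depth Tissue depth in um (user input, from 3-D imaging).
#' @return A `pt_tissue_geometry` with `area = width * depth` (um^2).
#' @export
tissue_geometry <- function(width, depth) {
  if (width <= 0 || depth <= 0) abort("Tissue width and depth must be positive.")
  structure(list(width = width, depth = depth, area = width * depth),
            class = "pt_tissue_geometry")
}

#' Twitch force from pillar displacement
#'
#' Applies Hooke's law per frame. The package's deflection convention is the
#' mean of the two pillars' deflections from rest; the alternative
#' "inter-pillar distance" convention (deflection = change in pillar
#' separation = sum of the two deflections for a symmetric contraction)
#' reports forces exactly twice as high and is provided for comparison only.
#'
#' @param series A `pt_displacement` with both sides.
#' @param k A `pt_stiffness` (or bare numeric, uN/um).
#' @param length_scale um per pixel; defaults to the series attribute.
#' @param convention `"pillar_mean"` (default) or `"pillar_distance"`.
#' @return A tibble with per-frame `delta_left_um`, `delta_right_um`,
#'   `delta_um` (convention deflection), `force_left_un`, `force_right_un`,
#'   `force_un`.
#' @export
twitch_force <- function(series, k, length_scale = NULL,
                         convention = c("pillar_mean", "pillar_distance")) {
  convention <- match.arg(convention)
  if (inherits(k, "pt_stiffness")) k <- k$k
  if (k <= 0) abort("Stiffness must be positive.")
  length_scale <- length_scale %||% attr(series, "length_scale")
  if (is.null(length_scale)) abort("`length_scale` is required (um/px).")
  wide <- series |>
    dplyr::select("frame", "side", "abs_px") |>
    tidyr::pivot_wider(names_from = "side", values_from = "abs_px") |>
    dplyr::arrange(.data$frame)
  out <- tibble(
    frame = wide$frame,
    delta_left_um = wide$left * length_scale,
    delta_right_um = wide$right * length_scale
  )
  out$delta_um <- if (convention == "pillar_mean") {
    (out$delta_left_um + out$delta_right_um) / 2
  } else {
    sep <- attr(series, "separation_px")
    if (is.null(sep)) {
      # without marker geometry the distance change is the sum of the two
      # per-pillar deflections (pillars move toward each other)
      out$delta_left_um + out$delta_right_um
    } else {
      abs(sep[1] - sep) * length_scale
    }
  }
  fps <- attr(series, "fps")
  if (!is.null(fps)) out$time_s <- (out$frame - 1) / fps
  out$force_left_un <- k * out$delta_left_um
  out$force_right_un <- k * out$delta_right_um
  out$force_un <- k * out$delta_um
  attr(out, "k") <- k
  attr(out, "convention") <- convention
  out
}

#' Tissue stress from force and cross-sectional area
#'
#' `sigma(t) = F(t) / (width * depth)` in uN/um^2, reported in kPa
#' (1 uN/um^2 = 1 MPa = 1000 kPa).
#'
#' @param force Force tibble from [twitch_force()].
#' @param tg A [tissue_geometry()].
#' @return The force tibble with an added `stress_kpa` column.
#' @export
tissue_stress <- function(force, tg) {
  if (tg$area <= 0) abort("Tissue cross-sectional area must be positive.")
  force$stress_kpa <- force$force_un / tg$area * 1000
  attr(force, "tissue_area_um2") <- tg$area
  force
}

#' Measure the tissue width on the first valley frame
#'
#' Takes a narrow vertical strip at the midline between the two pillars'
#' inner edges, thresholds it (Otsu on the strip, scale-invariant), and
#' measures the longest contiguous run of tissue rows.
#'
#' @param frame Grayscale matrix of the first valley frame.
#' @param masks A `pt_mask_pair`.
#' @param length_scale um per pixel.
#' @param strip_halfwidth Half-width of the midline strip in columns.
#' @return Width in um, with attribute `width_px`.
#' @export
measure_tissue_width <- function(frame, masks, length_scale = 1,
                                 strip_halfwidth = 2L) {
  inner_left <- mask_bbox(masks$left)["cmax"]
  inner_right <- mask_bbox(masks$right)["cmin"]
  if (inner_right - inner_left < 5) {
    abort("No inter-pillar gap to measure the tissue in.")
  }
  mid <- round((inner_left + inner_right) / 2)
  cols <- max(1, mid - strip_halfwidth):min(ncol(frame), mid + strip_halfwidth)
  strip <- matrix(as.numeric(frame[, cols]), nrow(frame))
  if (diff(range(strip)) <= 0) {
    abort("No detectable tissue band between the pillars; supply the width manually.",
          class = "pillartrack_width_error")
  }
  thr <- otsu_threshold(as.vector(strip))
  profile <- rowMeans(strip > thr) > 0.5
  runs <- rle(profile)
  if (!any(runs$values)) {
    abort("No detectable tissue band between the pillars; supply the width manually.",
          class = "pillartrack_width_error")
  }
  width_px <- max(runs$lengths[runs$values])
  structure(width_px * length_scale, width_px = width_px)
}
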