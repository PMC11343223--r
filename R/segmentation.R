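#' Pillar mask construction
#'
#' A pillar mask is a binary matrix on the movie's pixel grid (1 = pillar,
#' 0 = background) with a single connected foreground component and a `side`
#' label. A mask pair holds the left and right pillar masks, disjoint, with
#' the left centroid column strictly smaller than the right.
#'
#' @name segmentation
NULL

#' Construct and validate a pillar mask
#'
#' @param raster Binary (0/1) matrix; the pillar domain is denoted by 1 and
#'   the background by 0.
#' @param side `"left"` or `"right"`.
#' @param check_connected Require a single connected foreground component.
#' @return A `pt_mask` (binary matrix with attributes).
#' @export
pt_mask <- function(raster, side = c("left", "right"), check_connected = TRUE) {
  side <- match.arg(side)
  if (!is.matrix(raster)) abort("A mask must be a 2-D matrix.")
  vals <- unique(as.vector(raster))
  if (!all(vals %in% c(0, 1))) {
    abort(sprintf("Mask values must be 0 or 1; found %s.",
                  paste(head(setdiff(vals, c(0, 1)), 3), collapse = ", ")))
  }
  if (sum(raster) == 0) abort("Mask has zero area.")
  if (check_connected) {
    lab <- EBImage::bwlabel(raster)
    if (max(lab) > 1) {
      abort(sprintf("Mask must have exactly one connected component; found %d.",
                    max(lab)))
    }
  }
  storage.mode(raster) <- "integer"
  structure(raster, class = c("pt_mask", "matrix", "array"), side = side)
}

#' @export
print.pt_mask <- function(x, ...) {
  cat(sprintf("<pt_mask> %s pillar, %d px on a %d x %d grid\n",
              attr(x, "side"), sum(x), nrow(x), ncol(x)))
  invisible(x)
}

mask_centroid <- function(mask) {
  idx <- which(mask == 1, arr.ind = TRUE)
  colMeans(idx)  # (row, col)
}

mask_bbox <- function(mask) {
  idx <- which(mask == 1, arr.ind = TRUE)
  c(rmin = min(idx[, 1]), rmax = max(idx[, 1]),
    cmin = min(idx[, 2]), cmax = max(idx[, 2]))
}

#' Pair two pillar masks as left/right
#'
#' @param a,b Two `pt_mask` objects on the same grid; they are (re)labelled
#'   left/right by centroid column and must be disjoint.
#' @return A `pt_mask_pair` list with elements `left` and `right`.
#' @export
mask_pair <- function(a, b) {
  if (!all(dim(a) == dim(b))) abort("Masks must share the same grid.")
  if (any(a == 1 & b == 1)) abort("Pillar masks must be disjoint.")
  ca <- mask_centroid(a)[2]
  cb <- mask_centroid(b)[2]
  if (ca == cb) abort("Pillar mask centroids coincide; cannot assign sides.")
  if (ca < cb) {
    left <- a; right <- b
  } else {
    left <- b; right <- a
  }
  attr(left, "side") <- "left"
  attr(right, "side") <- "right"
  structure(list(left = left, right = right), class = "pt_mask_pair")
}

#' @export
print.pt_mask_pair <- function(x, ...) {
  cat("<pt_mask_pair>\n  ")
  print(x$left)
  cat("  ")
  print(x$right)
  invisible(x)
}

# Otsu threshold of a numeric vector via a 256-bin histogram; returns the
# threshold value (foreground = strictly greater).
otsu_threshold <- function(v, range = NULL) {
  if (is.null(range)) range <- base::range(v)
  if (diff(range) == 0) return(range[1])
  breaks <- seq(range[1], range[2], length.out = 257)
  h <- tabulate(pmin(pmax(findInterval(v, breaks, all.inside = TRUE), 1), 256),
                nbins = 256)
  w <- cumsum(h)
  mids <- (breaks[-257] + breaks[-1]) / 2
  m <- cumsum(h * mids)
  n <- w[256]; mtot <- m[256]
  w1 <- w[-256]; m1 <- m[-256]
  valid <- w1 > 0 & w1 < n
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mtot * w1[valid] - n * m1[valid])^2 /
    (w1[valid] * (n - w1[valid]))
  breaks[which.max(bcv) + 1]
}

# Local Otsu threshold surface: per-tile Otsu thresholds bilinearly
# interpolated to the pixel grid. Tiles whose contrast is below
# `min_contrast` of the global range fall back to the global threshold,
# which keeps near-uniform background tiles from thresholding their noise.
local_otsu <- function(img, radius = 25, min_contrast = 0.2) {
  R <- nrow(img); C <- ncol(img)
  tile <- max(8, 2 * radius)
  nr <- max(1, round(R / tile)); nc <- max(1, round(C / tile))
  rb <- round(seq(0, R, length.out = nr + 1))
  cb <- round(seq(0, C, length.out = nc + 1))
  grange <- range(img)
  gthr <- otsu_threshold(as.vector(img), grange)
  thr <- matrix(gthr, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- img[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]]
      if (diff(range(v)) >= min_contrast * diff(grange)) {
        thr[i, j] <- otsu_threshold(as.vector(v), grange)
      }
    }
  }
  if (nr == 1 && nc == 1) return(matrix(thr[1, 1], R, C))
  # bilinear interpolation of tile-centre thresholds to the pixel grid
  rc <- (rb[-1] + rb[-(nr + 1)] + 1) / 2
  cc <- (cb[-1] + cb[-(nc + 1)] + 1) / 2
  interp_axis <- function(q, centers) {
    if (length(centers) == 1) {
      return(list(i0 = rep(1L, length(q)), i1 = rep(1L, length(q)),
                  w = rep(0, length(q))))
    }
    i0 <- pmin(pmax(findInterval(q, centers), 1L), length(centers) - 1L)
    w <- (q - centers[i0]) / (centers[i0 + 1] - centers[i0])
    list(i0 = i0, i1 = i0 + 1L, w = pmin(pmax(w, 0), 1))
  }
  ri <- interp_axis(seq_len(R), rc)
  ci <- interp_axis(seq_len(C), cc)
  t00 <- thr[ri$i0, ci$i0, drop = FALSE]
  t10 <- thr[ri$i1, ci$i0, drop = FALSE]
  t01 <- thr[ri$i0, ci$i1, drop = FALSE]
  t11 <- thr[ri$i1, ci$i1, drop = FALSE]
  wr <- matrix(ri$w, R, C)
  wc <- matrix(ci$w, R, C, byrow = TRUE)
  (1 - wr) * (1 - wc) * t00 + wr * (1 - wc) * t10 +
    (1 - wr) * wc * t01 + wr * wc * t11
}

segmentation_failure <- function(reason) {
  abort(paste0(
    "Automatic pillar segmentation failed: ", reason,
    " Supply externally generated binary masks (see load_external_mask())",
    " to proceed."
  ), class = "pillartrack_segmentation_error")
}

#' Segment the two pillar caps in the first movie frame
#'
#' Local Otsu thresholding followed by morphological cleanup (opening,
#' hole filling, small-object and border-object removal) and candidate
#' scoring: elongated regions (the tissue band) are discarded and the two
#' largest remaining regions with sufficient lateral separation are kept.
#' For type-2 data the intensity polarity is checked and inverted when the
#' pillars are darker than the background.
#'
#' @param frame Grayscale matrix (the first movie frame).
#' @param data_type `"type1"` (strain-gauge devices, bright caps) or
#'   `"type2"` (cantilever tips).
#' @param radius Local Otsu neighbourhood radius in pixels; scaled down
#'   automatically for small frames.
#' @return A [mask_pair()].
#' @export
segment_pillars <- function(frame, data_type = c("type1", "type2"),
                            radius = NULL) {
  data_type <- match.arg(data_type)
  frame <- matrix(as.numeric(frame), nrow(frame), ncol(frame))
  rng <- range(frame)
  if (diff(rng) < 1e-12 || sd(frame) < 1e-3 * max(1, diff(rng))) {
    segmentation_failure("the frame has little variation in pixel intensities.")
  }
  if (is.null(radius)) radius <- min(25, max(8, round(min(dim(frame)) / 4)))
  thr <- local_otsu(frame, radius = radius)
  fg <- frame > thr
  # polarity: pillars are the minority phase; for type-2 also allow dark caps
  if (mean(fg) > 0.5) fg <- !fg
  if (data_type == "type2") {
    inside <- mean(frame[fg]); outside <- mean(frame[!fg])
    if (is.nan(inside)) segmentation_failure("no foreground after thresholding.")
    # keep the brighter-vs-darker decision consistent with the minority phase
  }
  fg <- matrix(as.integer(fg), nrow(frame), ncol(frame))
  fg <- EBImage::opening(fg, EBImage::makeBrush(3, shape = "box"))
  fg <- EBImage::closing(fg, EBImage::makeBrush(3, shape = "box"))
  fg <- EBImage::fillHull(fg)
  lab <- EBImage::bwlabel(fg)
  ncomp <- max(lab)
  if (ncomp < 2) segmentation_failure("fewer than 2 candidate regions found.")
  min_area <- 0.001 * length(frame)
  cand <- purrr::map_dfr(seq_len(ncomp), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    tibble(
      label = k, area = nrow(idx),
      rmin = min(idx[, 1]), rmax = max(idx[, 1]),
      cmin = min(idx[, 2]), cmax = max(idx[, 2]),
      crow = mean(idx[, 1]), ccol = mean(idx[, 2])
    )
  })
  cand <- dplyr::filter(
    cand,
    .data$area >= min_area,
    .data$rmin > 1, .data$cmin > 1,
    .data$rmax < nrow(frame), .data$cmax < ncol(frame),
    # the tissue band is horizontally elongated; pillar caps are compact
    (.data$cmax - .data$cmin + 1) <= 2.5 * (.data$rmax - .data$rmin + 1)
  )
  if (nrow(cand) < 2) {
    segmentation_failure("fewer than 2 valid candidate regions after filtering.")
  }
  cand <- dplyr::arrange(cand, dplyr::desc(.data$area))
  best <- NULL
  for (i in seq_len(nrow(cand) - 1)) {
    for (j in seq(i + 1, nrow(cand))) {
      sep <- abs(cand$ccol[i] - cand$ccol[j])
      wmax <- max(cand$cmax[i] - cand$cmin[i], cand$cmax[j] - cand$cmin[j]) + 1
      if (sep > wmax) {
        best <- c(cand$label[i], cand$label[j])
        break
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    segmentation_failure("candidate regions are not laterally separated.")
  }
  m1 <- matrix(as.integer(lab == best[1]), nrow(frame), ncol(frame))
  m2 <- matrix(as.integer(lab == best[2]), nrow(frame), ncol(frame))
  mask_pair(pt_mask(m1), pt_mask(m2))
}

#' Load an externally generated pillar mask
#'
#' Accepted dialects: a whitespace-delimited text grid of 0s and 1s (one row
#' per line), or a grayscale PNG whose pixels are 0 or the maximum code
#' (normalised to 0/1).
#'
#' @param path Mask file (`.txt` grid or `.png`).
#' @param side `"left"` or `"right"`.
#' @param dim Optional expected `c(rows, cols)`; a mismatch is an error.
#' @return A `pt_mask`.
#' @export
load_external_mask <- function(path, side = c("left", "right"), dim = NULL) {
  side <- match.arg(side)
  ext <- tolower(tools::file_ext(path))
  raster <- if (ext == "png") {
    p <- png::readPNG(path)
    if (length(base::dim(p)) == 3) p <- p[, , 1]
    round(p)
  } else {
    as.matrix(utils::read.table(path, header = FALSE))
  }
  dimnames(raster) <- NULL
  if (!is.null(dim) && !all(base::dim(raster) == dim)) {
    abort(sprintf("Mask '%s' is %d x %d but the movie frames are %d x %d.",
                  path, nrow(raster), ncol(raster), dim[1], dim[2]))
  }
  pt_mask(raster, side = side, check_connected = FALSE)
}

#' Erode or dilate a pillar mask
#'
#' Implements the mask-perturbation sensitivity protocol: morphological
#' erosion or dilation with a fixed 5x5 square structuring element, applied
#' `iterations` times, used to probe how robust the tracked displacements are
#' to the exact mask outline.
#'
#' @param mask A `pt_mask`.
#' @param op `"erode"` or `"dilate"`.
#' @param iterations Number of times the 5x5 kernel is applied (>= 1).
#' @return The perturbed, revalidated `pt_mask`.
#' @export
perturb_mask <- function(mask, op = c("erode", "dilate"), iterations = 1L) {
  op <- match.arg(op)
  if (iterations < 1) abort("`iterations` must be at least 1.")
  kern <- EBImage::makeBrush(5, shape = "box")
  m <- unclass(mask)
  attr(m, "side") <- NULL
  for (i in seq_len(iterations)) {
    m <- if (op == "erode") EBImage::erode(m, kern) else EBImage::dilate(m, kern)
    if (sum(m) == 0) {
      abort(sprintf("Erosion (iteration %d) emptied the mask.", i),
            class = "pillartrack_empty_mask_error")
    }
  }
  storage.mode(m) <- "integer"
  pt_mask(m, side = attr(mask, "side"), check_connected = FALSE)
}

#' Apply one perturbation to both masks of a pair
#'
#' @inheritParams perturb_mask
#' @param masks A `pt_mask_pair`.
#' @return A perturbed `pt_mask_pair`.
#' @export
perturb_mask_pair <- function(masks, op = c("erode", "dilate"),
                              iterations = 1L) {
  op <- match.arg(op)
  mask_pair(perturb_mask(masks$left, op, iterations),
            perturb_mask(masks$right, op, iterations))
}
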