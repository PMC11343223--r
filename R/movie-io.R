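#' Movie containers and frame-folder input/output
#'
#' A movie is stored as a `pt_movie` object: an integer array of dimension
#' `R x C x F` (rows, columns, frames) together with its bit depth and,
#' optionally, the acquisition metadata (frame rate in Hz, length scale in
#' micrometres per pixel).
#'
#' @name movie-io
NULL

#' Construct a movie object from a frame array
#'
#' @param frames Integer array `R x C x F` (or a list of `R x C` matrices) of
#'   pixel intensities.
#' @param bit_depth Either 8 or 16; intensities must fit the declared depth.
#' @param fps Frame rate in frames per second (optional until analysis).
#' @param length_scale Micrometres per pixel (optional until analysis).
#' @param source Optional provenance string (e.g. the folder the movie was
#'   read from).
#'
#' @return A `pt_movie` object.
#' @export
pt_movie <- function(frames, bit_depth = 8L, fps = NULL, length_scale = NULL,
                     source = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) {
      abort("All frames must share identical dimensions.")
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) != 3) {
    abort("`frames` must be an R x C x F array or a list of matrices.")
  }
  if (dim(frames)[3] < 2) {
    abort("A movie needs at least 2 frames.")
  }
  if (!bit_depth %in% c(8L, 16L)) {
    abort("`bit_depth` must be 8 or 16.")
  }
  maxval <- 2^bit_depth - 1
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > maxval) {
    abort(sprintf("Intensities [%s, %s] do not fit a %d-bit representation.",
                  format(rng[1]), format(rng[2]), bit_depth))
  }
  if (!is.null(fps) && fps <= 0) abort("`fps` must be positive.")
  if (!is.null(length_scale) && length_scale <= 0) {
    abort("`length_scale` must be positive.")
  }
  structure(
    list(frames = frames, bit_depth = as.integer(bit_depth),
         fps = fps, length_scale = length_scale, source = source),
    class = "pt_movie"
  )
}

#' @export
print.pt_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<pt_movie> %d frames of %d x %d px, %d-bit", d[3], d[1], d[2],
              x$bit_depth))
  if (!is.null(x$fps)) cat(sprintf(", %g fps", x$fps))
  if (!is.null(x$length_scale)) cat(sprintf(", %g um/px", x$length_scale))
  cat("\n")
  invisible(x)
}

#' Number of frames in a movie
#' @param movie A `pt_movie`.
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames)[3]

#' Extract one frame as a matrix
#' @param movie A `pt_movie`.
#' @param i Frame index (1-based).
#' @return Integer matrix `R x C`.
#' @export
get_frame <- function(movie, i) movie$frames[, , i]

# natural sort: numeric runs compared as numbers so frame_2 < frame_10
natural_order <- function(x) {
  pad <- gsub("(\\d+)", "~\\1~", x)
  parts <- strsplit(pad, "~", fixed = TRUE)
  width <- max(nchar(unlist(regmatches(x, gregexpr("\\d+", x)))), 0)
  keys <- vapply(parts, function(p) {
    num <- grepl("^\\d+$", p)
    p[num] <- formatC(p[num], width = width + 1, flag = "0")
    paste(p, collapse = "")
  }, character(1))
  order(keys, x)
}

read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
      png = {
        p <- png::readPNG(path)
        # readPNG rescales to [0,1]; recover the integer code assuming the
        # container depth (16-bit PNGs come back with > 8 bits of precision)
        depth <- if (any(abs(p * 255 - round(p * 255)) > 1e-6)) 16L else 8L
        round(p * (2^depth - 1))
      },
      abort(sprintf("Unsupported frame format '%s' for '%s'.", ext, path))
    ),
    error = function(e) {
      abort(sprintf("Failed to read frame '%s': %s", path, conditionMessage(e)))
    }
  )
  if (length(dim(img)) == 3) {
    # RGB(A): standard luminance conversion; brightfield data is nominally gray
    warn(sprintf("Frame '%s' is multi-channel; converting by luminance.",
                 basename(path)))
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  storage.mode(img) <- "integer"
  img
}

#' Load a movie from a folder of single-frame images
#'
#' Frames are read in natural (numeric-aware) filename order, so `frame_2`
#' sorts before `frame_10` whether or not the numbers are zero-padded.
#' Supported formats are single-page TIFF and PNG; RGB frames are converted
#' to grayscale by luminance with a warning.
#'
#' @param folder_path Folder containing at least two frame files.
#' @param fps,length_scale Optional acquisition metadata attached to the
#'   returned movie.
#'
#' @return A [pt_movie()] object with bit depth detected from the files.
#' @export
load_movie <- function(folder_path, fps = NULL, length_scale = NULL) {
  if (!dir.exists(folder_path)) {
    abort(sprintf("Movie folder '%s' does not exist.", folder_path))
  }
  files <- list.files(folder_path, pattern = "\\.(tif|tiff|png)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) < 2) {
    abort(sprintf("Movie folder '%s' contains %d readable frames; at least 2 are required.",
                  folder_path, length(files)))
  }
  files <- files[natural_order(basename(files))]
  frames <- lapply(files, read_frame_file)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    abort(sprintf("Frame '%s' has dimensions %d x %d but '%s' has %d x %d.",
                  basename(files[bad]), dims[1, bad], dims[2, bad],
                  basename(files[1]), dims[1, 1], dims[2, 1]))
  }
  maxval <- max(vapply(frames, max, numeric(1)))
  bit_depth <- if (maxval > 255) 16L else 8L
  pt_movie(frames, bit_depth = bit_depth, fps = fps,
           length_scale = length_scale, source = folder_path)
}

#' Write a movie to a folder of single-frame images
#'
#' The on-disk layout mirrors what [load_movie()] expects: one losslessly
#' compressed file per frame, numbered with zero padding.
#'
#' @param movie A `pt_movie`.
#' @param folder_path Output folder (created if missing).
#' @param format `"tiff"` or `"png"`.
#' @return `folder_path`, invisibly.
#' @export
write_movie <- function(movie, folder_path, format = c("tiff", "png")) {
  format <- match.arg(format)
  dir.create(folder_path, recursive = TRUE, showWarnings = FALSE)
  maxval <- 2^movie$bit_depth - 1
  nf <- n_frames(movie)
  width <- nchar(as.character(nf))
  for (i in seq_len(nf)) {
    fr <- movie$frames[, , i] / maxval
    name <- sprintf("frame_%0*d.%s", width, i,
                    if (format == "tiff") "tif" else "png")
    path <- file.path(folder_path, name)
    if (format == "tiff") {
      tiff::writeTIFF(fr, path, bits.per.sample = movie$bit_depth)
    } else {
      png::writePNG(fr, path)
    }
  }
  invisible(folder_path)
}

#' Write a table as a tab-delimited text file
#'
#' All tabular outputs of the pipeline are plain text: a single header line
#' (column names carry the units) followed by one row per record, at full
#' double precision so that a write/read round trip is lossless.
#'
#' @param table A data frame; all columns must have equal length by
#'   construction.
#' @param out_path Output file path.
#' @return `out_path`, invisibly.
#' @export
write_timeseries <- function(table, out_path) {
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    readr::write_tsv(as_tibble(table), out_path, progress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(sprintf("Cannot write table to '%s': %s", out_path,
                  conditionMessage(ok)))
  }
  invisible(out_path)
}

#' Read a table written by [write_timeseries()]
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_timeseries <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
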