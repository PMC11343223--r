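#' Run configuration
#'
#' The five-parameter user contract: data type, frame rate, length scale,
#' pillar stiffness (or geometry to derive it) and tissue depth. Everything
#' else is optional.
#'
#' @param data_type `"type1"` or `"type2"`.
#' @param fps Frame rate (Hz).
#' @param length_scale Micrometres per pixel.
#' @param stiffness Pillar stiffness in uN/um (exclusive with `geometry`).
#' @param geometry A [pillar_geometry()] (exclusive with `stiffness`).
#' @param tissue_depth Tissue depth in um.
#' @param split Compute per-beat outputs re-baselined at each valley
#'   (requires >= 3 complete beats; default `FALSE`).
#' @param mask_left,mask_right Optional external mask file paths.
#' @param output_dir Output folder (default `"<movie>_results"`).
#' @param drift_tol_px Drift tolerance at valleys (px).
#' @return A `pt_run_config` list.
#' @export
run_config <- function(data_type = c("type1", "type2"), fps, length_scale,
                       stiffness = NULL, geometry = NULL, tissue_depth,
                       split = FALSE, mask_left = NULL, mask_right = NULL,
                       output_dir = NULL, drift_tol_px = 0.5) {
  data_type <- match.arg(data_type)
  if (is.null(stiffness) == is.null(geometry)) {
    abort("Supply exactly one of `stiffness` or `geometry`.")
  }
  nums <- c(fps = fps, length_scale = length_scale,
            tissue_depth = tissue_depth,
            if (!is.null(stiffness)) c(stiffness = stiffness))
  if (any(nums <= 0)) {
    abort(sprintf("`%s` must be positive.", names(nums)[nums <= 0][1]))
  }
  k <- if (!is.null(stiffness)) measured_stiffness(stiffness)
       else pillar_stiffness(geometry)
  structure(list(data_type = data_type, fps = fps,
                 length_scale = length_scale, k = k,
                 tissue_depth = tissue_depth, split = isTRUE(split),
                 mask_left = mask_left, mask_right = mask_right,
                 output_dir = output_dir, drift_tol_px = drift_tol_px),
            class = "pt_run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys: `data_type`, `fps`, `length_scale`, `stiffness` *or* a
#' `geometry` block (`E`, `L`, `a`, plus `width`/`thickness` or `diameter`,
#' optional `E_unit`), `tissue_depth`, `split`, `mask_left`, `mask_right`,
#' `output_dir`, `drift_tol_px`.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  geom <- if (!is.null(y$geometry)) do.call(pillar_geometry, y$geometry)
  run_config(
    data_type = y$data_type %||% "type1",
    fps = y$fps, length_scale = y$length_scale,
    stiffness = y$stiffness, geometry = geom,
    tissue_depth = y$tissue_depth,
    split = y$split %||% FALSE,
    mask_left = y$mask_left, mask_right = y$mask_right,
    output_dir = y$output_dir,
    drift_tol_px = y$drift_tol_px %||% 0.5
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", name, conditionMessage(e)),
          class = "pillartrack_pipeline_error", parent = e)
  })
}

#' Analyse one movie in memory
#'
#' The full pipeline without file output: segmentation (or external masks),
#' automatic parameter adjustment, feature detection and tracking per pillar,
#' valley detection with re-anchoring to the first valley (plus a second
#' tracking pass when needed), displacement reduction, drift and
#' irregular-beat checks, optional per-beat splitting, mechanics and metrics.
#'
#' @param movie A `pt_movie` (metadata taken from `config`).
#' @param config A [run_config()].
#' @param masks Optional `pt_mask_pair` overriding segmentation.
#' @return A `pt_analysis` list: `series`, `segments`, `drift`, `irregular`,
#'   `force` (with stress), `report`, `per_beat` (when split), `masks`,
#'   `tissue_width_um`, `warnings` (character log).
#' @export
analyze_movie <- function(movie, config, masks = NULL) {
  log <- character(0)
  note <- function(msg) log <<- c(log, msg)
  first <- get_frame(movie, 1)
  if (is.null(masks)) {
    masks <- if (!is.null(config$mask_left)) {
      stage("segmentation", mask_pair(
        load_external_mask(config$mask_left, "left", dim = dim(first)),
        load_external_mask(config$mask_right, "right", dim = dim(first))
      ))
    } else {
      stage("segmentation", segment_pillars(first, config$data_type))
    }
  }
  track_pair <- function(mov) {
    fr <- get_frame(mov, 1)
    tracks <- purrr::map(masks, function(m) {
      p <- auto_adjust(fr, m, bit_depth = mov$bit_depth)
      mk <- detect_features(fr, m, p$feature, bit_depth = mov$bit_depth)
      tr <- withCallingHandlers(
        track_markers(mov, mk, p$flow),
        warning = function(w) {
          note(conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
      surv <- tr |>
        dplyr::summarise(n = dplyr::n(), .by = "marker") |>
        dplyr::filter(.data$n == n_frames(mov))
      if (nrow(surv) < 5) {
        abort(sprintf("Only %d marker(s) survive on the %s pillar (>= 5 required).",
                      nrow(surv), attr(m, "side")),
              class = "pillartrack_tracking_error")
      }
      tr
    })
    out <- dplyr::bind_rows(tracks)
    attr(out, "n_frames") <- n_frames(mov)
    out
  }
  tracks <- stage("tracking", track_pair(movie))
  series <- stage("displacement",
                  mean_displacement(tracks, fps = config$fps,
                                    length_scale = config$length_scale))
  segments <- stage("beat segmentation", find_valleys(series, config$fps))
  adj <- adjust_start(movie, segments)
  if (adj$retrack_needed) {
    note(sprintf("Movie did not start at a valley; re-anchored to frame %d and re-tracked.",
                 segments$valley_frames[1]))
    movie <- adj$movie
    tracks <- stage("tracking", track_pair(movie))
    series <- stage("displacement",
                    mean_displacement(tracks, fps = config$fps,
                                      length_scale = config$length_scale))
    segments <- stage("beat segmentation", find_valleys(series, config$fps))
  }
  drift <- withCallingHandlers(
    stage("drift detection",
          detect_drift(series, segments, config$drift_tol_px)),
    pillartrack_drift_warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    }
  )
  irregular <- withCallingHandlers(
    stage("irregularity check", detect_irregular(segments, series)),
    pillartrack_irregular_warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    }
  )
  tw <- tryCatch(
    measure_tissue_width(get_frame(movie, 1), masks, config$length_scale),
    error = function(e) {
      note(paste("Tissue width not measurable:", conditionMessage(e)))
      NULL
    }
  )
  tissue <- if (!is.null(tw)) tissue_geometry(as.numeric(tw),
                                              config$tissue_depth)
  force <- stage("mechanics", {
    f <- twitch_force(series, config$k, config$length_scale)
    if (!is.null(tissue)) f <- tissue_stress(f, tissue) else f
  })
  per_beat_series <- if (config$split) {
    stage("per-beat split",
          split_beats(tracks, segments, fps = config$fps,
                      length_scale = config$length_scale))
  } else {
    # metrics are still per beat, but re-baselined only at the movie start
    purrr::pmap(segments$beats, function(beat, start, end) {
      dplyr::filter(series, .data$frame >= start, .data$frame < end)
    })
  }
  per_beat <- stage("metrics", dplyr::bind_rows(purrr::map(
    per_beat_series, beat_metrics, fps = config$fps,
    length_scale = config$length_scale, k = config$k, tissue = tissue
  )))
  report <- stage("metrics",
                  summarize_beats(per_beat, segments, config$fps,
                                  irregular = as.logical(irregular)))
  structure(
    list(series = series, segments = segments, drift = drift,
         irregular = irregular, force = force, report = report,
         per_beat = if (config$split) per_beat_series,
         masks = masks, tissue_width_um = tw, warnings = log,
         movie = movie, config = config),
    class = "pt_analysis"
  )
}

#' @export
print.pt_analysis <- function(x, ...) {
  cat("<pt_analysis>\n")
  print(x$segments)
  if (x$drift$detected) cat("  drift detected\n")
  print(x$report)
  invisible(x)
}

write_displacement_txt <- function(series, out_dir) {
  for (s in unique(series$side)) {
    tbl <- series |>
      dplyr::filter(.data$side == s) |>
      dplyr::select("frame", d_row_px = "d_row", d_col_px = "d_col",
                    "abs_px", dplyr::any_of("abs_um"))
    write_timeseries(tbl, file.path(out_dir,
                                    sprintf("displacement_%s.txt", s)))
  }
}

#' Run the full pipeline on one movie folder
#'
#' Executes [analyze_movie()] and writes all outputs as plain-text tables:
#' per-pillar displacements, force/stress time series, per-beat metrics, a
#' one-row summary, a warnings log, and time-series plots (PDF).
#'
#' @param movie_folder Folder of frames (or a `pt_movie`).
#' @param config A [run_config()].
#' @param plots Write PDF time-series plots (default `TRUE`).
#' @return The `pt_analysis`, invisibly; side effect: the output folder.
#' @export
run_single <- function(movie_folder, config, plots = TRUE) {
  movie <- if (inherits(movie_folder, "pt_movie")) movie_folder else
    stage("load", load_movie(movie_folder, fps = config$fps,
                             length_scale = config$length_scale))
  out_dir <- config$output_dir %||%
    if (is.character(movie_folder)) paste0(sub("/+$", "", movie_folder), "_results")
    else "pillartrack_results"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- analyze_movie(movie, config)
  write_displacement_txt(res$series, out_dir)
  write_timeseries(res$force, file.path(out_dir, "force_stress.txt"))
  write_timeseries(tidy(res$report), file.path(out_dir, "beat_metrics.txt"))
  write_timeseries(glance(res$report), file.path(out_dir, "summary.txt"))
  if (!is.null(res$per_beat)) {
    for (i in seq_along(res$per_beat)) {
      b <- res$per_beat[[i]]
      write_timeseries(
        dplyr::select(b, "movie_frame", "frame", "side", d_row_px = "d_row",
                      d_col_px = "d_col", "abs_px", dplyr::any_of("abs_um")),
        file.path(out_dir, sprintf("displacement_beat_%02d.txt", i))
      )
    }
  }
  writeLines(if (length(res$warnings)) res$warnings else "none",
             file.path(out_dir, "warnings.txt"))
  if (plots) {
    ggplot2::ggsave(file.path(out_dir, "displacement.pdf"),
                    autoplot(res$series, segments = res$segments),
                    width = 7, height = 4)
    ggplot2::ggsave(file.path(out_dir, "force.pdf"), plot_force(res$force),
                    width = 7, height = 4)
  }
  invisible(res)
}

#' Run the pipeline on a batch of movie folders
#'
#' Every sub-folder of `parent_folder` containing frames is analysed with
#' the shared configuration; failures are isolated per movie and logged, and
#' an aggregate table (one row of summary metrics per movie) is written.
#'
#' @param parent_folder Folder whose sub-folders are movies.
#' @param config A [run_config()] (its `output_dir` is ignored; results go
#'   next to each movie).
#' @param plots Write plots per movie.
#' @return A list with `table` (aggregate tibble), `failures` (named list of
#'   error messages) and `status` (0 all ok, 2 partial, 1 none processed).
#' @export
run_batch <- function(parent_folder, config, plots = FALSE) {
  movies <- list.dirs(parent_folder, recursive = FALSE)
  movies <- movies[!grepl("_results$", movies)]
  if (length(movies) == 0) abort("No movie folders found in the batch parent.")
  rows <- list(); failures <- list()
  for (mv in movies) {
    cfg <- config
    cfg$output_dir <- paste0(mv, "_results")
    res <- tryCatch(run_single(mv, cfg, plots = plots), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[basename(mv)]] <- conditionMessage(res)
      inform(sprintf("Movie '%s' failed: %s", basename(mv),
                     conditionMessage(res)))
    } else {
      rows[[basename(mv)]] <- dplyr::bind_cols(
        tibble(movie = basename(mv)), glance(res$report)
      )
    }
  }
  tbl <- dplyr::bind_rows(rows)
  if (nrow(tbl) > 0) {
    write_timeseries(tbl, file.path(parent_folder, "batch_summary.txt"))
  }
  status <- if (length(failures) == 0) 0L
            else if (nrow(tbl) > 0) 2L else 1L
  if (status == 1L) abort("No movies in the batch could be processed.")
  list(table = tbl, failures = failures, status = status)
}
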