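#' Analyse a list of frames
#'
#' Runs [analyze_frame()] over in-memory frames and collects the object
#' table, fluorescence frame metrics, and confluence metrics.
#'
#' @param frames List of [phago_frame()]s (any mix of channels).
#' @param params An [analysis_params()] object.
#' @return A list with tibbles `objects`, `frame_metrics` (fluorescence) and
#'   `confluence` (phase).
#' @export
analyze_frames <- function(frames, params = analysis_params()) {
  keep <- vapply(frames, function(f)
    f$channel %in% c(params$channel_of_interest, "phase"), logical(1))
  frames <- frames[keep]
  res <- lapply(frames, analyze_frame, params = params)
  is_phase <- vapply(frames, function(f) f$channel == "phase", logical(1))
  objects <- dplyr::bind_rows(lapply(res[!is_phase], `[[`, "objects"))
  metrics <- dplyr::bind_rows(lapply(res[!is_phase], `[[`, "metrics"))
  confl <- dplyr::bind_rows(lapply(res[is_phase], `[[`, "metrics"))
  list(objects = objects, frame_metrics = metrics, confluence = confl)
}

#' Analyse a plate image directory end to end
#'
#' Reads every TIFF matching the canonical naming convention, runs the
#' per-frame pipeline on the channel of interest (and the confluence mask on
#' phase frames), assembles per-well time series for object count, total
#' area and total integrated intensity, and summarises each well's
#' kinetics. With a layout and `normalize = TRUE`, treatment groups are
#' normalised to the vehicle group (percent of control, fold change).
#'
#' @param images_dir Directory of TIFF frames.
#' @param layout Optional layout tibble or CSV path.
#' @param params An [analysis_params()] object.
#' @param pixel_size_um Micrometres per pixel edge of the acquisitions.
#' @param normalize Compute vehicle-normalised group summaries (requires a
#'   layout with a vehicle well).
#' @param endpoint_time Endpoint for normalisation, minutes (default: final
#'   timepoint).
#' @return An object of class `phago_run`: a list with tibbles `objects`,
#'   `frame_metrics`, `confluence`, `timeseries`, `well_summary`, and
#'   (when normalising) `group_summary`; plus `params` and `layout`.
#' @export
analyze_plate <- function(images_dir, layout = NULL,
                          params = analysis_params(), pixel_size_um = 2,
                          normalize = FALSE, endpoint_time = NULL) {
  paths <- list.files(images_dir, pattern = "\\.tiff?$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(paths) == 0)
    stop("no frames found in ", images_dir)
  if (!is.null(layout) && !is.data.frame(layout)) layout <- load_layout(layout)
  if (normalize) {
    if (is.null(layout)) stop("normalization requested but no layout given")
    assert_has_vehicle(layout)
  }
  frames <- lapply(sort(paths), read_frame, pixel_size_um = pixel_size_um)
  res <- analyze_frames(frames, params)
  if (nrow(res$frame_metrics) == 0)
    stop("no frames of channel '", params$channel_of_interest,
         "' found in ", images_dir)
  ts <- dplyr::bind_rows(
    build_timeseries(res$frame_metrics, "object_count"),
    build_timeseries(res$frame_metrics, "total_area"),
    build_timeseries(res$frame_metrics, "total_intensity"))
  ws <- summarize_kinetics(ts, endpoint_time = endpoint_time)
  out <- list(objects = res$objects, frame_metrics = res$frame_metrics,
              confluence = res$confluence, timeseries = ts,
              well_summary = ws, params = params, layout = layout)
  if (normalize)
    out$group_summary <- summarize_groups(ws, layout)
  structure(out, class = "phago_run")
}

#' @export
print.phago_run <- function(x, ...) {
  cat(sprintf("<phago_run> %d wells, %d fluorescence frames, %d objects\n",
              length(unique(x$frame_metrics$well_id)),
              nrow(x$frame_metrics), nrow(x$objects)))
  if (!is.null(x$group_summary)) {
    cat("group summary:\n")
    print(x$group_summary)
  }
  invisible(x)
}

#' Tidy a phagocytosis run into per-well summaries
#' @param x A `phago_run` from [analyze_plate()].
#' @param ... Unused.
#' @return The per-well kinetic summary tibble.
#' @export
tidy.phago_run <- function(x, ...) x$well_summary

#' One-row overview of a phagocytosis run
#' @param x A `phago_run` from [analyze_plate()].
#' @param ... Unused.
#' @return A one-row tibble: wells, frames, objects, timepoints, and mean
#'   final confluence (NA when no phase frames were analysed).
#' @export
glance.phago_run <- function(x, ...) {
  tibble::tibble(
    n_wells = length(unique(x$frame_metrics$well_id)),
    n_frames = nrow(x$frame_metrics),
    n_objects = nrow(x$objects),
    n_timepoints = length(unique(x$frame_metrics$time_min)),
    mean_confluence = if (nrow(x$confluence) > 0)
      mean(x$confluence$confluence_fraction) else NA_real_)
}

#' Turn an object into a tidy tibble
#' @param x Object to tidy.
#' @param ... Method-specific arguments.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of an object
#' @param x Object to summarise.
#' @param ... Method-specific arguments.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Write analysis tables to CSV files
#'
#' Writes `objects.csv`, `timeseries.csv` and `summary.csv` with fixed
#' column order. Re-running on identical input produces byte-identical
#' files.
#'
#' @param run A `phago_run`, or a list with `objects`, `timeseries` and a
#'   summary tibble (`group_summary` when present, else `well_summary`).
#' @param out_dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_results <- function(run, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir)
  }
  summ <- if (!is.null(run$group_summary)) run$group_summary else
    run$well_summary
  summ <- dplyr::mutate(summ, dplyr::across(
    dplyr::where(is.list),
    ~ vapply(.x, function(v) paste(v, collapse = ";"), character(1))))
  paths <- c(objects = file.path(out_dir, "objects.csv"),
             timeseries = file.path(out_dir, "timeseries.csv"),
             summary = file.path(out_dir, "summary.csv"))
  readr::write_csv(run$objects, paths["objects"])
  readr::write_csv(run$timeseries, paths["timeseries"])
  readr::write_csv(summ, paths["summary"])
  if (!is.null(run$confluence) && nrow(run$confluence) > 0)
    readr::write_csv(run$confluence, file.path(out_dir, "confluence.csv"))
  invisible(paths)
}

#' Write a run manifest
#'
#' Records tool version, parameters, input checksums, seed and output file
#' list as JSON. Reruns with identical inputs produce identical
#' non-timestamp fields.
#'
#' @param out_dir Directory receiving `manifest.json`.
#' @param params Parameter object (echoed verbatim).
#' @param inputs Character vector of input file paths (checksummed).
#' @param seed Seed used, if any.
#' @param outputs Character vector of output file paths.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(out_dir, params = NULL, inputs = character(0),
                           seed = NULL, outputs = character(0)) {
  inputs <- inputs[file.exists(inputs)]
  checksums <- if (length(inputs) > 0)
    as.list(tools::md5sum(sort(inputs))) else list()
  manifest <- list(
    tool = "phagoquant",
    version = as.character(utils::packageVersion("phagoquant")),
    params = unclass(params),
    input_md5 = checksums,
    seed = seed,
    outputs = sort(basename(outputs)),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
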