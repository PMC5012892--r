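#' Assemble per-well kinetic time series from frame metrics
#'
#' At each (well, timepoint) the metric is averaged over that well's
#' replicate images; series are sorted by time. Wells are the unit of
#' replication downstream, so replicate images are averaged here and never
#' re-enter later statistics.
#'
#' @param frame_metrics Tibble of per-frame metrics as produced by
#'   [analyze_frame()] (columns `well_id`, `image_index`, `time_min`, plus
#'   metric columns).
#' @param metric Which metric to extract: `"object_count"`, `"total_area"`,
#'   or `"total_intensity"`.
#' @return A tibble with columns `well_id`, `metric`, `time_min`, `value`,
#'   `n_images`, sorted by well then time.
#' @export
build_timeseries <- function(frame_metrics,
                             metric = c("object_count", "total_area",
                                        "total_intensity")) {
  metric <- match.arg(metric)
  col <- switch(metric,
                object_count = "object_count",
                total_area = "total_area_um2",
                total_intensity = "total_integrated_intensity")
  if (nrow(frame_metrics) == 0)
    stop("no frame metrics supplied: empty series")
  if (!col %in% names(frame_metrics))
    stop("frame metrics lack column '", col, "'")
  frame_metrics |>
    dplyr::group_by(.data$well_id, time_min = .data$time_min) |>
    dplyr::summarise(value = mean(.data[[col]]),
                     n_images = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(metric = metric, .after = "well_id") |>
    dplyr::arrange(.data$well_id, .data$time_min)
}

#' Rising-phase slope of a kinetic curve
#'
#' The curve is normalised by its maximum and an ordinary least-squares
#' slope is fit over the rising window, from the first timepoint to the
#' first timepoint at which the normalised signal reaches 0.9. Units are
#' fraction-of-maximum per minute. A series whose maximum is not positive,
#' or whose rising window degenerates to a single point, has slope 0 by
#' convention.
#'
#' @param times Strictly increasing times in minutes (length >= 3).
#' @param values Non-negative metric values, same length.
#' @return Slope in units of 1/min.
#' @export
slope_metric <- function(times, values) {
  check_series(times, values, min_len = 3)
  m <- max(values)
  if (m <= 0) return(0)
  norm <- values / m
  stop_i <- which(norm >= 0.9)[1]
  if (stop_i < 2) return(0)
  win <- seq_len(stop_i)
  unname(coef(lm(norm[win] ~ times[win]))[2])
}

#' Trapezoidal area under a kinetic curve
#'
#' @param times Strictly increasing times in minutes (length >= 2).
#' @param values Metric values, same length.
#' @return The trapezoidal integral, in metric-units x minutes.
#' @export
auc_trapezoid <- function(times, values) {
  check_series(times, values, min_len = 2)
  sum(diff(times) * (head(values, -1) + tail(values, -1)) / 2)
}

check_series <- function(times, values, min_len) {
  if (length(times) < min_len)
    stop(sprintf("series must have at least %d timepoints", min_len))
  if (length(values) != length(times))
    stop("times and values differ in length")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  invisible(TRUE)
}

#' Percent-of-control normalisation
#'
#' Treated endpoint values expressed as a percentage of the vehicle group:
#' `100 * mean(treated) / mean(vehicle)`. A vehicle group measured against
#' itself is exactly 100; percent reduction is `100 - result`.
#'
#' @param treated Numeric endpoint values of the treated group.
#' @param vehicle Numeric endpoint values of the vehicle group.
#' @return Percentage (>= 0).
#' @export
percent_of_control <- function(treated, vehicle) {
  if (length(vehicle) == 0 || mean(vehicle) <= 0)
    stop("vehicle group mean must be positive: control undefined")
  100 * mean(treated) / mean(vehicle)
}

#' Fold change relative to vehicle
#' @param treated Treated endpoint value (or group mean).
#' @param vehicle Vehicle endpoint value (or group mean); must be positive.
#' @return `treated / vehicle`.
#' @export
fold_change <- function(treated, vehicle) {
  if (mean(vehicle) <= 0) stop("vehicle value must be positive")
  mean(treated) / mean(vehicle)
}

#' Detect kinetic phases: peaks and plateau
#'
#' The series is smoothed with a centred 3-point moving average (truncated
#' at the ends). Peaks are interior local maxima of the smoothed series with
#' topographic prominence at least `min_prominence_frac` times the smoothed
#' maximum. The plateau time is the first time from which the absolute
#' between-frame change of the smoothed series stays at or below
#' `plateau_eps_frac` times the maximum for at least `plateau_len`
#' consecutive intervals; `NA` when never satisfied. Distinguishes a
#' biphasic uptake curve (two uptake waves, e.g. peaks near 4 h and 24 h)
#' from saturating uptake that plateaus and stays flat.
#'
#' @param times Strictly increasing times in minutes (length >= 5).
#' @param values Metric values, same length.
#' @param min_prominence_frac Peak prominence threshold as a fraction of the
#'   smoothed maximum (default 0.2).
#' @param plateau_eps_frac Flatness tolerance as a fraction of the smoothed
#'   maximum (default 0.02).
#' @param plateau_len Number of consecutive flat intervals required
#'   (default 3).
#' @return A list with `peak_times_min` (numeric vector, possibly empty)
#'   and `plateau_time_min` (number or `NA`).
#' @export
detect_phases <- function(times, values, min_prominence_frac = 0.2,
                          plateau_eps_frac = 0.02, plateau_len = 3L) {
  check_series(times, values, min_len = 5)
  n <- length(values)
  sm <- vapply(seq_len(n), function(i) {
    w <- max(1L, i - 1L):min(n, i + 1L)
    mean(values[w])
  }, numeric(1))
  m <- max(sm)

  peaks <- numeric(0)
  for (i in 2:(n - 1L)) {
    if (sm[i] > sm[i - 1L] && sm[i] >= sm[i + 1L]) {
      prom <- sm[i] - max(side_min(sm, i, -1L), side_min(sm, i, 1L))
      if (prom >= min_prominence_frac * m) peaks <- c(peaks, times[i])
    }
  }

  flat <- abs(diff(sm)) <= plateau_eps_frac * m
  plateau <- NA_real_
  if (n - 1L >= plateau_len) {
    run <- rle(flat)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    # the flat run must extend to the end of the series: "stays" flat
    k <- which(run$values & ends == n - 1L & run$lengths >= plateau_len)
    if (length(k) > 0) plateau <- times[starts[k[1]]]
  }
  list(peak_times_min = peaks, plateau_time_min = plateau)
}

# minimum of sm walking from peak i in direction dir until a strictly
# higher point (or the series end); standard prominence reference
side_min <- function(sm, i, dir) {
  lo <- sm[i]
  j <- i + dir
  while (j >= 1L && j <= length(sm) && sm[j] <= sm[i]) {
    lo <- min(lo, sm[j])
    j <- j + dir
  }
  lo
}

#' Per-well kinetic summaries
#'
#' For each well in a long-format time-series tibble, computes the rising
#' phase slope, trapezoidal AUC, endpoint value (at `endpoint_time`, default
#' the final timepoint), and peak/plateau descriptors.
#'
#' @param timeseries Tibble from [build_timeseries()].
#' @param endpoint_time Time (minutes) whose value is reported as the
#'   endpoint; defaults to each well's final timepoint.
#' @param ... Passed to [detect_phases()].
#' @return A tibble with one row per well: `well_id`, `metric`, `slope`,
#'   `auc`, `endpoint_time_min`, `endpoint`, `n_peaks`, `peak_times_min`
#'   (list column), `plateau_time_min`.
#' @export
summarize_kinetics <- function(timeseries, endpoint_time = NULL, ...) {
  timeseries |>
    dplyr::group_by(.data$well_id, .data$metric) |>
    dplyr::group_modify(function(df, key) {
      tt <- df$time_min; vv <- df$value
      et <- if (is.null(endpoint_time)) max(tt) else endpoint_time
      i <- which.min(abs(tt - et))
      ph <- if (length(tt) >= 5) detect_phases(tt, vv, ...) else
        list(peak_times_min = numeric(0), plateau_time_min = NA_real_)
      tibble::tibble(
        slope = if (length(tt) >= 3) slope_metric(tt, vv) else NA_real_,
        auc = if (length(tt) >= 2) auc_trapezoid(tt, vv) else NA_real_,
        endpoint_time_min = tt[i],
        endpoint = vv[i],
        n_peaks = length(ph$peak_times_min),
        peak_times_min = list(ph$peak_times_min),
        plateau_time_min = ph$plateau_time_min)
    }) |>
    dplyr::ungroup()
}

#' Treatment-group summaries with vehicle normalisation
#'
#' Joins per-well kinetic summaries to a plate layout and aggregates by
#' treatment: mean and SEM of the endpoint across wells, mean slope and
#' AUC, and — when a vehicle group is present — percent-of-control and fold
#' change of each group's endpoint against the vehicle group.
#'
#' @param well_summary Tibble from [summarize_kinetics()].
#' @param layout Layout tibble from [load_layout()].
#' @return A tibble with one row per (treatment, metric).
#' @export
summarize_groups <- function(well_summary, layout) {
  joined <- dplyr::inner_join(well_summary, layout, by = "well_id") |>
    dplyr::filter(.data$role != "blank")
  if (nrow(joined) == 0) stop("no analysed wells match the layout")
  grp <- joined |>
    dplyr::group_by(.data$treatment, .data$role, .data$metric) |>
    dplyr::summarise(
      n_wells = dplyr::n(),
      endpoint_mean = mean(.data$endpoint),
      endpoint_sem = ifelse(dplyr::n() > 1,
                            sd(.data$endpoint) / sqrt(dplyr::n()), NA_real_),
      slope_mean = mean(.data$slope),
      auc_mean = mean(.data$auc),
      .groups = "drop")
  veh <- dplyr::filter(joined, .data$role == "vehicle")
  if (nrow(veh) > 0) {
    veh_means <- veh |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(vehicle_endpoints = list(.data$endpoint),
                       .groups = "drop")
    grp <- grp |>
      dplyr::left_join(veh_means, by = "metric") |>
      dplyr::rowwise() |>
      dplyr::mutate(
        percent_of_control = percent_of_control(
          joined$endpoint[joined$treatment == .data$treatment &
                            joined$metric == .data$metric],
          unlist(.data$vehicle_endpoints)),
        fold_change_vs_vehicle = fold_change(
          joined$endpoint[joined$treatment == .data$treatment &
                            joined$metric == .data$metric],
          unlist(.data$vehicle_endpoints))) |>
      dplyr::ungroup() |>
      dplyr::select(-"vehicle_endpoints")
  }
  dplyr::arrange(grp, .data$metric, .data$treatment)
}
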