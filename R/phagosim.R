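#' Simulator configuration
#'
#' Parameters of the synthetic plate simulator. A well holds adherent cells
#' placed uniformly at random (minimum centre separation one cell radius);
#' each cell accrues engulfment events as a homogeneous Poisson process with
#' rate `rate_modifier * base_rate_per_cell_per_min * conc / (conc + half_sat_conc)`,
#' capped at `max_events_per_cell`. An engulfed particle only becomes
#' fluorescent after an exponential acidification lag (mean
#' `acid_lag_mean_min`), emulating pH-sensitive bioparticle dyes that light
#' up in the acidified phagolysosome, and is then rendered as an isotropic
#' Gaussian spot. Frames add a smooth quadratic background vignette and
#' Gaussian sensor noise. The seed fully determines the output.
#'
#' Defaults mirror the assay's standard conditions: images every 10 min for
#' 1 h, a 2 um pixel (20x objective class), spot amplitude five times the
#' 2-unit detection threshold, and a bioparticle dose of 200 ug/ml on a
#' saturation scale of `half_sat_conc` = 100 ug/ml.
#'
#' @param field_px Field size `(rows, cols)` in pixels.
#' @param pixel_size_um Micrometres per pixel edge.
#' @param n_cells Number of cells in the field.
#' @param cell_radius_um Cell footprint radius, um.
#' @param particle_conc Bioparticle concentration (arbitrary units, ug/ml).
#' @param base_rate_per_cell_per_min Maximal engulfment rate lambda0
#'   (events/cell/min at saturating concentration).
#' @param half_sat_conc Concentration giving half-maximal rate.
#' @param max_events_per_cell Engulfment cap per cell.
#' @param rate_modifier Multiplicative uptake modifier (inhibitor < 1,
#'   opsonin > 1; default 1).
#' @param acid_lag_mean_min Mean of the exponential acidification lag, min.
#' @param spot_sigma_px Gaussian spot sigma, pixels.
#' @param spot_amplitude Spot peak height in intensity units (must exceed
#'   the detection threshold to be visible).
#' @param background_amplitude Peak height of the smooth background
#'   vignette.
#' @param noise_sd Gaussian sensor noise standard deviation.
#' @param frame_interval_min Minutes between frames.
#' @param duration_min Total assay duration, minutes.
#' @param decay_tau_min Optional fluorescence decay time constant (minutes);
#'   `Inf` (default) disables decay. A finite value lets long simulations
#'   produce biphasic-looking curves for phase-detection work.
#' @param channel Rendered fluorescence channel, `"green"` or `"red"`.
#' @param seed Integer seed; per-well streams are derived from it and the
#'   well id, so adding wells never perturbs existing ones.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(field_px = c(128L, 128L), pixel_size_um = 2,
                       n_cells = 50L, cell_radius_um = 16,
                       particle_conc = 200, base_rate_per_cell_per_min = 0.03,
                       half_sat_conc = 100, max_events_per_cell = 10L,
                       rate_modifier = 1, acid_lag_mean_min = 15,
                       spot_sigma_px = 3, spot_amplitude = 10,
                       background_amplitude = 1, noise_sd = 0.2,
                       frame_interval_min = 10, duration_min = 60,
                       decay_tau_min = Inf, channel = c("green", "red"),
                       seed = 1L) {
  channel <- match.arg(channel)
  stopifnot(length(field_px) == 2, all(field_px >= 8), pixel_size_um > 0,
            n_cells >= 0, cell_radius_um > 0, particle_conc >= 0,
            base_rate_per_cell_per_min >= 0, half_sat_conc > 0,
            max_events_per_cell >= 1, rate_modifier > 0,
            acid_lag_mean_min > 0, spot_sigma_px > 0, spot_amplitude > 0,
            background_amplitude >= 0, noise_sd >= 0,
            frame_interval_min > 0, duration_min > 0, decay_tau_min > 0)
  structure(
    list(field_px = as.integer(field_px), pixel_size_um = pixel_size_um,
         n_cells = as.integer(n_cells), cell_radius_um = cell_radius_um,
         particle_conc = particle_conc,
         base_rate_per_cell_per_min = base_rate_per_cell_per_min,
         half_sat_conc = half_sat_conc,
         max_events_per_cell = as.integer(max_events_per_cell),
         rate_modifier = rate_modifier, acid_lag_mean_min = acid_lag_mean_min,
         spot_sigma_px = spot_sigma_px, spot_amplitude = spot_amplitude,
         background_amplitude = background_amplitude, noise_sd = noise_sd,
         frame_interval_min = frame_interval_min, duration_min = duration_min,
         decay_tau_min = decay_tau_min, channel = channel,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Derive a per-well RNG seed from the root seed
#'
#' Stable hash of the well id and image index mixed with the root seed, so
#' each well/image owns an independent reproducible stream and plates can
#' gain wells without perturbing existing ones.
#'
#' @param seed Root integer seed.
#' @param well_id Well coordinate string.
#' @param image_index Replicate image index.
#' @return Integer seed below 2^31.
#' @export
well_seed <- function(seed, well_id, image_index = 1L) {
  h <- 0
  for (ch in utf8ToInt(as.character(well_id))) h <- (h * 31 + ch) %% 1000000007
  as.integer((h * 65537 + as.numeric(image_index) * 257 +
                as.numeric(seed) * 2 + 1) %% 2147483647)
}

place_cells <- function(cfg) {
  nr <- cfg$field_px[1]; nc <- cfg$field_px[2]
  r_px <- cfg$cell_radius_um / cfg$pixel_size_um
  if (cfg$n_cells == 0)
    return(tibble::tibble(cell_id = integer(), row_px = numeric(),
                          col_px = numeric()))
  m <- min(r_px, (min(nr, nc) - 1) / 4)  # keep footprints mostly in-field
  rows <- numeric(cfg$n_cells); cols <- numeric(cfg$n_cells)
  for (i in seq_len(cfg$n_cells)) {
    placed <- FALSE
    for (attempt in seq_len(1000L)) {
      rr <- runif(1, m, nr - 1 - m)
      cc <- runif(1, m, nc - 1 - m)
      if (i == 1L ||
          all((rr - rows[seq_len(i - 1L)])^2 +
                (cc - cols[seq_len(i - 1L)])^2 >= r_px^2)) {
        rows[i] <- rr; cols[i] <- cc; placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(
        "could not place cell %d of %d at the requested density within 1000 attempts",
        i, cfg$n_cells))
  }
  tibble::tibble(cell_id = seq_len(cfg$n_cells), row_px = rows, col_px = cols)
}

render_spots <- function(img, truth, t, cfg) {
  vis <- truth[truth$onset_time_min <= t, , drop = FALSE]
  if (nrow(vis) == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  s <- cfg$spot_sigma_px
  ext <- ceiling(4 * s)
  for (e in seq_len(nrow(vis))) {
    r0 <- vis$row_px[e] + 1  # truth is 0-based
    c0 <- vis$col_px[e] + 1
    amp <- vis$amplitude[e]
    if (is.finite(cfg$decay_tau_min))
      amp <- amp * exp(-(t - vis$onset_time_min[e]) / cfg$decay_tau_min)
    rs <- max(1L, floor(r0 - ext)):min(nr, ceiling(r0 + ext))
    cs <- max(1L, floor(c0 - ext)):min(nc, ceiling(c0 + ext))
    g <- outer(exp(-(rs - r0)^2 / (2 * s^2)), exp(-(cs - c0)^2 / (2 * s^2)))
    img[rs, cs] <- img[rs, cs] + amp * g
  }
  img
}

background_vignette <- function(nr, nc, amplitude) {
  if (amplitude <= 0) return(matrix(0, nr, nc))
  rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
  d2 <- outer((seq_len(nr) - rc)^2, (seq_len(nc) - cc)^2, "+")
  amplitude * (0.5 + 0.5 * (1 - d2 / max(d2)))
}

cell_footprint_mask <- function(cells, nr, nc, r_px) {
  mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(cells))) {
    r0 <- cells$row_px[i] + 1; c0 <- cells$col_px[i] + 1
    rs <- max(1L, floor(r0 - r_px)):min(nr, ceiling(r0 + r_px))
    cs <- max(1L, floor(c0 - r_px)):min(nc, ceiling(c0 + r_px))
    patch <- outer((rs - r0)^2, (cs - c0)^2, "+") <= r_px^2
    mask[rs, cs] <- mask[rs, cs] | patch
  }
  mask
}

#' Simulate one well of a time-lapse phagocytosis assay
#'
#' Draws cell positions, engulfment events and acidification lags, then
#' renders a green (or red) fluorescence frame and a phase-contrast frame at
#' every timepoint, returning the frames together with the event-level
#' ground truth. Identical seeds give bit-identical output.
#'
#' @param cfg A [sim_config()].
#' @param well_id Well coordinate used for metadata and seed derivation.
#' @param image_index Replicate image index (independent stream).
#' @return A list with elements `fluor` (list of fluorescence
#'   [phago_frame()]s), `phase` (list of phase frames), `truth` (tibble of
#'   events: `cell_id`, `event_time_min`, `onset_time_min`, `row_px`,
#'   `col_px` in 0-based pixels, `amplitude`), `cells` (cell centre tibble),
#'   `coverage` (ground-truth cell area fraction) and `config`.
#' @export
simulate_well <- function(cfg, well_id = "A01", image_index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(well_seed(cfg$seed, well_id, image_index))
  nr <- cfg$field_px[1]; nc <- cfg$field_px[2]
  r_px <- cfg$cell_radius_um / cfg$pixel_size_um

  cells <- place_cells(cfg)
  lam <- cfg$rate_modifier * cfg$base_rate_per_cell_per_min *
    cfg$particle_conc / (cfg$particle_conc + cfg$half_sat_conc)

  ev <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    n_ev <- rpois(1, lam * cfg$duration_min)
    if (n_ev == 0) next
    times <- sort(runif(n_ev, 0, cfg$duration_min))
    if (n_ev > cfg$max_events_per_cell)
      times <- times[seq_len(cfg$max_events_per_cell)]
    k <- length(times)
    ang <- runif(k, 0, 2 * pi)
    rad <- r_px * sqrt(runif(k))
    ev[[i]] <- tibble::tibble(
      cell_id = cells$cell_id[i],
      event_time_min = times,
      onset_time_min = times + rexp(k, 1 / cfg$acid_lag_mean_min),
      row_px = pmin(pmax(cells$row_px[i] + rad * sin(ang), 0), nr - 1),
      col_px = pmin(pmax(cells$col_px[i] + rad * cos(ang), 0), nc - 1),
      amplitude = rep(cfg$spot_amplitude, k))
  }
  truth <- dplyr::bind_rows(ev)
  if (nrow(truth) == 0)
    truth <- tibble::tibble(cell_id = integer(), event_time_min = numeric(),
                            onset_time_min = numeric(), row_px = numeric(),
                            col_px = numeric(), amplitude = numeric())

  footprint <- cell_footprint_mask(cells, nr, nc, r_px)
  bg <- background_vignette(nr, nc, cfg$background_amplitude)
  frame_times <- seq(0, cfg$duration_min, by = cfg$frame_interval_min)

  fluor <- vector("list", length(frame_times))
  phase <- vector("list", length(frame_times))
  for (f in seq_along(frame_times)) {
    t <- frame_times[f]
    img <- render_spots(bg, truth, t, cfg)
    img <- pmax(img + rnorm(nr * nc, 0, cfg$noise_sd), 0)
    fluor[[f]] <- phago_frame(img, cfg$channel, t, well_id, image_index,
                              cfg$pixel_size_um)
    ph <- matrix(1, nr, nc)
    ph[footprint] <- ph[footprint] + 1.5 + rnorm(sum(footprint), 0, 1.2)
    ph <- pmax(ph + rnorm(nr * nc, 0, cfg$noise_sd), 0)
    phase[[f]] <- phago_frame(ph, "phase", t, well_id, image_index,
                              cfg$pixel_size_um)
  }
  list(fluor = fluor, phase = phase, truth = truth, cells = cells,
       coverage = mean(footprint), config = cfg)
}

#' Number of ground-truth events visible at a given time
#' @param truth Truth tibble from [simulate_well()].
#' @param t Time in minutes.
#' @return Count of events whose fluorescence onset is at or before `t`.
#' @export
visible_events <- function(truth, t) sum(truth$onset_time_min <= t)

#' Simulate a whole plate
#'
#' Each layout well is simulated with the config of its treatment
#' (`configs` is a named list keyed by treatment label). Vehicle wells are
#' forced to `rate_modifier = 1` and blank wells to zero cells. When
#' `out_dir` is given, frames are written as TIFFs under the canonical
#' `{well}_{image}_{channel}_t{min}.tif` naming plus `layout.csv` and
#' `truth.csv`, so [analyze_plate()] consumes simulator output unchanged.
#'
#' @param layout Layout tibble from [load_layout()] (or a CSV path).
#' @param configs Named list of [sim_config()]s keyed by treatment label.
#' @param seed Root seed, overriding the configs' own seeds.
#' @param n_images Replicate images per well.
#' @param out_dir Optional output directory.
#' @return A list with `wells` (nested per-well, per-image simulation
#'   results), `truth` (combined event tibble with `well_id` and
#'   `image_index`), `layout`, and `out_dir`.
#' @export
simulate_plate <- function(layout, configs, seed = 1L, n_images = 2L,
                           out_dir = NULL) {
  if (!is.data.frame(layout)) layout <- load_layout(layout)
  wells <- list()
  truth_all <- list()
  for (w in seq_len(nrow(layout))) {
    trt <- layout$treatment[w]
    cfg <- configs[[trt]]
    if (is.null(cfg))
      stop(sprintf("no simulator config for condition '%s' (well %s)",
                   trt, layout$well_id[w]))
    cfg$seed <- as.integer(seed)
    if (layout$role[w] == "vehicle") cfg$rate_modifier <- 1
    if (layout$role[w] == "blank") cfg$n_cells <- 0L
    for (img in seq_len(n_images)) {
      sim <- simulate_well(cfg, layout$well_id[w], img)
      wells[[paste(layout$well_id[w], img, sep = "_")]] <- sim
      if (nrow(sim$truth) > 0)
        truth_all[[length(truth_all) + 1L]] <- dplyr::mutate(
          sim$truth, well_id = layout$well_id[w], image_index = img,
          .before = 1L)
      if (!is.null(out_dir)) {
        for (fr in sim$fluor) write_frame(fr, out_dir)
        for (fr in sim$phase) write_frame(fr, out_dir)
      }
    }
  }
  truth <- dplyr::bind_rows(truth_all)
  if (!is.null(out_dir)) {
    readr::write_csv(
      tibble::tibble(well = layout$well_id, treatment = layout$treatment,
                     concentration = layout$concentration, unit = layout$unit,
                     role = layout$role, cells = layout$seeded_cells,
                     meal = layout$meal),
      file.path(out_dir, "layout.csv"))
    readr::write_csv(truth, file.path(out_dir, "truth.csv"))
  }
  list(wells = wells, truth = truth, layout = layout, out_dir = out_dir)
}
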