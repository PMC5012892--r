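test_that("zero uptake rate produces background-only frames", {
  cfg <- sim_config(field_px = c(64, 64), n_cells = 20,
                    base_rate_per_cell_per_min = 0, seed = 2)
  sim <- simulate_well(cfg)
  expect_equal(nrow(sim$truth), 0)
  last <- sim$fluor[[length(sim$fluor)]]$pixels
  expect_lt(max(last), cfg$background_amplitude + 6 * cfg$noise_sd)

  cfg0 <- sim_config(field_px = c(64, 64), n_cells = 20, particle_conc = 0,
                     seed = 2)
  expect_equal(nrow(simulate_well(cfg0)$truth), 0)
})

test_that("identical seeds give bit-identical wells", {
  cfg <- sim_config(field_px = c(64, 64), n_cells = 10, seed = 9)
  a <- simulate_well(cfg, "B02")
  b <- simulate_well(cfg, "B02")
  expect_identical(lapply(a$fluor, `[[`, "pixels"),
                   lapply(b$fluor, `[[`, "pixels"))
  expect_identical(a$truth, b$truth)
  # a different well draws a different stream
  c <- simulate_well(cfg, "B03")
  expect_false(identical(a$truth, c$truth))
})

test_that("event counts follow the Poisson expectation", {
  # lambda = 0.02/cell/min (conc = K halves the base rate), 60 min, 100 cells
  lam <- 0.02; T <- 60; n <- 100
  cfg <- sim_config(field_px = c(256, 256), n_cells = n, cell_radius_um = 10,
                    base_rate_per_cell_per_min = 2 * lam, particle_conc = 100,
                    half_sat_conc = 100, max_events_per_cell = 50,
                    noise_sd = 0, background_amplitude = 0,
                    frame_interval_min = 60)
  tot <- vapply(1:50, function(s) {
    cfg$seed <- s
    nrow(simulate_well(cfg, "F06")$truth)
  }, numeric(1))
  mu <- n * lam * T  # 120
  se <- sqrt(mu / 50)
  expect_lt(abs(mean(tot) - mu), 3 * se)
})

test_that("per-cell event counts pass a chi-square goodness of fit", {
  lam_t <- 0.9  # lambda*T per cell
  cfg <- sim_config(field_px = c(256, 256), n_cells = 200,
                    cell_radius_um = 8,
                    base_rate_per_cell_per_min = 2 * lam_t / 60,
                    particle_conc = 100, half_sat_conc = 100,
                    max_events_per_cell = 50, noise_sd = 0,
                    background_amplitude = 0, frame_interval_min = 60,
                    seed = 77)
  sim <- simulate_well(cfg, "G07")
  counts <- tabulate(factor(sim$truth$cell_id, levels = 1:200), 200)
  maxk <- 4
  obs <- tabulate(factor(pmin(counts, maxk), levels = 0:maxk), maxk + 1)
  p <- dpois(0:(maxk - 1), lam_t)
  p <- c(p, 1 - sum(p))
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("visible events are monotone over time and lag behind engulfment", {
  cfg <- sim_config(field_px = c(96, 96), n_cells = 30, seed = 15)
  sim <- simulate_well(cfg, "C08")
  expect_true(all(sim$truth$onset_time_min >= sim$truth$event_time_min))
  times <- seq(0, cfg$duration_min, by = cfg$frame_interval_min)
  vis <- vapply(times, function(t) visible_events(sim$truth, t), numeric(1))
  expect_true(all(diff(vis) >= 0))
})

test_that("cell packing respects the minimum separation or errors", {
  cfg <- sim_config(field_px = c(64, 64), n_cells = 25, cell_radius_um = 10,
                    seed = 4)
  sim <- simulate_well(cfg)
  d <- as.matrix(dist(cbind(sim$cells$row_px, sim$cells$col_px)))
  diag(d) <- Inf
  expect_gte(min(d), cfg$cell_radius_um / cfg$pixel_size_um)

  cfg_dense <- sim_config(field_px = c(32, 32), n_cells = 500,
                          cell_radius_um = 10, seed = 4)
  expect_error(simulate_well(cfg_dense), "1000 attempts")
})

test_that("plate simulation echoes the file convention end to end", {
  layout <- load_layout(tibble::tibble(
    well = c("B02", "B03", "H12"),
    treatment = c("vehicle", "cytoD", "empty"),
    concentration = c(0, 10, 0), unit = "uM",
    role = c("vehicle", "treated", "blank"),
    cells = c(20, 20, 0), meal = "E. coli"))
  cfg <- sim_config(field_px = c(48, 48), n_cells = 6, duration_min = 20,
                    frame_interval_min = 10)
  configs <- list(vehicle = cfg, empty = cfg,
                  cytoD = { c2 <- cfg; c2$rate_modifier <- 0.3; c2 })
  dir <- tempfile(); dir.create(dir)
  sim <- simulate_plate(layout, configs, seed = 5, n_images = 2,
                        out_dir = dir)
  files <- list.files(dir)
  # 3 wells x 2 images x 3 timepoints x 2 channels + layout + truth
  expect_equal(sum(grepl("\\.tif$", files)), 36)
  expect_true(all(c("layout.csv", "truth.csv") %in% files))
  meta <- dplyr::bind_rows(lapply(
    list.files(dir, pattern = "\\.tif$"), parse_frame_path))
  expect_setequal(unique(meta$well_id), c("B02", "B03", "H12"))
  # blank well renders background only
  blank <- read_frame(file.path(dir, "H12_1_green_t020.tif"), 2)
  expect_lt(max(blank$pixels), 3)
  expect_false("H12" %in% sim$truth$well_id)
})

test_that("a missing condition config is reported by name", {
  layout <- load_layout(tibble::tibble(
    well = "B02", treatment = "mystery", concentration = 0, unit = "x",
    role = "treated", cells = 10, meal = "m"))
  expect_error(simulate_plate(layout, list(), seed = 1),
               "no simulator config for condition 'mystery'")
})

test_that("adding wells never perturbs existing wells", {
  mk_layout <- function(wells, trts) load_layout(tibble::tibble(
    well = wells, treatment = trts, concentration = 0, unit = "x",
    role = "vehicle", cells = 5, meal = "m"))
  cfg <- sim_config(field_px = c(48, 48), n_cells = 5, duration_min = 10)
  s1 <- simulate_plate(mk_layout("B02", "a"), list(a = cfg), seed = 3,
                       n_images = 1)
  s2 <- simulate_plate(mk_layout(c("B02", "B03"), c("a", "a")),
                       list(a = cfg), seed = 3, n_images = 1)
  expect_identical(s1$wells[["B02_1"]]$truth, s2$wells[["B02_1"]]$truth)
  expect_identical(s1$wells[["B02_1"]]$fluor[[1]]$pixels,
                   s2$wells[["B02_1"]]$fluor[[1]]$pixels)
})

test_that("treated wells lag vehicle wells in expectation", {
  cfg <- sim_config(field_px = c(96, 96), n_cells = 40, duration_min = 60,
                    frame_interval_min = 60, max_events_per_cell = 20)
  ratio_n <- vapply(1:20, function(s) {
    v <- { c2 <- cfg; c2$seed <- s; simulate_well(c2, "V01") }
    tcfg <- cfg; tcfg$rate_modifier <- 0.3; tcfg$seed <- s
    t <- simulate_well(tcfg, "T01")
    c(nrow(t$truth), nrow(v$truth))
  }, numeric(2))
  expect_lt(sum(ratio_n[1, ]), sum(ratio_n[2, ]))
  expect_equal(sum(ratio_n[1, ]) / sum(ratio_n[2, ]), 0.3, tolerance = 0.15)
})
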