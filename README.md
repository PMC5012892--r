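# phagoquant

Quantification of live-cell phagocytosis assays from time-lapse fluorescence
images, with a ground-truthed synthetic plate simulator.

## The problem

Macrophage phagocytosis is routinely measured by feeding cells pH-sensitive
(pHrodo-style) bioparticles: a dye-labelled killed pathogen particle is dark
in the medium and only fluoresces once it is engulfed and delivered to the
acidified phagolysosome. Live-cell imaging platforms image each well of a
plate every few minutes in phase contrast plus one or two fluorescence
channels, so uptake can be followed as a kinetic curve rather than a single
endpoint. Turning those image stacks into numbers requires a reproducible
per-frame segmentation pipeline and per-well kinetic summaries — which is
what this package provides, for anyone who wants the analysis chain in open,
tested code rather than inside a vendor GUI.

## The pipeline

Per fluorescence frame (intensities in "corrected units" `u`, pixel size
`s` in µm/px):

1. **Background correction** — white top-hat transform
   `x − (x ∘ D_r)`, the image minus its grayscale opening by a flat disk of
   radius `r = 20 µm` (`round(r/s)` px). Removes smooth background
   non-uniformity wider than the disk, preserves spots smaller than it.
2. **Thresholding** — foreground iff corrected intensity `≥ 2 u`
   (inclusive).
3. **Labeling** — 8-connected components, deterministic label order.
4. **Edge split** — declumping of regions containing several closely spaced
   objects: seeds are local maxima of the Gaussian-smoothed (σ = 1 px)
   corrected image, thinned to the equivalent diameter of the minimum
   object area; regions with ≥ 2 seeds are re-partitioned by
   marker-controlled watershed so touching spots are counted separately.
5. **Area filter** — objects strictly below `50 µm²` are removed
   (area = pixel count × `s²`).

Phase-contrast frames get a texture-based **confluence mask** (local
variance → Otsu threshold → closing → erosion compensation), reported as
the cell-covered fraction.

Per well, replicate images are averaged at each timepoint and the kinetic
curve `v(t)` is summarised by:

- **slope** — OLS slope of `v(t)/max(v)` over the rising window up to the
  first time `v` reaches `0.9·max(v)` (units 1/min);
- **AUC** — trapezoidal `∫ v dt`;
- **percent of control** — `100 · mean(treated) / mean(vehicle)` at the
  endpoint (vehicle ≡ 100 %), and the matching fold change;
- **phase descriptors** — prominence-filtered peaks and plateau onset,
  separating biphasic uptake (two waves) from saturating uptake.

The `sim_config()`/`simulate_well()`/`simulate_plate()` simulator generates
matching synthetic acquisitions: Poisson engulfment per cell with
Michaelis-type concentration saturation `λ = m·λ₀·c/(c+K)`, an exponential
acidification lag before a particle lights up, Gaussian spot rendering over
a smooth vignette with sensor noise, and an event-level ground-truth log —
so every stage of the pipeline is validated against known truth.

## Worked example

Simulate a three-well plate (vehicle plus a 0.35× uptake inhibitor in
duplicate), analyse it with the default parameters, and normalise to
vehicle:

```r
library(phagoquant)
library(dplyr)

dir <- tempfile(); dir.create(dir)
layout <- load_layout(tibble::tibble(
  well = c("B02", "B03", "B04"),
  treatment = c("vehicle", "cytoD_1uM", "cytoD_1uM"),
  concentration = c(0, 1, 1), unit = "uM",
  role = c("vehicle", "treated", "treated"),
  cells = 50000, meal = "E. coli"))

cfg <- sim_config(n_cells = 40, seed = 11)
configs <- list(vehicle = cfg,
                cytoD_1uM = { c2 <- cfg; c2$rate_modifier <- 0.35; c2 })
sim <- simulate_plate(layout, configs, seed = 11, n_images = 2, out_dir = dir)

run <- analyze_plate(dir, layout = layout, normalize = TRUE)
glance(run)
#> # A tibble: 1 × 5
#>   n_wells n_frames n_objects n_timepoints mean_confluence
#>     <int>    <int>     <int>        <int>           <dbl>
#> 1       3       42       322            7           0.471

tidy(run) |> filter(metric == "object_count") |>
  select(well_id, slope, auc, endpoint)
#> # A tibble: 3 × 4
#>   well_id  slope   auc endpoint
#>   <chr>    <dbl> <dbl>    <dbl>
#> 1 B02     0.0168  648.     26.5
#> 2 B03     0.0193  315      13
#> 3 B04     0.0170  385      13

run$group_summary |> filter(metric == "object_count") |>
  select(treatment, n_wells, endpoint_mean, endpoint_sem, percent_of_control)
#> # A tibble: 2 × 5
#>   treatment n_wells endpoint_mean endpoint_sem percent_of_control
#>   <chr>       <int>         <dbl>        <dbl>              <dbl>
#> 1 cytoD_1uM       2          13              0               49.1
#> 2 vehicle         1          26.5           NA              100
```

Reading the numbers: each well's final-timepoint mean object count (26.5
fluorescent objects per image for vehicle, 13 for the inhibitor wells)
gives the treated group 49.1 % of the vehicle control. At this cell
density engulfed particles frequently sit inside the same cell, so the
*count* metric saturates even with edge splitting; the total integrated
intensity endpoint (`metric == "total_intensity"`, 45.8 % here) is the
more linear readout, and is what the package's validation uses for rate
recovery. `autoplot(run)` draws the per-well kinetic curves;
`write_results(run, out)` writes `objects.csv`, `timeseries.csv` and
`summary.csv`.

A shell entry point wrapping the same functions is installed at
`inst/cli/phagoquant.R`:

```sh
Rscript inst/cli/phagoquant.R simulate --config inst/extdata/example_simulate.toml --out plate/
Rscript inst/cli/phagoquant.R analyze  --images plate/ --layout plate/layout.csv --out results/ --normalize
Rscript inst/cli/phagoquant.R summarize --results results/ --layout plate/layout.csv
```

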