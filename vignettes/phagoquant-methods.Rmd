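---
title: "phagoquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phagoquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagoquant)
```

This vignette is the package's own account of what it computes, the
assumptions behind each step, and the design choices that were genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement model

pH-sensitive bioparticle assays exploit a dye that is quenched at neutral
pH and fluoresces in acid. A particle therefore produces no signal while it
sits in the medium or on the cell surface; it lights up only after
engulfment, once the phagosome has matured and fused with lysosomes into
the acidic phagolysosome. The fluorescence signal in a well is thus a
direct, if lagged, readout of cumulative engulfment, and a time-lapse
imager turns it into a kinetic curve per well.

The analysis chain treats each acquired frame independently:

$$\mathrm{corrected} = x - (x \circ D_r), \qquad
  \mathrm{mask} = [\mathrm{corrected} \ge \tau], $$

where $x \circ D_r$ is the grayscale opening by a flat disk of radius $r$
and $\tau$ is a fixed threshold in the corrected intensity units. Opening
removes any background structure wider than the disk (illumination
vignette, medium autofluorescence) while structures smaller than the disk
— the fluorescent particles — survive in full. The mask is labelled
8-connected, declumped (below), measured, and area-filtered.

## Parameters, units, defaults

| parameter | default | units | role |
|---|---|---|---|
| `tophat_radius_um` | 20 | µm | disk radius of the opening; anything wider is background |
| `threshold_corrected_units` | 2 | corrected units | inclusive foreground cut |
| `min_object_area_um2` | 50 | µm² | strict "below" exclusion; 50 µm² itself is kept |
| `edge_split` | on | — | declumping of touching objects |
| `smoothing_sigma_px` | 1 | px | Gaussian smoothing before seed detection |
| `channel_of_interest` | green | — | which fluorescence channel is quantified |

These defaults are the standard settings of this assay class and are
asserted as such in the test suite. All spatial parameters are accepted in
micrometres and converted per frame via the pixel size, because imaging
platforms differ in magnification; the conversion is
`round(radius_um / pixel_size_um)` px, clamped to 1 px with a warning.
Acquisition exposure times are metadata only and never rescale
intensities, since no rescaling rule can be derived from exposure time
alone.

Two boundary conventions needed a decision and are fixed, documented and
tested rather than left implicit: the threshold is **inclusive** (a pixel
at exactly 2 corrected units is foreground), and the area filter reads
"below 50 µm²" **strictly** (an object of exactly 50 µm² is retained).
Pixel coordinates are 0-based `(row, col)`; bounding boxes are half-open.
Labels are assigned in the order of each component's first pixel in R's
column-major scan, which makes the whole chain bit-reproducible.

## Morphology implementation

Erosion, dilation and opening are computed by vectorised shifted-submatrix
`pmin`/`pmax` over the disk offsets $\{(i,j): i^2+j^2 \le r^2\}$. At the
border the structuring element is clipped to its in-bounds part; with a
symmetric flat element this keeps $x \circ D_r \le x$ pointwise, so the
top-hat residual is non-negative everywhere. The test suite checks the
implementation two independent ways: exact equality with a literal
double-loop sliding-window oracle on small grids, and agreement (to
~1 ulp) with EBImage's compiled dilation via the duality
$\varepsilon(x) = C - \delta(C - x)$. A ramp-plus-plateau fixture checks
the scientifically relevant behaviour — a smooth gradient is removed
exactly while a small plateau survives at full height — and a
translation-equivariance test guards against off-by-one drift.

## Edge split (declumping)

When two particles land close together their thresholded regions merge,
and counting merged blobs as one object underestimates uptake. The
splitter re-partitions each labelled region by marker-controlled
watershed: seeds are the local intensity maxima of the Gaussian-smoothed
corrected image inside the region, greedily thinned so that no two seeds
are closer than the equivalent diameter of the minimum object area
($2\sqrt{A_{\min}/\pi}$, converted to px); pixels are then claimed in
order of decreasing smoothed intensity, each taking the label of its
brightest already-claimed 8-neighbour. The union of children always
equals the parent exactly, so the split changes counts, never foreground
area or total intensity. Regions with at most one seed pass through
unchanged, and disabling `edge_split` makes the operation the identity —
both are asserted in tests.

The seed-separation constraint ties the splitter to the area filter: a
region cannot be split into fragments that the filter would discard as
sub-minimum. Whether the vendor software applies its area filter to
fluorescent objects or only to phase objects is ambiguous; the package
applies it to both by default, switchable via
`apply_area_filter_to_fluorescence`, on the reasoning that sub-50 µm²
fluorescent specks are below single-particle scale and are noise in
either channel. The threshold → label → split order is likewise a
documented choice.

## Confluence mask

The phase-contrast mask is this package's own construction (the assay
platform documents only that cells are masked from background): cells
differ from background mainly in local texture, so the mask thresholds
the local intensity variance. The window half-width is half the top-hat
pixel radius; the threshold is Otsu's, floored at 4× the 5th-percentile
variance. The floor matters: on a cell-free noise field the variance map
is unimodal and tightly concentrated (its max is about twice its low
quantile), and Otsu — which always splits a histogram — would otherwise
hallucinate confluence. The variance response extends roughly one window
half-width $h$ beyond the true texture edge; after closing (disk 2 px)
the mask is eroded by $h - 2$ px, the 2 px being where the Otsu cut
already falls inside the soft shoulder of the response. This geometry was
validated against simulator ground-truth coverage (~30 % fields agree
within ±0.05) before being frozen. The confluence fraction feeds
reporting only; fluorescence metrics never depend on it.

## Kinetics

Replicate images within a well are averaged per timepoint; wells are the
unit of replication for all downstream statistics (mean ± SEM across
wells in group summaries).

The **slope metric** is defined here as the OLS slope of the
max-normalised curve over the rising window — from the first timepoint to
the first timepoint reaching 90 % of the maximum — in units of
fraction-of-max per minute. Vendor software reports a "slope" for such
curves without a published formula or units, so this package defines its
own and does not attempt to match vendor numbers; scale invariance
(multiplying the curve by any $c>0$ leaves the slope unchanged) and time
rescaling (doubling timestamps halves it) are asserted as properties.
A curve with non-positive maximum, or whose rising window degenerates to
one point (e.g. a constant curve), has slope 0 by convention.

**Phase detection** smooths with a centred 3-point moving average, then
reports interior local maxima with topographic prominence at least
`min_prominence_frac` (default 0.2) of the smoothed maximum, and the
plateau onset: the first time from which successive smoothed changes stay
within `plateau_eps_frac` (default 0.02) of the maximum for at least
`plateau_len` (default 3) intervals *through the end of the series* — a
genuine "stays flat", not a momentary pause. These defaults separate the
two qualitative regimes this assay class produces over long runs:
biphasic uptake with two waves (e.g. peaks near 4 h and 24 h) versus
saturating uptake that plateaus within hours and stays flat.

**Normalisation** follows the convention of expressing treated groups
against the vehicle group at an endpoint (default: the final timepoint):
`100 · mean(treated) / mean(vehicle)`, so vehicle ≡ 100 % exactly and a
reduction reads as `100 − result`.

## The simulator

`simulate_well()` is a test harness, not a biological model. Its
mechanism is the simplest one that reproduces the qualitative features of
real assays: each of `n_cells` cells (placed uniformly with minimum
centre separation of one cell radius) accrues engulfment events as a
homogeneous Poisson process with rate
$\lambda = m \cdot \lambda_0 \cdot c/(c+K)$ — a Michaelis-type saturation
in bioparticle concentration $c$, with $m$ the inhibitor/opsonin rate
modifier — capped at `max_events_per_cell`. Each event becomes visible
after an exponential acidification lag (mean 15 min by default),
encoding the phagolysosome-activation mechanism of the dye; it is then
rendered as an isotropic Gaussian spot (σ = 3 px, peak 10 units = 5× the
detection threshold) at a uniform position inside its cell. Frames add a
smooth quadratic vignette (amplitude 1 unit) and Gaussian sensor noise
(sd 0.2 units), and are clipped at zero. Defaults mirror the standard
acquisition of this assay class — images every 10 min for 1 h, 2 µm/px —
and a 200 µg/ml dose on a saturation scale of $K$ = 100 µg/ml.

Randomness design: one root seed; each (well, image) stream is derived by
a stable hash of the well id and image index, so adding wells to a plate
never perturbs existing wells. Identical seeds give bit-identical frames,
CSVs and TIFFs, which the suite asserts by checksum.

What the simulator deliberately does **not** model: optics (no PSF,
aberration or shading beyond the vignette), cell motility and division,
multi-stage phagosome maturation, photobleaching (an optional exponential
decay term exists, off by default, to emulate long-run biphasic shapes),
and spot amplitude variability. Tests passing on simulated data therefore
demonstrate that the *pipeline* recovers known truth under controlled
conditions — they do not certify performance on real micrographs, where
debris, uneven focus and heterogeneous particle load add failure modes
the simulator does not produce.

## Validation scenarios and problem sizes

The acceptance suite and `scripts/acceptance.R` use these study
conditions, chosen to exercise each claim at desk scale:

- *Morphology*: 200 random grids up to 64×64, disk radii 1–6 px, against
  the independent opening oracle.
- *Detection exactness*: frames qualify when every visible spot is > 4σ
  from every other and from the border (the regime in which "counts equal
  truth exactly" is the right contract); 50 qualifying frames are drawn
  from a deterministic seed sequence at 4 cells/field, 128×128 px.
- *Edge split*: 100 two-blob clumps, centres 8 px apart, σ = 3 px,
  amplitude 10, mild noise; ≥ 95 must split into exactly two objects each
  containing its generating centre, and all 100 must stay single with the
  splitter off.
- *Rate recovery*: 20 seeds × (modifier 1.0 vs 0.3), 120 cells in
  192×192 px, endpoint **total integrated intensity** as the
  percent-of-control readout. Intensity rather than count is used here
  because two events in one cell often land within the seed-separation
  distance, where counts saturate but integrated fluorescence stays
  additive; the recovered percent must lie within 15 % relative of 30 %.
- *Dose dependence*: 5 concentrations spanning the saturation curve
  (10–1000 on $K$ = 100), 20 seeds each; endpoint means must increase
  with dose and the per-concentration efficiency must fall — saturating,
  not linear.

These sizes keep the full suite in the low minutes while leaving the
statistical margins (binomial and Poisson standard errors) several-fold
inside the asserted tolerances.

## Known limitations

- The threshold applies to whatever intensity units the input carries
  after correction; no absolute radiometric calibration is attempted, and
  TIFF round-trips use a documented fixed full-scale of 256 units at
  16-bit (quantisation 0.004 units).
- Object counts are biased low at high spot density even with edge
  splitting (nearby spots inside one cell merge below the seed-separation
  distance); use the integrated-intensity metric when linearity matters.
- The confluence mask assumes texture-rich cells on smooth background;
  flat, spread cells with little phase texture will be under-masked.
- No per-cell assignment of fluorescent objects, no 3-D, no vendor
  archive ingestion: frames enter as plain single-plane TIFFs under the
  documented naming convention.
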