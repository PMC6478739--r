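---
title: "Simulating forest cover change scenarios and their carbon consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating forest cover change scenarios and their carbon consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sspforest)
```

## The problem

Shared socioeconomic pathway (SSP) databases project how much forest a world
region will hold at future dates, but only as quantities: a pathway says the
region gains 38 million ha by 2050, not *where*. Impact analysis — carbon
accounting, biodiversity exposure, protected-area monitoring — needs maps.
`sspforest` closes that gap with a demand-driven, pattern-based land-change
simulation: it learns *where* forest change has historically happened from a
pair of observed land-cover epochs, converts the regional SSP trajectory into
per-country net change demands, places those demands on the pixels most prone
to change, and then prices the resulting map in aboveground forest carbon
stock (AFCS).

The pipeline has six stages, each exposed as ordinary functions:

1. **Reclassification** (`reclassify_to_fnf`): a class-coded land-cover grid
   (ESA-CCI dialect, 300 m) becomes a binary forest/non-forest (F/NF) map.
   Tree-cover classes 50, 60–62, 70–72, 80–82, 90, 160 and 170 count as
   forest; any unknown code is a hard error.
2. **Change detection and demand** (`detect_change`, `historical_shares`,
   `allocate_demand`): each country's share of the region's historical loss
   (or gain) becomes its share of the projected regional net change. Pixel
   demands are rounded by largest remainder so the regional pixel total is
   conserved exactly.
3. **Drivers** (`build_driver_stack`): seven continuous predictor grids —
   elevation, slope (Horn's method), Euclidean distance to roads, to urban
   areas, to past change, distance to the forest edge (inward for loss
   models, outward for gain models), and the province's historical change
   share.
4. **Transition potentials** (`draw_samples`, `train_tpm`): per country and
   direction, a single-hidden-layer back-propagation network is trained on
   balanced samples of changed vs. eligible-but-persistent pixels and emits a
   change probability for every eligible pixel (prior 0.5 by construction).
   Validation uses the Skill Measure.
5. **Allocation** (`allocate`, `mosaic`): the demanded number of pixels flips,
   highest potential first, with seeded tie-breaking; countries are mosaicked
   back into the regional 2050 map. Forest never replaces urban or water.
6. **Carbon** (`classify_forest`, `project_acd_2050`, `afcs_loss_projected`,
   `afcs_gain_projected`, `annualize_and_convert`): forest is sub-classified
   by age, carbon density is grown to 2050 with class-specific sequestration
   rates, and zonal ledgers are summed.

`run_scenario()` chains all six and returns a classed result with `print`
and `summary` methods.

## The transition model and its validation

For each country and direction the model is a feed-forward network with one
hidden layer (width `max(3, ceiling((k+1)/2))` for `k` retained drivers,
logistic activations, weight decay 5e-4, at most 200 iterations — all
configurable). Drivers are z-scored over the country's eligible pixels;
zero-variance drivers are dropped with a warning. Equal numbers of changed
and persistent pixels are sampled (default `min(pool, 10000)` per class) and
split 50/50 into training and testing halves, so chance-level test accuracy
is 0.5.

Model skill is summarised by

$$\mathrm{SM} = \frac{A - E(A)}{1 - E(A)}, \qquad E(A) = \frac{1}{T+P},$$

with `A` the measured test accuracy, `T` the number of transitions and `P`
the number of persistence classes in the sub-model (here `T = P = 1`). SM is
1 for perfect prediction, 0 at chance and −1 at total failure; it corrects
accuracy for the number of classes, which makes sub-models comparable.

**No target leakage.** Two of the seven drivers are derived from change
itself (distance to past change; the province share), and a third (edge
distance) from a forest map. These are always measured *before* the
calibration interval: edge distance on the start epoch of the calibration
pair, distance-to-change and province shares on the preceding period. If the
drivers were instead computed from the calibration pair, distance-to-change
would be zero exactly at the pixels being predicted and the model would
appear perfect while learning nothing. The package's null-model test (change
uncorrelated with any driver must give SM ≈ 0) guards this property.

When a country's calibration pools contain fewer than two changed or two
persistent pixels (possible on small synthetic landscapes), its model is
trained on the regional balanced samples instead, with a warning; its
potentials are still predicted from its own pixels' drivers.

## Demand semantics

A scenario carries only a *net* regional change (the SSP source reports net
areas), so a run is either all-loss or all-gain — the package never mixes
directions within a scenario, and a single 2015→2050 step is simulated with
no intermediate years. Demands below the eligible pool are satisfied
exactly; a demand exceeding the pool flips the whole pool and reports the
shortfall rather than inventing change elsewhere.

The bundled `asia_ssp_table()` emulates the Asian-region baseline
trajectories: +38 Mha (SSP1) and −10 Mha (SSP3) over 2015–2050 as reported;
the intermediate pathways (+28.5, +20.6, −6 Mha for SSP2/4/5) are scaled
from the reported ordering of Southeast-Asian net changes since their
regional values are not printed. The 600 Mha base area is a round figure —
only differences between years enter the analysis.
`synthetic_ssp_table(area_2015_ha)` rescales the table to a toy landscape so
relative demands stay realistic (a few percent of the forest area).

## The carbon model

All carbon arithmetic is in Mg C internally; ledgers report Tg C
(1 Tg = 10⁶ Mg). Carbon density is `ACD = 0.5 × AGB` (Mg C ha⁻¹), and a
300 m cell is 9 ha.

Forest is sub-classified from three inputs — an intact-forest-landscape
(IFL) mask, the reference-epoch ACD and a carbon-sequestration-rate (CSR)
table stratified by forest class × ecozone × geography
(continental/insular):

* **old growth**: forest inside the IFL with ACD at or above a floor
  (default 100 Mg C ha⁻¹; set `ifl_only = TRUE` to use IFL membership
  alone);
* otherwise the stand age is the inverse of the young accumulation model,
  `age = ACD / CSR_young`; ages ≤ 20 yr are **young secondary** (the age is
  kept per pixel), older stands are **old secondary** (minimum age 21 yr).

Because degradation is not modelled, a degraded old stand with low ACD
classifies as young — a conservative bias acknowledged by design. The old
secondary → old growth transition is not modelled (no age threshold
separates them).

Projection to 2050 uses the stratum CSRs:

* old classes grow linearly for the 40-yr period from the carbon-density
  epoch (2010) to 2050: `ACD₂₀₅₀ = ACD + CSR × 40`;
* young stands grow in two phases: at their young rate until age 21
  (`ACD₂₁ = ACD + CSR_young × (21 − age)`), then at the old-secondary rate
  for the remaining `40 − (21 − age)` years — the transition into old
  secondary during the projection window;
* newly gained forest is credited `CSR_young × 17.5` — trees are assumed
  planted uniformly across the 35-yr scenario window, so the average stand
  is half the window old.

Deforestation is assumed to occur at the horizon, so lost pixels are priced
at their full projected 2050 density. Zonal ledgers sum `ACD × area` over
loss (or gain) pixels by country, province, forest class, IFL and protected
area; provinces partition countries and classes partition the forest, so
ledger sums are exact by construction and tested as such. Totals annualise
over the 35-yr window and convert at 3.67 Mg CO₂ per Mg C.

**CSR values.** The stratum-specific rates are measurement inputs the
package cannot supply; `default_csr_table()` ships documented placeholders
(young secondary 3.0, old secondary 1.2, old growth 0.5 Mg C ha⁻¹ yr⁻¹,
with ±10%/±5% ecozone/geography variation) that respect the ecological
ordering young > old secondary > old growth enforced by the validator.
Replace them with measured rates for real analyses; every result scales
accordingly.

## The synthetic landscape generator

`generate_landscape()` builds the full co-registered input set on an
equal-area grid with constant cell area (no geodesy): a smoothed
random-field elevation (and Horn slope), Bresenham-rasterised road
polylines, road-adjacent towns and a water mask kept disjoint from them,
Voronoi countries sub-partitioned into nested Voronoi provinces, ecozone and
continental/insular labels, a protected-area disk and an intact-forest core
inside the final forest.

The land-cover series (default three epochs, labelled 1992/2005/2015)
evolves under a *known* logistic change process: per step, `loss_frac`
(default 0.05) of the forest is lost and `gain_frac` (default 0.02, also
relative to forest count) is gained, with selection weights
`σ(β₀ + β_road z_road + β_edge z_edge)` over z-scored distances (defaults
β = −1.5, concentrating change near roads and edges as in real
deforestation frontiers). Changes are drawn as an exact count by weighted
sampling without replacement, so requested fractions are honoured exactly
while the spatial pattern follows the logistic. Losses only come from
forest; gains never land on urban or water — asserted exhaustively in
tests.

Stand ages are planted (1–40 yr) and biomass is built to invert exactly:
`AGB = 2 × age × CSR_young`, so `ACD / CSR` recovers the planted age
pixel-perfectly when the lognormal noise parameter is 0 (the default;
increase `agb_sigma` for robustness experiments). Intact-forest pixels get
ACD 1.5 × the old-growth floor.

What the generator does *not* emulate: realistic road topology, terrain-
correlated land-cover, sensor artefacts, mixed-severity degradation,
within-period demand fluctuations. Passing tests therefore demonstrate the
*mechanics* (conservation, ordering, inversion, learnability) on data whose
generating process is known — not predictive skill on real landscapes.

## Numerical and design choices

* Pixel counts are the internal currency; hectares appear only at reporting
  time (`area_of(n, cell) = n·cell²/10⁴`). Largest-remainder rounding makes
  country pixel demands sum exactly to the regional demand.
* Allocation ties are broken by a seeded uniform key attached to each pixel,
  so reruns are bit-identical and growing demand nests previous selections.
* A pixel that is nodata in either epoch is nodata in the change grid — no
  change claims without two observations.
* Edge distances use the nearest-other-class convention: a boundary pixel is
  one cell (not zero) from the other class, avoiding a degenerate
  zero-variance predictor along the boundary.
* Slope uses Horn's 3×3 kernel with linear-extrapolation padding, so edge
  pixels reduce to one-sided differences and a planar ramp has constant
  slope everywhere.
* All stochastic stages (field generation, change draws, sampling, network
  initialisation, tie-breaking) take explicit seeds derived from one master
  seed; a scenario result is reproducible from its manifest.

Test and example problem sizes are 32×32–64×64 for exact-arithmetic checks
and 128×128 for the statistical recovery experiments — large enough for a
few thousand balanced samples per model, small enough to iterate quickly.

## A worked run

```{r run, eval = FALSE}
b <- generate_landscape(c(64, 64), cell_size = 300, seed = 7)
scn <- run_scenario(b, scenario = "SSP3", seed = 3)
summary(scn)
afcs_report(scn$ledger, n = 5)
```

`summary()` prints the per-country demands, the allocation log (demanded =
realised when the pool suffices), the per-country Skill Measures, and the
regional AFCS change with its annual rate and CO₂ equivalent.
`afcs_report()` ranks zones by absolute AFCS change with percentage shares
of the regional total.

## Known limitations

* Net-change-only scenarios; gross loss and gain cannot co-occur in one run.
* One allocation step to the horizon; no intermediate-year dynamics.
* Purely rank-based allocation: no contiguity or patch-size constraints.
* The carbon model covers aboveground live biomass only — no soil,
  belowground or dead pools, and no pre-deforestation biomass increment.
* Placeholder CSRs until users supply measured rates.
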