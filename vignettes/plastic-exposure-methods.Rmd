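---
title: "Methods: mapping marine plastic exposure risk from seabird tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping marine plastic exposure risk from seabird tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the statistic

Petrels and other highly pelagic seabirds range across entire ocean
basins, forage at the surface, and frequently ingest floating plastic.
Where, and under whose jurisdiction, are they most at risk? `plasticrisk`
answers this with a relative co-occurrence statistic. Let $u_i$ be a
bird utilisation distribution and $p_i$ a plastic density layer, both on
a common $1^\circ \times 1^\circ$ global grid and both normalised to unit
sum. The exposure risk score is

$$ E = 10^6 \sum_i u_i \, p_i, $$

the cellwise product summed over the grid and scaled by $10^6$ for
readability. $E$ is dimensionless and bounded by $[0, 10^6]$; the
maximum occurs only when both distributions occupy the same single cell.
It is *not* an ingestion rate: it measures how strongly time spent at
sea co-locates with floating plastic, under the assumption that density
of regularly-sampled tracking locations is proportional to time spent,
and time spent to opportunity for exposure.

A useful yardstick is the uniform-plastic reference: if plastic were
spread evenly over the $N$ grid cells that have a plastic estimate, any
bird distribution supported on those cells would score exactly
$10^6 / N$. Scores above the reference mean the birds use
above-average-plastic waters.

## From raw locations to utilisation distributions

Tracking data mix three device types with very different error
structures: GPS (sub-km), Argos PTT (km to tens of km) and light-based
geolocators (GLS, roughly 200 km). The cleaning stages, in the fixed
order applied by `preprocess_tracks()`:

1. **Standardise**: sort by individual and time, drop duplicate
   timestamps (first kept), wrap longitudes to $[-180, 180)$.
2. **Equinox stripping** (GLS only): latitude from day length is
   unresolvable near the equinoxes, so fixes from 21 d before to 7 d
   after 20 March and 7 d before to 21 d after 22 September (bounds
   inclusive, UTC) are removed — unless the dataset was already
   corrected upstream (e.g. via sea-surface temperature), in which case
   it passes through. The fixed calendar dates are adequate because the
   window widths dwarf the ±1 d astronomical drift of the true equinox.
3. **Speed filter** (GPS/PTT only): a forward pass drops any fix whose
   implied speed from the previously *retained* fix strictly exceeds
   90 km/h; after a drop, the next speed is computed from the last
   retained fix, so a single spike cannot cascade.
4. **Colony buffer**: fixes closer than 5 km (GPS) or 15 km (PTT) to
   the colony are removed — colony attendance is not at-sea habitat
   use. GLS fixes are never trimmed; their error exceeds any sensible
   buffer.
5. **Resampling**: GPS/PTT tracks are linearly interpolated in time and
   resampled every 12 h from each individual's first to last retained
   fix, matching the native GLS frequency of two fixes per day so that
   location density means time, not logging rate. Longitudes are
   unwrapped before interpolation, so antimeridian crossings interpolate
   the short way round. Interpolation is linear in lon/lat — at 12-h
   petrel step lengths the departure from the great-circle path is
   negligible, and the function is isolated so a geodesic interpolator
   could be swapped in. Gaps of any length within one deployment are
   spanned; whole months of interpolated sparsity are caught later by
   the five-locations rule.

The pipeline is idempotent: re-running it on its own output changes
nothing, which the suite asserts.

Locations are then pooled per population across individuals and years by
calendar month, and any population-month with fewer than five locations
is dropped (`month_filter()`).

For each retained population-month, `monthly_uds()`:

* centres a spherical Lambert azimuthal equal-area projection on the
  month's spherical centroid (the normalised mean of location unit
  vectors);
* estimates a fixed-bandwidth bivariate Gaussian kernel density with
  $h = 200$ km (the scale of GLS error; a 50 km option mirrors
  high-frequency GPS work) on a 10 km grid whose cell centres lie on
  multiples of the cell size, extended 6 bandwidths beyond the data.
  The margin choice is numerical: truncating at 3 bandwidths loses
  about 1% of kernel mass ($e^{-9/2}$ radially), while 6 keeps
  truncation below $2 \times 10^{-8}$, so per-cell masses behave as
  exact Gaussian integrals at the tolerances the tests use. The kernel
  is separable, so the grid is computed as an outer product — identical,
  cell for cell, to the brute-force sum over points;
* keeps the 95% isopleth: the smallest set of highest-density cells
  holding 95% of the mass, ties broken in stable cell order. Interior
  density values are retained (not flattened), preserving graded
  time-spent structure inside the home range;
* zeroes cells whose centre back-projects onto land (these species do
  not forage terrestrially), using cell centres rather than polygon
  intersection for determinism and speed;
* adds each fine cell's mass to the $1^\circ$ cell containing its
  centre ($[i, i+1)$ half-open, indexed by south-west corner). Mass is
  conserved exactly; monthly grids stay *unnormalised* so that
  normalisation happens exactly once, at scoring time.

## Breeding phenology from distance to colony

Seasonal splits need month labels. For each population,
`monthly_colony_stats()` computes per-month mean and minimum distance to
the colony over all pooled locations. The distance rule
(`classify_months()`): a month is non-breeding if its mean exceeds the
grand mean of the tracked monthly means, or if no location came within
200 km of the colony; ties on the grand mean count as breeding (the rule
is strictly "greater than"), so a single tracked month is breeding.

`smooth_labels()` then enforces a coherent annual cycle on the cyclic
month sequence (December adjacent to January, untracked months skipped):
an isolated month flanked by the opposite label is flipped, in calendar
order with in-place updates, repeated to a fixed point. Sequential
updating matters: flipping all isolated months simultaneously oscillates
forever on alternating sequences, whereas each in-place flip removes two
label boundaries, so the pass provably terminates. Because a year should
contain one breeding and one non-breeding season, residual multi-run
patterns (which the isolated-month rule cannot fix, e.g. two separate
two-month stints) are collapsed by flipping whole runs, shortest first,
earliest on ties, until one cyclic run of each label remains.

Published schedules, where available, take precedence
(`reconcile_with_published()`) with a single override: a month published
as breeding in which the tracked birds demonstrably did not attend
(minimum pooled distance ≥ 200 km) takes the distance-rule label. Months
without a published value use the inferred label. The package reports
which source each final label came from, and
`phenology_sensitivity()` quantifies how much the choice matters by
rank-correlating seasonal scores computed under each labelling.

## The plastic layer

Three published Lagrangian transport models provide global
$1^\circ$ grids of floating plastic density (pieces km$^{-2}$). Their
estimates differ on a log scale, and surface concentrations through time
are approximately lognormal, so the central tendency across models is
the per-cell **geometric mean** (`combine_models()`), which is also
robust to any single model's high outliers. Missing-data fallback per
cell: three values → geometric mean of three; two → of two; one → that
value; none → missing. A zero from any contributing model yields zero
(zero means "no plastic predicted", not "unknown"). The band at
0–1°W — corrupted by the models' 180°-centred native storage — is
imputed per latitude row from the arithmetic mean of the non-missing
values among the six cells at 177–180°E and 1–4°W (`impute_band()`;
imputation runs after combination, which is equivalent for fully
observed rows and simpler). The combined layer is finally normalised to
unit sum. Scores are therefore invariant to any positive rescaling of
the raw densities, which the suite asserts.

## Scores, aggregation and weighting

Per population-month: normalise the monthly grid, multiply cellwise by
the normalised plastic layer, sum and scale by $10^6$. Bird mass sitting
on plastic-missing cells contributes zero; the lost mass fraction is
attached to every map so users can judge coverage. Aggregation:

* **Season score** = mean of that season's monthly scores (a season with
  no tracked months is absent, not zero).
* **Population score** = mean over *all* tracked months (not
  season-balanced), so populations with different tracking durations are
  comparable. Population maps are the matching month-means.
* **Species score** = population-size-weighted mean of population
  scores, with a coverage factor of 0.5 for populations tracked only in
  the breeding season (otherwise scores would be biased towards
  colony-adjacent waters). Missing sizes trigger an equal-weight
  fallback, with a warning. Species grids weight populations by size
  *after* per-population normalisation, so a population contributes in
  proportion to its size rather than to its tracking effort — the
  alternative (weighting raw grids) would let heavily tracked
  populations dominate.
* **All-species map**: species grids summed with weight 1 (tracked in
  both seasons) or 0.5 (breeding-only), renormalised, multiplied by the
  plastic layer.
* Shares of the total score per IUCN threat category, and a
  species-richness map (count of species with positive 95%-UD mass per
  cell), complete the species-level products.

## Jurisdictional attribution

`assign_cells()` assigns each $1^\circ$ cell to the first jurisdiction
polygon (EEZ, theoretical EEZ, or joint regime) containing its centre;
no polygon means high seas. Centre-point assignment is the
resolution-limited approximation appropriate at $1^\circ$; boundary
cells belong wholly to the centre's polygon, and ties resolve to the
earlier polygon in file order. `partition_score()` credits each cell's
exposure to its jurisdiction, splitting joint-regime cells evenly among
their sovereigns; shares sum exactly to the total.
`breeding_country_linkage()` then reports, per population, the fraction
of exposure inside the breeding country's own jurisdiction versus the
high seas and other states — the quantity that shows whether exposure
risk is a domestic or an international problem for each breeding state.

## The synthetic world

Real multi-colony tracking compilations are restricted-access, so the
package ships a seeded generator whose outputs have the statistical
features the pipeline's rules react to — no more.

* `build_world()`: rectangular toy continents; an ocean plastic field
  that is lognormal cell noise (log-sd 0.8 around a background of
  200 pieces km$^{-2}$) plus Gaussian gyre-like hotspots added in log
  space (default: one hotspot of amplitude $\log 60$ and scale 1500 km
  in the eastern North Pacific); three model missing-masks built from
  polar coverage bands of different extents (so cells missing in exactly
  one, exactly two and all three models all exist) plus 2% random
  dropout; and a toy jurisdiction layer of two EEZs, a theoretical EEZ
  and one two-sovereign joint regime, all rectangles — partition logic
  is topology-independent, so rectangles test it fully.
* `derive_model_layers()`: truth × independent cellwise lognormal noise
  with median 1 (log-sd 0.5), masked per model. The per-cell geometric
  mean across layers is therefore a consistent estimator of the truth,
  which a Monte-Carlo test over 200 seeds verifies.
* `simulate_population_tracks()`: breeding months are central-place
  trips — colony distance rises and falls sinusoidally over each trip
  with a random-walk bearing, never exceeding the foraging range before
  location error; short colony-attendance bouts separate trips.
  Non-breeding months are stationary AR(1) scatter around a wintering
  centroid. Fixes are taken on the device schedule through one calendar
  year and perturbed by isotropic Gaussian error. This is the simplest
  process with central-place structure; it makes no claim to behavioural
  realism (no area-restricted search, no wind, no memory), and
  passing tests say nothing about such features of real data.
* `demo_world()`: two species, three populations (one year-round GLS
  population wintering in low-plastic waters, one breeding-only GPS
  population, one GLS population wintering inside the hotspot),
  roughly 43,000 raw locations. It deliberately exercises every
  cleaning rule: equinox-window GLS fixes, at-colony GPS fixes,
  injected teleport spikes for the speed filter, a stray
  three-location month for the five-locations rule, and a published
  schedule that labels one post-departure month as breeding so the
  reconciliation override fires.

All generators are pure functions of (seed, parameters); the same seed
reproduces byte-identical worlds and tracks.

## Numerical choices and degenerate inputs

* Distances: haversine on a 6371 km sphere throughout.
* Normalisation refuses all-missing or non-positive grids; exposure
  refuses unnormalised inputs rather than silently renormalising.
* Degenerate spherical centroids (antipodally symmetric sets) fall back
  to the first point with a warning.
* Isopleth ties at the 95% boundary include the tied cell that first
  reaches the level in stable cell order.
* Single-location tracks cannot be interpolated and are dropped with a
  warning.
* Scores are reported at one decimal place at or above 1 and four
  significant figures below 1; full precision is kept internally.

## Problem sizes and limitations

The shipped tests run the full pipeline on the demo world (3
populations, ~43k raw locations, 28 population-months of kernel UDs on
10 km grids) in well under a minute on one core; the brute-force KDE and
point-in-polygon oracles run on reduced grids (tens of cells per axis,
$\le$ 64800 points) sized for exactness checks rather than realism.

Known limitations: the plastic layers are static 2014-era model outputs,
so interannual plastic dynamics are out of reach; exposure is
co-occurrence, not dose; centre-point jurisdiction assignment
mis-attributes sub-cell boundary detail; fixed-bandwidth KDE ignores
device-specific error differences after resampling; and the movement
simulator is a testing instrument, not a behavioural model — results on
synthetic data validate the *pipeline*, not ecological conclusions.
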