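---
title: "The momentum framework: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The momentum framework: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nismomentum)
```

## The model

The framework treats basin-scale invasion as a sequence of discrete
occupation events. A species' record table is reduced to its *momentum
sequence*: the first record in each country, ordered in time, indexed
t₀, t₁, …, tₓ. Presence is boolean at the country (EEZ) level — once a
country is occupied, later records there carry no new information. Three
assumptions are implicit and worth stating:

- **Detection equals arrival.** A first record marks the occupation of a
  country. Detection lag is real (and simulable with the generator's
  `detect_lag`), but the analysis takes the record years at face value.
- **Country-level resolution.** Spread within a country is invisible;
  two species entering the same country at opposite ends are equivalent.
- **Cross-species pooling.** The delta-of-momenta statistics pool year gaps
  over species at a fixed transition index, so the "typical" pace at step k
  is a population summary, not a per-species model.

From the sequences we compute, per transition k, the pooled sample of gaps
Δt(k)−t(k−1) and summarize it with the empirical-CDF median. These samples
are strongly right-skewed (rare decades-long stalls coexist with frequent
same-year jumps), which is why the median, not the mean, is the location
summary throughout; the mean is never used for inference. Prefix sums of
the step medians produce the cumulative median spread curve: the central
estimate of years from basin entry to momentum k.

## Scenarios and the dominant hotspot

Two sample restrictions are supported. Scenario (1) pools every species.
Scenario (2) restricts each transition's sample to the *dominant hotspot*:
countries are ranked by their record count at momentum k (ties broken
alphabetically by code, for determinism) and the minimal prefix whose
cumulative share strictly exceeds 50 % is selected. The strictness matters
at the boundary: a 50/50 split selects both countries.

The restriction is applied per transition: a species contributes its
Δt(k)−t(k−1) gap under scenario (2) only if its momentum-k record lies in a
country selected at momentum k. This is one of several defensible readings
of a hotspot-restricted sample (one could instead filter on the k−1 end, or
require whole-trajectory membership); filtering at the destination momentum
keeps each transition's sample aligned with the hotspot polygon drawn for
that same momentum, which is what the trajectory uses. The per-step
percentage deviation between the two scenarios' medians
(100·|m₁−m₂|/m₁, reference scenario (1)) quantifies how much the
restriction distorts the temporal signal; the reference scenario is
configurable since either convention is defensible.

## Spatial construction

Hotspot geometry is driven by country membership, never by record
coordinates: the selected countries' polygons are unioned and dilated by a
buffer in planar degree space, and the trajectory vertex is the
area-weighted (Green's theorem) centroid of the result. Decisions here:

- **Buffer default 1°, legal band 1°–3°.** The band is the documented
  expansion range for encompassing neighbouring polygons; with no stated
  rule for choosing within it we default to the minimum and accept either a
  scalar or a per-momentum schedule. Values outside the band warn (or error
  under `strict`), since a sub-degree buffer fails to bridge adjacent EEZs
  and a super-3° buffer smears regions together. The buffer used is recorded
  on every trajectory point and in all outputs.
- **Planar degree-space geometry.** Union, dilation, area and centroid are
  computed on lon/lat as if Cartesian. At Mediterranean latitudes (≈30–46°N)
  a degree of longitude is 0.7–0.8 of a degree of latitude, so planar
  centroids sit slightly east/west of their geodesic counterparts; the
  discrepancy is far below the EEZ-polygon coarseness and matches how such
  layers are commonly processed in a GIS over geographic coordinates.
  Great-circle distance *is* used where distances are compared
  (endmost-centroid matching), via the haversine formula.
- **Round joins, arc tolerance.** Dilation uses round joins with an arc
  sagitta tolerance of buffer/1000, which keeps the polygonal approximation
  of circular arcs within ~0.5 % of the true dilated area — an order of
  magnitude tighter than the raster oracle the tests compare against.
- **Degenerate inputs.** Zero-area geometry is rejected by the centroid
  (explicit error), an empty selection or empty clip result is an error
  naming the momentum, and trajectory construction refuses gaps in the
  momentum index sequence.

The packaged EEZ layer is a deliberately coarse synthetic stand-in
(rectangles and simple quads, one per country); it preserves adjacency and
east-to-west ordering of the real Mediterranean EEZs but nothing else, so
trajectories computed from it are structurally faithful and numerically
approximate. A loader accepts any GeoJSON FeatureCollection keyed by
country code for real Marine Regions geometry. Our region table assigns
each multi-basin country (Greece, Italy, Tunisia, Libya) an ordered MSFD
membership list and a configurable default (GR→EMED, IT→CMED, TN→CMED,
LY→EMED); records may override the default per row. Montenegro is coded ME
and Malta sits in the Central Mediterranean only.

## Temporal validation

The validation score for a species with actual invasion duration *a* and
curve-inferred duration *b* is 100·min(a,b)/max(a,b). This formula is a
design choice of this package: it is symmetric, bounded by 100, monotone as
the inferred duration approaches the actual one — and it reproduces the
three published reference values exactly from their printed duration pairs
(15 vs 13.5 → 90; 17 vs 19.5 → 87.2; 19 vs 13.5 → 71 at integer
precision), which is how it was identified. Durations count both endpoint
years (2008–2022 is 15 years). The moving-average centroid uses a trailing
window of up to five available record-years (a centered window is available
by flag); "available" matters — years without records are skipped, not
zero-filled. Endmost-centroid matching is nearest-neighbour under
great-circle distance with ties to the lower momentum; no distance
threshold is imposed, so the diagnostics should be inspected when the
nearest centroid is far. The trajectory verdict is a net-displacement sign
test (north and west of the first moving-average centroid); an
angular-sector rule is available when a different drift direction is under
test.

## The synthetic generator

The generator emulates exactly the structure the analysis consumes: each
species enters at the head of an ordered country chain in a uniform random
year, then advances one country per momentum with i.i.d. integer gaps
(fixed, geometric on {0, 1, 2, …}, or an arbitrary discrete table —
geometric p = 0.4 by default, giving frequent same-year jumps and a median
gap of 1 year, a right-skewed shape of the kind the method is built for),
truncated per species to plant a known establishment fraction. It does
*not* emulate: branching or backtracking trajectories, spatially
heterogeneous detection effort, correlated gaps between species sharing a
vector, or within-country coordinates for the spread table. Passing tests
therefore demonstrate correct recovery of a stepping-stone process with
known truth — not that real record tables satisfy the model's assumptions.
Detection lag is off by default and additive per record when enabled. All
generation is seeded and leaves the caller's RNG state untouched; identical
config and seed give byte-identical CSV output.

Sizes used in the shipped tests: oracle sweeps use 1,000 fuzzed multisets
(median), 200 random simple polygons (centroid) and 500 random count
vectors (hotspot minimality); parameter recovery runs 500 species with
geometric(0.4) gaps on a seven-country chain, where the central-order-
statistic window of the sample median (±3/(2√n) in quantile space) pins the
recovered median to the true value of 1; the end-to-end determinism check
runs the full pipeline twice on the packaged 20-species fixture. These
sizes were chosen so the whole suite runs in well under a minute while the
order-statistic bounds remain tight.

## Other numerical choices

- Sample medians are the standard midpoint-of-central-order-statistics
  median, so fractional half-year values are legitimate curve outputs.
- Same-year first records of one species in two countries are ordered by
  input row order (`source_rank`), which is recorded on every cleaned
  record; the ordering is deterministic and permutation-stable.
- Deduplication removes exact (species, country, year) triples only;
  momentum assignment then keeps the earliest record per country.
- Steps whose delta sample has a single observation still report a median
  (the value itself) but are flagged `low_n`.
- A transition with an empty sample truncates the curve rather than being
  interpolated.
- Pipeline outputs carry no timestamps, so reruns on identical inputs are
  byte-identical; the manifest stores MD5 checksums of every input and
  output.

## Limitations

Country-level momenta inherit the politics of EEZ boundaries: a long
coastline counts the same as a short one, and the multi-basin default
assignment (e.g. Greece to the Eastern Mediterranean) shifts MSFD-level
counts in ways records with explicit subregion tags would not. The
cumulative curve adds medians of different species subsets at different
steps, so it is a population-level summary, not the expected itinerary of
any single species. The synthetic EEZ layer is for testing; quantitative
trajectory coordinates should be computed from real polygon data. Finally,
nearest-neighbour momentum matching always returns some momentum — a
species that left the basin's trajectory corridor entirely will still be
matched, which is why the verdict and the match distance diagnostics are
reported separately.
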