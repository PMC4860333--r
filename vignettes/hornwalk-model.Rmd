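---
title: "The hornwalk movement model: rules, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hornwalk movement model: rules, design choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hornwalk)
```

## The model

`hornwalk` simulates bighorn sheep as independent agents performing a
pseudo-biased random walk on a raster landscape. The walk is *pseudo*-biased
because there is no goal and no gradient: bias enters only through which
neighbouring cells an agent is willing to occupy. An agent carries no state
beyond its current cell, its previous cell, and a step counter.

Each time step:

1. The 8 Moore neighbours of the current cell are listed in a uniformly
   random order, excluding the previous cell (the no-backtrack rule, which
   prevents agents oscillating between two cells).
2. Candidates are evaluated in that order. A candidate is rejected if it is
   impassable: a road cell, a water (lake or river) cell, a cell with
   strictly more than 40% crown cover, or unmapped (nodata) ground.
3. A passable candidate within 400 m of escape terrain — any cell with
   slope strictly above 40 degrees — is accepted outright. Beyond 400 m a
   uniform draw $u \in (0, 100)$ is compared against the distance-decay
   curve $y = 188.21\,e^{-0.0016 x}$ (with $x$ the cell's distance to
   escape terrain in metres); the candidate is accepted when $u < y$.
4. The agent moves to the first accepted candidate. If the ordered list
   reaches a neighbour outside the mapped extent, the agent is removed
   (`left_extent`); if the list is exhausted, it is removed (`stuck`); and
   an agent that has made 2,000 moves is removed (`max_steps`) before it
   can move again.

The landscape is static — no diurnal or seasonal variation — and agents do
not interact, so a simulation is simply a sum of independent walks. Every
occupied cell (the seed included, revisits counted again) increments a
per-pixel usage map; dividing by the most-used pixel's count gives the
relative frequency-of-use surface, with never-used pixels carried as nodata
rather than zero so that downstream maps can distinguish "unused" from
"rarely used".

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `slope_threshold_deg` | 40 | degrees | strictly above: escape terrain |
| `cover_threshold_pct` | 40 | % crown cover | strictly above: impassable |
| `escape_accept_dist_m` | 400 | m | deterministic-acceptance radius |
| `prob_coef_a` | 188.21 | % | decay curve value at distance 0 |
| `prob_rate_b` | 0.0016 | per m | decay rate of acceptance probability |
| `max_steps` | 2000 | moves | removal cap per agent |
| `distance_metric` | `"euclidean"` | — | distance-to-escape definition |

The thresholds and the decay constants are the field-calibrated values for
Okanagan bighorn sheep, derived from a regional habitat-suitability model;
they are data, not tunables, and the package treats them as the defaults of
[movement_rules()]. Note $188.21\,e^{-0.0016 x} > 100$ for $x \lesssim
395$ m, so the curve alone would accept near cells anyway; the 400 m
deterministic rule is a rule, not a consequence of the curve, and
acceptance within it consumes no random draw.

Scenario protocols modify exactly one rule each: the fire-restored scenario
disables the cover rule (prescribed burns and tree removal open the
canopy), and the permeable-roads scenario disables road blocking while
keeping road pixels flagged so crossings can be counted. Water blocks in
every scenario.

## Distance to escape terrain: two metrics

The distance from a cell to escape terrain is defined two ways, both
exposed because the model's own description is ambiguous between them:

* `euclidean` (default): exact centre-to-centre Euclidean distance
  transform. Geometrically realistic; a diagonal neighbour of an escape
  cell is at $75\sqrt{2} \approx 106$ m.
* `grid_ring`: Chebyshev ring count times the cell size, so distances come
  in multiples of 75 m and a diagonal neighbour is at 75 m. Under this
  metric the probabilistic rule first takes effect at 450 m — the smallest
  multiple of 75 exceeding 400 ([min_distance_beyond_accept()]).

The Euclidean transform is computed by `EBImage::distmap` (an exact
Euclidean distance transform); the Chebyshev variant is a two-pass
(1,1)-chamfer scan written here, since no installed package provides a
chessboard transform. Both are verified in the test suite against a
brute-force minimum over all escape cells on random masks, to within
$10^{-9}$ m.

## Randomness and reproducibility

All stochasticity flows through R's global RNG in a documented order: one
permutation (`sample.int`) per step for the candidate shuffle, then one
uniform draw per probabilistically evaluated candidate, in list order. A
chance-rejected candidate is treated as unsuitable *for this step only* —
iteration proceeds to the next cell in the list, and each candidate gets at
most one draw per step. The draw is continuous on (0, 100) with a strict
comparison; a continuous draw avoids the discretisation artifact an
integer draw would introduce at probabilities near the curve's values.

Scenario runs derive a child seed for trajectory $k$ from the master seed
by a fixed integer mix, so any single trajectory can be replayed in
isolation and results are bit-for-bit reproducible from `(config, seed)` —
the determinism the test suite asserts on usage maps, written rasters and
crossing reports. The parameter sweep runs every combination under the same
master seed, making rows paired comparisons rather than independent
replicates.

## Degenerate inputs and tie-breaks

* A landscape with no escape terrain has every distance `Inf`; no cell is
  suitable for seeding and the seeded protocols refuse to run.
* Nodata in any layer makes a cell impassable and never escape terrain —
  conservative, so walks cannot cross unmapped ground.
* Boundary values sit outside their rules by strict inequality: slope
  40.0° is not escape terrain, cover 40.0% is passable.
* Out-of-extent neighbours are genuine candidates (exit markers): they are
  evaluated in shuffled order like any cell, never pre-empting an
  acceptable in-extent candidate ahead of them. This realises the
  "leave the landscape" removal cause; whether the original implementation
  allowed exits or stalled at edges is not documented, and this choice at
  least keeps edge cells unprivileged.
* Crossing-site ranking sorts by count, then row, then column, so reports
  are deterministic; the top-10% cutoff is nearest-rank
  ($\lceil 0.1N \rceil$) with all ties at the cutoff included, over road
  pixels that were actually used.
* Step cap: the cap counts moves per agent (a trajectory has at most 2,001
  cells). Since agents are independent and all start at tick zero, a
  per-agent cap is operationally identical to a global simulation-tick cap.
* Cell indices are 1-based with row 1 at the north edge, matching R's
  matrix convention; the map-to-cell mapping floors, so a point on a shared
  edge belongs to the larger-index (east/south) cell.

## The synthetic landscape generator

Real inputs for this model are regional GIS layers that cannot ship with a
package, so [make_synthetic_landscape()] generates landscapes with the same
statistical structure: a gentle smoothed terrain with `n_ridges` elongated
steep segments (slope 55° by default, comfortably above the 40° threshold)
providing escape terrain; crown cover as a smoothed Gaussian field rescaled
to mean 35% so that contiguous patches exceed the 40% movement threshold
and act as barriers; and one river (north–south) and one road (east–west)
polyline rasterised with a supercover traversal so the linear barriers have
no diagonal leaks. Defaults describe a 100 × 100 grid of 75 m cells
(7.5 km × 7.5 km) — large enough for multi-kilometre walks yet small enough
that a 2,000-iteration protocol runs in seconds. Occurrence points are
drawn uniformly from *suitable* cells (passable and within 400 m of escape
terrain), jittered within the cell, emulating the concentration of real
sighting records in good habitat near escape terrain.

What the generator does **not** emulate: real topographic autocorrelation
(ridges are independent segments, not a drainage network), road networks
that follow valley contours, observation bias in occurrence data, and the
sheer extent of a real study region. Tests passing on synthetic landscapes
therefore demonstrate that the mechanics — rules, bookkeeping,
reproducibility, the calibration metric — are correct, not that any
particular real landscape is well or poorly connected.

## Problem sizes used in the checks

The validation-metric check runs the potential-connectivity protocol at a
reduced scale chosen to exercise the full pipeline quickly: a 100 × 100
synthetic landscape, 50 occurrence points, 2,000 iterations (versus 20,000
in a full protocol). At this scale the usage surface saturates suitable
habitat and occurrence coverage sits well above the 0.8 calibration bar.
The 20,000-iteration default is exercised on a small fully passable
landscape where agents exit within a few steps. The step-cap check uses a
201 × 201 fully passable landscape: a random walk of 2,000 steps has a
root-mean-square displacement near $\sqrt{2000} \approx 45$ cells, so an
agent seeded at the centre cannot plausibly reach an edge before the cap.

## Known limitations

* Movement is restricted to secure habitat; dispersal through poor habitat
  is excluded by design, so connectivity is likely underestimated.
* All agents share one rule set — no inter-individual variability, no
  correlated-walk persistence, no energy budget.
* The landscape is static; seasonal range shifts are out of scope.
* Raster I/O is ESRI ASCII only; convert GeoTIFFs externally (e.g.
  `gdal_translate -of AAIGrid`). Reprojection and DEM-to-slope derivation
  are out of scope — slope arrives in degrees.
* Crossing sites are reported as pixels; grouping contiguous pixels into
  road sections is left to downstream GIS.
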