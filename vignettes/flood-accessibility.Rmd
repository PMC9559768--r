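---
title: "Methods: flood-time healthcare accessibility and road criticality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flood-time healthcare accessibility and road criticality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floodaccess)
```

## The question the package answers

When a flood severs a road network, who can still reach a health facility,
how much longer does it take, and which road segments were the ones that
mattered? `floodaccess` answers this with two deliberately different
models of travel and a criticality indicator defined on the road graph,
all runnable offline on seeded synthetic scenarios.

## Two accessibility engines

**Network engine.** The classed road network becomes an undirected graph
whose edge weights are minutes: `length_m / (speed_kmh * 1000 / 60)`,
with class speeds taken from a `speed_profile()`. Driving defaults are
trunk 80, primary 60, secondary 50, tertiary 40, unclassified 30 and
track 10 km/h, and driving does not traverse `path`-class segments;
walking traverses every class at a flat 5 km/h. These speeds are explicit
configuration, not estimates: routing engines bury their per-class speed
tables, so we surface them as defaults the user can override. Travel time
per node is the multi-source shortest-path time to the nearest facility
(facilities snap to their nearest node within `max_snap_m`, default
2000 m, ties to the smallest node id). Because the engine only knows
roads, anywhere without a road is simply out of range — the
characteristic bias of network models where mapping is incomplete.

Isochrone membership is evaluated directly on the population grid rather
than as vector polygons: a cell takes the minimum time over all nodes
within `reach_radius_m` (default 500 m) of its center, and a cell with no
node in radius is unreachable. Polygonization schemes differ between
routing engines and are rarely documented; evaluating membership on the
grid is deterministic, testable, and already at the resolution at which
population is counted.

**Raster engine.** A friction surface assigns each cell a cost in minutes
per meter; travel time is the least-cost path on the 8-connected cell
graph, where a step between adjacent cells costs the mean of their
frictions times the center distance (`cell_m`, or `cell_m * sqrt(2)`
diagonally). The mean-of-endpoints step cost is the standard
cost-distance convention; 16-connectivity (adding knight moves with a
`sqrt(5)` factor) is available via `connectivity = 16`, but 8 is the
default and what the tests pin down, including the closed form on uniform
grids: time = octile distance × cell size × cost. On a 1 km grid the
traversal time of one cell is 6 min for a motorized vehicle on a track
(10 km/h) and 24 min walking on bare ground (2.5 km/h) — the time
resolution of this engine. Off-road cells get the bare-ground walking
cost, which is why the raster engine reaches populations the network
engine calls stranded.

## Flood disruption

The flood mask is a set of polygons with union semantics; a point is
flooded when it lies in any member polygon (even-odd rule with holes,
boundary counted as inside — conservative and deterministic). Masks from
several sources are simplified per ring (Visvalingam, by default
retaining rings as-is in the pipeline; the canonical satellite-mask
preprocessing retains 1% of points) and then merged; simplify-first is
the default order because simplification budgets are defined per source
ring.

The network is disrupted by removing every node inside the mask together
with its incident edges. This node rule has a known blind spot: an edge
whose interior crosses the mask while both endpoints stay dry survives.
We keep that behaviour as the default because it is the documented
procedure this pipeline mirrors; `strict_edge_flooding = TRUE` also drops
such interior-crossing edges for sensitivity analysis. On the raster
side, cells whose *center* falls in the mask become impassable
(cell-center containment rather than any-overlap: unambiguous and fast).

## Population impact

Travel times are binned into 10-minute intervals up to a cap — 60 min
driving, 360 min walking — with half-open bins `[k·i, (k+1)·i)`; times at
or beyond the cap are `BEYOND_CAP` and unreachable elements stay
`UNREACHABLE`. Population counts are attributed to bins by summation;
when the population raster is finer than the access grid it is
block-summed, never interpolated, so every table conserves the raster
total to numerical precision (asserted at 1e-6 relative in the tests).
Any quantity derived from bins inherits a precision error of at most one
interval (10 min) per cell, which the tests verify on random fields.

The loss of access compares the per-cell time fields of the two
conditions: `INCREASED` (both reachable, time rose), `LOST_ACCESS`
(within the cap before, unreachable or beyond it after), `NO_CHANGE`
otherwise. Floods cannot improve travel on a fixed graph — the flooded
edge set is a subset — but one modelled artifact can produce small
negative increases: when a facility's snapped entry node is itself
flooded, the facility re-snaps to the nearest surviving node (as a
routing engine would), which can shorten a few node times. Such cells are
clamped to `NO_CHANGE` and counted (`n_clamped`, surfaced in the
pipeline manifest) rather than silently kept or dropped.

## Targeted edge betweenness centrality

Classic edge betweenness counts shortest paths between *all* node pairs
and therefore reflects network topology more than network use. The
targeted variant restricts origins to population nuclei — centroids of
the 1 km-aggregated population raster blocks with nonzero count — and
destinations to the health facilities within a 20 km planar buffer of
each nucleus. Each origin `s` contributes one minimum-travel-time path to
each in-range facility, and every edge on that path gains `1/N_s`, where
`N_s` is the number of in-range facilities of `s`. `N_s` is counted
before any reachability check, so an in-range facility cut off by the
flood still divides the weight; unreachable pairs simply contribute
nothing to the numerator. Scores are computed for the normal and the
flooded graph; per edge, the comparison classes are `FLOODED` (removed),
`LOST` (positive score falling to zero on an intact edge), `DECREASED`,
`UNCHANGED` (|delta| ≤ 1e-9) and `BACKUP_INCREASED` — the backup roads
that absorb rerouted access paths and deserve attention in preparedness
planning. A dispersion summary (maximum score and Gini coefficient of
positive scores) captures whether access funnels through a few axes.

Three interpretation decisions were genuinely open and are resolved as
follows. Ties between equal-cost paths are broken by selecting the
lexicographically smallest node-id sequence: a single deterministic path
per pair reproduces bit-for-bit across platforms, which we preferred over
the fractional splitting of classic betweenness (shortest-path tooling
typically returns one path anyway). The 20 km buffer is Euclidean, not
network distance — a buffer is a planar construct — and the same radius
is used for both profiles unless overridden. Origins with no facility in
range are skipped with a logged count rather than having their range
expanded; silently growing the buffer would make `N_s` incomparable
across origins.

## The synthetic scenario generator

Every generator is a pure function of `(seed, config)`; per-generator RNG
streams are derived from the scenario seed by fixed offsets so the
components do not couple. The generator emulates the statistical shape of
the real inputs this kind of study uses: a sparse trunk skeleton
(Euclidean minimum spanning tree over trunk nodes plus a few redundancy
links) with denser local roads attached to their nearest neighbour;
log-normal population clusters binned into 100 m cells that sum exactly
to the configured total, with most cells empty; facilities jittered at
most 200 m from network nodes; a friction raster derived from the
network by rasterizing the fastest road class into each 1 km cell (a
class is "in" a cell when the cell center lies within half a cell
diagonal of a segment); and a ribbon flood — a buffered wiggly polyline
crossing the extent, anchored on a trunk node so it actually severs the
skeleton.

What the generator does *not* emulate: real floods follow terrain, not
ribbons; real road geometries are polylines, not straight segments (the
`length_m` field still admits inflated lengths); real population
gridding is dasymetric, not Gaussian. Passing tests therefore demonstrate
the correctness and internal consistency of the algorithms, not the
fidelity of any particular real-world estimate — country-scale results
require the real network, population, friction and flood datasets.

The default study scenario is a 20 × 20 km extent with 12 trunk and 80
local nodes, 6 facilities, 8 population clusters totalling 50,000 people
on 100 m cells, a 1 km friction grid and a 1.5 km wide flood; the "small"
preset (10 × 10 km, 36 nodes, 20,000 people) keeps property suites fast,
and the "bridge" preset is a fixed, hand-enumerable single-bridge
scenario: a settlement (2,000 people) and a riverside hamlet (300) reach
the one facility across a river; the flood removes the bridge's mid-river
node and the hamlet's junction, so the hamlet's 300 inhabitants lose
access entirely, the settlement detours over a northern crossing whose
dry-ended span survives the node rule, and those detour edges classify as
backup roads.

```{r bridge}
sc <- scenario_preset("bridge")
res <- run_pipeline(sc, speed_profile("driving"))
res
glance(res)
```

## Numerical choices and degenerate inputs

Boundary points count as flooded everywhere (network nodes, cell centers,
point queries). Snapping ties break on the smallest node id. Equal-cost
path ties break lexicographically. Unreachability is a distinct sentinel
(`NA`), never a large number. The Visvalingam implementation recomputes
neighbour areas after each removal and carries the running maximum of
removed areas (the standard monotone update), with ties on the lowest
original vertex index and a floor of four points per closed ring. TEBC
accumulation reduces per edge over distinct `N` in ascending order, so
scores are reproducible to the last bit and comparable to exact rational
accumulation. Degenerate cases are defined rather than accidental: an
empty flood mask is a no-op, a flood covering every node yields an empty
graph whose downstream tables are all `UNREACHABLE`, an all-zero score
field reports a Gini of 0 with a flag, and facilities whose containing
cells are all impassable are an error naming them.

All inputs to a pipeline must share one projected CRS in meters; the
readers refuse to reproject. File formats are deliberately plain:
GeoJSON for vector types, Esri ASCII for rasters, CSV for tables, with a
manifest recording parameters, stage counts and output hashes.

## Limitations

Turn restrictions, one-way streets, congestion and capacity, multimodal
trips, anisotropic (slope-aware) costs and open-space routing in the
network engine are out of scope. The criticality indicator weights all
origins equally; a population-weighted variant is deliberately not
provided, since it would make remote, already-underserved nuclei
invisible unless that trade-off is an explicit operational decision.
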