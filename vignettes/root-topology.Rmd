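---
title: "Topological analysis of root system architectures with rootTDA"
author: "rootTDA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological analysis of root system architectures with rootTDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootTDA)
```

## The problem

Root systems are usually summarised by geometric aggregates — total root
length, surface, diameter, counts per branching order. Two root systems can
share all of these and still branch in profoundly different ways, so a
purely geometric description misses the *topology*: how individual roots
are connected through branching. rootTDA implements two complementary
topological readouts on top of a common data model for root architectures:

* **Fitter's link indices** — magnitude, altitude and external path
  length of the link representation of the branching network; and
* **zero-order persistent homology** — the H0 persistence barcode of the
  geodesic distance function, compared between plants with the bottleneck
  distance and embedded with non-metric multidimensional scaling (NMDS).

Input is the Root System Markup Language (RSML): nested polylines with
per-node diameters and, optionally, ages. A seeded growth model generates
synthetic fibrous and tap-rooted architectures so the entire pipeline can
be exercised, tested and benchmarked without any external data.

## Data model and conventions

An RSML `<plant>` becomes a `RootSystemTree`: a list of `Root` axes, each
an ordered polyline of nodes (x, y, z, diameter, age) with a parent link
and the index of the parent node nearest its branching point. Conventions,
chosen once and applied everywhere:

* **y points down** (depth positive). Files using y-up can be mirrored on
  read with `readRSML(..., flipY = TRUE)`.
* **Units are never converted.** The metadata unit label travels verbatim
  into every table and barcode.
* **Diameter dialects.** Both per-node `diameter` sample functions and a
  single root-level diameter are accepted; a root-level value is broadcast
  to all nodes.
* **Age functions.** Any RSML `function` whose name contains "age" or
  "time" (case-insensitively) is taken as node age. RSML does not
  standardise this name, so the substring rule is a documented choice;
  absent ages leave the growth-rate column `NA`.
* **Collar join.** A plant with several first-order axes is treated as one
  connected structure joined at a virtual collar at geodesic distance 0.
  Without this, fibrous systems would be forests and neither the barcode
  conservation property nor whole-plant Fitter indices would be defined.

`buildSegmentTable()` flattens trees into one row per inter-node segment
with 25 columns (coordinates, diameters, length, frustum surface
`pi*L*(d1+d2)/2` and volume `(pi*L/12)*(d1^2+d1*d2+d2^2)`, orientation
from the downward vertical in degrees, growth rate as the finite
difference `length / (age2 - age1)`, geodesic distance, and topology
bookkeeping). The geodesic distance of a node is the distance from the
collar measured *along* the roots; a lateral continues from the geodesic
value of its insertion node. Zero-length segments (duplicate vectorisation
points) are dropped with a warning so that every remaining row has
positive length.

## The persistence barcode

The barcode is computed by a superlevel-set sweep of the geodesic distance
over the tree graph. Sweeping from the largest geodesic value down to 0,
every root tip births a connected component at its geodesic value; when
two components meet at a junction the **elder rule** applies — the
component with the larger birth (the longer branch) persists and the
shorter one dies at the junction's geodesic value; the last component dies
at 0. The implementation sorts vertices by decreasing geodesic value and
merges with a union-find structure.

Sign convention: births and deaths are stored as non-negative geodesic
values with birth > death, and the base component gets death 0 rather than
infinity. Every bar is therefore finite, no infinity handling is needed in
the bottleneck distance, and two exact identities hold (both are asserted
in the test suite):

* one bar per root tip (for generic, i.e. pairwise distinct, tip values);
* the persistences (birth − death) sum exactly to the total root length.

Ties (two components with equal birth meeting at one junction) are broken
deterministically in favour of the tip with the smaller (root id, node
index); the bar multiset is unaffected, only the surviving label.
Zero-persistence pairs (a tip exactly at a junction value) are dropped.

```{r barcode}
tree <- generateRootSystem(genotypePreset("taproot"), seed = 1)
st <- buildSegmentTable(tree)
b <- computeBarcode(st)
b
head(renderBarcode(b), 3)
```

## Bottleneck distance

Barcodes are compared as persistence diagrams (points (birth, death) in
the plane) under the bottleneck distance: the minimum over matchings of
the maximum L-infinity displacement, where an unmatched point may be
matched to the diagonal at cost persistence/2. The distance is computed
*exactly*: the optimum is always attained at one of the finitely many
candidate costs (a pairwise L-infinity distance or a half-persistence), so
a binary search over the sorted candidates with a Hopcroft–Karp
feasibility matching (in C++) returns the exact value with no
approximation parameter. The feasibility test uses the Mendelsohn–Dulmage
reduction: a matching within cost c exists iff the points of each diagram
whose half-persistence exceeds c can be saturated into the other diagram
using edges of cost at most c. Diagrams here have at most a few hundred
points, which keeps the exact computation fast; the pairwise matrix over
100 simulated systems takes seconds.

The test suite checks hand-computed distances, exact agreement with an
exhaustive minimax-matching oracle on random diagram pairs, the metric
axioms on random diagram triples, and a stability property (perturbing
births by at most epsilon moves the distance by at most epsilon).

## Fitter indices

The link representation partitions a root system at its branching points:
base-to-first-branch and branch-to-branch portions are internal links,
branch-to-tip portions external links. Magnitude is the number of external
links, altitude the number of links on the longest base-to-tip path, and
the external path length the sum of those path lengths over all tips.
Two choices are deliberate: path lengths count **links, not nodes** (the
altitude of an unbranched root is 1), and laterals inserted at the same
parent node form a single multi-way branching point, as happens in real
tracings. With multi-way points the binary-tree lower bound
altitude ≥ log2(magnitude) + 1 need not hold; the tests assert it only for
binary link graphs. Indices are reported per plant and are two of the 20
aggregated traits.

## The trait panel

`computeTraits()` returns 20 aggregates per plant: TRL, L1R, TN1R, TNLR,
TLRL, N2LR, N3LR, L2LR, L3LR, MD1, MDLR, D2LR, Convexhull, Stot, Vtot,
Magnitude, Altitude, ExtPathLength, Depth and Width. The named core of the
panel is the classical 16-trait set plus the two Fitter-index extremes;
Depth (vertical extent of the node cloud) and Width (maximum horizontal
extent) complete the panel to 20 — they are standard architectural
aggregates and carry the steep/shallow gravitropism contrast. Mean
diameters are length-weighted, which makes them robust to uneven
vectorisation density. The convex hull is the 2D hull area for planar data
and the 3D hull volume otherwise; the 3D hull is computed by an
incremental convex-hull algorithm implemented in the package and is
cross-checked in the tests against analytic solids and an independent
implementation.

## The synthetic generator

`generateRootSystem()` is a minimal discrete-time growth model standing in
for ArchiSimple-class simulators — deliberately *not* a reimplementation:
there is no soil, no diameter-driven elongation, no root death. Each axis
elongates along its heading; per step the heading relaxes toward the
gravity vector by the gravitropism fraction and receives Gaussian jitter;
a lateral initiates every `interLateralDistance` of parent growth, with a
normally distributed insertion angle and uniform azimuth; diameters taper
by `diameterRatioLateral` per order; node ages are recorded. Three
internal rules are held fixed across presets: order-k roots elongate at
`elongationRate * ratio^(k-1)`; laterals stop elongating after 3 days
(determinate laterals keep tip counts realistic); and the inter-lateral
distance of an order-k parent scales as `ratio^(-2(k-1))`, so thinner
roots branch sparser. Every root draws a private elongation multiplier
from U(0.8, 1.2) at birth, giving the inter-individual variability that
real simulation libraries show.

The seven genotype presets (`mock`, `dense`, `sparse`, `steep`, `shallow`,
`slow`, `fast`) are the mock baseline with exactly one parameter changed —
inter-lateral distance (0.8 → 0.4 / 1.6 cm), gravitropism (0.10 → 0.30 /
0.02) or elongation rate (1.5 → 0.9 / 2.2 cm/day). `fibrous` (10 thin
axes) and `taproot` (one dominant fast axis, third-order branching) are
the two habit categories. The parameter values are this package's own
calibration, shipped as a plain-text table
(`inst/extdata/genotype_presets.tsv`); the defaults produce plants of a
few hundred cm total root length with tens of tips in ~0.1 s each, which
is the scale used throughout the tests and the acceptance analysis (the
methods are scale-free; `calibrateLength()` bisects the simulated duration
to reach any target length, e.g. the 20 m ± 15% window used for
field-scale libraries, exploiting that growth is prefix-stable in
duration, so total length is monotone and bisection converges).

What the generator deliberately does **not** emulate: tropism interactions
with soil layers, root decay and self-pruning, diameter-dependent
elongation, anastomosis, and measurement noise of image-based tracings
(missing laterals, merged axes). Passing tests on synthetic data therefore
demonstrate the correctness of the computations, not robustness to
tracing artefacts.

## Ordination and the habit contrast

NMDS uses `vegan::monoMDS` (Kruskal stress-1, global monotone model) with
one metric-scaling start plus 20 seeded random restarts, keeping the
lowest-stress solution; inputs with n ≤ k+1 points are embedded exactly by
classical scaling (any 3-point metric is planar). Coordinates are rotated
to principal axes and sign-canonicalised, so equal inputs give equal
outputs regardless of row order. PCA is the correlation-matrix PCA
(`prcomp` on standardized variables); constant columns are dropped with a
warning.

The headline analysis — 50 fibrous + 50 taproot simulated systems,
barcodes, pairwise bottleneck matrix, NMDS, then a k-medoids 2-way split
of the scores — recovers the generating habit for every plant at the
default problem size (the acceptance threshold is ≥ 90%). The two habits
differ most in their longest bars (one dominant axis versus ten medium
axes), which the bottleneck distance picks up directly.

```{r pipeline, eval = FALSE}
out <- tempfile()
res <- runPipeline(list(presets = c("fibrous", "taproot"), replicates = 5),
                   out = out, seed = 1)
recoveryRate(res$nmds, rep(c("fibrous", "taproot"), each = 5))
```

## Numerical choices and degenerate inputs

* Barcode sweep order is (geodesic desc, root id, node index): fully
  deterministic, including symmetric trees.
* Bottleneck candidates include 0, so identical diagrams give exactly 0;
  empty diagrams are valid (everything matches the diagonal).
* Round-tripping RSML preserves coordinates to ~1e-7 (9 significant
  digits are written); the round-trip test tolerance is 1e-6.
* Zero-length segments are dropped (with a count) rather than poisoning
  geodesics; barcode graph construction re-links across dropped rows.
* Hull computations: degenerate clouds (collinear, coplanar with z = 0)
  fall back to the measure of their affine dimension (0 for lines, area
  for planes).
* `calibrateLength()` reports the closest achieved length if the target
  window cannot be reached within its iteration budget.

## Limitations

* Only H0 persistence is computed; H1+ is meaningless on trees and other
  filtration functions (Euclidean depth, branch order) are extension
  points, not implemented.
* DART tracing files and multi-scene RSML time series are out of scope;
  time enters only through per-node ages.
* The NMDS embedding is unique only up to rotation/reflection; the
  canonical orientation makes runs comparable but is still a convention.
* Bottleneck cost grows with diagram size and pair count (the pairwise
  matrix is quadratic in the number of plants); for libraries of
  thousands of field-scale systems, expect the bottleneck stage to
  dominate run time.
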