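# rootTDA

Topological analysis of plant root system architectures in R.

Geometric aggregates (total root length, surface, tip counts) often fail
to distinguish root systems that branch in very different ways. rootTDA
quantifies the *topology* of root systems vectorised in the Root System
Markup Language (RSML), for root phenotypers and root-architecture
modellers:

* **RSML I/O** — read/write nested-polyline root architectures with
  per-node diameters and ages (`readRSML()`, `writeRSML()`);
* **segment tables** — one row per root segment with geometry and the
  geodesic distance (distance from the collar measured along the roots)
  (`buildSegmentTable()`);
* **persistent homology** — the H0 persistence barcode of the geodesic
  distance function by the elder rule: each root tip births a connected
  component at its geodesic value, and when two branches merge the longer
  one persists while the shorter dies at the junction
  (`computeBarcode()`); bars are (birth, death) pairs with
  Σ (birth − death) = total root length, exactly;
* **bottleneck distances** — exact d_B(A, B) = min over matchings of the
  max L∞ displacement, diagonal matches allowed at cost persistence/2,
  computed by binary search over candidate costs with a Hopcroft–Karp
  feasibility matching in C++ (`bottleneckDistance()`,
  `pairwiseBottleneck()`);
* **Fitter indices** — magnitude μ (external links), altitude a (links on
  the longest base-to-tip path), external path length Pe (sum of
  base-to-tip path lengths) (`fitterIndices()`);
* **trait panel** — 20 aggregated architectural traits per plant
  (`computeTraits()`, `traitMatrix()`);
* **ordination** — NMDS (Kruskal stress-1) of bottleneck matrices and
  correlation-matrix PCA of traits (`ordinateNMDS()`, `ordinatePCA()`);
* **synthetic root systems** — a seeded growth model with seven
  single-parameter genotype presets plus fibrous/taproot habit presets
  (`generateRootSystem()`, `generateLibrary()`, `calibrateLength()`).

## Worked example

```r
library(rootTDA)

tree <- generateRootSystem(genotypePreset("taproot"), seed = 1)
tree
#> RootSystemTree 'taproot_s1': 86 roots (max order 3), TRL 225.958 cm

st <- buildSegmentTable(tree)   # 25 columns, one row per segment
b <- computeBarcode(st)
b
#> Barcode 'taproot_s1': 78 H0 bars, total persistence 225.9581

cat(renderBarcode(b, width = 40)[1:4], sep = "\n")
#> [   0.000,   22.655] ========================================
#> [  21.522,   22.258]                                      ==
#> [  21.522,   22.181]                                      ==
#> [  21.522,   22.064]                                      ==

fitterIndices(st)
#> FitterIndices: magnitude 78, altitude 20, external path length 892

round(computeTraits(st)[c("TRL", "L1R", "TNLR", "N2LR", "N3LR",
                          "Depth", "Width")], 2)
#>    TRL    L1R   TNLR   N2LR   N3LR  Depth  Width
#> 225.96  22.66  85.00  43.00  42.00  21.40  10.72

fib <- computeBarcode(buildSegmentTable(
  generateRootSystem(genotypePreset("fibrous"), seed = 2)))
bottleneckDistance(b, fib)
#> [1] 8.958
```

Reading: the tap-rooted plant has one dominant bar spanning the whole
geodesic axis (the 22.7 cm main axis) and 77 short bars (laterals), and
its 78 tips sit on average 892/78 ≈ 11 links from the collar. The
bottleneck distance to a fibrous plant is large (≈ 9 cm) because no bar of
the fibrous barcode matches the taproot's dominant axis bar.

The full pipeline (simulate or ingest → table → traits + barcodes →
bottleneck matrix → NMDS + PCA, all stages written as CSV with a JSON
manifest) is one call:

```r
res <- runPipeline(list(presets = c("fibrous", "taproot"),
                        replicates = 50), out = "run1", seed = 1)
```

## Documentation

The methods vignette (`vignettes/root-topology.Rmd`) describes the data
model and conventions, the elder-rule sweep, the exact bottleneck
algorithm, the link decomposition, the trait panel, the growth model
behind the synthetic presets, and the package's numerical choices and
limitations.
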