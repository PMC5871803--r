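# Aggregated trait panel.

test_that("a single root yields the expected aggregates", {
  st <- buildSegmentTable(singleRootTree(len = 5, diameter = 0.1))
  tv <- computeTraits(st)
  expect_named(tv, c("TRL", "L1R", "TN1R", "TNLR", "TLRL", "N2LR", "N3LR",
                     "L2LR", "L3LR", "MD1", "MDLR", "D2LR", "Convexhull",
                     "Stot", "Vtot", "Magnitude", "Altitude",
                     "ExtPathLength", "Depth", "Width"))
  expect_length(tv, 20)
  expect_equal(unname(tv[c("TRL", "TN1R", "TNLR", "TLRL", "MD1")]),
               c(5, 1, 0, 0, 0.1))
})

test_that("the Y-tree aggregates match hand computation", {
  tv <- computeTraits(buildSegmentTable(yTree()))
  expect_equal(unname(tv[c("TRL", "L1R", "TLRL", "N2LR", "D2LR")]),
               c(6, 5, 1, 1, 0.2))
  expect_equal(unname(tv["Depth"]), 5)
  expect_equal(unname(tv["Width"]), 1)
})

test_that("the convex hull of a unit square of nodes has area 1", {
  r <- Root("sq", data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1),
                             diameter = 0.1))
  tv <- computeTraits(buildSegmentTable(rootSystemTree("p", list(r))))
  expect_equal(unname(tv["Convexhull"]), 1.0)
})

test_that("3D node clouds use hull volume, checked against known solids", {
  # unit cube traced as one polyline through all 8 corners
  corners <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  ord <- c(1, 2, 4, 3, 7, 8, 6, 5)
  r <- Root("cube", cbind(corners[ord, ], diameter = 0.01))
  tv <- computeTraits(buildSegmentTable(rootSystemTree("p", list(r))))
  expect_equal(unname(tv["Convexhull"]), 1.0, tolerance = 1e-9)
  # regular octahedron with vertices at distance 1 from the origin: V = 4/3
  octa <- data.frame(x = c(1, -1, 0, 0, 0, 0), y = c(0, 0, 1, -1, 0, 0),
                     z = c(0, 0, 0, 0, 1, -1))
  expect_equal(rootTDA:::.hull3dVolume(as.matrix(octa)), 4 / 3,
               tolerance = 1e-9)
})

test_that("hull volumes of random clouds match an independent implementation", {
  pyOk <- nzchar(Sys.which("python"))
  expect_true(pyOk)
  set.seed(7)
  P <- matrix(stats::runif(3 * 40), ncol = 3)
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(P, csv, row.names = FALSE, col.names = FALSE, sep = ",")
  out <- system2("python", c("-c", shQuote(paste0(
    "import numpy, scipy.spatial; ",
    "p = numpy.loadtxt('", csv, "', delimiter=','); ",
    "print(repr(scipy.spatial.ConvexHull(p).volume))"
  ))), stdout = TRUE)
  expect_equal(rootTDA:::.hull3dVolume(P), as.numeric(out[length(out)]),
               tolerance = 1e-9)
})

test_that("additivity and scale equivariance hold", {
  tree <- randomTree(11)
  st <- buildSegmentTable(tree)
  tv <- computeTraits(st)
  expect_equal(unname(tv["TRL"]), sum(segments(st)$length), tolerance = 1e-12)
  expect_equal(unname(tv["TRL"]), unname(tv["L1R"] + tv["TLRL"]))
  expect_equal(unname(tv["TNLR"]),
               unname(tv["N2LR"] + tv["N3LR"]) +
                 sum(segments(st)$order[!duplicated(segments(st)$root)] > 3))

  k <- 2.5
  scaled <- rootSystemTree(plantId(tree), lapply(roots(tree), function(r) {
    nd <- r@nodes
    nd[, c("x", "y", "z", "diameter")] <- nd[, c("x", "y", "z", "diameter")] * k
    Root(r@id, nd, order = r@order, parentId = r@parentId,
         insertionIndex = r@insertionIndex)
  }))
  tvk <- computeTraits(buildSegmentTable(scaled))
  expect_equal(unname(tvk["TRL"]), unname(k * tv["TRL"]), tolerance = 1e-9)
  expect_equal(unname(tvk["Stot"]), unname(k^2 * tv["Stot"]), tolerance = 1e-9)
  expect_equal(unname(tvk["Vtot"]), unname(k^3 * tv["Vtot"]), tolerance = 1e-9)
  expect_equal(unname(tvk[c("Magnitude", "Altitude", "ExtPathLength")]),
               unname(tv[c("Magnitude", "Altitude", "ExtPathLength")]))
})

test_that("the trait matrix is one row per plant and permutation-stable", {
  trees <- lapply(1:4, randomTree)
  st <- buildSegmentTable(trees)
  tm <- traitMatrix(st)
  expect_equal(dim(tm), c(4, 20))
  p2 <- plantId(trees[[2]])
  expect_equal(unlist(tm[p2, ]), computeTraits(st, p2), tolerance = 1e-12,
               ignore_attr = TRUE)
  shuffled <- traitMatrix(buildSegmentTable(trees[c(3, 1, 4, 2)]))
  expect_equal(as.matrix(shuffled[rownames(tm), ]), as.matrix(tm))
})

test_that("unknown plants are rejected", {
  st <- buildSegmentTable(yTree())
  expect_error(computeTraits(st, "ghost"), "not in table")
})
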