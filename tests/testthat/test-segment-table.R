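# Per-segment table and geodesic distances.

test_that("a single vertical root flattens to hand-computed records", {
  st <- buildSegmentTable(singleRootTree(len = 5))
  rec <- segments(st)
  expect_equal(nrow(rec), 2)
  expect_gte(ncol(rec), 23)
  expect_equal(rec$length, c(3, 2))
  expect_equal(rec$geodesic, c(3, 5))
  expect_equal(rec$orientation, c(0, 0))           # straight down
  expect_equal(rec$apical, c(FALSE, TRUE))
  expect_equal(rec$dist_from_base, c(3, 5))
})

test_that("the schema covers every required column role", {
  st <- buildSegmentTable(yTree())
  expect_true(all(c(
    "file", "plant", "root", "order", "parent_root", "apical", "time",
    "x1", "y1", "z1", "x2", "y2", "z2", "diameter1", "diameter2",
    "length", "surface", "volume", "orientation", "growth_rate",
    "geodesic", "branching_node_geodesic", "dist_from_base"
  ) %in% names(segments(st))))
})

test_that("a lateral's geodesic continues from its insertion node", {
  st <- buildSegmentTable(yTree())
  lat <- segments(st)[segments(st)$root == "l", ]
  expect_equal(lat$branching_node_geodesic, 2)
  expect_equal(lat$geodesic, 2 + 1)                # insertion + own length
  expect_equal(geodesicDistance(yTree(), "l", 2), 3)
  expect_equal(geodesicDistance(yTree(), "a", 1), 0)
  expect_equal(geodesicDistance(yTree(), "a", 3), 5)
})

test_that("geodesic lookups validate root and node", {
  expect_error(geodesicDistance(yTree(), "nope", 1), "unknown root")
  expect_error(geodesicDistance(yTree(), "a", 9), "no node")
})

test_that("frustum surface and volume formulas are applied per segment", {
  r <- Root("cone", data.frame(x = c(0, 0), y = c(0, 1),
                               diameter = c(0.2, 0)))
  rec <- segments(buildSegmentTable(rootSystemTree("p", list(r))))
  expect_equal(rec$surface, pi * 1 * (0.2 + 0) / 2)        # pi*L*(d1+d2)/2
  expect_equal(rec$volume, pi * 1 * 0.2^2 / 12)            # frustum volume
})

test_that("growth rate is a finite difference of node ages", {
  r <- Root("aged", data.frame(x = c(0, 0, 0), y = c(0, 2, 3),
                               diameter = 0.1, age = c(0, 1, 1)))
  rec <- segments(suppressWarnings(buildSegmentTable(rootSystemTree("p", list(r)))))
  expect_equal(rec$growth_rate[1], 2)
  expect_true(is.na(rec$growth_rate[2]))           # equal ages
})

test_that("zero-length segments are dropped with a warning", {
  r <- Root("dup", data.frame(x = c(0, 0, 0, 0), y = c(0, 2, 2, 5),
                              diameter = 0.1))
  expect_warning(st <- buildSegmentTable(rootSystemTree("p", list(r))),
                 "1 zero-length segment")
  expect_equal(nrow(segments(st)), 2)
  expect_equal(segments(st)$geodesic, c(2, 5))
})

test_that("length is conserved and geodesics dominate straight-line distance", {
  for (seed in 1:8) {
    tree <- randomTree(seed)
    st <- buildSegmentTable(tree)
    rec <- segments(st)
    expect_equal(sum(rec$length), totalRootLength(tree), tolerance = 1e-12)
    for (rid in unique(rec$root)) {
      expect_false(is.unsorted(rec$geodesic[rec$root == rid], strictly = TRUE))
    }
    expect_true(all(rec$geodesic >= rec$dist_from_base - 1e-9))
  }
})

test_that("CSV export round-trips the records", {
  st <- buildSegmentTable(yTree())
  path <- withr::local_tempfile(fileext = ".csv")
  writeSegmentTable(st, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_identical(names(back), names(segments(st)))
  expect_equal(back$geodesic, segments(st)$geodesic)
})
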