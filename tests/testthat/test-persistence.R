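# Elder-rule H0 barcodes of the geodesic distance function.

test_that("a single root yields one bar spanning its length", {
  st <- buildSegmentTable(singleRootTree(len = 5))
  b <- computeBarcode(st)
  expect_s4_class(b, "Barcode")
  expect_equal(unname(as.matrix(b)),
               matrix(c(0, 5, 0), 1, 3), tolerance = 1e-12)
})

test_that("the Y-tree barcode applies the elder rule at the junction", {
  st <- buildSegmentTable(yTree())
  m <- as.matrix(computeBarcode(st, "p"))
  expect_equal(unname(m[, "birth"]), c(5, 3))
  expect_equal(unname(m[, "death"]), c(0, 2))
  expect_equal(unname(m[, "dimension"]), c(0, 0))
})

test_that("bar count equals tip count and persistence sums to total length", {
  for (seed in c(1:6, 101:104)) {
    tree <- randomTree(seed)
    st <- buildSegmentTable(tree)
    b <- computeBarcode(st)
    expect_equal(length(b), tipCount(tree), label = paste("seed", seed))
    p <- persistencePairs(b)
    expect_equal(sum(p[, "birth"] - p[, "death"]), totalRootLength(tree),
                 tolerance = 1e-9)
    # single-based system: exactly one bar reaches the base
    expect_equal(sum(p[, "death"] == 0), 1L)
  }
})

test_that("barcodes match the brute-force threshold-sweep oracle", {
  for (seed in 1:25) {
    tree <- randomTree(seed)
    got <- as.matrix(computeBarcode(buildSegmentTable(tree)))
    want <- oracleBarcode(tree)
    expect_equal(unname(got[, c("birth", "death"), drop = FALSE]),
                 unname(want), tolerance = 1e-12,
                 label = paste("seed", seed))
  }
})

test_that("plants with several first-order axes join at the collar", {
  r1 <- Root("a1", data.frame(x = c(0, 0), y = c(0, 5), diameter = 0.1))
  r2 <- Root("a2", data.frame(x = c(0, 1), y = c(0, 3), diameter = 0.1))
  st <- buildSegmentTable(rootSystemTree("twin", list(r1, r2)))
  m <- as.matrix(computeBarcode(st))
  expect_equal(unname(m[, "birth"]), c(5, sqrt(10)))
  expect_equal(unname(m[, "death"]), c(0, 0))
  expect_equal(sum(m[, "birth"] - m[, "death"]), totalRootLength(
    rootSystemTree("twin", list(r1, r2))))
})

test_that("an orphan lateral is reported as a disconnected plant", {
  st <- buildSegmentTable(yTree())
  cut <- segments(st)[segments(st)$root == "l", , drop = FALSE]
  broken <- new("SegmentTable", records = cut, unit = "cm")
  expect_error(computeBarcode(broken, "p"), "disconnected.*l")
})

test_that("computeBarcodes returns one barcode per plant", {
  st <- buildSegmentTable(list(singleRootTree(), yTree()))
  bcs <- computeBarcodes(st)
  expect_named(bcs, c("p1", "p"))
  expect_equal(as.matrix(bcs[["p"]]),
               as.matrix(computeBarcode(st, "p")))
})

test_that("text and graphical renderings cover every bar", {
  st <- buildSegmentTable(yTree())
  b <- computeBarcode(st)
  txt <- renderBarcode(b)
  expect_length(txt, length(b))
  expect_match(txt[1], "5\\.000")                 # longest bar first
  expect_match(txt[1], "=")
  one <- renderBarcode(computeBarcode(buildSegmentTable(singleRootTree())))
  expect_length(one, 1)
  expect_false(grepl(" =", substr(one[1], 22, 100)))  # bar spans from 0
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(b))
})

test_that("barcode CSV export has exactly the three canonical columns", {
  st <- buildSegmentTable(yTree())
  path <- withr::local_tempfile(fileext = ".csv")
  writeBarcode(computeBarcode(st), path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("dimension", "birth", "death"))
  expect_equal(nrow(back), 2)
})
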