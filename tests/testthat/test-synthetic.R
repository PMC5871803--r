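# Synthetic root-system generator.

treeDepthWidth <- function(tree) {
  xyz <- do.call(rbind, lapply(roots(tree), function(r) {
    as.matrix(r@nodes[, c("x", "y", "z")])
  }))
  c(depth = diff(range(xyz[, 2])),
    width = max(stats::dist(unique(xyz[, c(1, 3)]))))
}

test_that("generation is deterministic in (params, seed)", {
  p <- genotypePreset("mock")
  a <- generateRootSystem(p, 123)
  b <- generateRootSystem(p, 123)
  expect_equal(lapply(roots(a), function(r) r@nodes),
               lapply(roots(b), function(r) r@nodes))
  c_ <- generateRootSystem(p, 124)
  expect_false(isTRUE(all.equal(roots(a)[[1]]@nodes, roots(c_)[[1]]@nodes)))
  expect_false(isTRUE(all.equal(totalRootLength(a), totalRootLength(c_))))
})

test_that("generated trees satisfy the architecture invariants", {
  for (name in c("mock", "fibrous", "taproot")) {
    tree <- generateRootSystem(genotypePreset(name), 5)
    expect_true(validObject(tree, test = TRUE))
    orders <- vapply(roots(tree), function(r) r@order, integer(1))
    ids <- vapply(roots(tree), function(r) r@id, character(1))
    parents <- vapply(roots(tree), function(r) r@parentId, character(1))
    for (i in which(orders > 1L)) {
      expect_equal(orders[match(parents[i], ids)], orders[i] - 1L)
    }
    for (r in roots(tree)) {
      expect_false(is.unsorted(r@nodes$age))
    }
  }
})

test_that("preset contrasts emerge in the simulated architectures", {
  nrep <- 10
  sim <- function(name) lapply(seq_len(nrep), function(s) {
    generateRootSystem(genotypePreset(name), 100 + s)
  })
  nLaterals <- function(tr) sum(vapply(roots(tr), function(r) r@order,
                                       integer(1)) > 1L)
  dense <- sim("dense"); sparse <- sim("sparse")
  for (i in seq_len(nrep)) {
    expect_gt(nLaterals(dense[[i]]), nLaterals(sparse[[i]]))
  }
  fast <- sim("fast"); slow <- sim("slow")
  for (i in seq_len(nrep)) {
    expect_gt(totalRootLength(fast[[i]]), totalRootLength(slow[[i]]))
  }
  steep <- sim("steep"); shallow <- sim("shallow")
  ratio <- function(tr) {dw <- treeDepthWidth(tr); dw["depth"] / dw["width"]}
  expect_gt(mean(vapply(steep, ratio, numeric(1))),
            mean(vapply(shallow, ratio, numeric(1))))
  # fibrous habit: more first-order axes than the taproot habit
  fib <- generateRootSystem(genotypePreset("fibrous"), 9)
  tap <- generateRootSystem(genotypePreset("taproot"), 9)
  n1 <- function(tr) sum(vapply(roots(tr), function(r) r@order,
                                integer(1)) == 1L)
  expect_gt(n1(fib), n1(tap))
})

test_that("libraries are written file-per-replicate with a faithful manifest", {
  outDir <- withr::local_tempdir()
  man <- generateLibrary(c("mock", "taproot"), replicates = 1, seed = 3,
                         outDir = outDir)
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(file.path(outDir, man$file))))
  expect_equal(man$seed, (3 + 7919 * seq_len(2)) %% 2147483647)
  # manifest TRL equals TRL recomputed through the table pipeline
  for (i in seq_len(2)) {
    tree <- readRSML(file.path(outDir, man$file[i]))[[1]]
    tv <- computeTraits(buildSegmentTable(tree))
    expect_equal(man$TRL[i], unname(tv["TRL"]), tolerance = 1e-6)
  }
})

test_that("parameter validation rejects impossible settings", {
  expect_error(genotypeParams(step = -1), "> 0")
  expect_error(genotypeParams(gravitropism = 2), "gravitropism")
  expect_error(genotypeParams(diameterRatioLateral = 0), "diameterRatio")
  expect_error(genotypePreset("unicorn"), "unknown preset")
})

test_that("total root length is monotone in simulated duration", {
  p <- genotypePreset("mock")
  trls <- vapply(c(2, 4, 6, 8, 10, 12), function(d) {
    q <- p; q@duration <- d
    totalRootLength(generateRootSystem(q, 77))
  }, numeric(1))
  expect_false(is.unsorted(trls, strictly = TRUE))
})

test_that("length calibration reaches a loose target quickly", {
  p <- genotypePreset("mock")
  tree <- calibrateLength(p, targetTRL = 60, tolerance = 0.5, seed = 4)
  expect_true(abs(totalRootLength(tree) - 60) <= 0.5 * 60)
  expect_error(calibrateLength(p, targetTRL = -5, tolerance = 0.1, seed = 1))
})
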