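# RSML reading and writing.

minimalRSML <- '<?xml version="1.0"?>
<rsml version="1.0">
  <metadata><version>1</version><unit>mm</unit><resolution>2</resolution></metadata>
  <scene><plant ID="p1"><root ID="r1">
    <geometry><polyline><point x="0" y="0"/><point x="0" y="5"/></polyline></geometry>
    <functions><function name="diameter" domain="polyline">
      <sample value="0.1"/><sample value="0.1"/></function></functions>
  </root></plant></scene></rsml>'

test_that("a minimal RSML document parses into one tree", {
  trees <- readRSML(minimalRSML)
  expect_length(trees, 1)
  tree <- trees[[1]]
  expect_s4_class(tree, "RootSystemTree")
  expect_identical(plantId(tree), "p1")
  expect_identical(lengthUnit(tree), "mm")
  expect_equal(tree@resolution, 2)
  expect_length(roots(tree), 1)
  nd <- roots(tree)[[1]]@nodes
  expect_equal(nd$x, c(0, 0))
  expect_equal(nd$y, c(0, 5))
  expect_equal(nd$z, c(0, 0))          # 2D file: z = 0 everywhere
  expect_equal(nd$diameter, c(0.1, 0.1))
})

test_that("nested laterals are read with resolved parent links and orders", {
  path <- system.file("extdata", "ytree.rsml", package = "rootTDA")
  tree <- readRSML(path)[[1]]
  expect_length(roots(tree), 3)
  byId <- roots(tree)
  names(byId) <- vapply(byId, function(r) r@id, character(1))
  expect_equal(byId[["axis"]]@order, 1L)
  expect_equal(byId[["lat1"]]@order, 2L)
  expect_equal(byId[["lat2"]]@order, 2L)
  expect_equal(byId[["lat1"]]@parentId, "axis")
  expect_equal(byId[["lat1"]]@insertionIndex, 2L)   # nearest node to (0,2)
  expect_equal(byId[["lat2"]]@insertionIndex, 3L)
  # order consistency invariant
  for (r in roots(tree)) {
    if (r@order > 1L) {
      expect_equal(byId[[r@parentId]]@order, r@order - 1L)
    }
  }
})

test_that("read(write(tree)) reproduces coordinates, diameters and ages", {
  tree <- generateRootSystem(genotypePreset("mock"), seed = 42)
  path <- withr::local_tempfile(fileext = ".rsml")
  writeRSML(tree, path)
  tree2 <- readRSML(path)[[1]]
  expect_identical(lengthUnit(tree2), "cm")
  r1 <- roots(tree); r2 <- roots(tree2)
  names(r1) <- vapply(r1, function(r) r@id, character(1))
  names(r2) <- vapply(r2, function(r) r@id, character(1))
  expect_setequal(names(r1), names(r2))
  for (id in names(r1)) {
    expect_equal(as.matrix(r1[[id]]@nodes), as.matrix(r2[[id]]@nodes),
                 tolerance = 1e-6)
    expect_identical(r1[[id]]@order, r2[[id]]@order)
    expect_identical(r1[[id]]@insertionIndex, r2[[id]]@insertionIndex)
  }
})

test_that("writeRSML validates its input before writing", {
  path <- withr::local_tempfile(fileext = ".rsml")
  expect_error(writeRSML(list(), path), "no trees")
  expect_false(file.exists(path))
  expect_error(writeRSML(list(1), path), "RootSystemTree")
  expect_false(file.exists(path))
})

test_that("a one-root tree writes one root element with two points", {
  path <- withr::local_tempfile(fileext = ".rsml")
  writeRSML(rootSystemTree("p", list(
    Root("r", data.frame(x = c(0, 0), y = c(0, 5), diameter = 0.1)))), path)
  doc <- xml2::read_xml(path)
  expect_length(xml2::xml_find_all(doc, "//root"), 1)
  expect_length(xml2::xml_find_all(doc, "//point"), 2)
  expect_equal(xml2::xml_text(xml2::xml_find_first(doc, "//metadata/unit")), "cm")
})

test_that("malformed or invalid documents raise informative errors", {
  expect_error(readRSML("<rsml><scene></rsml>"), regexp = ".")   # parse error
  expect_error(readRSML("<notrsml/>"), "rsml")
  expect_error(readRSML("<rsml><scene/></rsml>"), "no scene/plant")
  oneNode <- '<rsml><metadata><unit>cm</unit></metadata><scene><plant><root ID="stub">
    <geometry><polyline><point x="0" y="0"/></polyline></geometry></root></plant></scene></rsml>'
  expect_error(readRSML(oneNode), "stub")
  noGeom <- '<rsml><metadata><unit>cm</unit></metadata><scene><plant><root ID="bare"/></plant></scene></rsml>'
  expect_error(readRSML(noGeom), "bare.*geometry")
})

test_that("root-level diameter dialect is broadcast and age functions are detected", {
  doc <- '<rsml><metadata><unit>cm</unit></metadata><scene><plant ID="p"><root ID="r" diameter="0.3">
    <geometry><polyline><point x="0" y="0"/><point x="0" y="4"/></polyline></geometry>
    <functions><function name="Time_since_emergence" domain="polyline">
      <sample value="0"/><sample value="2"/></function></functions>
  </root></plant></scene></rsml>'
  tree <- readRSML(doc)[[1]]
  nd <- roots(tree)[[1]]@nodes
  expect_equal(nd$diameter, c(0.3, 0.3))
  expect_equal(nd$age, c(0, 2))
  st <- buildSegmentTable(tree)
  expect_equal(segments(st)$growth_rate, 2)        # 4 length units / 2 days
})

test_that("flipY mirrors the vertical axis on read", {
  up <- sub('y="5"', 'y="-5"', minimalRSML)
  tree <- readRSML(up, flipY = TRUE)[[1]]
  expect_equal(roots(tree)[[1]]@nodes$y, c(0, 5))
})
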