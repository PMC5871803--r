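# RSML 1.0 reader/writer.
#
# Coordinate convention: y increases downward (depth positive). Readers of
# files produced with the opposite convention can set flipY = TRUE. No unit
# conversion is ever performed; the metadata unit label travels verbatim.

.xmlText1 <- function(node, xpath) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
}

.sampleValues <- function(fn) {
  smp <- xml2::xml_find_all(fn, "./sample")
  if (!length(smp)) return(numeric(0))
  v <- xml2::xml_attr(smp, "value")
  if (all(is.na(v))) v <- xml2::xml_text(smp)
  as.numeric(v)
}

# Parse one <root> element (and its nested laterals) into Root objects.
.parseRoot <- function(node, order, parentId, parentNodes, counter, flipY) {
  id <- xml2::xml_attr(node, "ID")
  if (is.na(id)) id <- xml2::xml_attr(node, "id")
  if (is.na(id)) id <- sprintf("root_%d", counter$bump())

  pts <- xml2::xml_find_all(node, "./geometry/polyline/point")
  if (!length(pts)) stop(sprintf("root '%s': missing geometry", id), call. = FALSE)
  x <- as.numeric(xml2::xml_attr(pts, "x"))
  y <- as.numeric(xml2::xml_attr(pts, "y"))
  z <- as.numeric(xml2::xml_attr(pts, "z"))
  z[is.na(z)] <- 0
  if (flipY) y <- -y
  if (length(x) < 2L) {
    stop(sprintf("root '%s': polyline has fewer than 2 nodes", id), call. = FALSE)
  }

  fns <- xml2::xml_find_all(node, "./functions/function")
  fnames <- tolower(xml2::xml_attr(fns, "name"))
  diameter <- rep(NA_real_, length(x))
  age <- rep(NA_real_, length(x))
  for (k in seq_along(fns)) {
    vals <- .sampleValues(fns[[k]])
    if (length(vals) != length(x)) next
    if (grepl("diam", fnames[k])) diameter <- vals
    if (grepl("age|time", fnames[k])) age <- vals
  }
  if (all(is.na(diameter))) {
    # root-level diameter dialect: a single property or attribute, broadcast
    d1 <- xml2::xml_attr(node, "diameter")
    if (is.na(d1)) {
      d1 <- xml2::xml_attr(
        xml2::xml_find_first(
          node, "./properties/property[translate(@name,'DIAMETER','diameter')='diameter']"),
        "value")
    }
    diameter <- rep(if (is.na(d1)) 0 else as.numeric(d1), length(x))
  }

  insertion <- NA_integer_
  if (!is.null(parentNodes)) {
    d2 <- (parentNodes$x - x[1])^2 + (parentNodes$y - y[1])^2 +
      (parentNodes$z - z[1])^2
    insertion <- which.min(d2)
  }
  root <- Root(id, data.frame(x = x, y = y, z = z, diameter = diameter,
                              age = age),
               order = order, parentId = parentId,
               insertionIndex = insertion)

  out <- list(root)
  for (child in xml2::xml_find_all(node, "./root")) {
    out <- c(out, .parseRoot(child, order + 1L, id, root@nodes, counter, flipY))
  }
  out
}

#' Read RSML files
#'
#' Parses a Root System Markup Language (RSML 1.0) document into one
#' [RootSystemTree-class] per `<plant>`. Per-node `diameter` and age-like
#' functions (any `function` whose name contains "age" or "time",
#' case-insensitively) are attached to the nodes; a single root-level
#' diameter is broadcast to all nodes of that root. 2D files yield z = 0.
#'
#' @param path path to an RSML file, or a string containing the XML itself.
#' @param flipY set TRUE when the file encodes y increasing upward; rootTDA
#'   uses the y-down convention (depth positive).
#' @return A list of [RootSystemTree-class] objects (one per plant).
#' @seealso [writeRSML()], [buildSegmentTable()]
#' @examples
#' rsml <- system.file("extdata", "ytree.rsml", package = "rootTDA")
#' trees <- readRSML(rsml)
#' trees[[1]]
#' @export
readRSML <- function(path, flipY = FALSE) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "rsml") {
    stop("not an RSML document (missing <rsml> root element)", call. = FALSE)
  }
  unit <- .xmlText1(doc, "./metadata/unit")
  if (is.na(unit) || !nzchar(unit)) unit <- "cm"
  resolution <- suppressWarnings(as.numeric(.xmlText1(doc, "./metadata/resolution")))
  if (is.na(resolution)) resolution <- 1
  label <- if (is.character(path) && length(path) == 1L && file.exists(path)) {
    basename(path)
  } else ""

  plants <- xml2::xml_find_all(doc, "./scene/plant")
  if (!length(plants)) stop("RSML document contains no scene/plant", call. = FALSE)

  trees <- vector("list", length(plants))
  for (i in seq_along(plants)) {
    pid <- xml2::xml_attr(plants[[i]], "ID")
    if (is.na(pid)) pid <- xml2::xml_attr(plants[[i]], "id")
    if (is.na(pid)) pid <- sprintf("plant_%d", i)
    counter <- local({n <- 0L; list(bump = function() {n <<- n + 1L; n})})
    roots <- list()
    for (rn in xml2::xml_find_all(plants[[i]], "./root")) {
      roots <- c(roots, .parseRoot(rn, 1L, NA_character_, NULL, counter, flipY))
    }
    if (!length(roots)) {
      stop(sprintf("plant '%s' contains no root", pid), call. = FALSE)
    }
    trees[[i]] <- rootSystemTree(pid, roots, unit = unit,
                                 resolution = resolution, sourceFile = label)
  }
  trees
}

.fmt <- function(v) sprintf("%.9g", v)

#' Write RSML files
#'
#' Serialises [RootSystemTree-class] objects into a schema-conformant RSML
#' 1.0 document: a metadata block (version, unit, resolution), one
#' `<plant>` per tree in a single scene, nested `<root>` elements with
#' `geometry/polyline/point` nodes and per-node `diameter` (and, when
#' present, `age`) functions.
#'
#' @param trees a [RootSystemTree-class] or list of them.
#' @param path destination file.
#' @return Invisibly, `path`.
#' @seealso [readRSML()]
#' @export
writeRSML <- function(trees, path) {
  if (is(trees, "RootSystemTree")) trees <- list(trees)
  if (!length(trees)) stop("no trees to write", call. = FALSE)
  for (t in trees) {
    if (!is(t, "RootSystemTree")) stop("inputs must be RootSystemTree objects", call. = FALSE)
    validObject(t)
  }

  doc <- xml2::xml_new_root("rsml", version = "1.0")
  meta <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(meta, "version", "1")
  xml2::xml_add_child(meta, "unit", trees[[1]]@unit)
  xml2::xml_add_child(meta, "resolution", .fmt(trees[[1]]@resolution))
  xml2::xml_add_child(meta, "software", "rootTDA")
  scene <- xml2::xml_add_child(doc, "scene")

  writeRoot <- function(parentNode, tree, root) {
    rn <- xml2::xml_add_child(parentNode, "root", ID = root@id)
    geom <- xml2::xml_add_child(rn, "geometry")
    poly <- xml2::xml_add_child(geom, "polyline")
    nd <- root@nodes
    for (k in seq_len(nrow(nd))) {
      xml2::xml_add_child(poly, "point", x = .fmt(nd$x[k]), y = .fmt(nd$y[k]),
                          z = .fmt(nd$z[k]))
    }
    fns <- xml2::xml_add_child(rn, "functions")
    dfn <- xml2::xml_add_child(fns, "function", name = "diameter",
                               domain = "polyline")
    for (k in seq_len(nrow(nd))) {
      xml2::xml_add_child(dfn, "sample", value = .fmt(nd$diameter[k]))
    }
    if (!all(is.na(nd$age))) {
      afn <- xml2::xml_add_child(fns, "function", name = "age",
                                 domain = "polyline")
      for (k in seq_len(nrow(nd))) {
        xml2::xml_add_child(afn, "sample", value = .fmt(nd$age[k]))
      }
    }
    for (child in .childRoots(tree, root@id)) writeRoot(rn, tree, child)
  }

  for (tree in trees) {
    pl <- xml2::xml_add_child(scene, "plant", ID = tree@plantId)
    for (root in tree@roots) {
      if (root@order == 1L) writeRoot(pl, tree, root)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.childRoots <- function(tree, id) {
  Filter(function(r) !is.na(r@parentId) && r@parentId == id, tree@roots)
}
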