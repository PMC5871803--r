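#' @import methods
NULL

#' Root: one root axis of a root system
#'
#' A single root axis: an ordered polyline of nodes with per-node diameters
#' and (optionally) ages, plus its topological attachment to a parent root.
#' Node coordinates follow the y-down convention (depth increases with y);
#' 2D data carry z = 0.
#'
#' @slot id character(1), unique within the plant.
#' @slot order integer(1), branching order (1 = seminal/primary axis).
#' @slot parentId character(1) id of the parent root, or `NA` for order 1.
#' @slot insertionIndex integer(1) index of the parent-polyline node nearest
#'   the branching point (`NA` for order-1 roots).
#' @slot nodes data.frame with columns `x`, `y`, `z`, `diameter`, `age`
#'   (age may be all `NA`), at least two rows.
#'
#' @exportClass Root
setClass("Root",
  representation(
    id = "character",
    order = "integer",
    parentId = "character",
    insertionIndex = "integer",
    nodes = "data.frame"
  )
)

setValidity("Root", function(object) {
  msg <- character(0)
  nd <- object@nodes
  need <- c("x", "y", "z", "diameter", "age")
  if (!all(need %in% names(nd))) {
    return(sprintf("root '%s': nodes must have columns %s",
                   object@id, paste(need, collapse = ", ")))
  }
  if (nrow(nd) < 2L) {
    msg <- c(msg, sprintf("root '%s' has fewer than 2 nodes", object@id))
  }
  coords <- as.matrix(nd[, c("x", "y", "z")])
  if (!all(is.finite(coords))) {
    msg <- c(msg, sprintf("root '%s': non-finite coordinates", object@id))
  }
  if (any(!is.finite(nd$diameter)) || any(nd$diameter < 0)) {
    msg <- c(msg, sprintf("root '%s': diameters must be finite and >= 0", object@id))
  }
  age <- nd$age[!is.na(nd$age)]
  if (length(age) && (any(age < 0) || is.unsorted(age))) {
    msg <- c(msg, sprintf("root '%s': ages must be >= 0 and non-decreasing", object@id))
  }
  if (object@order < 1L) {
    msg <- c(msg, sprintf("root '%s': order must be >= 1", object@id))
  }
  if ((object@order == 1L) != is.na(object@parentId)) {
    msg <- c(msg, sprintf("root '%s': order 1 iff parentId is NA", object@id))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Root
#'
#' @param id root identifier, unique within the plant.
#' @param nodes data.frame (or matrix) with columns `x`, `y` and optionally
#'   `z`, `diameter`, `age`; missing `z` is set to 0, missing `diameter`
#'   to 0, missing `age` to `NA`.
#' @param order branching order (1 for a first-order axis).
#' @param parentId id of the parent root or `NA`.
#' @param insertionIndex node index on the parent polyline where this root
#'   inserts (`NA` for order-1 roots).
#' @return A [Root-class] object.
#' @examples
#' Root("r1", data.frame(x = c(0, 0), y = c(0, 5), diameter = 0.1))
#' @export
Root <- function(id, nodes, order = 1L, parentId = NA_character_,
                 insertionIndex = NA_integer_) {
  nodes <- as.data.frame(nodes)
  if (is.null(nodes$z)) nodes$z <- 0
  if (is.null(nodes$diameter)) nodes$diameter <- 0
  if (is.null(nodes$age)) nodes$age <- NA_real_
  nodes <- data.frame(x = as.numeric(nodes$x), y = as.numeric(nodes$y),
                      z = as.numeric(nodes$z),
                      diameter = as.numeric(nodes$diameter),
                      age = as.numeric(nodes$age))
  new("Root", id = as.character(id), order = as.integer(order),
      parentId = as.character(parentId),
      insertionIndex = as.integer(insertionIndex), nodes = nodes)
}

#' RootSystemTree: one plant's root architecture
#'
#' The hierarchical architecture of a single plant: a set of [Root-class]
#' axes connected by parent links. Roots of order 1 are the bases of the
#' system; all laterals must reference a parent of exactly one order less.
#'
#' @slot plantId character(1).
#' @slot roots list of [Root-class].
#' @slot unit length-unit label propagated from RSML metadata (default "cm").
#' @slot resolution numeric(1) RSML resolution metadata (pixels per unit).
#' @slot sourceFile character(1) provenance label (file name or "" ).
#'
#' @exportClass RootSystemTree
setClass("RootSystemTree",
  representation(
    plantId = "character",
    roots = "list",
    unit = "character",
    resolution = "numeric",
    sourceFile = "character"
  ),
  prototype(unit = "cm", resolution = 1, sourceFile = "")
)

setValidity("RootSystemTree", function(object) {
  msg <- character(0)
  if (!length(object@roots)) return("plant has no roots")
  ids <- vapply(object@roots, function(r) r@id, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "root ids are not unique")
  orders <- vapply(object@roots, function(r) r@order, integer(1))
  parents <- vapply(object@roots, function(r) r@parentId, character(1))
  if (!any(orders == 1L)) msg <- c(msg, "no first-order root")
  lateral <- which(orders > 1L)
  for (i in lateral) {
    j <- match(parents[i], ids)
    if (is.na(j)) {
      msg <- c(msg, sprintf("root '%s': parent '%s' not found", ids[i], parents[i]))
    } else if (orders[j] != orders[i] - 1L) {
      msg <- c(msg, sprintf("root '%s': parent order %d, expected %d",
                            ids[i], orders[j], orders[i] - 1L))
    } else {
      ii <- object@roots[[i]]@insertionIndex
      if (is.na(ii) || ii < 1L || ii > nrow(object@roots[[j]]@nodes)) {
        msg <- c(msg, sprintf("root '%s': invalid insertion index", ids[i]))
      }
    }
  }
  for (r in object@roots) {
    v <- validObject(r, test = TRUE)
    if (!isTRUE(v)) msg <- c(msg, v)
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RootSystemTree
#'
#' @param plantId plant identifier.
#' @param roots list of [Root-class] objects.
#' @param unit length-unit label (propagated verbatim, never converted).
#' @param resolution RSML resolution metadata.
#' @param sourceFile provenance label.
#' @return A validated [RootSystemTree-class].
#' @examples
#' r <- Root("r1", data.frame(x = c(0, 0), y = c(0, 5), diameter = 0.1))
#' rootSystemTree("plant1", list(r))
#' @export
rootSystemTree <- function(plantId, roots, unit = "cm", resolution = 1,
                           sourceFile = "") {
  obj <- new("RootSystemTree", plantId = as.character(plantId), roots = roots,
             unit = as.character(unit), resolution = as.numeric(resolution),
             sourceFile = as.character(sourceFile))
  validObject(obj)
  obj
}

#' SegmentTable: per-segment flat table of one or more root systems
#'
#' One row per inter-node segment (the straight line between two
#' consecutive polyline nodes), with geometry, topology and geodesic
#' distance columns. See [buildSegmentTable()] for the column schema.
#'
#' @slot records data.frame, one row per segment.
#' @slot unit character(1) length-unit label.
#'
#' @exportClass SegmentTable
setClass("SegmentTable",
  representation(records = "data.frame", unit = "character"),
  prototype(unit = "cm")
)

setValidity("SegmentTable", function(object) {
  req <- .segmentTableColumns()
  missing <- setdiff(req, names(object@records))
  if (length(missing)) {
    return(sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  }
  if (nrow(object@records) && any(object@records$length <= 0)) {
    return("segment lengths must be > 0")
  }
  TRUE
})

#' Barcode: H0 persistence barcode of one root system
#'
#' The multiset of zero-order persistence pairs of the geodesic distance
#' function over a root system, stored as a matrix with columns
#' `dimension`, `birth`, `death` (one row per bar). Births and deaths are
#' non-negative geodesic values with birth > death; the globally oldest
#' component dies at 0.
#'
#' @slot pairs numeric matrix with columns `dimension`, `birth`, `death`.
#' @slot sourceId character(1) identifier of the root system.
#'
#' @exportClass Barcode
setClass("Barcode",
  representation(pairs = "matrix", sourceId = "character")
)

setValidity("Barcode", function(object) {
  p <- object@pairs
  if (ncol(p) != 3L || !identical(colnames(p), c("dimension", "birth", "death"))) {
    return("pairs must have columns dimension, birth, death")
  }
  if (nrow(p)) {
    if (any(p[, "death"] < 0)) return("deaths must be >= 0")
    if (any(p[, "birth"] <= p[, "death"])) return("birth must exceed death")
    # the globally oldest component dies at 0; root systems with several
    # first-order axes merge the younger axes at the collar, also at 0
    if (!any(p[, "death"] == 0)) {
      return("one pair must have death 0 (the base component)")
    }
    if (p[which.max(p[, "birth"]), "death"] != 0) {
      return("the maximal-birth pair must die at 0")
    }
  }
  TRUE
})

#' Construct a Barcode
#'
#' @param pairs matrix (or data.frame) with columns dimension, birth, death.
#' @param sourceId identifier of the root system the barcode describes.
#' @return A [Barcode-class] object.
#' @export
Barcode <- function(pairs, sourceId = "") {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) == 2L) pairs <- cbind(0, pairs)
  colnames(pairs) <- c("dimension", "birth", "death")
  new("Barcode", pairs = pairs, sourceId = as.character(sourceId))
}

#' LinkGraph: Fitter link representation of a root system
#'
#' Decomposes a root system into links: the portions of root between the
#' base and the first branching point, between consecutive branching
#' points (internal links), and between the last branching point and a
#' root tip (external links). The link graph is a rooted tree whose
#' external links are the root tips.
#'
#' @slot links data.frame with columns `link` (integer id), `parent`
#'   (integer id of parent link, 0 for base links) and `kind`
#'   ("internal" or "external").
#' @slot sourceId character(1).
#'
#' @exportClass LinkGraph
setClass("LinkGraph",
  representation(links = "data.frame", sourceId = "character")
)

setValidity("LinkGraph", function(object) {
  l <- object@links
  if (!all(c("link", "parent", "kind") %in% names(l))) {
    return("links must have columns link, parent, kind")
  }
  if (!all(l$kind %in% c("internal", "external"))) {
    return("kind must be 'internal' or 'external'")
  }
  if (nrow(l) && !any(l$parent == 0L)) return("no base link")
  TRUE
})

#' FitterIndices: Fitter's topological indices
#'
#' @slot magnitude integer(1), number of external links (root tips).
#' @slot altitude integer(1), number of links on the longest base-to-tip path.
#' @slot extPathLength integer(1), sum over external links of the number of
#'   links on the base-to-tip path.
#'
#' @exportClass FitterIndices
setClass("FitterIndices",
  representation(magnitude = "integer", altitude = "integer",
                 extPathLength = "integer")
)

setValidity("FitterIndices", function(object) {
  mu <- object@magnitude; al <- object@altitude; pe <- object@extPathLength
  msg <- character(0)
  if (mu < 1L || al < 1L || pe < 1L) msg <- c(msg, "indices must be >= 1")
  if (al > mu) msg <- c(msg, "altitude cannot exceed magnitude")
  if (mu > pe) msg <- c(msg, "magnitude cannot exceed external path length")
  if (length(msg)) msg else TRUE
})

#' BottleneckMatrix: pairwise bottleneck distances between barcodes
#'
#' @slot values symmetric numeric matrix, zero diagonal, dimnames = ids.
#'
#' @exportClass BottleneckMatrix
setClass("BottleneckMatrix", representation(values = "matrix"))

setValidity("BottleneckMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v))) {
    return("dimnames must carry matching source ids")
  }
  if (any(v < 0)) return("distances must be >= 0")
  if (any(abs(diag(v)) > 1e-12)) return("diagonal must be zero")
  if (max(abs(v - t(v))) > 1e-9) return("matrix must be symmetric")
  TRUE
})

#' GenotypeParams: parameters of the synthetic root system generator
#'
#' Parameter set of the minimal root growth model used to emulate
#' ArchiSimple-style simulations. Each named genotype preset (see
#' [genotypePreset()]) is the `mock` baseline with one parameter changed.
#'
#' @slot name preset label.
#' @slot nFirstOrder number of first-order axes emitted at the collar.
#' @slot elongationRate axis elongation rate, length units per day.
#' @slot interLateralDistance parent growth between successive lateral
#'   initiations (length units).
#' @slot insertionAngleMean,insertionAngleSd normal law of the lateral
#'   insertion angle away from the parent heading, degrees.
#' @slot gravitropism per-step reorientation of headings toward the
#'   downward vertical, in [0, 1].
#' @slot headingNoiseSd sd of the per-step Gaussian heading jitter
#'   (radians on each transverse component).
#' @slot maxOrder deepest branching order allowed to form.
#' @slot diameterBase diameter of first-order axes (length units).
#' @slot diameterRatioLateral multiplicative diameter taper per order, (0, 1].
#' @slot duration simulated time, days.
#' @slot step time step, days.
#'
#' @exportClass GenotypeParams
setClass("GenotypeParams",
  representation(
    name = "character",
    nFirstOrder = "integer",
    elongationRate = "numeric",
    interLateralDistance = "numeric",
    insertionAngleMean = "numeric",
    insertionAngleSd = "numeric",
    gravitropism = "numeric",
    headingNoiseSd = "numeric",
    maxOrder = "integer",
    diameterBase = "numeric",
    diameterRatioLateral = "numeric",
    duration = "numeric",
    step = "numeric"
  )
)

setValidity("GenotypeParams", function(object) {
  msg <- character(0)
  pos <- c(nFirstOrder = object@nFirstOrder,
           elongationRate = object@elongationRate,
           interLateralDistance = object@interLateralDistance,
           diameterBase = object@diameterBase,
           duration = object@duration, step = object@step)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) msg <- c(msg, sprintf("must be > 0: %s", paste(bad, collapse = ", ")))
  if (object@gravitropism < 0 || object@gravitropism > 1) {
    msg <- c(msg, "gravitropism must be in [0, 1]")
  }
  if (object@diameterRatioLateral <= 0 || object@diameterRatioLateral > 1) {
    msg <- c(msg, "diameterRatioLateral must be in (0, 1]")
  }
  if (object@maxOrder < 1L) msg <- c(msg, "maxOrder must be >= 1")
  if (length(msg)) msg else TRUE
})

#' OrdinationResult: low-dimensional embedding of root systems
#'
#' @slot ids character vector of root system ids (one per row of scores).
#' @slot coordinates numeric matrix of scores, one row per id.
#' @slot stress Kruskal stress-1 (NMDS) or NA (PCA).
#' @slot varianceExplained per-axis explained-variance fractions (PCA) or
#'   empty (NMDS).
#' @slot loadings variable loadings (PCA) or empty matrix (NMDS).
#' @slot method "NMDS" or "PCA".
#' @slot seed integer seed used (NA when deterministic).
#'
#' @exportClass OrdinationResult
setClass("OrdinationResult",
  representation(
    ids = "character",
    coordinates = "matrix",
    stress = "numeric",
    varianceExplained = "numeric",
    loadings = "matrix",
    method = "character",
    seed = "integer"
  )
)

setValidity("OrdinationResult", function(object) {
  if (nrow(object@coordinates) != length(object@ids)) {
    return("one coordinate row per id required")
  }
  if (object@method == "NMDS" && (is.na(object@stress) || object@stress < 0)) {
    return("NMDS stress must be a non-negative number")
  }
  if (object@method == "PCA" && length(object@varianceExplained) &&
      sum(object@varianceExplained) > 1 + 1e-8) {
    return("variance fractions must sum to <= 1")
  }
  TRUE
})
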