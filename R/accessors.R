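# Generics and accessors for the core classes.

#' @rdname accessors
#' @export
setGeneric("plantId", function(x) standardGeneric("plantId"))
#' @rdname accessors
#' @export
setGeneric("roots", function(x) standardGeneric("roots"))
#' @rdname accessors
#' @export
setGeneric("lengthUnit", function(x) standardGeneric("lengthUnit"))
#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @rdname accessors
#' @export
setGeneric("persistencePairs", function(x) standardGeneric("persistencePairs"))
#' @rdname accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("magnitude", function(x) standardGeneric("magnitude"))
#' @rdname accessors
#' @export
setGeneric("altitude", function(x) standardGeneric("altitude"))
#' @rdname accessors
#' @export
setGeneric("extPathLength", function(x) standardGeneric("extPathLength"))
#' @rdname accessors
#' @export
setGeneric("totalRootLength", function(x) standardGeneric("totalRootLength"))
#' @rdname accessors
#' @export
setGeneric("tipCount", function(x) standardGeneric("tipCount"))

#' Accessors for rootTDA classes
#'
#' `plantId()`, `roots()` and `lengthUnit()` read the corresponding slots
#' of a [RootSystemTree-class]; `segments()` returns the data.frame of a
#' [SegmentTable-class]; `persistencePairs()` returns the bar matrix of a
#' [Barcode-class]; `magnitude()`, `altitude()` and `extPathLength()` read
#' [FitterIndices-class]; `totalRootLength()` and `tipCount()` summarise a
#' tree or table.
#'
#' @param x object.
#' @return The slot value (see details above).
#' @name accessors
NULL

#' @rdname accessors
setMethod("plantId", "RootSystemTree", function(x) x@plantId)
#' @rdname accessors
setMethod("roots", "RootSystemTree", function(x) x@roots)
#' @rdname accessors
setMethod("lengthUnit", "RootSystemTree", function(x) x@unit)
#' @rdname accessors
setMethod("lengthUnit", "SegmentTable", function(x) x@unit)
#' @rdname accessors
setMethod("segments", "SegmentTable", function(x) x@records)
#' @rdname accessors
setMethod("sourceId", "Barcode", function(x) x@sourceId)
#' @rdname accessors
setMethod("persistencePairs", "Barcode", function(x) x@pairs)
#' @rdname accessors
setMethod("magnitude", "FitterIndices", function(x) x@magnitude)
#' @rdname accessors
setMethod("altitude", "FitterIndices", function(x) x@altitude)
#' @rdname accessors
setMethod("extPathLength", "FitterIndices", function(x) x@extPathLength)

.rootLength <- function(root) {
  nd <- root@nodes
  d <- sqrt(diff(nd$x)^2 + diff(nd$y)^2 + diff(nd$z)^2)
  sum(d)
}

#' @rdname accessors
setMethod("totalRootLength", "RootSystemTree", function(x) {
  sum(vapply(x@roots, .rootLength, numeric(1)))
})
#' @rdname accessors
setMethod("totalRootLength", "SegmentTable", function(x) sum(x@records$length))

#' @rdname accessors
setMethod("tipCount", "RootSystemTree", function(x) length(.treeTips(x)))

#' @describeIn Barcode-class number of bars
#' @param x a Barcode
#' @export
setMethod("length", "Barcode", function(x) nrow(x@pairs))

#' Coerce rootTDA containers to base types
#'
#' @param x object to coerce.
#' @param ... ignored.
#' @name coercion
NULL

#' @rdname coercion
#' @export
setMethod("as.matrix", "Barcode", function(x, ...) x@pairs)
#' @rdname coercion
#' @export
setMethod("as.matrix", "BottleneckMatrix", function(x, ...) x@values)
#' @rdname coercion
#' @param row.names,optional passed through (unused).
#' @export
setMethod("as.data.frame", "SegmentTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@records)

setMethod("show", "RootSystemTree", function(object) {
  n <- length(object@roots)
  orders <- vapply(object@roots, function(r) r@order, integer(1))
  cat(sprintf("RootSystemTree '%s': %d root%s (max order %d), TRL %.3f %s\n",
              object@plantId, n, if (n == 1) "" else "s", max(orders),
              totalRootLength(object), object@unit))
})

setMethod("show", "SegmentTable", function(object) {
  r <- object@records
  cat(sprintf("SegmentTable: %d segments, %d plants, %d columns, unit '%s'\n",
              nrow(r), length(unique(r$plant)), ncol(r), object@unit))
})

setMethod("show", "Barcode", function(object) {
  cat(sprintf("Barcode '%s': %d H0 bars, total persistence %.4f\n",
              object@sourceId, nrow(object@pairs),
              sum(object@pairs[, "birth"] - object@pairs[, "death"])))
})

setMethod("show", "FitterIndices", function(object) {
  cat(sprintf("FitterIndices: magnitude %d, altitude %d, external path length %d\n",
              object@magnitude, object@altitude, object@extPathLength))
})

setMethod("show", "BottleneckMatrix", function(object) {
  cat(sprintf("BottleneckMatrix: %d x %d, max distance %.4f\n",
              nrow(object@values), ncol(object@values),
              if (length(object@values)) max(object@values) else 0))
})

setMethod("show", "GenotypeParams", function(object) {
  cat(sprintf(paste0(
    "GenotypeParams '%s': %d first-order axes, elongation %.2f/day, ",
    "inter-lateral %.2f, gravitropism %.2f, max order %d, %g days\n"),
    object@name, object@nFirstOrder, object@elongationRate,
    object@interLateralDistance, object@gravitropism, object@maxOrder,
    object@duration))
})

setMethod("show", "OrdinationResult", function(object) {
  extra <- if (object@method == "NMDS") {
    sprintf("stress %.4g", object@stress)
  } else {
    sprintf("PC1 %.1f%% of variance", 100 * object@varianceExplained[1])
  }
  cat(sprintf("OrdinationResult (%s): %d points in %d dimensions, %s\n",
              object@method, length(object@ids), ncol(object@coordinates), extra))
})
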