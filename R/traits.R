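# Aggregated architectural traits per root system (architect-style panel).

.traitNames <- function() {
  c("TRL", "L1R", "TN1R", "TNLR", "TLRL", "N2LR", "N3LR", "L2LR", "L3LR",
    "MD1", "MDLR", "D2LR", "Convexhull", "Stot", "Vtot",
    "Magnitude", "Altitude", "ExtPathLength", "Depth", "Width")
}

.weightedMeanDiameter <- function(rec) {
  if (!nrow(rec)) return(NA_real_)
  d <- (rec$diameter1 + rec$diameter2) / 2
  sum(d * rec$length) / sum(rec$length)
}

#' Compute the aggregated trait vector of one root system
#'
#' The 20-trait panel describing a root system's global morphology,
#' architecture and topology: TRL (total root length), L1R (total
#' first-order root length), TN1R (number of first-order roots), TNLR
#' (total number of lateral roots), TLRL (total lateral root length),
#' N2LR/N3LR (numbers of second-/third-order roots), L2LR/L3LR (total
#' second-/third-order root lengths), MD1/MDLR (length-weighted mean
#' diameters of first-order and lateral roots), D2LR (second-order roots
#' per unit first-order length), Convexhull (hull area for 2D data, hull
#' volume for 3D), Stot (total root surface), Vtot (total root volume),
#' the three Fitter indices (Magnitude, Altitude, ExtPathLength), Depth
#' (vertical extent of the node cloud, y-down) and Width (maximum
#' horizontal extent).
#'
#' @param table a [SegmentTable-class] holding (or restricted to) the plant.
#' @param plant plant id; may be omitted when the table holds one plant.
#' @param indices optional precomputed [FitterIndices-class]; computed
#'   from the table when missing.
#' @return Named numeric vector of the 20 traits.
#' @examples
#' r <- Root("axis", data.frame(x = c(0, 0), y = c(0, 5), diameter = 0.1))
#' st <- buildSegmentTable(rootSystemTree("p1", list(r)))
#' computeTraits(st)[c("TRL", "TN1R", "MD1")]
#' @export
computeTraits <- function(table, plant = NULL, indices = NULL) {
  stopifnot(is(table, "SegmentTable"))
  rec <- table@records
  if (is.null(plant)) {
    plants <- unique(rec$plant)
    if (length(plants) != 1L) stop("table holds several plants; name one", call. = FALSE)
    plant <- plants
  }
  rec <- rec[rec$plant == plant, , drop = FALSE]
  if (!nrow(rec)) stop(sprintf("plant '%s' not in table", plant), call. = FALSE)
  sub <- new("SegmentTable", records = rec, unit = table@unit)
  if (is.null(indices)) indices <- fitterIndices(sub)

  perRoot <- unique(rec[, c("root", "order")])
  first <- rec[rec$order == 1L, , drop = FALSE]
  lat <- rec[rec$order >= 2L, , drop = FALSE]
  L1R <- sum(first$length)
  N2LR <- sum(perRoot$order == 2L)

  nodes <- unique(rbind(
    stats::setNames(rec[, c("x1", "y1", "z1")], c("x", "y", "z")),
    stats::setNames(rec[, c("x2", "y2", "z2")], c("x", "y", "z"))
  ))

  c(TRL = sum(rec$length),
    L1R = L1R,
    TN1R = sum(perRoot$order == 1L),
    TNLR = sum(perRoot$order >= 2L),
    TLRL = sum(lat$length),
    N2LR = N2LR,
    N3LR = sum(perRoot$order == 3L),
    L2LR = sum(rec$length[rec$order == 2L]),
    L3LR = sum(rec$length[rec$order == 3L]),
    MD1 = .weightedMeanDiameter(first),
    MDLR = if (nrow(lat)) .weightedMeanDiameter(lat) else 0,
    D2LR = N2LR / L1R,
    Convexhull = .convexHullMeasure(nodes),
    Stot = sum(rec$surface),
    Vtot = sum(rec$volume),
    Magnitude = as.numeric(indices@magnitude),
    Altitude = as.numeric(indices@altitude),
    ExtPathLength = as.numeric(indices@extPathLength),
    Depth = diff(range(c(rec$y1, rec$y2))),
    Width = .horizontalWidth(nodes))
}

#' Trait matrix over all plants of a segment table
#'
#' One row per plant (row names are the plant ids), 20 trait columns in a
#' stable order; directly usable as PCA input and exportable as CSV with
#' [writeTraitMatrix()].
#'
#' @param table a [SegmentTable-class] with >= 1 plant.
#' @return data.frame of traits, plants as row names.
#' @export
traitMatrix <- function(table) {
  stopifnot(is(table, "SegmentTable"))
  plants <- unique(table@records$plant)
  m <- t(vapply(plants, function(p) computeTraits(table, p),
                numeric(length(.traitNames()))))
  df <- as.data.frame(m)
  rownames(df) <- plants
  df
}

#' Export a trait matrix as CSV
#'
#' Plants x traits, header row, plant ids in the first column.
#'
#' @param traits data.frame from [traitMatrix()].
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
writeTraitMatrix <- function(traits, path) {
  utils::write.csv(traits, path, row.names = TRUE)
  invisible(path)
}
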