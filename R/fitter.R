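# Fitter's link-based topological indices.
#
# A link is the portion of root between two consecutive branching points,
# between the base and the first branching point, or between the last
# branching point and a root tip. Path lengths count links, not nodes.
# Laterals inserted at the same parent node form a single multi-way
# branching point.

# Shared link decomposition over an abstract per-root description:
# a data.frame with columns id, order, parent, insertion, nNodes.
.linkify <- function(info, sourceId) {
  links <- list()
  addLink <- function(parent, kind) {
    id <- length(links) + 1L
    links[[id]] <<- data.frame(link = id, parent = parent, kind = kind,
                               stringsAsFactors = FALSE)
    id
  }
  descend <- function(rid, parentLink) {
    row <- info[info$id == rid, ]
    kids <- info[!is.na(info$parent) & info$parent == rid, , drop = FALSE]
    idx <- sort(unique(kids$insertion))
    cur <- parentLink
    for (b in idx) {
      if (b > 1L) cur <- addLink(cur, "internal")
      for (kid in kids$id[kids$insertion == b]) descend(kid, cur)
    }
    lastIdx <- if (length(idx)) max(idx) else 1L
    if (lastIdx < row$nNodes) addLink(cur, "external")
  }
  for (rid in info$id[info$order == 1L]) descend(rid, 0L)
  new("LinkGraph", links = do.call(rbind, links), sourceId = sourceId)
}

#' Build the Fitter link graph of a root system
#'
#' Decomposes a root system into its link representation (see
#' [LinkGraph-class]). When a plant carries several first-order axes they
#' are joined at a virtual collar, so the link graph is a single rooted
#' tree whose base links are the collar's children. Accepts either a
#' [RootSystemTree-class] or a [SegmentTable-class] holding one plant.
#'
#' @param x a [RootSystemTree-class], or a [SegmentTable-class] restricted
#'   to a single plant.
#' @return A [LinkGraph-class].
#' @examples
#' axis <- Root("a", data.frame(x = c(0, 0, 0), y = c(0, 2, 5), diameter = 0.1))
#' lat <- Root("l", data.frame(x = c(0, 1), y = c(2, 3), diameter = 0.05),
#'             order = 2, parentId = "a", insertionIndex = 2)
#' buildLinkGraph(rootSystemTree("p", list(axis, lat)))
#' @export
setGeneric("buildLinkGraph", function(x) standardGeneric("buildLinkGraph"))

#' @rdname buildLinkGraph
setMethod("buildLinkGraph", "RootSystemTree", function(x) {
  validObject(x)
  info <- data.frame(
    id = vapply(x@roots, function(r) r@id, character(1)),
    order = vapply(x@roots, function(r) r@order, integer(1)),
    parent = vapply(x@roots, function(r) r@parentId, character(1)),
    insertion = vapply(x@roots, function(r) r@insertionIndex, integer(1)),
    nNodes = vapply(x@roots, function(r) nrow(r@nodes), integer(1)),
    stringsAsFactors = FALSE
  )
  .linkify(info, x@plantId)
})

#' @rdname buildLinkGraph
setMethod("buildLinkGraph", "SegmentTable", function(x) {
  rec <- x@records
  plants <- unique(rec$plant)
  if (length(plants) != 1L) {
    stop("link graph needs a single plant; subset the table first", call. = FALSE)
  }
  info <- do.call(rbind, lapply(split(rec, rec$root), function(rr) {
    data.frame(id = rr$root[1], order = rr$order[1],
               parent = rr$parent_root[1], insertion = rr$insertion_index[1],
               nNodes = max(rr$node), stringsAsFactors = FALSE)
  }))
  rownames(info) <- NULL
  .linkify(info, plants)
})

#' Fitter's topological indices
#'
#' Computes the three Fitter indices of a root system: the magnitude
#' (number of external links, i.e. root tips), the altitude (number of
#' links on the longest base-to-tip path) and the external path length
#' (sum over all external links of the number of links on the base-to-tip
#' path). Accepts a [LinkGraph-class], a [RootSystemTree-class] or a
#' single-plant [SegmentTable-class] (which are first decomposed with
#' [buildLinkGraph()]).
#'
#' @param x a [LinkGraph-class], [RootSystemTree-class] or
#'   [SegmentTable-class].
#' @return A [FitterIndices-class].
#' @examples
#' axis <- Root("a", data.frame(x = c(0, 0, 0), y = c(0, 2, 5), diameter = 0.1))
#' lat <- Root("l", data.frame(x = c(0, 1), y = c(2, 3), diameter = 0.05),
#'             order = 2, parentId = "a", insertionIndex = 2)
#' fitterIndices(rootSystemTree("p", list(axis, lat)))
#' @export
setGeneric("fitterIndices", function(x) standardGeneric("fitterIndices"))

#' @rdname fitterIndices
setMethod("fitterIndices", "LinkGraph", function(x) {
  lk <- x@links
  if (is.null(lk) || !nrow(lk)) stop("empty link graph", call. = FALSE)
  depth <- integer(nrow(lk))
  # links are created parents-first, so a single forward pass suffices
  for (i in seq_len(nrow(lk))) {
    p <- lk$parent[i]
    depth[i] <- if (p == 0L) 1L else depth[p] + 1L
  }
  ext <- lk$kind == "external"
  new("FitterIndices",
      magnitude = sum(ext),
      altitude = max(depth[ext]),
      extPathLength = sum(depth[ext]))
})

#' @rdname fitterIndices
setMethod("fitterIndices", "RootSystemTree", function(x) {
  fitterIndices(buildLinkGraph(x))
})

#' @rdname fitterIndices
setMethod("fitterIndices", "SegmentTable", function(x) {
  fitterIndices(buildLinkGraph(x))
})
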