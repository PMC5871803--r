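# Flattening root systems into per-segment tables with geodesic distances.
#
# The geodesic distance of a node is the distance from the plant base
# measured along the roots: along a first-order axis it accumulates segment
# lengths from the first polyline node; a lateral starts from the geodesic
# value of its insertion node on the parent and accumulates its own lengths.

.segmentTableColumns <- function() {
  c("file", "plant", "root", "order", "parent_root", "apical", "time",
    "x1", "y1", "z1", "x2", "y2", "z2", "diameter1", "diameter2",
    "length", "surface", "volume", "orientation", "growth_rate",
    "geodesic", "branching_node_geodesic", "dist_from_base",
    "node", "insertion_index")
}

# Per-root vectors of node geodesic distances, in root-list order.
.nodeGeodesics <- function(tree) {
  ids <- vapply(tree@roots, function(r) r@id, character(1))
  orders <- vapply(tree@roots, function(r) r@order, integer(1))
  geo <- vector("list", length(ids))
  names(geo) <- ids
  for (i in order(orders)) {
    r <- tree@roots[[i]]
    nd <- r@nodes
    seglen <- sqrt(diff(nd$x)^2 + diff(nd$y)^2 + diff(nd$z)^2)
    g0 <- if (r@order == 1L) 0 else geo[[r@parentId]][r@insertionIndex]
    geo[[r@id]] <- g0 + c(0, cumsum(seglen))
  }
  geo
}

# Coordinates of the base node of each root's order-1 ancestor.
.ancestralBase <- function(tree) {
  ids <- vapply(tree@roots, function(r) r@id, character(1))
  orders <- vapply(tree@roots, function(r) r@order, integer(1))
  base <- vector("list", length(ids))
  names(base) <- ids
  for (i in order(orders)) {
    r <- tree@roots[[i]]
    base[[r@id]] <- if (r@order == 1L) {
      unlist(r@nodes[1, c("x", "y", "z")])
    } else {
      base[[r@parentId]]
    }
  }
  base
}

# Root tips: (root id, node index, geodesic) of every polyline end that has
# no lateral inserted at that very node.
.treeTips <- function(tree, geo = .nodeGeodesics(tree)) {
  tips <- list()
  for (r in tree@roots) {
    n <- nrow(r@nodes)
    blocked <- any(vapply(.childRoots(tree, r@id),
                          function(ch) ch@insertionIndex == n, logical(1)))
    if (!blocked) {
      tips[[length(tips) + 1L]] <- list(root = r@id, node = n,
                                        geodesic = geo[[r@id]][n])
    }
  }
  tips
}

#' Build the per-segment table of one or more root systems
#'
#' Flattens [RootSystemTree-class] objects into a [SegmentTable-class]
#' with one row per inter-node segment (the straight line between two
#' consecutive polyline nodes) and 25 columns: `file`, `plant`, `root`,
#' `order`, `parent_root`, `apical`, `time`, the endpoint coordinates
#' `x1,y1,z1,x2,y2,z2`, endpoint diameters `diameter1`/`diameter2`,
#' `length`, `surface`, `volume`, `orientation`, `growth_rate`,
#' `geodesic`, `branching_node_geodesic`, `dist_from_base`, `node` and
#' `insertion_index`.
#'
#' Segment surface and volume use conical-frustum geometry with slant
#' equal to the segment length L: surface = pi*L*(d1+d2)/2 and
#' volume = (pi*L/12)*(d1^2 + d1*d2 + d2^2). `orientation` is the angle in
#' degrees between the segment and the downward vertical (the +y axis in
#' the y-down convention), in [0, 180]. `growth_rate` is
#' length / (age(distal) - age(proximal)), `NA` when ages are missing or
#' equal. `geodesic` is the geodesic distance of the distal node;
#' `branching_node_geodesic` the geodesic of the root's insertion node on
#' its parent (0 for first-order roots); `dist_from_base` the straight-line
#' distance from the distal node to the plant base. Zero-length segments
#' (coincident consecutive nodes) are dropped with a warning reporting the
#' count.
#'
#' @param trees a [RootSystemTree-class] or list of them.
#' @return A [SegmentTable-class].
#' @examples
#' r <- Root("axis", data.frame(x = c(0, 0, 0), y = c(0, 3, 5),
#'                              diameter = 0.1))
#' st <- buildSegmentTable(rootSystemTree("p1", list(r)))
#' segments(st)[, c("root", "length", "geodesic", "orientation")]
#' @export
buildSegmentTable <- function(trees) {
  if (is(trees, "RootSystemTree")) trees <- list(trees)
  stopifnot(length(trees) > 0)
  out <- vector("list", length(trees))
  dropped <- 0L
  for (ti in seq_along(trees)) {
    tree <- trees[[ti]]
    validObject(tree)
    geo <- .nodeGeodesics(tree)
    bases <- .ancestralBase(tree)
    rows <- vector("list", length(tree@roots))
    for (ri in seq_along(tree@roots)) {
      r <- tree@roots[[ri]]
      nd <- r@nodes
      n <- nrow(nd)
      i1 <- seq_len(n - 1L); i2 <- i1 + 1L
      dx <- nd$x[i2] - nd$x[i1]
      dy <- nd$y[i2] - nd$y[i1]
      dz <- nd$z[i2] - nd$z[i1]
      len <- sqrt(dx^2 + dy^2 + dz^2)
      d1 <- nd$diameter[i1]; d2 <- nd$diameter[i2]
      dt <- nd$age[i2] - nd$age[i1]
      gr <- ifelse(!is.na(dt) & dt > 0, len / dt, NA_real_)
      base <- bases[[r@id]]
      bng <- if (r@order == 1L) 0 else geo[[r@parentId]][r@insertionIndex]
      rows[[ri]] <- data.frame(
        file = tree@sourceFile,
        plant = tree@plantId,
        root = r@id,
        order = r@order,
        parent_root = r@parentId,
        apical = i2 == n,
        time = nd$age[i2],
        x1 = nd$x[i1], y1 = nd$y[i1], z1 = nd$z[i1],
        x2 = nd$x[i2], y2 = nd$y[i2], z2 = nd$z[i2],
        diameter1 = d1, diameter2 = d2,
        length = len,
        surface = pi * len * (d1 + d2) / 2,
        volume = pi * len * (d1^2 + d1 * d2 + d2^2) / 12,
        orientation = acos(pmin(1, pmax(-1, ifelse(len > 0, dy / len, 1)))) * 180 / pi,
        growth_rate = gr,
        geodesic = geo[[r@id]][i2],
        branching_node_geodesic = bng,
        dist_from_base = sqrt((nd$x[i2] - base[1])^2 + (nd$y[i2] - base[2])^2 +
                              (nd$z[i2] - base[3])^2),
        node = i2,
        insertion_index = r@insertionIndex,
        stringsAsFactors = FALSE
      )
      zero <- rows[[ri]]$length <= 0
      if (any(zero)) {
        dropped <- dropped + sum(zero)
        rows[[ri]] <- rows[[ri]][!zero, , drop = FALSE]
      }
    }
    out[[ti]] <- do.call(rbind, rows)
  }
  if (dropped > 0L) {
    warning(sprintf("dropped %d zero-length segment%s", dropped,
                    if (dropped == 1L) "" else "s"), call. = FALSE)
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  new("SegmentTable", records = rec, unit = trees[[1]]@unit)
}

#' Geodesic distance from the plant base to a node
#'
#' The distance measured along the roots between the root system base and
#' the given polyline node (as opposed to the straight-line distance).
#'
#' @param tree a [RootSystemTree-class].
#' @param rootId id of the root carrying the node.
#' @param nodeIndex index of the node on that root's polyline.
#' @return The geodesic distance (same unit as the tree).
#' @examples
#' r <- Root("axis", data.frame(x = c(0, 0), y = c(0, 5), diameter = 0.1))
#' geodesicDistance(rootSystemTree("p1", list(r)), "axis", 2)
#' @export
geodesicDistance <- function(tree, rootId, nodeIndex) {
  stopifnot(is(tree, "RootSystemTree"))
  geo <- .nodeGeodesics(tree)
  if (!rootId %in% names(geo)) {
    stop(sprintf("unknown root '%s'", rootId), call. = FALSE)
  }
  g <- geo[[rootId]]
  if (nodeIndex < 1L || nodeIndex > length(g)) {
    stop(sprintf("root '%s' has no node %d", rootId, nodeIndex), call. = FALSE)
  }
  g[[nodeIndex]]
}

#' Export a SegmentTable as CSV
#'
#' Writes the 25-column segment table with a header row, UTF-8 encoded,
#' "." as the decimal separator.
#'
#' @param table a [SegmentTable-class].
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
writeSegmentTable <- function(table, path) {
  stopifnot(is(table, "SegmentTable"))
  utils::write.csv(table@records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
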