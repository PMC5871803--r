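# H0 persistent homology of the geodesic distance function over a root
# system, by the elder rule: sweeping the geodesic function from its
# maximum down to 0, every root tip (local maximum) births a connected
# component at its geodesic value; when two components meet at a junction
# the one with the larger birth persists and the other dies at the
# junction's geodesic value; the last surviving component dies at 0.

# Build the vertex graph of one plant from its segment-table records.
# Vertices are polyline nodes; a lateral's entry point is aliased to its
# parent's insertion node, and all order-1 bases to a single collar vertex.
.plantGraph <- function(rec) {
  rootIds <- unique(rec$root)
  info <- unique(rec[, c("root", "order", "parent_root", "insertion_index")])
  orphan <- with(info, !is.na(parent_root) & !(parent_root %in% rootIds))
  if (any(orphan)) {
    stop(sprintf("disconnected plant '%s': orphan roots %s", rec$plant[1],
                 paste(info$root[orphan], collapse = ", ")), call. = FALSE)
  }

  g <- numeric(1); g[1] <- 0              # vertex 1 = collar
  vroot <- "";  vnode <- 0L               # tip identity per vertex
  edges <- list()
  vertexOf <- new.env(parent = emptyenv())  # "root#node" -> vertex id

  info <- info[order(info$order), , drop = FALSE]
  for (k in seq_len(nrow(info))) {
    rid <- info$root[k]
    rows <- rec[rec$root == rid, , drop = FALSE]
    rows <- rows[order(rows$node), , drop = FALSE]
    prev <- if (info$order[k] == 1L) 1L else {
      # entry vertex on the parent: the insertion node, or the nearest
      # recorded node at the same geodesic if that segment was dropped
      ii <- info$insertion_index[k]
      key <- paste0(info$parent_root[k], "#", ii)
      while (ii > 1L && is.null(vertexOf[[key]])) {
        ii <- ii - 1L
        key <- paste0(info$parent_root[k], "#", ii)
      }
      if (is.null(vertexOf[[key]])) 1L else vertexOf[[key]]
    }
    vertexOf[[paste0(rid, "#1")]] <- prev   # the root's entry vertex
    for (j in seq_len(nrow(rows))) {
      v <- length(g) + 1L
      g[v] <- rows$geodesic[j]
      vroot[v] <- rid
      vnode[v] <- rows$node[j]
      vertexOf[[paste0(rid, "#", rows$node[j])]] <- v
      edges[[length(edges) + 1L]] <- c(prev, v)
      prev <- v
    }
  }
  list(g = g, vroot = vroot, vnode = vnode,
       edges = do.call(rbind, edges))
}

.elderSweep <- function(graph) {
  g <- graph$g
  n <- length(g)
  adj <- vector("list", n)
  for (e in seq_len(nrow(graph$edges))) {
    a <- graph$edges[e, 1]; b <- graph$edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }

  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  birth <- g
  tipRoot <- graph$vroot
  tipNode <- graph$vnode

  ord <- order(-g, graph$vroot, graph$vnode)
  active <- logical(n)
  bars <- list()
  for (v in ord) {
    active[v] <- TRUE
    for (u in adj[[v]]) {
      if (!active[u]) next
      ru <- find(u); rv <- find(v)
      if (ru == rv) next
      # elder rule: larger birth survives; ties broken by smaller
      # (root id, node index) of the component's tip
      older <- if (birth[ru] > birth[rv]) ru
        else if (birth[rv] > birth[ru]) rv
        else if (paste(tipRoot[ru], sprintf("%09d", tipNode[ru])) <
                 paste(tipRoot[rv], sprintf("%09d", tipNode[rv]))) ru
        else rv
      younger <- if (older == ru) rv else ru
      if (birth[younger] > g[v]) {
        bars[[length(bars) + 1L]] <- c(birth[younger], g[v])
      }
      parent[younger] <- older
    }
  }
  root <- find(1L)
  bars[[length(bars) + 1L]] <- c(birth[root], 0)
  m <- do.call(rbind, bars)
  m <- m[order(-m[, 1], -m[, 2]), , drop = FALSE]
  m
}

#' Compute the H0 persistence barcode of a root system
#'
#' Sweeps the geodesic distance function of one plant from its maximum
#' down to 0 and records the birth (appearance at a root tip) and death
#' (merge into an older branch at a junction) of every connected
#' component, applying the elder rule: when two branches merge, the one
#' with the larger birth (the longer branch) persists and the shorter one
#' dies. The globally oldest component dies at 0, so every bar is finite
#' and the persistences sum exactly to the total root length.
#'
#' @param table a [SegmentTable-class] with the geodesic column populated.
#' @param plant plant id to extract; may be omitted when the table holds a
#'   single plant.
#' @return A [Barcode-class]; one bar per root tip (for generic tip
#'   distances), with columns dimension (always 0), birth and death.
#' @examples
#' r <- Root("axis", data.frame(x = c(0, 0), y = c(0, 5), diameter = 0.1))
#' st <- buildSegmentTable(rootSystemTree("p1", list(r)))
#' as.matrix(computeBarcode(st, "p1"))
#' @export
computeBarcode <- function(table, plant = NULL) {
  stopifnot(is(table, "SegmentTable"))
  rec <- table@records
  if (is.null(plant)) {
    plants <- unique(rec$plant)
    if (length(plants) != 1L) {
      stop("table holds several plants; name one", call. = FALSE)
    }
    plant <- plants
  }
  rec <- rec[rec$plant == plant, , drop = FALSE]
  if (!nrow(rec)) stop(sprintf("plant '%s' not in table", plant), call. = FALSE)
  bars <- .elderSweep(.plantGraph(rec))
  Barcode(cbind(dimension = 0, birth = bars[, 1], death = bars[, 2]),
          sourceId = plant)
}

#' Compute barcodes for every plant of a segment table
#'
#' @param table a [SegmentTable-class].
#' @return A named list of [Barcode-class], one per plant, in order of
#'   first appearance.
#' @export
computeBarcodes <- function(table) {
  stopifnot(is(table, "SegmentTable"))
  plants <- unique(table@records$plant)
  out <- lapply(plants, function(p) computeBarcode(table, p))
  names(out) <- plants
  out
}

#' Render a barcode as text
#'
#' Plain-text rendering for logs and tests: one line per bar, sorted by
#' birth descending, with an ASCII bar spanning death..birth on the
#' geodesic axis.
#'
#' @param barcode a [Barcode-class].
#' @param width character width of the geodesic axis.
#' @return Character vector, one element per bar.
#' @export
renderBarcode <- function(barcode, width = 60L) {
  stopifnot(is(barcode, "Barcode"))
  p <- barcode@pairs
  p <- p[order(-p[, "birth"], -p[, "death"]), , drop = FALSE]
  gmax <- max(p[, "birth"])
  vapply(seq_len(nrow(p)), function(i) {
    from <- 1L + floor((width - 1L) * p[i, "death"] / gmax)
    to <- 1L + round((width - 1L) * p[i, "birth"] / gmax)
    line <- rep(" ", width)
    line[from:to] <- "="
    sprintf("[%8.3f, %8.3f] %s", p[i, "death"], p[i, "birth"],
            paste(line, collapse = ""))
  }, character(1))
}

#' Plot a persistence barcode
#'
#' Horizontal bars from death to birth on the geodesic-distance axis,
#' sorted by birth descending (longest bar on top).
#'
#' @param x a [Barcode-class].
#' @param y ignored.
#' @param col bar colour.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
setMethod("plot", signature(x = "Barcode", y = "missing"),
  function(x, y, col = "forestgreen", ...) {
    p <- x@pairs
    p <- p[order(p[, "birth"]), , drop = FALSE]
    n <- nrow(p)
    graphics::plot(NA, xlim = c(0, max(p[, "birth"])), ylim = c(0, n + 1),
                   xlab = "Geodesic distance", ylab = "H0 bar",
                   main = x@sourceId, yaxt = "n", ...)
    graphics::segments(p[, "death"], seq_len(n), p[, "birth"], seq_len(n),
                       col = col, lwd = 2)
    invisible(x)
  })

#' Export a barcode as CSV
#'
#' Writes the 3-column bar matrix (dimension, birth, death) with a header.
#'
#' @param barcode a [Barcode-class].
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
writeBarcode <- function(barcode, path) {
  stopifnot(is(barcode, "Barcode"))
  utils::write.csv(as.data.frame(barcode@pairs), path, row.names = FALSE)
  invisible(path)
}
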