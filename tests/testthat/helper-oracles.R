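# Independent oracles. These recompute the quantities under test from
# first principles (explicit path enumeration, threshold sweeps with
# igraph connected components, exhaustive matching enumeration) and never
# share code with the implementation paths they check.

# Node graph of a tree: vertices with geodesic values computed by direct
# cumulative summation; edges between consecutive polyline nodes; lateral
# entry nodes aliased onto the parent, order-1 bases onto a collar.
oracleNodeGraph <- function(tree) {
  rootsL <- roots(tree)
  names(rootsL) <- vapply(rootsL, function(r) r@id, character(1))
  ord <- order(vapply(rootsL, function(r) r@order, integer(1)))
  vid <- 1L                      # vertex 1 = collar
  g <- 0
  label <- "collar#0"
  vertexOf <- list()             # per root: node index -> vertex id
  edges <- NULL
  geoOf <- list()
  for (r in rootsL[ord]) {
    nd <- r@nodes
    seglen <- sqrt(diff(nd$x)^2 + diff(nd$y)^2 + diff(nd$z)^2)
    g0 <- if (r@order == 1L) 0 else geoOf[[r@parentId]][r@insertionIndex]
    geo <- g0 + c(0, cumsum(seglen))
    geoOf[[r@id]] <- geo
    v <- integer(nrow(nd))
    v[1] <- if (r@order == 1L) 1L else vertexOf[[r@parentId]][r@insertionIndex]
    for (i in 2:nrow(nd)) {
      vid <- vid + 1L
      v[i] <- vid
      g[vid] <- geo[i]
      label[vid] <- paste0(r@id, "#", i)
      edges <- rbind(edges, c(v[i - 1], v[i]))
    }
    vertexOf[[r@id]] <- v
  }
  list(g = g, label = label, edges = edges)
}

# Elder-rule barcode by brute-force threshold sweep: at every junction /
# tip value (descending), take the superlevel subgraph and its igraph
# connected components; when previously distinct components fuse, the one
# with the larger birth (tie: lexicographically smallest tip label)
# survives and the others die at the current threshold.
oracleBarcode <- function(tree) {
  ng <- oracleNodeGraph(tree)
  n <- length(ng$g)
  gr <- igraph::graph_from_edgelist(ng$edges, directed = FALSE)
  thresholds <- sort(unique(ng$g), decreasing = TRUE)
  comp <- rep(NA_integer_, n)       # current component id per vertex
  birth <- numeric(0)
  tip <- character(0)
  bars <- NULL
  nextId <- 0L
  for (t in thresholds) {
    keep <- which(ng$g >= t)
    sub <- igraph::induced_subgraph(gr, keep)
    mem <- igraph::components(sub)$membership
    for (cid in unique(mem)) {
      verts <- keep[mem == cid]
      olds <- unique(stats::na.omit(comp[verts]))
      if (length(olds) == 0L) {            # newborn component
        nextId <- nextId + 1L
        birth[nextId] <- max(ng$g[verts])
        tip[nextId] <- min(ng$label[verts][ng$g[verts] == birth[nextId]])
        comp[verts] <- nextId
      } else if (length(olds) == 1L) {
        comp[verts] <- olds
      } else {                             # merge: elder rule
        ok <- order(-birth[olds], tip[olds])
        survivor <- olds[ok[1]]
        for (dead in olds[ok[-1]]) {
          if (birth[dead] > t) bars <- rbind(bars, c(birth[dead], t))
        }
        comp[verts] <- survivor
      }
    }
  }
  last <- unique(comp)
  stopifnot(length(last) == 1L)
  bars <- rbind(bars, c(birth[last], 0))
  bars[order(-bars[, 1], -bars[, 2]), , drop = FALSE]
}

# Fitter indices by explicit base-to-tip path enumeration on the node
# graph: the number of links on a path is 1 + the number of interior
# vertices of degree >= 3.
oracleFitter <- function(tree) {
  ng <- oracleNodeGraph(tree)
  gr <- igraph::graph_from_edgelist(ng$edges, directed = FALSE)
  deg <- igraph::degree(gr)
  tips <- setdiff(which(deg == 1L), 1L)
  nlinks <- vapply(tips, function(tp) {
    path <- igraph::shortest_paths(gr, from = 1, to = tp)$vpath[[1]]
    interior <- as.integer(path)[-c(1, length(path))]
    1L + sum(deg[interior] >= 3L)
  }, integer(1))
  c(magnitude = length(tips), altitude = max(nlinks), pe = sum(nlinks))
}

.allPerms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in .allPerms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Exact bottleneck distance by exhaustive enumeration: both diagrams are
# padded with diagonal slots and every perfect matching of the padded
# sets is scored by its maximum cost; diagrams of up to 4 points each.
oracleBottleneck <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  nA <- nrow(A); nB <- nrow(B); n <- nA + nB
  if (n == 0L) return(0)
  stopifnot(n <= 8L)
  cost <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      cost[i, j] <- if (i <= nA && j <= nB) {
        max(abs(A[i, 1] - B[j, 1]), abs(A[i, 2] - B[j, 2]))
      } else if (i <= nA) {
        (A[i, 1] - A[i, 2]) / 2          # A point onto the diagonal
      } else if (j <= nB) {
        (B[j, 1] - B[j, 2]) / 2          # diagonal slot takes a B point
      } else 0
    }
  }
  best <- Inf
  for (p in .allPerms(seq_len(n))) {
    best <- min(best, max(cost[cbind(seq_len(n), p)]))
  }
  best
}
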