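# Fixture builders used across the suite. All fixtures are built in code.

singleRootTree <- function(len = 5, diameter = 0.1) {
  rootSystemTree("p1", list(
    Root("axis", data.frame(x = c(0, 0, 0), y = c(0, len * 0.6, len),
                            diameter = diameter))
  ))
}

# First-order axis (0,0)->(0,2)->(0,5) with one unit-length lateral at the
# (0,2) node; lateral tip at geodesic 3.
yTree <- function() {
  axis <- Root("a", data.frame(x = c(0, 0, 0), y = c(0, 2, 5), diameter = 0.1))
  lat <- Root("l", data.frame(x = c(0, 1), y = c(2, 2), diameter = 0.05),
              order = 2, parentId = "a", insertionIndex = 2)
  rootSystemTree("p", list(axis, lat))
}

# Herringbone: one axis with mu - 1 laterals, one per interior node.
herringbone <- function(mu, axisStep = 2, latLen = 1) {
  stopifnot(mu >= 1)
  n <- mu + 1                                     # axis nodes
  axis <- Root("axis", data.frame(x = rep(0, n), y = axisStep * (0:(n - 1)),
                                  diameter = 0.1))
  roots <- list(axis)
  for (k in seq_len(mu - 1)) {
    roots[[k + 1]] <- Root(sprintf("lat%02d", k),
                           data.frame(x = c(0, latLen),
                                      y = axisStep * c(k, k),
                                      diameter = 0.05),
                           order = 2, parentId = "axis",
                           insertionIndex = k + 1)
  }
  rootSystemTree(sprintf("hb%d", mu), roots)
}

# Perfect dichotomous topology with 2^depth tips, built from nested
# two-node roots branching at their tip-1 node.
dichotomous <- function(depth = 2, len = 4) {
  roots <- list(Root("r", data.frame(x = c(0, 0), y = c(0, len),
                                     diameter = 0.1)))
  leaves <- list(list(id = "r", order = 1L, y = len, x = 0))
  for (d in seq_len(depth)) {
    newLeaves <- list()
    for (lf in leaves) {
      for (side in c(-1, 1)) {
        id <- sprintf("%s%s", lf$id, if (side < 0) "L" else "R")
        x2 <- lf$x + side * len / 2^d
        y2 <- lf$y + len / 2^d
        roots[[length(roots) + 1]] <- Root(
          id, data.frame(x = c(lf$x, x2), y = c(lf$y, y2), diameter = 0.05),
          order = lf$order + 1L, parentId = lf$id, insertionIndex = 2L)
        newLeaves[[length(newLeaves) + 1]] <- list(id = id,
                                                   order = lf$order + 1L,
                                                   y = y2, x = x2)
      }
    }
    leaves <- newLeaves
  }
  rootSystemTree(sprintf("di%d", depth), roots)
}

# Random valid tree for property tests: random 3D polylines, laterals
# attached at random *interior* parent nodes (never node 1 or the tip
# node, so branch points always have degree >= 3). Multifurcations are
# allowed. Deterministic given seed.
randomTree <- function(seed, nRootsMax = 12, nodesMax = 7) {
  set.seed(seed)
  mkNodes <- function(origin, n, order) {
    dx <- stats::rnorm(n - 1, 0, 0.6)
    dy <- stats::runif(n - 1, 0.3, 1.5)
    dz <- stats::rnorm(n - 1, 0, 0.6)
    data.frame(x = origin[1] + c(0, cumsum(dx)),
               y = origin[2] + c(0, cumsum(dy)),
               z = origin[3] + c(0, cumsum(dz)),
               diameter = 0.1 * 0.6^(order - 1))
  }
  n1 <- sample(4:nodesMax, 1)
  roots <- list(Root("r01", mkNodes(c(0, 0, 0), n1, 1)))
  meta <- list(r01 = list(order = 1L, n = n1))
  nRoots <- sample(seq_len(nRootsMax), 1)
  for (k in seq_len(nRoots - 1L)) {
    # candidate parents need an interior node
    cand <- names(meta)[vapply(meta, function(m) m$n >= 3L, logical(1))]
    if (!length(cand)) break
    pid <- cand[sample.int(length(cand), 1)]
    interior <- 2:(meta[[pid]]$n - 1L)
    ins <- interior[sample.int(length(interior), 1)]
    pr <- roots[[match(pid, vapply(roots, function(r) r@id, character(1)))]]
    origin <- unlist(pr@nodes[ins, c("x", "y", "z")])
    n <- sample(2:nodesMax, 1)
    id <- sprintf("r%02d", k + 1L)
    roots[[length(roots) + 1L]] <- Root(
      id, mkNodes(origin, n, pr@order + 1L), order = pr@order + 1L,
      parentId = pid, insertionIndex = ins)
    meta[[id]] <- list(order = pr@order + 1L, n = n)
  }
  rootSystemTree(sprintf("rand%d", seed), roots)
}

# Random persistence diagram as a (birth, death) matrix.
randomDiagram <- function(seed, nMax = 4, scale = 10) {
  set.seed(seed)
  n <- sample(0:nMax, 1)
  if (n == 0) return(matrix(numeric(0), 0, 2))
  birth <- stats::runif(n, 0.5, scale)
  death <- stats::runif(n, 0, 0.9) * birth
  cbind(birth, death)
}
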