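# Convex hull measures of a root system's node cloud.
#
# 2D data (all z = 0): hull area via grDevices::chull + the shoelace
# formula. 3D data: hull volume via an incremental convex hull (visible
# faces are removed and the horizon re-triangulated point by point).

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.hull2dArea <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3L) return(0)
  h <- grDevices::chull(xy)
  x <- xy[h, 1]; y <- xy[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

.hull3dVolume <- function(P, tol = 1e-9) {
  P <- unique(P)
  n <- nrow(P)
  if (n < 4L) return(0)
  span <- max(apply(P, 2, function(v) diff(range(v))))
  if (span == 0) return(0)
  eps <- tol * span

  # initial tetrahedron: extreme point, farthest point, farthest from the
  # line, farthest from the plane; degenerate clouds have zero volume
  i1 <- which.min(P[, 1])
  w <- sweep(P, 2, P[i1, ])
  i2 <- which.max(rowSums(w^2))
  v1 <- P[i2, ] - P[i1, ]
  crs <- cbind(w[, 2] * v1[3] - w[, 3] * v1[2],
               w[, 3] * v1[1] - w[, 1] * v1[3],
               w[, 1] * v1[2] - w[, 2] * v1[1])
  i3 <- which.max(rowSums(crs^2))
  nrm <- .cross3(v1, P[i3, ] - P[i1, ])
  nn <- sqrt(sum(nrm^2))
  if (nn < eps * span) return(0)               # collinear cloud
  h <- abs(w %*% (nrm / nn))
  i4 <- which.max(h)
  if (h[i4] < eps) return(0)                   # coplanar cloud
  C <- colMeans(P[c(i1, i2, i3, i4), ])        # strictly interior point

  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(f) {
    nv <- .cross3(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
    if (sum(nv * (C - P[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient))

  faceNormal <- function(f) {
    nv <- .cross3(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
    c(nv, sum(nv * P[f[1], ]))                 # (normal, offset)
  }
  geom <- t(apply(faces, 1, faceNormal))

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    d <- geom[, 1:3, drop = FALSE] %*% P[p, ] - geom[, 4]
    vis <- d > eps * pmax(1, sqrt(rowSums(geom[, 1:3, drop = FALSE]^2)))
    if (!any(vis)) next
    visFaces <- faces[vis, , drop = FALSE]
    edges <- rbind(visFaces[, c(1, 2)], visFaces[, c(2, 3)], visFaces[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    newFaces <- t(apply(horizon, 1, function(e) orient(c(e[1], e[2], p))))
    faces <- rbind(faces[!vis, , drop = FALSE], newFaces)
    geom <- rbind(geom[!vis, , drop = FALSE], t(apply(newFaces, 1, faceNormal)))
  }

  vol <- 0
  for (k in seq_len(nrow(faces))) {
    f <- faces[k, ]
    vol <- vol + abs(sum(.cross3(P[f[2], ] - C, P[f[3], ] - C) * (P[f[1], ] - C))) / 6
  }
  vol
}

# Hull area (2D cloud) or volume (any z != 0) of an n x 3 coordinate matrix.
.convexHullMeasure <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (all(abs(xyz[, 3]) < 1e-12)) {
    .hull2dArea(xyz[, 1:2, drop = FALSE])
  } else {
    .hull3dVolume(xyz)
  }
}

# Maximum horizontal extent: diameter of the node cloud projected on the
# horizontal plane (x, z); hull vertices only, so the pairwise search is
# cheap.
.horizontalWidth <- function(xyz) {
  xz <- unique(as.matrix(xyz)[, c(1, 3), drop = FALSE])
  if (nrow(xz) < 2L) return(0)
  if (nrow(xz) > 3L) {
    h <- grDevices::chull(xz)
    xz <- xz[h, , drop = FALSE]
  }
  max(stats::dist(xz))
}
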