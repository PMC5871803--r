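# Ordination of root systems: NMDS on a bottleneck distance matrix and
# correlation-matrix PCA on the trait panel.

# Canonical orientation: principal-component rotation is done by monoMDS
# (pc = TRUE); on top of that, flip each axis so the coordinate of largest
# magnitude is positive. Keeps the embedding stable under permutation of
# the input ids (up to numerical noise).
.canonicalSigns <- function(m) {
  for (k in seq_len(ncol(m))) {
    i <- which.max(abs(m[, k]))
    if (m[i, k] < 0) m[, k] <- -m[, k]
  }
  m
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Embeds a pairwise (bottleneck) distance matrix in `k` dimensions by
#' Kruskal's non-metric MDS (stress-1), using `vegan::monoMDS` with one
#' metric-scaling start plus `restarts` seeded random starts; the
#' lowest-stress solution is kept. Deterministic given `seed`.
#'
#' @param matrix a [BottleneckMatrix-class] or symmetric numeric matrix.
#' @param k embedding dimension.
#' @param seed integer seed for the random restarts.
#' @param restarts number of random starts besides the metric start.
#' @return An [OrdinationResult-class] with Kruskal stress-1.
#' @export
ordinateNMDS <- function(matrix, k = 2, seed = 1, restarts = 20L) {
  if (is(matrix, "BottleneckMatrix")) matrix <- matrix@values
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix) || max(abs(matrix - t(matrix))) > 1e-8) {
    stop("input must be a symmetric distance matrix", call. = FALSE)
  }
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- sprintf("item_%d", seq_len(nrow(matrix)))
  n <- nrow(matrix)
  if (all(matrix == 0)) {
    coords <- base::matrix(0, n, k, dimnames = list(ids, paste0("NMDS", seq_len(k))))
    return(new("OrdinationResult", ids = ids, coordinates = coords,
               stress = 0, varianceExplained = numeric(0),
               loadings = base::matrix(numeric(0), 0, 0),
               method = "NMDS", seed = as.integer(seed)))
  }
  d <- stats::as.dist(matrix)
  if (n <= k + 1L) {
    # n points with a valid metric always embed exactly in n-1 dimensions
    y <- stats::cmdscale(d, k = min(k, n - 1L))
    if (ncol(y) < k) y <- cbind(y, base::matrix(0, n, k - ncol(y)))
    coords <- .canonicalSigns(y)
    dimnames(coords) <- list(ids, paste0("NMDS", seq_len(k)))
    resid <- sqrt(sum((stats::dist(coords) - d)^2) / sum(d^2))
    return(new("OrdinationResult", ids = ids, coordinates = coords,
               stress = resid, varianceExplained = numeric(0),
               loadings = base::matrix(numeric(0), 0, 0),
               method = "NMDS", seed = as.integer(seed)))
  }
  fits <- vector("list", restarts + 1L)
  set.seed(as.integer(seed))
  fits[[1]] <- vegan::monoMDS(d, k = k, model = "global",
                              smin = 1e-9, sfgrmin = 1e-10)
  for (r in seq_len(restarts)) {
    y0 <- base::matrix(stats::rnorm(n * k), n, k)
    fits[[r + 1L]] <- vegan::monoMDS(d, y = y0, k = k, model = "global",
                                     smin = 1e-9, sfgrmin = 1e-10)
  }
  best <- fits[[which.min(vapply(fits, function(f) f$stress, numeric(1)))]]
  coords <- .canonicalSigns(best$points)
  dimnames(coords) <- list(ids, paste0("NMDS", seq_len(k)))
  new("OrdinationResult", ids = ids, coordinates = coords,
      stress = best$stress, varianceExplained = numeric(0),
      loadings = base::matrix(numeric(0), 0, 0),
      method = "NMDS", seed = as.integer(seed))
}

#' Correlation-matrix PCA of a trait matrix
#'
#' Principal component analysis on standardized variables (the
#' correlation matrix). Constant columns are dropped with a warning;
#' an all-constant matrix is an error.
#'
#' @param traits data.frame or matrix, plants in rows, traits in columns.
#' @return An [OrdinationResult-class] with scores, orthonormal loadings
#'   and per-axis explained-variance fractions.
#' @export
ordinatePCA <- function(traits) {
  m <- as.matrix(traits)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 plants and 2 traits", call. = FALSE)
  }
  constant <- apply(m, 2, function(v) stats::sd(v) == 0 || all(is.na(v)))
  if (all(constant)) stop("all trait columns are constant", call. = FALSE)
  if (any(constant)) {
    warning(sprintf("dropping constant trait column%s: %s",
                    if (sum(constant) > 1) "s" else "",
                    paste(colnames(m)[constant], collapse = ", ")),
            call. = FALSE)
    m <- m[, !constant, drop = FALSE]
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  varFrac <- fit$sdev^2 / sum(fit$sdev^2)
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("plant_%d", seq_len(nrow(m)))
  coords <- fit$x
  rownames(coords) <- ids
  new("OrdinationResult", ids = ids, coordinates = coords,
      stress = NA_real_, varianceExplained = varFrac,
      loadings = fit$rotation, method = "PCA", seed = NA_integer_)
}

#' Class-recovery rate of a 2-group ordination
#'
#' Partitions the ordination scores with k-medoids (`cluster::pam`,
#' k = number of distinct labels) and returns the fraction of points whose
#' cluster matches their generating label, maximised over the label-to-
#' cluster assignment.
#'
#' @param ordination an [OrdinationResult-class] (or a score matrix).
#' @param labels generating category per point.
#' @return Fraction in [0, 1].
#' @export
recoveryRate <- function(ordination, labels) {
  coords <- if (is(ordination, "OrdinationResult")) {
    ordination@coordinates
  } else {
    as.matrix(ordination)
  }
  labels <- as.factor(labels)
  k <- nlevels(labels)
  stopifnot(nrow(coords) == length(labels), k >= 2L)
  cl <- cluster::pam(coords, k = k, cluster.only = TRUE)
  tab <- table(cl, labels)
  # best one-to-one assignment of clusters to labels (k is small)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(k))) {
    hit <- sum(vapply(seq_len(k), function(i) tab[i, p[i]], numeric(1)))
    best <- max(best, hit)
  }
  best / length(labels)
}
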