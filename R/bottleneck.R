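# Bottleneck distance between persistence barcodes (exact, via binary
# search over candidate costs with bipartite feasibility matching in C++).

.diagramPoints <- function(x) {
  if (is(x, "Barcode")) x <- x@pairs
  x <- as.matrix(x)
  if (!nrow(x)) return(matrix(numeric(0), 0, 2))
  if (ncol(x) == 3L) x <- x[, c("birth", "death"), drop = FALSE]
  storage.mode(x) <- "double"
  unname(x)
}

#' Bottleneck distance between two barcodes
#'
#' The standard bottleneck distance between two persistence diagrams:
#' the minimum over perfect matchings (unmatched points may be matched to
#' the diagonal at cost persistence/2) of the maximum L-infinity
#' displacement. Computed exactly by binary search over the finite set of
#' candidate costs with a Hopcroft-Karp feasibility matching; no
#' approximation parameter. An empty barcode is the empty diagram (every
#' point of the other diagram is matched to the diagonal).
#'
#' @param a,b [Barcode-class] objects (or plain matrices with birth and
#'   death columns).
#' @return Non-negative distance; symmetric in its arguments.
#' @examples
#' A <- Barcode(cbind(0, c(5, 3), c(0, 2)))
#' B <- Barcode(cbind(0, c(5, 3.4), c(0, 2)))
#' bottleneckDistance(A, B)  # 0.4
#' @export
bottleneckDistance <- function(a, b) {
  .bottleneckCpp(.diagramPoints(a), .diagramPoints(b))
}

#' Pairwise bottleneck distance matrix
#'
#' Computes the symmetric matrix of bottleneck distances over a set of
#' barcodes. Computation time grows with the number and complexity of the
#' root systems compared; set `verbose = TRUE` for progress messages.
#'
#' @param barcodes list of [Barcode-class] (>= 2); names (or source ids)
#'   label the matrix.
#' @param verbose emit a progress message every `every` rows.
#' @param every row interval between progress messages.
#' @return A [BottleneckMatrix-class].
#' @export
pairwiseBottleneck <- function(barcodes, verbose = FALSE, every = 10L) {
  stopifnot(is.list(barcodes), length(barcodes) >= 2L)
  n <- length(barcodes)
  ids <- names(barcodes)
  if (is.null(ids)) ids <- vapply(barcodes, sourceId, character(1))
  ids[!nzchar(ids)] <- sprintf("barcode_%d", which(!nzchar(ids)))
  ids <- make.unique(ids)
  pts <- lapply(barcodes, .diagramPoints)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      m[i, j] <- m[j, i] <- .bottleneckCpp(pts[[i]], pts[[j]])
    }
    if (verbose && (i %% every == 0L)) {
      message(sprintf("pairwiseBottleneck: %d / %d rows done", i, n))
    }
  }
  new("BottleneckMatrix", values = m)
}

#' Export a bottleneck distance matrix as CSV
#'
#' Square CSV with the source ids as header row and first column, the
#' format consumed by downstream ordination.
#'
#' @param matrix a [BottleneckMatrix-class].
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
writeBottleneckMatrix <- function(matrix, path) {
  stopifnot(is(matrix, "BottleneckMatrix"))
  utils::write.csv(matrix@values, path, row.names = TRUE)
  invisible(path)
}
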