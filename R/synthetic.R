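# Seeded generator of ArchiSimple-style synthetic root systems.
#
# A minimal discrete-time growth model (not a reimplementation of
# ArchiSimple: no soil interaction, no diameter-driven elongation, no root
# death): each axis elongates along its heading, headings relax toward the
# gravity vector and receive Gaussian jitter, laterals initiate every
# interLateralDistance of parent growth with a normally distributed
# insertion angle, and diameters taper by diameterRatioLateral per order.
# Lengths are in cm, time in days, the y axis points down (depth).
#
# Internal rules held fixed across presets (see the methods vignette):
# roots of order k elongate at elongationRate * ratio^(k-1); laterals
# (order >= 2) elongate for at most 3 days; the inter-lateral distance of
# an order-k parent is interLateralDistance / ratio^(2*(k-1)), so thinner
# roots branch proportionally sparser.

.LATERAL_GROWTH_DAYS <- 3

#' Construct generator parameters
#'
#' See [GenotypeParams-class] for the meaning of each parameter; defaults
#' are the `mock` baseline genotype.
#'
#' @param name preset label.
#' @param nFirstOrder number of first-order axes.
#' @param elongationRate cm/day elongation of first-order axes.
#' @param interLateralDistance cm of parent growth between laterals.
#' @param insertionAngleMean,insertionAngleSd degrees, normal law of the
#'   lateral insertion angle.
#' @param gravitropism per-step heading relaxation toward vertical, [0, 1].
#' @param headingNoiseSd per-step Gaussian heading jitter (radians).
#' @param maxOrder deepest branching order.
#' @param diameterBase cm, first-order diameter.
#' @param diameterRatioLateral diameter taper per order, (0, 1].
#' @param duration days simulated.
#' @param step days per growth step.
#' @return A validated [GenotypeParams-class].
#' @export
genotypeParams <- function(name = "mock", nFirstOrder = 3,
                           elongationRate = 1.5, interLateralDistance = 0.8,
                           insertionAngleMean = 60, insertionAngleSd = 8,
                           gravitropism = 0.10, headingNoiseSd = 0.12,
                           maxOrder = 3, diameterBase = 0.10,
                           diameterRatioLateral = 0.5, duration = 10,
                           step = 0.5) {
  obj <- new("GenotypeParams", name = as.character(name),
             nFirstOrder = as.integer(nFirstOrder),
             elongationRate = as.numeric(elongationRate),
             interLateralDistance = as.numeric(interLateralDistance),
             insertionAngleMean = as.numeric(insertionAngleMean),
             insertionAngleSd = as.numeric(insertionAngleSd),
             gravitropism = as.numeric(gravitropism),
             headingNoiseSd = as.numeric(headingNoiseSd),
             maxOrder = as.integer(maxOrder),
             diameterBase = as.numeric(diameterBase),
             diameterRatioLateral = as.numeric(diameterRatioLateral),
             duration = as.numeric(duration), step = as.numeric(step))
  validObject(obj)
  obj
}

#' Named genotype presets
#'
#' Returns the parameter set of one of the built-in genotypes. The seven
#' single-parameter genotypes (`mock`, `dense`, `sparse`, `steep`,
#' `shallow`, `slow`, `fast`) are the `mock` baseline with exactly one
#' parameter changed (inter-lateral distance, gravitropism or elongation
#' rate); `fibrous` (many thin first-order axes) and `taproot` (one
#' dominant axis) are the two root-system categories. Preset values are
#' shipped as a plain-text table in
#' `system.file("extdata", "genotype_presets.tsv", package = "rootTDA")`.
#'
#' @param name one of `mock`, `dense`, `sparse`, `steep`, `shallow`,
#'   `slow`, `fast`, `fibrous`, `taproot`.
#' @return A [GenotypeParams-class].
#' @examples
#' genotypePreset("taproot")
#' @export
genotypePreset <- function(name) {
  tab <- utils::read.delim(system.file("extdata", "genotype_presets.tsv",
                                       package = "rootTDA"),
                           stringsAsFactors = FALSE)
  row <- tab[tab$name == name, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(tab$name, collapse = ", ")), call. = FALSE)
  }
  do.call(genotypeParams, as.list(row))
}

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) c(0, 1, 0) else v / n
}

# Unit vector at `angleDeg` degrees from `h`, with random azimuth.
.rotateAway <- function(h, angleDeg) {
  ref <- if (abs(h[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
  u1 <- .normalize(.cross3(h, ref))
  u2 <- .cross3(h, u1)
  phi <- stats::runif(1, 0, 2 * pi)
  u <- cos(phi) * u1 + sin(phi) * u2
  th <- angleDeg * pi / 180
  .normalize(cos(th) * h + sin(th) * u)
}

#' Generate one synthetic root system
#'
#' Runs the growth model for `duration` days and returns the resulting
#' [RootSystemTree-class]. Deterministic given `(params, seed)`; with the
#' same seed, a longer duration extends the same simulation (growth is
#' prefix-stable), which makes [calibrateLength()] monotone.
#'
#' @param params a [GenotypeParams-class] (see [genotypePreset()]).
#' @param seed integer seed.
#' @return A [RootSystemTree-class] (unit cm, ages in days).
#' @examples
#' tree <- generateRootSystem(genotypePreset("mock"), seed = 1)
#' tree
#' @export
generateRootSystem <- function(params, seed) {
  stopifnot(is(params, "GenotypeParams"))
  validObject(params)
  if (params@step <= 0 || params@duration <= 0) {
    stop("step and duration must be > 0", call. = FALSE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)

  ratio <- params@diameterRatioLateral
  rateOf <- function(order) params@elongationRate * ratio^(order - 1)
  ildOf <- function(order) params@interLateralDistance / ratio^(2 * (order - 1))
  diamOf <- function(order) params@diameterBase * ratio^(order - 1)

  roots <- list()
  newRoot <- function(order, parentId, insertionIndex, pos, heading, t) {
    id <- sprintf("r%04d", length(roots) + 1L)
    roots[[id]] <<- list(
      id = id, order = order, parentId = parentId,
      insertionIndex = insertionIndex, heading = heading,
      # inter-individual growth variability: each root keeps a private
      # elongation multiplier for its whole life
      rateMult = stats::runif(1, 0.8, 1.2),
      birth = t, sinceLateral = 0,
      x = pos[1], y = pos[2], z = pos[3],
      diameter = diamOf(order), age = t
    )
    id
  }

  for (i in seq_len(params@nFirstOrder)) {
    if (params@nFirstOrder == 1L) {
      h <- c(0, 1, 0)
    } else {
      a <- stats::rnorm(1, params@insertionAngleMean, params@insertionAngleSd)
      a <- min(max(a, 0), 90) * pi / 180
      phi <- 2 * pi * (i - 1) / params@nFirstOrder + stats::runif(1, 0, 0.3)
      h <- .normalize(c(sin(a) * cos(phi), cos(a), sin(a) * sin(phi)))
    }
    newRoot(1L, NA_character_, NA_integer_, c(0, 0, 0), h, 0)
  }

  t <- 0
  gvec <- c(0, 1, 0)
  while (t < params@duration - 1e-12) {
    dt <- min(params@step, params@duration - t)
    t <- t + dt
    snapshot <- names(roots)   # laterals born this step start next step
    for (id in snapshot) {
      r <- roots[[id]]
      if (r$order > 1L && (t - dt) - r$birth >= .LATERAL_GROWTH_DAYS) next
      h <- .normalize((1 - params@gravitropism) * r$heading +
                        params@gravitropism * gvec)
      h <- .normalize(h + stats::rnorm(3, 0, params@headingNoiseSd))
      grown <- rateOf(r$order) * r$rateMult * dt
      n <- length(r$x)
      pos <- c(r$x[n], r$y[n], r$z[n]) + h * grown
      r$heading <- h
      r$x <- c(r$x, pos[1]); r$y <- c(r$y, pos[2]); r$z <- c(r$z, pos[3])
      r$diameter <- c(r$diameter, diamOf(r$order))
      r$age <- c(r$age, t)
      r$sinceLateral <- r$sinceLateral + grown
      if (r$order < params@maxOrder) {
        while (r$sinceLateral >= ildOf(r$order)) {
          r$sinceLateral <- r$sinceLateral - ildOf(r$order)
          theta <- abs(stats::rnorm(1, params@insertionAngleMean,
                                    params@insertionAngleSd))
          theta <- min(theta, 120)
          newRoot(r$order + 1L, r$id, length(r$x), pos,
                  .rotateAway(h, theta), t)
        }
      }
      roots[[id]] <- r
    }
  }

  # laterals born on the very last step have a single node; drop them
  keep <- vapply(roots, function(r) length(r$x) >= 2L, logical(1))
  roots <- roots[keep]
  objs <- lapply(roots, function(r) {
    Root(r$id, data.frame(x = r$x, y = r$y, z = r$z,
                          diameter = r$diameter, age = r$age),
         order = r$order, parentId = r$parentId,
         insertionIndex = r$insertionIndex)
  })
  tree <- rootSystemTree(sprintf("%s_s%d", params@name, as.integer(seed)),
                         unname(objs), unit = "cm")
  attr(tree, "params") <- params
  tree
}

# Per-file seed derivation: documented splitting rule so libraries are
# reproducible file by file.
.deriveSeed <- function(master, index) {
  (as.numeric(master) + 7919 * index) %% 2147483647
}

#' Generate a library of RSML files
#'
#' Writes one RSML file per (preset, replicate) with per-replicate seeds
#' derived from the master seed as `(seed + 7919 * fileIndex) mod 2^31-1`,
#' and returns (and writes, as `manifest.csv`) a manifest.
#'
#' @param presets list of [GenotypeParams-class], or character vector of
#'   preset names resolved with [genotypePreset()].
#' @param replicates simulations per preset.
#' @param seed master seed.
#' @param outDir destination directory (created if needed).
#' @return data.frame manifest: file, genotype, seed, total root length.
#' @examples
#' \dontrun{
#' man <- generateLibrary(c("mock", "taproot"), replicates = 2, seed = 1,
#'                        outDir = tempfile())
#' }
#' @export
generateLibrary <- function(presets, replicates, seed, outDir) {
  if (is.character(presets)) presets <- lapply(presets, genotypePreset)
  stopifnot(length(presets) >= 1L, replicates >= 1L)
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE)) {
    stop(sprintf("cannot create output directory '%s'", outDir), call. = FALSE)
  }
  rows <- list()
  idx <- 0L
  for (p in presets) {
    for (rep in seq_len(replicates)) {
      idx <- idx + 1L
      s <- .deriveSeed(seed, idx)
      tree <- generateRootSystem(p, s)
      file <- sprintf("%s_%02d.rsml", p@name, rep)
      writeRSML(tree, file.path(outDir, file))
      rows[[idx]] <- data.frame(file = file, genotype = p@name, seed = s,
                                TRL = totalRootLength(tree),
                                stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Calibrate simulation duration to a target total root length
#'
#' Bisects the simulated duration (with a fixed seed, so growth is
#' prefix-stable and total root length is monotone in duration) until the
#' generated system's total root length is within `tolerance * target` of
#' `target`. The paper-scale selection window of 20 m +/- 15% corresponds
#' to `target = 2000` cm, `tolerance = 0.15`.
#'
#' @param params a [GenotypeParams-class]; its `duration` seeds the search.
#' @param targetTRL target total root length (same unit as the generator, cm).
#' @param tolerance relative tolerance in (0, 1).
#' @param seed integer seed.
#' @param maxIter bisection iterations before giving up.
#' @return The calibrated [RootSystemTree-class]; the duration used is in
#'   `attr(tree, "duration")`.
#' @export
calibrateLength <- function(params, targetTRL, tolerance = 0.15, seed = 1,
                            maxIter = 60L) {
  stopifnot(is(params, "GenotypeParams"), targetTRL > 0,
            tolerance > 0, tolerance < 1)
  evalAt <- function(d) {
    p <- params; p@duration <- d
    tree <- generateRootSystem(p, seed)
    attr(tree, "duration") <- d
    list(d = d, tree = tree, trl = totalRootLength(tree))
  }
  lo <- params@step
  cur <- evalAt(params@duration)
  grow <- 0L
  while (cur$trl < targetTRL && grow < 20L) {
    lo <- cur$d
    cur <- evalAt(cur$d * 2)
    grow <- grow + 1L
  }
  hi <- cur$d
  best <- cur
  for (it in seq_len(maxIter)) {
    if (abs(best$trl - targetTRL) <= tolerance * targetTRL) return(best$tree)
    mid <- (lo + hi) / 2
    cur <- evalAt(mid)
    if (abs(cur$trl - targetTRL) < abs(best$trl - targetTRL)) best <- cur
    if (cur$trl < targetTRL) lo <- mid else hi <- mid
  }
  if (abs(best$trl - targetTRL) <= tolerance * targetTRL) return(best$tree)
  stop(sprintf("calibration did not reach %.1f +/- %.0f%% (closest TRL %.1f)",
               targetTRL, 100 * tolerance, best$trl), call. = FALSE)
}
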