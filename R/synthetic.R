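#' @include AllClasses.R
NULL

# run expr under an explicit seed without touching the caller's RNG stream
.withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# triangular/square lattice sites on an extended grid, cropped to the
# window; row parity anchored at the window centre so the pattern is
# translation-stable under window resize
.croppedLattice <- function(spacing, window, hexagonal) {
  cx <- (window@xmin + window@xmax) / 2
  cy <- (window@ymin + window@ymax) / 2
  dy <- if (hexagonal) spacing * sqrt(3) / 2 else spacing
  ny <- ceiling((window@ymax - window@ymin) / (2 * dy)) + 1L
  nx <- ceiling((window@xmax - window@xmin) / (2 * spacing)) + 1L
  rows <- seq(-ny, ny)
  pts <- lapply(rows, function(j) {
    off <- if (hexagonal && j %% 2L != 0L) spacing / 2 else 0
    xs <- cx + off + seq(-nx - 1L, nx + 1L) * spacing
    cbind(xs, cy + j * dy)
  })
  xy <- do.call(rbind, pts)
  xy <- xy[.inWindow(xy, window), , drop = FALSE]
  if (nrow(xy) < 1L)
    stop("window too small to hold a single lattice site at this intensity")
  xy
}

#' Hexagonal (triangular) reference lattice
#'
#' Generates a triangular lattice matched to a target intensity
#' \eqn{\lambda}: the nearest-neighbour spacing is
#' \eqn{2 r_{hex} = (2 / (\lambda \sqrt{3}))^{1/2}}, the spacing of the
#' hexagonal lattice whose Voronoi cell area equals \eqn{1/\lambda}. Sites
#' are generated on an extended grid anchored at the window centre, then
#' cropped to the window, so the realized count is within one row/column
#' of \eqn{\lambda A_{box}}.
#'
#' @param intensity target points per unit area (> 0).
#' @param window an [ObsWindow-class].
#' @return A [PointPattern-class].
#' @examples
#' w <- obsWindow(0, 10, 0, 10)
#' p <- hexagonalLattice(2 / sqrt(3), w)  # spacing exactly 1
#' @export
hexagonalLattice <- function(intensity, window) {
  stopifnot(intensity > 0)
  if (intensity * windowArea(window) < 1)
    stop("window too small to hold a lattice site at this intensity")
  spacing <- hexagonalSpacing(intensity)
  xy <- .croppedLattice(spacing, window, hexagonal = TRUE)
  pointPattern(xy, window = window, label = "hexagonal")
}

#' Hexagonal lattice spacing for a given intensity
#'
#' The spacing \eqn{2 r_{hex} = (2/(\lambda \sqrt 3))^{1/2}} of the
#' hexagonal lattice with intensity \eqn{\lambda}: obtained by solving for
#' the apothem of a hexagon whose area equals the per-particle area
#' \eqn{1/\lambda}.
#'
#' @param intensity points per unit area.
#' @return The nearest-neighbour spacing, same length unit.
#' @export
hexagonalSpacing <- function(intensity) sqrt(2 / (intensity * sqrt(3)))

#' Square reference lattice
#'
#' Square lattice at a target intensity; spacing \eqn{\lambda^{-1/2}}.
#' The exact square grid has four-fold Voronoi coordination once
#' degenerate zero-length facets are filtered (see [tessellate()]).
#'
#' @inheritParams hexagonalLattice
#' @return A [PointPattern-class].
#' @export
squareLattice <- function(intensity, window) {
  stopifnot(intensity > 0)
  if (intensity * windowArea(window) < 1)
    stop("window too small to hold a lattice site at this intensity")
  spacing <- 1 / sqrt(intensity)
  xy <- .croppedLattice(spacing, window, hexagonal = FALSE)
  pointPattern(xy, window = window, label = "square")
}

#' Hexatic ensemble: Gaussian-jittered lattice realizations
#'
#' Generates `nRealizations` independent copies of a base pattern with
#' every point displaced by an isotropic 2D Gaussian of per-axis standard
#' deviation `deltaR` (displacements are always drawn about the base
#' positions, never chained). Displaced points are clamped to the
#' observation window so each realization keeps the base pattern's N and
#' window. This is the tunable reference between crystal and liquid used
#' both as a comparison lattice and for bootstrap smoothing of \eqn{g(r)}.
#'
#' @param base a [PointPattern-class] (typically [hexagonalLattice()]).
#' @param deltaR per-axis Gaussian displacement scale (>= 0), in the
#'   pattern's length unit.
#' @param nRealizations number of independent realizations (>= 1).
#' @param seed integer seed; results are reproducible.
#' @return A list of [PointPattern-class] objects.
#' @examples
#' w <- obsWindow(0, 10, 0, 10)
#' ens <- hexaticEnsemble(hexagonalLattice(1, w), deltaR = 0.05,
#'                        nRealizations = 3, seed = 1)
#' @export
hexaticEnsemble <- function(base, deltaR, nRealizations = 1000L, seed = 1L) {
  stopifnot(is(base, "PointPattern"), deltaR >= 0, nRealizations >= 1)
  xy <- coordinates(base)
  w <- patternWindow(base)
  n <- nrow(xy)
  .withSeed(seed, {
    lapply(seq_len(nRealizations), function(k) {
      d <- matrix(stats::rnorm(2L * n, sd = deltaR), ncol = 2L)
      shaken <- xy + d
      shaken[, 1] <- pmin(pmax(shaken[, 1], w@xmin), w@xmax)
      shaken[, 2] <- pmin(pmax(shaken[, 2], w@ymin), w@ymax)
      pointPattern(shaken, window = w,
                   label = sprintf("%s hexatic %d", patternLabel(base), k))
    })
  })
}

#' Complete spatial randomness
#'
#' A homogeneous Poisson process: N is drawn Poisson(\eqn{\lambda A_{box}})
#' and points are placed uniformly in the window.
#'
#' @inheritParams hexagonalLattice
#' @param seed integer seed.
#' @return A [PointPattern-class].
#' @export
csrPattern <- function(intensity, window, seed = 1L) {
  stopifnot(intensity > 0)
  .withSeed(seed, {
    n <- stats::rpois(1L, intensity * windowArea(window))
    if (n < 1L)
      stop("Poisson draw produced zero points; increase intensity or window")
    x <- stats::runif(n, window@xmin, window@xmax)
    y <- stats::runif(n, window@ymin, window@ymax)
    pointPattern(x, y, window = window, label = "csr")
  })
}

#' Confined-packing fixture
#'
#' A deterministic fixture emulating short-range-repulsive particles
#' relaxed inside hard walls: points start uniformly at random, then repeat
#' steps of pairwise soft repulsion (within a cutoff of 1.8 mean spacings)
#' and clamping to the walls. Ordered wall-aligned rows form at the
#' boundary around a frustrated, less-ordered interior. The fixture is
#' qualitative: it reproduces the morphology class, not any quantitative
#' packing claim.
#'
#' @param n number of particles (>= 4).
#' @param window an [ObsWindow-class] (square recommended).
#' @param seed integer seed.
#' @param maxIter iteration cap; non-convergence returns the current state
#'   with a warning.
#' @return A [PointPattern-class].
#' @export
confinedPacking <- function(n, window, seed = 1L, maxIter = 1000L) {
  stopifnot(n >= 4)
  a <- sqrt(windowArea(window) / n)      # mean spacing
  cutoff <- 1.8 * a
  .withSeed(seed, {
    xy <- cbind(stats::runif(n, window@xmin, window@xmax),
                stats::runif(n, window@ymin, window@ymax))
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      dx <- outer(xy[, 1], xy[, 1], "-")
      dy <- outer(xy[, 2], xy[, 2], "-")
      d <- sqrt(dx^2 + dy^2)
      diag(d) <- Inf
      # linear soft repulsion within the cutoff
      f <- pmax(cutoff - d, 0) / pmax(d, 1e-12)
      fx <- rowSums(f * dx)
      fy <- rowSums(f * dy)
      step <- 0.05
      xy[, 1] <- pmin(pmax(xy[, 1] + step * fx, window@xmin), window@xmax)
      xy[, 2] <- pmin(pmax(xy[, 2] + step * fy, window@ymin), window@ymax)
      # dilute arrangements relax to rest; jammed ones keep oscillating
      # at a few percent of the spacing and hit the iteration cap instead
      if (max(abs(c(step * fx, step * fy))) < 1e-3 * a) {
        converged <- TRUE
        break
      }
    }
    if (!converged)
      warning("confinedPacking: relaxation not fully converged after ",
              maxIter, " iterations; returning current state")
    pointPattern(xy, window = window, label = "confined")
  })
}
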