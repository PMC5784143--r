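#' @include AllClasses.R
NULL

# cache for the m-sum coefficients and q_l^sym values
.qCache <- new.env(parent = emptyenv())

# Coefficients c_m, m = 0..l, of the planar reduction of the bond order
# parameter. Bonds lie in the equatorial plane of the spherical-harmonic
# frame (polar angle pi/2, azimuth = bond angle), so
#   q_l^2 = (4 pi / (2l+1)) sum_m |sum_b w_b Y_lm(pi/2, phi_b)|^2
#         = sum_{m=0..l} (2 - [m==0]) c_m |S_m|^2,  S_m = sum_b w_b e^{i m phi_b}
# with c_m = [(l-m)!/(l+m)!] P_lm(0)^2 (orthonormalized harmonics; the
# Condon-Shortley phase squares away). P_lm(0) comes from pracma.
.planarCoefs <- function(ell) {
  key <- sprintf("c%d", ell)
  if (!is.null(.qCache[[key]])) return(.qCache[[key]])
  m <- 0:ell
  P0 <- as.vector(pracma::legendre(ell, 0))   # P_l^m(0), m = 0..l
  cm <- exp(lgamma(ell - m + 1) - lgamma(ell + m + 1)) * P0^2
  .qCache[[key]] <- cm
  cm
}

# q_l from bond azimuths and weights (weights must sum to 1)
.qFromAzimuths <- function(phi, wts, ell) {
  cm <- .planarCoefs(ell)
  m <- 0:ell
  S2 <- vapply(m, function(mm) {
    sum(wts * cos(mm * phi))^2 + sum(wts * sin(mm * phi))^2
  }, numeric(1))
  mult <- ifelse(m == 0L, 1, 2)
  val <- sum(mult * cm * S2)
  sqrt(max(val, 0))
}

#' Perfect-symmetry bond order reference
#'
#' \eqn{q_\ell^{sym}}: the bond order parameter of a single particle with
#' \eqn{\ell} equally weighted neighbours at equal arc spacing
#' \eqn{2\pi/\ell} - the highest-symmetry neighbour configuration in that
#' basis. Observed means are divided by it so that a perfect lattice of
#' the matching symmetry scores exactly 1. Values are computed numerically
#' on first use and cached (never hard-coded).
#'
#' @param ell symmetry order (integer >= 1).
#' @return The reference value in (0, 1].
#' @examples
#' qSym(1)  # 1: a single neighbour is always perfectly "ordered"
#' qSym(6)
#' @export
qSym <- function(ell) {
  stopifnot(ell >= 1)
  ell <- as.integer(ell)
  key <- sprintf("q%d", ell)
  if (!is.null(.qCache[[key]])) return(.qCache[[key]])
  phi <- 2 * pi * (seq_len(ell) - 1L) / ell
  v <- .qFromAzimuths(phi, rep(1 / ell, ell), ell)
  .qCache[[key]] <- v
  v
}

#' Minkowski bond orientational order parameter
#'
#' Per-particle \eqn{q_\ell} measuring \eqn{\ell}-fold angular symmetry of
#' the bonds to a particle's Voronoi-facet neighbours:
#' \deqn{q_\ell(i) = \Big[\frac{4\pi}{2\ell+1} \sum_{m=-\ell}^{\ell}
#'   \big| \sum_b w_b \, Y_{\ell m}(\pi/2, \phi_b) \big|^2 \Big]^{1/2}}
#' with bond azimuths \eqn{\phi_b} measured from the +x axis and bonds
#' embedded in the equatorial plane of the spherical-harmonic frame. In
#' `"facet"` mode (the Minkowski variant, the default) the weights are the
#' Voronoi facet lengths through each bond, \eqn{w_b = p_b / \sum p}, which
#' de-emphasizes metastable slivers of the tessellation; `"uniform"` mode
#' uses \eqn{w_b = 1/n}. Weights sum to one per particle, \eqn{q_\ell}
#' lies in \eqn{[0, 1]}, equals 1 for a single bond in any basis, and is
#' invariant under rigid rotation and translation of the pattern.
#'
#' @param partition a [VoronoiPartition-class].
#' @param ell symmetry order (integer >= 1).
#' @param weighting `"facet"` or `"uniform"`.
#' @param excludeEdge exclude window-truncated edge cells from the mean
#'   (default `TRUE`; their values are still reported per particle).
#' @return A [BondOrderResult-class].
#' @seealso [qSym()], [bondOrderPanel()]
#' @export
bondOrder <- function(partition, ell, weighting = c("facet", "uniform"),
                      excludeEdge = TRUE) {
  stopifnot(is(partition, "VoronoiPartition"))
  if (ell < 1) stop("ell must be >= 1")
  ell <- as.integer(ell)
  weighting <- match.arg(weighting)
  nb <- neighbourList(partition)
  fl <- facetLengthList(partition)
  xy <- coordinates(partition)
  n <- nrow(xy)
  q <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    js <- nb[[i]]
    if (!length(js)) stop("particle ", i, " has no retained facets")
    phi <- atan2(xy[js, 2] - xy[i, 2], xy[js, 1] - xy[i, 1])
    wts <- if (weighting == "facet") fl[[i]] / sum(fl[[i]])
           else rep(1 / length(js), length(js))
    q[i] <- .qFromAzimuths(phi, wts, ell)
  }
  included <- if (excludeEdge) !isEdgeCell(partition) else rep(TRUE, n)
  if (!any(included)) stop("no particles left after edge exclusion")
  m <- mean(q[included])
  qs <- qSym(ell)
  out <- q
  out[!included] <- NA_real_
  new("BondOrderResult", ell = ell, perParticle = out,
      included = included, mean = m, qSymValue = qs,
      normalizedMean = m / qs, weighting = weighting)
}

#' Bond order over several symmetry bases
#'
#' Computes [bondOrder()] for each requested \eqn{\ell} on one shared
#' tessellation; the overlay of \eqn{\ell = 4, 5, 6, 7} separates square
#' regions, disclination lines and hexagonal grains. For disordered
#' (CSR-like) patterns the normalized means converge to a similar value
#' in every basis, while ordered patterns single out their symmetry.
#'
#' @inheritParams bondOrder
#' @param ells integer vector of symmetry orders.
#' @return Named list of [BondOrderResult-class], names `"q4"`, `"q5"`, ...
#' @export
bondOrderPanel <- function(partition, ells = c(4L, 5L, 6L, 7L),
                           weighting = c("facet", "uniform"),
                           excludeEdge = TRUE) {
  weighting <- match.arg(weighting)
  res <- lapply(ells, function(l)
    bondOrder(partition, l, weighting = weighting,
              excludeEdge = excludeEdge))
  names(res) <- paste0("q", ells)
  res
}
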