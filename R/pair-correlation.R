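#' @include AllClasses.R
NULL

# spacing used for defaulted binning: interior Voronoi mean when
# available, else the hexagonal spacing at the global intensity
.defaultSpacing <- function(pattern) {
  sp <- tryCatch(meanSpacing(pattern), error = function(e) NULL)
  if (is.null(sp) || !is.finite(sp) || sp <= 0)
    sp <- hexagonalSpacing(intensity(pattern))
  sp
}

# fraction of the circle of radius r centred at (x, y) lying inside the
# rectangular window (exact, for r up to half the shorter side); the
# weight of the isotropic edge correction. Each side cuts an exterior arc
# of half-angle acos(d/r); adjacent sides overlap near a cut corner by
# (a_i + a_j - pi/2) when positive.
.arcFraction <- function(x, y, r, w) {
  d <- cbind(x - w@xmin, w@xmax - x, y - w@ymin, w@ymax - y)
  a <- acos(pmin(pmax(d / r, 0), 1))
  corner <- function(i, j) pmax(a[, i] + a[, j] - pi / 2, 0)
  ext <- 2 * rowSums(a) -
    corner(1, 3) - corner(2, 3) - corner(1, 4) - corner(2, 4)
  1 - ext / (2 * pi)
}

#' Pair correlation function g(r)
#'
#' The radially averaged neighbour density at distance r from a typical
#' particle, normalized by the global density:
#' \deqn{g(r) = \frac{n_n(r)}{2 \pi r \Delta r \rho}}
#' where \eqn{n_n(r)} is the mean number of neighbours per particle in the
#' circular shell of width \eqn{\Delta r} around r, and
#' \eqn{\rho = N / A_{box}}. Self-pairs are excluded and each unordered
#' pair is counted once per centre (ordered pairs). r in the denominator
#' is the bin centre. g(r) is 1 for complete spatial randomness and peaked
#' at shell distances for lattices; with no edge correction it decays at
#' large r as neighbours fall outside the window (matching the behaviour
#' of uncorrected estimates on micrograph data).
#'
#' @param pattern a [PointPattern-class] with at least 2 points.
#' @param binWidth shell width \eqn{\Delta r}; default 1/20 of the
#'   pattern's mean Voronoi spacing.
#' @param rMax maximum distance; default
#'   `min(5 * spacing, half short window side)`. Values beyond half the
#'   shorter window side trigger a warning (edge losses dominate there)
#'   but are honoured.
#' @param edgeCorrection apply the isotropic (arc-in-window) correction:
#'   each pair count is weighted by the inverse fraction of the circle
#'   through the neighbour that lies inside the window. Off by default.
#' @return A [RadialDistribution-class] with state `"raw"`.
#' @examples
#' w <- obsWindow(0, 20, 0, 20)
#' g <- pairCorrelation(hexagonalLattice(1, w))
#' @export
pairCorrelation <- function(pattern, binWidth = NULL, rMax = NULL,
                            edgeCorrection = FALSE) {
  stopifnot(is(pattern, "PointPattern"))
  n <- nPoints(pattern)
  if (n < 2L) stop("g(r) needs at least 2 points")
  w <- patternWindow(pattern)
  halfShort <- min(w@xmax - w@xmin, w@ymax - w@ymin) / 2
  if (is.null(binWidth) || is.null(rMax)) {
    sp <- .defaultSpacing(pattern)
    if (is.null(binWidth)) binWidth <- sp / 20
    if (is.null(rMax)) rMax <- min(5 * sp, halfShort)
  }
  stopifnot(binWidth > 0, rMax > binWidth)
  if (rMax > halfShort + 1e-12 * halfShort)
    warning("rMax exceeds half the shorter window side; ",
            "edge losses will dominate the tail")
  .grFromCoords(coordinates(pattern), w, n / windowArea(w),
                binWidth, rMax, edgeCorrection)
}

# core binned estimator shared by pairCorrelation and the bootstrap
.grFromCoords <- function(xy, w, rho, binWidth, rMax, edgeCorrection) {
  n <- nrow(xy)
  nb <- ceiling(rMax / binWidth - 1e-9)
  breaks <- seq(0, by = binWidth, length.out = nb + 1L)
  centres <- breaks[-1L] - binWidth / 2
  d <- stats::dist(xy)
  dv <- as.vector(d)
  sel <- dv <= breaks[nb + 1L]
  dv <- dv[sel]
  idx <- pmin(pmax(ceiling(dv / binWidth), 1L), nb)
  if (edgeCorrection) {
    # weight each ordered pair by 1/(arc fraction) at both centres
    ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)[sel, , drop = FALSE]
    wt1 <- 1 / .arcFraction(xy[ij[, 2], 1], xy[ij[, 2], 2], dv, w)
    wt2 <- 1 / .arcFraction(xy[ij[, 1], 1], xy[ij[, 1], 2], dv, w)
    counts <- vapply(seq_len(nb),
                     function(b) sum((wt1 + wt2)[idx == b]), numeric(1))
  } else {
    counts <- 2 * as.numeric(tabulate(idx, nbins = nb))
  }
  nn <- counts / n                       # mean neighbours per particle
  g <- nn / (2 * pi * centres * binWidth * rho)
  new("RadialDistribution", binCentres = centres, values = g,
      binWidth = binWidth, density = rho,
      normalization = "raw", kind = "gr")
}

#' Bootstrap-smoothed pair correlation function
#'
#' g(r) is poorly defined for samples of a few hundred particles: single
#' pair separations produce spurious spikes. Smoothing follows the shaken
#' ensemble idea: the pattern is replicated `nRealizations` times with
#' every particle displaced by an isotropic Gaussian of per-axis scale
#' `sigma` (the positional measurement uncertainty - e.g. half a pixel
#' width), and the per-realization g(r) estimates are averaged into one
#' global curve. With `sigma = 0` the result equals [pairCorrelation()].
#'
#' @inheritParams pairCorrelation
#' @param sigma per-axis Gaussian displacement scale (>= 0).
#' @param nRealizations ensemble size (default 1000).
#' @param seed integer seed; reproducible.
#' @return A [RadialDistribution-class] with state `"raw"`.
#' @export
bootstrapPairCorrelation <- function(pattern, sigma, nRealizations = 1000L,
                                     seed = 1L, binWidth = NULL, rMax = NULL,
                                     edgeCorrection = FALSE) {
  stopifnot(sigma >= 0, nRealizations >= 1)
  if (sigma == 0)
    return(pairCorrelation(pattern, binWidth, rMax, edgeCorrection))
  w <- patternWindow(pattern)
  halfShort <- min(w@xmax - w@xmin, w@ymax - w@ymin) / 2
  if (is.null(binWidth) || is.null(rMax)) {
    sp <- .defaultSpacing(pattern)
    if (is.null(binWidth)) binWidth <- sp / 20
    if (is.null(rMax)) rMax <- min(5 * sp, halfShort)
  }
  ens <- hexaticEnsemble(pattern, deltaR = sigma,
                         nRealizations = nRealizations, seed = seed)
  rho <- intensity(pattern)
  acc <- NULL
  for (p in ens) {
    gk <- .grFromCoords(coordinates(p), w, rho, binWidth, rMax,
                        edgeCorrection)
    acc <- if (is.null(acc)) grValues(gk) else acc + grValues(gk)
  }
  new("RadialDistribution",
      binCentres = seq(binWidth / 2, by = binWidth,
                       length.out = length(acc)),
      values = acc / nRealizations, binWidth = binWidth,
      density = rho, normalization = "raw", kind = "gr")
}

#' Normalize g(r) distances to a lattice spacing
#'
#' Rescales bin centres (and the bin width) by the average spacing
#' \eqn{2 r_{hex}}, collapsing curves from samples of different density
#' into a shared frame where the first-neighbour peak sits at 1.
#' Applying it twice is an error (the state machine forbids it).
#'
#' @param rdf a [RadialDistribution-class] not yet distance-normalized.
#' @param spacing the spacing to divide by (> 0), typically
#'   [meanSpacing()] of the same pattern.
#' @return A distance-normalized [RadialDistribution-class].
#' @export
normalizeDistance <- function(rdf, spacing) {
  stopifnot(is(rdf, "RadialDistribution"), spacing > 0)
  if (rdf@normalization %in% c("distance_normalized", "both"))
    stop("distances are already normalized")
  state <- if (rdf@normalization == "height_normalized") "both"
           else "distance_normalized"
  new("RadialDistribution", binCentres = rdf@binCentres / spacing,
      values = rdf@values, binWidth = rdf@binWidth / spacing,
      density = rdf@density, normalization = state, kind = rdf@kind)
}

#' Normalize g(r) by its maximum
#'
#' Divides the values by their maximum so the highest peak is 1
#' (idempotent).
#'
#' @param rdf a [RadialDistribution-class] with a positive maximum.
#' @return A height-normalized [RadialDistribution-class].
#' @export
normalizeHeight <- function(rdf) {
  stopifnot(is(rdf, "RadialDistribution"))
  m <- max(rdf@values)
  if (m <= 0) stop("cannot height-normalize an all-zero distribution")
  state <- if (rdf@normalization %in% c("distance_normalized", "both"))
    "both" else "height_normalized"
  new("RadialDistribution", binCentres = rdf@binCentres,
      values = rdf@values / m, binWidth = rdf@binWidth,
      density = rdf@density, normalization = state, kind = rdf@kind)
}

# squared distances i^2 + i*j + j^2 of the triangular lattice (spacing 1)
.hexShells <- function(rMax) {
  k <- ceiling(rMax) + 1L
  ij <- expand.grid(i = -k:k, j = -k:k)
  ij <- ij[!(ij$i == 0 & ij$j == 0), ]
  d2 <- ij$i^2 + ij$i * ij$j + ij$j^2
  d <- sqrt(d2)
  keep <- d <= rMax + 1e-12
  tab <- table(round(d[keep], 9))
  list(distance = as.numeric(names(tab)), multiplicity = as.integer(tab))
}

#' Reference g(r) of a perfect hexagonal lattice
#'
#' The pair correlation function of the ideal triangular lattice in
#' normalized units (nearest-neighbour spacing 1): delta-function peaks at
#' the shell distances \eqn{1, \sqrt 3, 2, \sqrt 7, 3, \ldots} with shell
#' multiplicities \eqn{6, 6, 6, 12, 6, \ldots}, each deposited as a
#' single-bin impulse scaled by the shell-area denominator
#' \eqn{2 \pi r \Delta r \lambda} with \eqn{\lambda = 2/\sqrt 3} (the
#' density of the unit-spacing lattice). The split second shell - an inner
#' peak at \eqn{\sqrt 3 \approx 1.73} and an outer one at exactly 2
#' normalized diameters - is the signature used to recognize hexagonal
#' order. For a broadened reference run [pairCorrelation()] on
#' [hexaticEnsemble()] output instead.
#'
#' @param binWidth bin width in normalized diameters (default 0.02).
#' @param rMax maximum normalized distance (default 3.2).
#' @return A distance-normalized [RadialDistribution-class].
#' @export
hexagonalReferenceGr <- function(binWidth = 0.02, rMax = 3.2) {
  stopifnot(binWidth > 0, rMax > 1)
  nb <- ceiling(rMax / binWidth - 1e-9)
  centres <- seq(binWidth / 2, by = binWidth, length.out = nb)
  vals <- numeric(nb)
  lambda <- 2 / sqrt(3)
  sh <- .hexShells(rMax)
  for (k in seq_along(sh$distance)) {
    b <- min(max(ceiling(sh$distance[k] / binWidth), 1L), nb)
    vals[b] <- vals[b] +
      sh$multiplicity[k] / (2 * pi * centres[b] * binWidth * lambda)
  }
  new("RadialDistribution", binCentres = centres, values = vals,
      binWidth = binWidth, density = lambda,
      normalization = "distance_normalized", kind = "gr")
}

#' Difference spectrum between two pair correlation functions
#'
#' \eqn{\Delta g(r) = g_a(r) - g_b(r)}: the residual after subtracting a
#' reference (e.g. the hexagonal or a matched hexatic lattice) from a
#' sample. Both inputs must be distance- and height-normalized so the
#' comparison is scale-free; the reference is linearly interpolated onto
#' the sample's bin centres (no extrapolation). Values may be negative:
#' areas above zero mean excess neighbour probability at that normalized
#' distance relative to the reference. The residual is maximal for
#' complete spatial randomness against a lattice reference and vanishes
#' when sample and reference agree.
#'
#' @param rdfA,rdfB [RadialDistribution-class] objects with normalization
#'   state `"both"`.
#' @return A [RadialDistribution-class] of kind `"difference"` on `rdfA`'s
#'   bins (restricted to the overlap).
#' @seealso [deltaRms()]
#' @export
differenceSpectrum <- function(rdfA, rdfB) {
  stopifnot(is(rdfA, "RadialDistribution"), is(rdfB, "RadialDistribution"))
  if (rdfA@normalization != "both" || rdfB@normalization != "both")
    stop("both spectra must be distance- and height-normalized ",
         "(state 'both') before differencing")
  keep <- rdfA@binCentres >= min(rdfB@binCentres) - 1e-12 &
          rdfA@binCentres <= max(rdfB@binCentres) + 1e-12
  if (!any(keep)) stop("non-overlapping distance ranges")
  ctr <- rdfA@binCentres[keep]
  bInterp <- stats::approx(rdfB@binCentres, rdfB@values, xout = ctr,
                           rule = 1)$y
  new("RadialDistribution", binCentres = ctr,
      values = rdfA@values[keep] - bInterp,
      binWidth = rdfA@binWidth, density = rdfA@density,
      normalization = "both", kind = "difference")
}

#' RMS of a difference spectrum
#'
#' The root of the mean squared \eqn{\Delta g} over bins inside `rRange`:
#' a single number summarizing how far a sample deviates from its
#' reference lattice. Larger values mean broader/more displaced peaks,
#' i.e. more translational disorder.
#'
#' @param diff a difference spectrum from [differenceSpectrum()].
#' @param rRange length-2 interval of normalized distances; default the
#'   full support.
#' @return A non-negative number.
#' @export
deltaRms <- function(diff, rRange = NULL) {
  stopifnot(is(diff, "RadialDistribution"))
  if (diff@kind != "difference")
    stop("deltaRms expects a difference spectrum")
  ctr <- diff@binCentres
  if (is.null(rRange)) rRange <- range(ctr)
  sel <- ctr >= rRange[1] & ctr <= rRange[2]
  if (!any(sel)) stop("empty distance range")
  sqrt(mean(diff@values[sel]^2))
}
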