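#' @include AllGenerics.R
NULL

# tolerance used for "on the boundary" decisions, relative to window size
.boundary_rtol <- 1e-9

#' Rectangular observation window
#'
#' An axis-aligned rectangle bounding a point pattern. Its area is the
#' \eqn{A_{box}} entering the intensity \eqn{\lambda = N / A_{box}} and the
#' pair-correlation density normalization.
#'
#' @slot xmin,xmax,ymin,ymax numeric scalars, in the pattern's length unit
#'   (nm, um or px); `xmax > xmin`, `ymax > ymin`.
#'
#' @seealso [obsWindow()], [windowArea()]
#' @export
setClass("ObsWindow",
  representation(xmin = "numeric", xmax = "numeric",
                 ymin = "numeric", ymax = "numeric"),
  validity = function(object) {
    v <- c(object@xmin, object@xmax, object@ymin, object@ymax)
    if (length(v) != 4L || !all(is.finite(v)))
      return("window bounds must be four finite numbers")
    if (object@xmax <= object@xmin) return("xmax must exceed xmin")
    if (object@ymax <= object@ymin) return("ymax must exceed ymin")
    TRUE
  })

#' Construct an observation window
#'
#' @param xmin,xmax,ymin,ymax window bounds. Alternatively `xmin` may be a
#'   length-4 vector `c(xmin, xmax, ymin, ymax)`.
#' @return An [ObsWindow-class].
#' @examples
#' w <- obsWindow(0, 10, 0, 10)
#' windowArea(w)
#' @export
obsWindow <- function(xmin, xmax = NULL, ymin = NULL, ymax = NULL) {
  if (is.null(xmax) && length(xmin) == 4L) {
    ymax <- xmin[4]; ymin <- xmin[3]; xmax <- xmin[2]; xmin <- xmin[1]
  }
  new("ObsWindow", xmin = as.numeric(xmin), xmax = as.numeric(xmax),
      ymin = as.numeric(ymin), ymax = as.numeric(ymax))
}

#' Window geometry helpers
#'
#' `windowArea` returns \eqn{A_{box}}; `windowDiagonal` the diagonal length;
#' `windowRange` the bounds as `c(xmin, xmax, ymin, ymax)` (the `rw` layout
#' used by deldir).
#'
#' @param w an [ObsWindow-class].
#' @return A numeric scalar (or length-4 vector for `windowRange`).
#' @export
windowArea <- function(w) (w@xmax - w@xmin) * (w@ymax - w@ymin)

#' @rdname windowArea
#' @export
windowDiagonal <- function(w) sqrt((w@xmax - w@xmin)^2 + (w@ymax - w@ymin)^2)

#' @rdname windowArea
#' @export
windowRange <- function(w) c(w@xmin, w@xmax, w@ymin, w@ymax)

.inWindow <- function(xy, w, tol = 0) {
  xy[, 1] >= w@xmin - tol & xy[, 1] <= w@xmax + tol &
  xy[, 2] >= w@ymin - tol & xy[, 2] <= w@ymax + tol
}

#' Planar point pattern
#'
#' Centroids of objects observed in a bounded rectangular window; the
#' universal input to every analysis in the package. All coordinates share
#' one length unit; any pixel-to-physical conversion happens once, at
#' ingestion ([readPattern()]).
#'
#' @slot coords two-column numeric matrix of (x, y) positions; every point
#'   lies inside or on the window.
#' @slot window the [ObsWindow-class].
#' @slot pixelSize length per pixel applied at read time, or `NA_real_`
#'   when coordinates were taken as-is.
#' @slot radii per-object radius (same unit), or `numeric(0)` when absent.
#' @slot label free-text sample label.
#'
#' @seealso [pointPattern()], [readPattern()], [tessellate()],
#'   [pairCorrelation()]
#' @export
setClass("PointPattern",
  representation(coords = "matrix", window = "ObsWindow",
                 pixelSize = "numeric", radii = "numeric",
                 label = "character"),
  validity = function(object) {
    xy <- object@coords
    if (!is.numeric(xy) || ncol(xy) != 2L)
      return("coords must be a two-column numeric matrix")
    if (nrow(xy) < 1L) return("a pattern needs at least one point")
    if (!all(is.finite(xy))) return("coordinates must be finite")
    tol <- .boundary_rtol * windowDiagonal(object@window)
    if (!all(.inWindow(xy, object@window, tol)))
      return("all points must lie inside or on the observation window")
    if (length(object@radii) && length(object@radii) != nrow(xy))
      return("radii must be absent or one per point")
    if (length(object@radii) && any(!is.finite(object@radii) | object@radii < 0))
      return("radii must be finite and non-negative")
    TRUE
  })

#' Construct a point pattern
#'
#' @param x,y numeric coordinate vectors (or `x` a two-column matrix).
#' @param window an [ObsWindow-class]; when `NULL` the tight axis-aligned
#'   bounding box of the points is used.
#' @param radii optional per-point radii.
#' @param pixelSize optional length-per-pixel already applied to the
#'   coordinates (metadata only; see [readPattern()] for conversion).
#' @param label sample label.
#' @return A [PointPattern-class].
#' @examples
#' p <- pointPattern(c(0, 1, 0), c(0, 0, 1))
#' nPoints(p)
#' intensity(p)
#' @export
pointPattern <- function(x, y = NULL, window = NULL, radii = numeric(0),
                         pixelSize = NA_real_, label = "") {
  if (is.null(y)) {
    xy <- as.matrix(x)
  } else {
    xy <- cbind(as.numeric(x), as.numeric(y))
  }
  storage.mode(xy) <- "double"
  dimnames(xy) <- list(NULL, c("x", "y"))
  if (is.null(window)) {
    if (nrow(xy) < 1L) stop("no points")
    window <- obsWindow(min(xy[, 1]), max(xy[, 1]), min(xy[, 2]), max(xy[, 2]))
    # a degenerate (collinear) bounding box is widened minimally
    if (window@xmax - window@xmin <= 0) window@xmax <- window@xmin + 1
    if (window@ymax - window@ymin <= 0) window@ymax <- window@ymin + 1
  }
  new("PointPattern", coords = xy, window = window,
      pixelSize = as.numeric(pixelSize),
      radii = as.numeric(radii), label = as.character(label))
}

#' @rdname nPoints
#' @export
setMethod("nPoints", "PointPattern", function(x) nrow(x@coords))

#' @rdname coordinates
#' @export
setMethod("coordinates", "PointPattern", function(x) x@coords)

#' @rdname patternWindow
#' @export
setMethod("patternWindow", "PointPattern", function(x) x@window)

#' @rdname intensity
#' @export
setMethod("intensity", "PointPattern",
          function(x) nPoints(x) / windowArea(x@window))

#' Per-point radii of a pattern
#' @param x a [PointPattern-class].
#' @return Numeric vector of radii, or `numeric(0)` when absent.
#' @export
patternRadii <- function(x) x@radii

#' Sample label of a pattern
#' @param x a [PointPattern-class].
#' @return Character scalar.
#' @export
patternLabel <- function(x) x@label

#' Window-clipped Voronoi partition
#'
#' The tessellation of a pattern into Voronoi cells clipped to the
#' observation window: per-cell polygon, area \eqn{A_{vor}}, facet lengths
#' and neighbour identities, and an edge flag for cells touching the window
#' boundary. Facets shorter than `facetEpsilon` are treated as degenerate
#' point contacts and dropped symmetrically (this resolves, e.g., the
#' metastable four-vertex degeneracy of an exact square lattice).
#'
#' The clipped cell areas tile the window: their sum equals the window area
#' to relative tolerance `1e-9` (enforced by the validity method).
#'
#' @slot coords generating points (copied from the pattern).
#' @slot window the [ObsWindow-class] the cells are clipped to.
#' @slot areas per-cell clipped area.
#' @slot polygons list of two-column vertex matrices, one per cell.
#' @slot neighbours list of integer vectors: Voronoi-facet neighbours of
#'   each particle after degeneracy filtering (symmetric relation).
#' @slot facetLengths list of numeric vectors parallel to `neighbours`.
#' @slot isEdge logical: cell touches the window boundary.
#' @slot facetEpsilon length tolerance used for degeneracy filtering.
#' @slot nDroppedFacets number of facet pairs removed as degenerate.
#'
#' @seealso [tessellate()], [coordination()], [disorderEstimate()],
#'   [bondOrder()]
#' @export
setClass("VoronoiPartition",
  representation(coords = "matrix", window = "ObsWindow", areas = "numeric",
                 polygons = "list", neighbours = "list",
                 facetLengths = "list", isEdge = "logical",
                 facetEpsilon = "numeric", nDroppedFacets = "integer"),
  validity = function(object) {
    n <- nrow(object@coords)
    if (length(object@areas) != n || length(object@neighbours) != n ||
        length(object@facetLengths) != n || length(object@isEdge) != n ||
        length(object@polygons) != n)
      return("per-cell slots must all have one entry per particle")
    if (any(object@areas <= 0)) return("cell areas must be positive")
    tot <- sum(object@areas)
    if (abs(tot - windowArea(object@window)) > 1e-9 * windowArea(object@window))
      return("clipped cell areas must sum to the window area")
    for (i in seq_len(n)) {
      if (length(object@neighbours[[i]]) != length(object@facetLengths[[i]]))
        return("facet lengths must parallel neighbour lists")
    }
    TRUE
  })

#' @rdname nPoints
#' @export
setMethod("nPoints", "VoronoiPartition", function(x) nrow(x@coords))

#' @rdname coordinates
#' @export
setMethod("coordinates", "VoronoiPartition", function(x) x@coords)

#' @rdname patternWindow
#' @export
setMethod("patternWindow", "VoronoiPartition", function(x) x@window)

#' @rdname intensity
#' @export
setMethod("intensity", "VoronoiPartition",
          function(x) nPoints(x) / windowArea(x@window))

#' Voronoi partition accessors
#'
#' `cellAreas` returns the clipped cell areas \eqn{A_{vor}}; `isEdgeCell`
#' the boundary flags; `neighbourList` and `facetLengthList` the
#' degeneracy-filtered facet graph; `cellPolygons` the clipped vertex
#' polygons.
#'
#' @param x a [VoronoiPartition-class].
#' @return See description.
#' @export
cellAreas <- function(x) x@areas

#' @rdname cellAreas
#' @export
isEdgeCell <- function(x) x@isEdge

#' @rdname cellAreas
#' @export
neighbourList <- function(x) x@neighbours

#' @rdname cellAreas
#' @export
facetLengthList <- function(x) x@facetLengths

#' @rdname cellAreas
#' @export
cellPolygons <- function(x) x@polygons

#' Binned radial distribution function
#'
#' A binned pair correlation function \eqn{g(r)} (or a difference spectrum
#' \eqn{\Delta g(r)}), together with its bin metadata, the density used in
#' the normalization, and a normalization state that tracks whether
#' distances have been rescaled to the mean spacing and/or values rescaled
#' by the maximum.
#'
#' @slot binCentres strictly increasing, equally spaced bin centres.
#' @slot values \eqn{g} at each bin centre (non-negative unless `kind`
#'   is `"difference"`).
#' @slot binWidth the shell width \eqn{\Delta r} of the estimator.
#' @slot density the number density \eqn{\rho} used in the denominator.
#' @slot normalization one of `"raw"`, `"distance_normalized"`,
#'   `"height_normalized"`, `"both"`.
#' @slot kind `"gr"` or `"difference"`.
#'
#' @seealso [pairCorrelation()], [normalizeDistance()], [normalizeHeight()],
#'   [differenceSpectrum()]
#' @export
setClass("RadialDistribution",
  representation(binCentres = "numeric", values = "numeric",
                 binWidth = "numeric", density = "numeric",
                 normalization = "character", kind = "character"),
  validity = function(object) {
    if (length(object@binCentres) != length(object@values))
      return("bin centres and values must have equal length")
    if (length(object@binCentres) < 1L) return("empty distribution")
    if (!(object@normalization %in%
          c("raw", "distance_normalized", "height_normalized", "both")))
      return("unknown normalization state")
    if (!(object@kind %in% c("gr", "difference")))
      return("kind must be 'gr' or 'difference'")
    if (object@kind == "gr" && any(object@values < 0))
      return("g(r) values must be non-negative")
    d <- diff(object@binCentres)
    if (length(d) && (any(d <= 0) ||
        max(abs(d - object@binWidth)) > 1e-6 * object@binWidth))
      return("bin centres must increase by the bin width")
    TRUE
  })

#' Radial distribution accessors
#'
#' @param x a [RadialDistribution-class].
#' @return `binCentres`/`grValues`: numeric vectors; `binWidth` the shell
#'   width; `normalizationState` the state string.
#' @export
binCentres <- function(x) x@binCentres

#' @rdname binCentres
#' @export
grValues <- function(x) x@values

#' @rdname binCentres
#' @export
binWidth <- function(x) x@binWidth

#' @rdname binCentres
#' @export
normalizationState <- function(x) x@normalization

#' Minkowski bond order result
#'
#' Per-particle bond orientational order parameters \eqn{q_\ell} in one
#' symmetry basis \eqn{\ell}, with the configuration mean
#' \eqn{\langle q_\ell \rangle}, the perfect-symmetry reference
#' \eqn{q_\ell^{sym}}, and the normalized mean
#' \eqn{\langle q_\ell \rangle / q_\ell^{sym}}.
#'
#' @slot ell the symmetry order (integer >= 1).
#' @slot perParticle \eqn{q_\ell(i)} for each particle; `NA` for excluded
#'   (edge) particles.
#' @slot included logical: particle entered the mean.
#' @slot mean arithmetic mean over included particles.
#' @slot qSymValue \eqn{q_\ell^{sym}}.
#' @slot normalizedMean `mean / qSymValue`.
#' @slot weighting `"facet"` (Voronoi facet-length weights) or `"uniform"`.
#'
#' @seealso [bondOrder()], [qSym()], [bondOrderPanel()]
#' @export
setClass("BondOrderResult",
  representation(ell = "integer", perParticle = "numeric",
                 included = "logical", mean = "numeric",
                 qSymValue = "numeric", normalizedMean = "numeric",
                 weighting = "character"),
  validity = function(object) {
    if (object@ell < 1L) return("ell must be >= 1")
    q <- object@perParticle[object@included]
    if (any(q < -1e-9 | q > 1 + 1e-9, na.rm = TRUE))
      return("q_l values must lie in [0, 1]")
    if (object@qSymValue <= 0) return("q_l^sym must be positive")
    if (!(object@weighting %in% c("facet", "uniform")))
      return("weighting must be 'facet' or 'uniform'")
    TRUE
  })

#' Bond order accessors
#' @param x a [BondOrderResult-class].
#' @return See description.
#' @export
bondOrderValues <- function(x) x@perParticle

#' @rdname bondOrderValues
#' @export
bondOrderMean <- function(x) x@mean

#' @rdname bondOrderValues
#' @export
normalizedBondOrder <- function(x) x@normalizedMean

#' Lattice disorder estimate
#'
#' Summary of translational disorder derived from interior Voronoi cell
#' areas: the mean expected spacing \eqn{\langle 2 r_{hex}^{vor} \rangle},
#' the error-propagated disorder parameter
#' \eqn{\Delta r = |\partial r_{hex} / \partial A| \, \Delta u_r}, and the
#' direct form \eqn{\Delta r = \sqrt{Var(r_{hex})}}.
#'
#' @slot meanSpacing \eqn{\langle 2 r_{hex}^{vor} \rangle}.
#' @slot deltaRPropagated error-propagated \eqn{\Delta r}.
#' @slot deltaRVariance \eqn{\sqrt{Var(r_{hex})}} (the canonical value).
#' @slot areaSD standard deviation \eqn{\Delta u_r} of interior cell areas.
#' @slot nInterior number of non-edge cells used.
#'
#' @seealso [disorderEstimate()]
#' @export
setClass("DisorderEstimate",
  representation(meanSpacing = "numeric", deltaRPropagated = "numeric",
                 deltaRVariance = "numeric", areaSD = "numeric",
                 nInterior = "integer"),
  validity = function(object) {
    v <- c(object@meanSpacing, object@deltaRPropagated,
           object@deltaRVariance, object@areaSD)
    if (any(!is.finite(v)) || any(v < 0))
      return("disorder summary fields must be finite and non-negative")
    TRUE
  })

#' Entropic valence probability map
#'
#' A 2D probability histogram of neighbour displacement vectors pooled over
#' particles translated to a common origin (optionally rotated to a common
#' orientation and subset by coordination number). Grid values sum to one
#' whenever at least one particle contributed.
#'
#' @slot grid `nBins x nBins` matrix of probabilities; rows index x bins
#'   (increasing), columns y bins (increasing).
#' @slot halfWidth map half-width R; the grid covers `[-R, R]^2`.
#' @slot oriented whether clouds were rotated to a common orientation.
#' @slot orientationRule rule used when oriented (`""` otherwise).
#' @slot coordinationFilter coordination subset, or `NA_integer_`.
#' @slot nContributing number of particles included.
#' @slot nOutOfRange neighbour endpoints falling outside the grid.
#'
#' @seealso [bondCloud()], [orientClouds()], [probabilityMap()]
#' @export
setClass("ValenceMap",
  representation(grid = "matrix", halfWidth = "numeric",
                 oriented = "logical", orientationRule = "character",
                 coordinationFilter = "integer", nContributing = "integer",
                 nOutOfRange = "integer"),
  validity = function(object) {
    if (nrow(object@grid) != ncol(object@grid))
      return("grid must be square")
    if (object@halfWidth <= 0) return("half-width must be positive")
    if (any(object@grid < 0)) return("probabilities must be non-negative")
    if (object@nContributing > 0L &&
        abs(sum(object@grid) - 1) > 1e-9)
      return("grid probabilities must sum to one")
    TRUE
  })

#' Combined order report
#'
#' One row of order metrics per sample (counts, intensity, mean spacing,
#' disorder parameter, coordination histogram summary, normalized bond
#' orders, difference-spectrum RMS) plus a run manifest sufficient to
#' reproduce the numbers bit-identically.
#'
#' @slot summary data.frame, one row per sample.
#' @slot coordinationHistograms named list of per-sample coordination
#'   probability tables.
#' @slot manifest list: seeds, windows, units and every defaulted
#'   parameter of the run.
#'
#' @seealso [orderReport()]
#' @export
setClass("OrderReport",
  representation(summary = "data.frame", coordinationHistograms = "list",
                 manifest = "list"))

#' @rdname orderReport
#' @param x an `OrderReport`.
#' @export
reportSummary <- function(x) x@summary

#' @rdname orderReport
#' @export
reportManifest <- function(x) x@manifest
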