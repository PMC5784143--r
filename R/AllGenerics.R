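#' @include AllGenerics.R
NULL

#' Number of points in an object
#'
#' @param x a [PointPattern-class] or [VoronoiPartition-class].
#' @return Integer count of particles.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' Centroid coordinates
#'
#' @param x a [PointPattern-class] or [VoronoiPartition-class].
#' @return A two-column numeric matrix (`x`, `y`).
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))

#' Observation window of an object
#'
#' @param x an object carrying an [ObsWindow-class].
#' @return The [ObsWindow-class].
#' @export
setGeneric("patternWindow", function(x) standardGeneric("patternWindow"))

#' Point intensity (number per unit area)
#'
#' The intensity \eqn{\lambda = N / A_{box}} of a pattern: the number of
#' particles divided by the area of its observation window.
#'
#' @param x a [PointPattern-class] or [VoronoiPartition-class].
#' @return A positive number, in units of inverse squared length.
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' Mean local lattice spacing
#'
#' The mean expected hexagonal spacing \eqn{\langle 2 r_{hex}^{vor} \rangle}
#' derived from interior (non-edge) Voronoi cell areas.
#'
#' @param x a [VoronoiPartition-class], or a [PointPattern-class] which is
#'   tessellated first.
#' @param ... passed to [tessellate()] for the pattern method.
#' @return Mean spacing in the pattern's length unit.
#' @export
setGeneric("meanSpacing", function(x, ...) standardGeneric("meanSpacing"))
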