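#' @include AllClasses.R
NULL

# Clip the Voronoi cell of one point against the window rectangle and the
# perpendicular bisectors to its Delaunay neighbours (the cell of a point
# is exactly the intersection of those half-planes). Sutherland-Hodgman
# with edge provenance: each polygon edge carries the id of the neighbour
# whose bisector it lies on, or a negative id for a window side. Computing
# the polygons in double precision here (rather than taking deldir's
# clipped tiles, whose areas round at ~1e-6) is what makes the cell areas
# tile the window to relative 1e-9.
.clipCell <- function(pt, nbrXY, nbrIds, w) {
  px <- c(w@xmin, w@xmax, w@xmax, w@xmin)
  py <- c(w@ymin, w@ymin, w@ymax, w@ymax)
  lab <- -(1:4)
  for (m in seq_along(nbrIds)) {
    a <- nbrXY[m, 1] - pt[1]
    b <- nbrXY[m, 2] - pt[2]
    c0 <- (a * (nbrXY[m, 1] + pt[1]) + b * (nbrXY[m, 2] + pt[2])) / 2
    val <- a * px + b * py - c0          # <= 0 on the point's side
    inside <- val <= 0
    if (all(inside)) next
    if (!any(inside)) return(NULL)       # empty cell (cannot happen here)
    n <- length(px)
    nx <- numeric(0); ny <- numeric(0); nl <- integer(0)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      if (inside[k]) {
        nx <- c(nx, px[k]); ny <- c(ny, py[k]); nl <- c(nl, lab[k])
        if (!inside[k2]) {
          t <- val[k] / (val[k] - val[k2])
          nx <- c(nx, px[k] + t * (px[k2] - px[k]))
          ny <- c(ny, py[k] + t * (py[k2] - py[k]))
          nl <- c(nl, nbrIds[m])         # exit: next edge runs on the cut
        }
      } else if (inside[k2]) {
        t <- val[k] / (val[k] - val[k2])
        nx <- c(nx, px[k] + t * (px[k2] - px[k]))
        ny <- c(ny, py[k] + t * (py[k2] - py[k]))
        nl <- c(nl, lab[k])              # entry: edge continues on lab[k]
      }
    }
    px <- nx; py <- ny; lab <- nl
  }
  list(x = px, y = py, lab = lab)
}

.shoelace <- function(x, y) {
  abs(sum(x * (c(y[-1], y[1])) - c(x[-1], x[1]) * y)) / 2
}

#' Window-clipped Voronoi tessellation
#'
#' Partitions the window into one Voronoi cell per particle, built from
#' perpendicular bisectors between neighbouring particles and clipped to
#' the observation window so that cell areas tile it exactly (their sum
#' equals the window area to relative `1e-9`). Facets shorter than
#' `facetEpsilon` are degenerate point contacts: they are removed and the
#' corresponding neighbour pair dropped on both sides. Cells whose polygon
#' touches the window boundary are flagged `isEdge`; local statistics
#' exclude them by default because their true cells extend beyond the
#' image.
#'
#' @param pattern a [PointPattern-class] with at least 2 points and no
#'   coincident points (within `1e-12` of the window diagonal).
#' @param facetEpsilon degeneracy tolerance; default `1e-6` times the
#'   window diagonal.
#' @return A [VoronoiPartition-class].
#' @examples
#' p <- pointPattern(c(0.25, 0.75), c(0.5, 0.5), obsWindow(0, 1, 0, 1))
#' v <- tessellate(p)
#' cellAreas(v)  # 0.5 0.5
#' @export
tessellate <- function(pattern, facetEpsilon = NULL) {
  stopifnot(is(pattern, "PointPattern"))
  xy <- coordinates(pattern)
  n <- nrow(xy)
  if (n < 2L) stop("tessellation needs at least 2 points")
  w <- patternWindow(pattern)
  diag <- windowDiagonal(w)
  if (is.null(facetEpsilon)) facetEpsilon <- 1e-6 * diag
  dupTol <- 1e-12 * diag
  o <- order(xy[, 1], xy[, 2])
  sx <- xy[o, , drop = FALSE]
  close <- which(abs(diff(sx[, 1])) <= dupTol & abs(diff(sx[, 2])) <= dupTol)
  if (length(close))
    stop("duplicate points (tessellation is undefined for coincident ",
         "generators): e.g. indices ", o[close[1]], " and ", o[close[1] + 1L])

  # Delaunay neighbour graph (the half-planes that can bound each cell)
  dd <- deldir::deldir(xy[, 1], xy[, 2], rw = windowRange(w),
                       suppressMsge = TRUE)
  s <- dd$delsgs
  adj <- vector("list", n)
  for (k in seq_len(nrow(s))) {
    i <- s$ind1[k]; j <- s$ind2[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }

  areas <- numeric(n)
  polys <- vector("list", n)
  isEdge <- logical(n)
  facetLen <- vector("list", n)   # per cell: named by neighbour id
  for (i in seq_len(n)) {
    js <- unique(adj[[i]])
    cell <- .clipCell(xy[i, ], xy[js, , drop = FALSE], js, w)
    if (is.null(cell) || length(cell$x) < 3L)
      stop("degenerate Voronoi cell for particle ", i)
    areas[i] <- .shoelace(cell$x, cell$y)
    polys[[i]] <- cbind(x = cell$x, y = cell$y)
    isEdge[i] <- any(cell$lab < 0L)
    ex <- c(cell$x[-1], cell$x[1]) - cell$x
    ey <- c(cell$y[-1], cell$y[1]) - cell$y
    el <- sqrt(ex^2 + ey^2)
    pos <- cell$lab > 0L
    facetLen[[i]] <- vapply(unique(cell$lab[pos]), function(j)
      sum(el[pos][cell$lab[pos] == j]), numeric(1))
    names(facetLen[[i]]) <- unique(cell$lab[pos])
  }

  # one facet length per unordered pair (taken from the lower-index cell)
  # so filtering is exactly symmetric
  nb <- lapply(seq_len(n), function(i) integer(0))
  fl <- lapply(seq_len(n), function(i) numeric(0))
  nDropped <- 0L
  for (i in seq_len(n)) {
    for (jname in names(facetLen[[i]])) {
      j <- as.integer(jname)
      if (j < i) next
      len <- facetLen[[i]][[jname]]
      if (len < facetEpsilon) {
        nDropped <- nDropped + 1L
        next
      }
      nb[[i]] <- c(nb[[i]], j); fl[[i]] <- c(fl[[i]], len)
      nb[[j]] <- c(nb[[j]], i); fl[[j]] <- c(fl[[j]], len)
    }
  }
  new("VoronoiPartition", coords = xy, window = w, areas = areas,
      polygons = polys, neighbours = nb, facetLengths = fl,
      isEdge = isEdge, facetEpsilon = facetEpsilon,
      nDroppedFacets = as.integer(nDropped))
}

#' Voronoi coordination numbers
#'
#' The coordination number of a particle is the number of Voronoi cell
#' facets its cell retains after degeneracy filtering - its geometric
#' neighbours. For a hexagonal lattice every interior particle has
#' coordination 6; 5/7 pairs mark disclination defects decorating grain
#' boundaries.
#'
#' @param partition a [VoronoiPartition-class].
#' @param excludeEdge when `TRUE` (default) edge cells get `NA` (their
#'   facet sets are truncated by the window).
#' @return Integer vector, one entry per particle (`NA` for excluded).
#' @seealso [coordinationHistogram()]
#' @export
coordination <- function(partition, excludeEdge = TRUE) {
  k <- lengths(neighbourList(partition))
  k <- as.integer(k)
  if (excludeEdge) k[isEdgeCell(partition)] <- NA_integer_
  k
}

#' Coordination probability histogram
#'
#' Probabilities of each observed coordination number; sums to one.
#'
#' @inheritParams coordination
#' @return Named numeric vector of probabilities (names = coordination).
#' @export
coordinationHistogram <- function(partition, excludeEdge = TRUE) {
  k <- coordination(partition, excludeEdge = excludeEdge)
  k <- k[!is.na(k)]
  if (!length(k)) stop("no cells left after edge exclusion")
  tab <- table(k)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p
}

#' Interior (analysis-grade) cells of a partition
#'
#' Logical mask of cells whose local statistics are trustworthy. Edge
#' cells (touching the window boundary) are always excluded. With
#' `buffer = TRUE` (the default for area-based disorder statistics) cells
#' Voronoi-adjacent to an edge cell are excluded as well: when the window
#' crops a lattice close to a row boundary, cells of the outermost
#' retained particles can stop just short of the window and leak their
#' truncated - hence inflated - areas into the interior set.
#'
#' @param partition a [VoronoiPartition-class].
#' @param buffer also exclude neighbours of edge cells.
#' @return Logical vector, one entry per particle.
#' @export
interiorCells <- function(partition, buffer = TRUE) {
  interior <- !isEdgeCell(partition)
  if (!buffer) return(interior)
  nb <- neighbourList(partition)
  touching <- vapply(nb, function(js)
    any(isEdgeCell(partition)[js]), logical(1))
  interior & !touching
}

#' Local hexagonal radius from a Voronoi cell area
#'
#' The radius \eqn{r_{hex} = \sqrt{A_{vor}} (2 \sqrt 3)^{-1/2}} of the
#' circular particle whose hexagonal Voronoi cell (area
#' \eqn{2 \sqrt{3} r^2}) matches the given local cell area. Twice this
#' radius is the local lattice spacing implied by the local density.
#'
#' @param area positive cell area(s).
#' @return Numeric vector of radii.
#' @examples
#' localHexRadius(2 * sqrt(3))  # 1
#' @export
localHexRadius <- function(area) {
  if (any(area <= 0)) stop("cell areas must be positive")
  sqrt(area) * (2 * sqrt(3))^(-1 / 2)
}

#' Lattice disorder estimate from Voronoi cell areas
#'
#' Derives translational-disorder metrics from interior (non-edge) cells:
#' the mean expected spacing
#' \eqn{\langle 2 r_{hex}^{vor} \rangle = mean(2 r_{hex}(A_{vor}))},
#' and the lattice disorder parameter \eqn{\Delta r} in two forms:
#' error propagation through the spacing function,
#' \eqn{\Delta r = |\partial r_{hex}/\partial A| \, \Delta u_r} with
#' \eqn{\Delta u_r} the standard deviation of interior areas and the
#' derivative \eqn{\frac{1}{2} A^{-1/2} (2\sqrt 3)^{-1/2}} evaluated at
#' the mean interior area; and the direct variance form
#' \eqn{\Delta r = \sqrt{Var(r_{hex})}}, which is the canonical value
#' reported by [orderReport()]. Both are zero for a perfect lattice and
#' grow with positional jitter.
#'
#' Cells entering the statistics are the buffered interior (see
#' [interiorCells()]): edge cells and their direct neighbours are
#' excluded, which keeps the estimate free of window-cropping artifacts.
#'
#' @param partition a [VoronoiPartition-class] with at least 3 interior
#'   cells.
#' @return A [DisorderEstimate-class].
#' @export
disorderEstimate <- function(partition) {
  interior <- interiorCells(partition)
  if (sum(interior) < 3L)
    stop("disorder estimation needs at least 3 interior (non-edge) cells")
  A <- cellAreas(partition)[interior]
  r <- localHexRadius(A)
  meanA <- mean(A)
  sdA <- stats::sd(A)
  deriv <- 0.5 * meanA^(-1 / 2) * (2 * sqrt(3))^(-1 / 2)
  new("DisorderEstimate",
      meanSpacing = mean(2 * r),
      deltaRPropagated = abs(deriv) * sdA,
      deltaRVariance = stats::sd(r),
      areaSD = sdA,
      nInterior = as.integer(sum(interior)))
}

#' @rdname meanSpacing
#' @export
setMethod("meanSpacing", "VoronoiPartition", function(x, ...) {
  interior <- interiorCells(x)
  if (sum(interior) < 1L) stop("no interior cells")
  mean(2 * localHexRadius(cellAreas(x)[interior]))
})

#' @rdname meanSpacing
#' @export
setMethod("meanSpacing", "PointPattern", function(x, ...) {
  meanSpacing(tessellate(x, ...))
})

#' Global density metrics of a pattern
#'
#' Number count N, intensity \eqn{\lambda = N/A_{box}}, and - when radii
#' are present - the mean radius and the covering fraction
#' \eqn{\phi = \sum \pi r_i^2 / A_{box}} (no overlap correction).
#'
#' @param pattern a [PointPattern-class].
#' @return Named list with `N`, `lambda`, and when radii are present
#'   `meanRadius` and `phi`.
#' @export
globalDensityMetrics <- function(pattern) {
  out <- list(N = nPoints(pattern), lambda = intensity(pattern))
  r <- patternRadii(pattern)
  if (length(r)) {
    out$meanRadius <- mean(r)
    out$phi <- sum(pi * r^2) / windowArea(patternWindow(pattern))
  }
  out
}
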