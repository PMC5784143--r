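#' @include AllClasses.R
NULL

#' Per-particle neighbour displacement clouds
#'
#' Translates every included particle to a common origin, bringing with it
#' the displacement vectors to its Voronoi-facet neighbours (its entropic
#' "bonds"). Optionally keeps only particles of one coordination number,
#' exposing the hidden rotational symmetry of disclination defects. Each
#' particle contributes as many vectors as its coordination number.
#'
#' @param partition a [VoronoiPartition-class].
#' @param coordinationFilter keep only particles with exactly this many
#'   neighbours (`NULL` keeps all). A filter matching no particle returns
#'   an empty list with a warning.
#' @param excludeEdge drop window-truncated edge cells (default `TRUE`).
#' @return A list, one element per included particle: a two-column
#'   displacement matrix with attribute `"facetLengths"` (used by
#'   [orientClouds()]) and `"particle"` (the particle index).
#' @seealso [orientClouds()], [probabilityMap()]
#' @export
bondCloud <- function(partition, coordinationFilter = NULL,
                      excludeEdge = TRUE) {
  stopifnot(is(partition, "VoronoiPartition"))
  nb <- neighbourList(partition)
  fl <- facetLengthList(partition)
  xy <- coordinates(partition)
  keep <- if (excludeEdge) !isEdgeCell(partition) else rep(TRUE, nrow(xy))
  if (!is.null(coordinationFilter))
    keep <- keep & lengths(nb) == as.integer(coordinationFilter)
  idx <- which(keep)
  if (!length(idx)) {
    warning("no particles match the requested coordination filter")
    return(structure(list(),
                     coordinationFilter = coordinationFilter))
  }
  out <- lapply(idx, function(i) {
    js <- nb[[i]]
    v <- cbind(xy[js, 1] - xy[i, 1], xy[js, 2] - xy[i, 2])
    attr(v, "facetLengths") <- fl[[i]]
    attr(v, "particle") <- i
    v
  })
  structure(out, coordinationFilter = coordinationFilter)
}

#' Rotate displacement clouds to a common orientation
#'
#' Rigidly rotates each particle's bond cloud so that its reference bond
#' points along +y; pairwise angles within a cloud are preserved exactly.
#' Two deterministic reference rules are available: `"longest_facet"`
#' (default) picks the neighbour subtending the longest Voronoi facet -
#' the most strongly "bonded" neighbour - and `"first_ccw"` picks the bond
#' with the smallest counter-clockwise angle from the +x axis. Oriented
#' maps depend on the rule, so record it with the results (see the
#' `orientationRule` slot of [ValenceMap-class]).
#'
#' @param clouds output of [bondCloud()] (each cloud non-empty).
#' @param rule orientation reference rule.
#' @return Clouds of the same shape, rotated; attribute `"rule"` records
#'   the rule.
#' @export
orientClouds <- function(clouds, rule = c("longest_facet", "first_ccw")) {
  rule <- match.arg(rule)
  out <- lapply(clouds, function(v) {
    ang <- atan2(v[, 2], v[, 1])
    ref <- if (rule == "longest_facet") {
      which.max(attr(v, "facetLengths"))
    } else {
      which.min(ang %% (2 * pi))
    }
    rot <- pi / 2 - ang[ref]
    # row-vector convention: w = v R rotates every bond by rot
    R <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2)
    w <- v %*% R
    attributes(w)[c("facetLengths", "particle")] <-
      attributes(v)[c("facetLengths", "particle")]
    w
  })
  structure(out, coordinationFilter = attr(clouds, "coordinationFilter"),
            rule = rule)
}

#' Entropic valence probability map
#'
#' Histograms all neighbour displacement endpoints into a square grid over
#' `[-R, R]^2` and normalizes to total probability one: the planar
#' first-neighbour (entropic valence) map. Hexagonal order shows as six
#' sharp maxima at arc separations \eqn{2\pi/6}; complete spatial
#' randomness as an angularly uniform ring. Counts are deposited as unit
#' weights per neighbour (no kernel smoothing - smoothing is a rendering
#' concern). Endpoints outside the grid are counted in `nOutOfRange`.
#'
#' @param clouds output of [bondCloud()] or [orientClouds()].
#' @param nBins grid side (>= 8, default 64).
#' @param halfWidth map half-width R (> 0).
#' @return A [ValenceMap-class].
#' @export
probabilityMap <- function(clouds, nBins = 64L, halfWidth) {
  stopifnot(nBins >= 8L, halfWidth > 0)
  nBins <- as.integer(nBins)
  pts <- do.call(rbind, c(clouds, list(matrix(numeric(0), ncol = 2))))
  if (is.null(pts) || !nrow(pts)) stop("no displacement vectors to map")
  ix <- floor((pts[, 1] + halfWidth) / (2 * halfWidth) * nBins) + 1L
  iy <- floor((pts[, 2] + halfWidth) / (2 * halfWidth) * nBins) + 1L
  inside <- ix >= 1L & ix <= nBins & iy >= 1L & iy <= nBins
  if (!any(inside)) stop("all displacement endpoints fall outside the map")
  grid <- matrix(0, nBins, nBins)
  tab <- table(factor(ix[inside], levels = seq_len(nBins)),
               factor(iy[inside], levels = seq_len(nBins)))
  grid[] <- as.numeric(tab)
  grid <- grid / sum(grid)
  filt <- attr(clouds, "coordinationFilter")
  new("ValenceMap", grid = grid, halfWidth = halfWidth,
      oriented = !is.null(attr(clouds, "rule")),
      orientationRule = if (is.null(attr(clouds, "rule"))) ""
                        else attr(clouds, "rule"),
      coordinationFilter = if (is.null(filt)) NA_integer_
                           else as.integer(filt),
      nContributing = length(clouds),
      nOutOfRange = as.integer(sum(!inside)))
}

#' Write a valence map as a dense matrix text file
#'
#' Tab-separated `nBins x nBins` probabilities, x bins in rows, preceded
#' by comment lines recording half-width, orientation rule and filter.
#'
#' @param map a [ValenceMap-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeValenceMap <- function(map, path) {
  hdr <- c(sprintf("# halfWidth %.17g", map@halfWidth),
           sprintf("# oriented %s rule %s", map@oriented,
                   if (nzchar(map@orientationRule)) map@orientationRule
                   else "none"),
           sprintf("# coordinationFilter %s nContributing %d outOfRange %d",
                   map@coordinationFilter, map@nContributing,
                   map@nOutOfRange))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(map@grid, con, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(path)
}
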