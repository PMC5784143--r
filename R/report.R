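#' @include AllClasses.R
NULL

.pkgVersion <- function() as.character(utils::packageVersion("PlanarOrder"))

# normalized, height-scaled g(r) of a pattern plus the spacing used
.normalizedGr <- function(pattern, binWidth = NULL, rMax = NULL,
                          bootstrapSigma = 0, nRealizations = 200L,
                          seed = 1L) {
  sp <- .defaultSpacing(pattern)
  g <- if (bootstrapSigma > 0)
    bootstrapPairCorrelation(pattern, sigma = bootstrapSigma,
                             nRealizations = nRealizations, seed = seed,
                             binWidth = binWidth, rMax = rMax)
  else
    pairCorrelation(pattern, binWidth = binWidth, rMax = rMax)
  list(gr = normalizeHeight(normalizeDistance(g, sp)), spacing = sp)
}

# build the reference spectrum requested by compareToReference
.referenceGr <- function(reference, pattern, sampleGr, seed) {
  if (is(reference, "PointPattern"))
    return(.normalizedGr(reference)$gr)
  bw <- binWidth(sampleGr)
  rmax <- max(binCentres(sampleGr)) + bw / 2
  if (identical(reference, "hexagonal"))
    return(normalizeHeight(hexagonalReferenceGr(binWidth = bw,
                                                rMax = rmax)))
  if (identical(reference, "hexatic")) {
    # hexagonal lattice at the sample's intensity, shaken by the sample's
    # own estimated disorder parameter, averaged over the ensemble
    lam <- intensity(pattern)
    base <- hexagonalLattice(lam, patternWindow(pattern))
    dr <- disorderEstimate(tessellate(pattern))@deltaRVariance
    g <- bootstrapPairCorrelation(base, sigma = dr, nRealizations = 100L,
                                  seed = seed)
    return(normalizeHeight(normalizeDistance(g, .defaultSpacing(base))))
  }
  stop("reference must be 'hexagonal', 'hexatic' or a PointPattern")
}

#' Compare a pattern against a reference lattice
#'
#' Runs the full positional-order comparison workflow: estimate the
#' sample's mean Voronoi spacing, compute its (optionally bootstrapped)
#' g(r), normalize distances by the spacing and heights by the maximum, do
#' the same for the reference, and report the difference spectrum
#' \eqn{\Delta g(r)} and its RMS. References: the ideal hexagonal lattice
#' (`"hexagonal"`), a hexatic lattice matched to the sample's intensity
#' and estimated disorder (`"hexatic"`), or any other [PointPattern-class]
#' (processed through the identical pipeline).
#'
#' @param pattern a [PointPattern-class].
#' @param reference `"hexagonal"`, `"hexatic"`, or a [PointPattern-class].
#' @param rRange normalized-distance interval for the RMS (default
#'   `c(0.5, 3)` clipped to the overlap).
#' @param bootstrapSigma when > 0, smooth the sample g(r) with a shaken
#'   ensemble of this per-axis scale.
#' @param nRealizations ensemble size for bootstrap/hexatic references.
#' @param seed integer seed for all stochastic steps.
#' @return A list: `delta` (the [RadialDistribution-class] difference
#'   spectrum), `deltaRms`, `spacing` (the sample spacing used), and
#'   `manifest` (parameters of the run, including the RMS definition).
#' @export
compareToReference <- function(pattern, reference = "hexagonal",
                               rRange = c(0.5, 3), bootstrapSigma = 0,
                               nRealizations = 200L, seed = 1L) {
  s <- .normalizedGr(pattern, bootstrapSigma = bootstrapSigma,
                     nRealizations = nRealizations, seed = seed)
  ref <- .referenceGr(reference, pattern, s$gr, seed)
  d <- differenceSpectrum(s$gr, ref)
  rr <- c(max(rRange[1], min(binCentres(d))),
          min(rRange[2], max(binCentres(d))))
  rms <- deltaRms(d, rr)
  list(delta = d, deltaRms = rms, spacing = s$spacing,
       manifest = list(
         reference = if (is(reference, "PointPattern"))
           paste0("pattern:", patternLabel(reference)) else reference,
         rRange = rr, bootstrapSigma = bootstrapSigma,
         nRealizations = nRealizations, seed = seed,
         deltaRmsDefinition = "rms of delta-g over rRange",
         version = .pkgVersion()))
}

#' Combined order report for one or more samples
#'
#' Joins the package's metrics into one table, one row per sample: N,
#' intensity \eqn{\lambda}, mean spacing
#' \eqn{\langle 2 r_{hex}^{vor} \rangle}, the lattice disorder parameter
#' \eqn{\Delta r} (variance and error-propagation forms), the probability
#' of 5/6/7-fold coordination, normalized bond order means for the
#' requested symmetry bases, and \eqn{\Delta_{rms}} against the chosen
#' reference. Full coordination histograms and a run manifest (seeds,
#' windows, units, every defaulted parameter) ride along so a run can be
#' reproduced bit-identically.
#'
#' @param patterns a [PointPattern-class], a list of them, or a character
#'   vector of file paths (read with [readPattern()] defaults).
#' @param ells symmetry bases for the bond order panel.
#' @param reference reference for \eqn{\Delta_{rms}} (`"hexagonal"`,
#'   `"hexatic"`, or `"none"` to skip).
#' @param seed integer seed for stochastic steps.
#' @param ... passed to [compareToReference()].
#' @return An [OrderReport-class].
#' @export
orderReport <- function(patterns, ells = c(4L, 5L, 6L, 7L),
                        reference = "hexagonal", seed = 1L, ...) {
  if (is(patterns, "PointPattern")) patterns <- list(patterns)
  if (is.character(patterns)) patterns <- lapply(patterns, readPattern)
  stopifnot(length(patterns) >= 1L)
  rows <- list()
  hists <- list()
  manifests <- list()
  for (k in seq_along(patterns)) {
    p <- patterns[[k]]
    lab <- if (nzchar(patternLabel(p))) patternLabel(p)
           else sprintf("sample%d", k)
    part <- tessellate(p)
    dis <- disorderEstimate(part)
    hist <- coordinationHistogram(part)
    bo <- bondOrderPanel(part, ells = ells)
    pOf <- function(k) if (k %in% names(hist)) unname(hist[k]) else 0
    row <- data.frame(
      label = lab, N = nPoints(p), lambda = intensity(p),
      meanSpacing = dis@meanSpacing,
      deltaR = dis@deltaRVariance,
      deltaRPropagated = dis@deltaRPropagated,
      p5 = pOf("5"), p6 = pOf("6"), p7 = pOf("7"),
      stringsAsFactors = FALSE)
    for (l in ells)
      row[[sprintf("q%dNorm", l)]] <- normalizedBondOrder(bo[[sprintf("q%d", l)]])
    if (!identical(reference, "none")) {
      cmp <- compareToReference(p, reference = reference, seed = seed, ...)
      row$deltaRms <- cmp$deltaRms
      manifests[[lab]] <- cmp$manifest
    }
    rows[[k]] <- row
    hists[[lab]] <- hist
  }
  summary <- do.call(rbind, rows)
  w1 <- patternWindow(patterns[[1]])
  new("OrderReport", summary = summary, coordinationHistograms = hists,
      manifest = list(
        seed = seed, ells = ells, reference = reference,
        window = windowRange(w1),
        pixelSize = patterns[[1]]@pixelSize,
        facetEpsilonRule = "1e-6 * window diagonal",
        edgePolicy = "edge cells excluded from local statistics",
        binWidthRule = "meanSpacing / 20",
        orientationRule = "longest_facet",
        perSample = manifests,
        version = .pkgVersion()))
}

#' Generate and write reference patterns
#'
#' Front end over the pattern generators that writes centroid tables in
#' the [readPattern()] format plus a JSON manifest with the seed and
#' parameters; the same generator spec and seed always produce
#' byte-identical coordinate files.
#'
#' @param kind one of `"hexagonal"`, `"square"`, `"csr"`, `"hexatic"`,
#'   `"confined"`.
#' @param outDir output directory (created if missing).
#' @param intensity target intensity (lattices, csr).
#' @param window an [ObsWindow-class].
#' @param deltaR displacement scale (hexatic).
#' @param nRealizations realization count (hexatic; one file each).
#' @param n particle count (confined).
#' @param seed integer seed.
#' @return Invisibly, the written file paths.
#' @export
simulatePatterns <- function(kind = c("hexagonal", "square", "csr",
                                      "hexatic", "confined"),
                             outDir, intensity = 1, window = obsWindow(0, 20, 0, 20),
                             deltaR = 0.05, nRealizations = 1L, n = 256L,
                             seed = 1L) {
  kind <- match.arg(kind)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  pats <- switch(kind,
    hexagonal = list(hexagonalLattice(intensity, window)),
    square = list(squareLattice(intensity, window)),
    csr = list(csrPattern(intensity, window, seed = seed)),
    hexatic = hexaticEnsemble(hexagonalLattice(intensity, window),
                              deltaR = deltaR,
                              nRealizations = nRealizations, seed = seed),
    confined = list(confinedPacking(n, window, seed = seed)))
  for (k in seq_along(pats)) {
    f <- file.path(outDir, sprintf("%s_%03d.csv", kind, k))
    writePattern(pats[[k]], f)
    paths <- c(paths, f)
  }
  writeManifest(list(kind = kind, seed = seed, intensity = intensity,
                     window = windowRange(window), deltaR = deltaR,
                     nRealizations = nRealizations, n = n,
                     files = paths, version = .pkgVersion()),
                file.path(outDir, sprintf("%s_manifest.json", kind)))
  invisible(paths)
}
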