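#' @include AllClasses.R
NULL

setMethod("show", "ObsWindow", function(object) {
  cat(sprintf("ObsWindow [%g, %g] x [%g, %g], area %g\n",
              object@xmin, object@xmax, object@ymin, object@ymax,
              windowArea(object)))
})

setMethod("show", "PointPattern", function(object) {
  cat(sprintf("PointPattern%s: %d points, intensity %.6g\n",
              if (nzchar(object@label)) paste0(" '", object@label, "'")
              else "",
              nPoints(object), intensity(object)))
  cat(sprintf("  window [%g, %g] x [%g, %g]",
              object@window@xmin, object@window@xmax,
              object@window@ymin, object@window@ymax))
  if (!is.na(object@pixelSize))
    cat(sprintf("; pixel size %g", object@pixelSize))
  if (length(object@radii))
    cat(sprintf("; mean radius %.4g", mean(object@radii)))
  cat("\n")
})

setMethod("show", "VoronoiPartition", function(object) {
  k <- lengths(object@neighbours)
  cat(sprintf("VoronoiPartition: %d cells (%d interior), %d degenerate facet(s) dropped\n",
              nPoints(object), sum(!object@isEdge), object@nDroppedFacets))
  cat(sprintf("  coordination range %d-%d; facet epsilon %.3g\n",
              min(k), max(k), object@facetEpsilon))
})

setMethod("show", "RadialDistribution", function(object) {
  cat(sprintf("%s: %d bins, width %.4g, state '%s'\n",
              if (object@kind == "gr") "RadialDistribution g(r)"
              else "Difference spectrum dg(r)",
              length(object@values), object@binWidth,
              object@normalization))
  i <- which.max(abs(object@values))
  cat(sprintf("  extremum %.4g at r = %.4g\n",
              object@values[i], object@binCentres[i]))
})

setMethod("show", "BondOrderResult", function(object) {
  cat(sprintf("BondOrderResult l = %d (%s weights): <q_%d> = %.4f, q_sym = %.4f, normalized %.4f\n",
              object@ell, object@weighting, object@ell, object@mean,
              object@qSymValue, object@normalizedMean))
  cat(sprintf("  %d of %d particles in the mean\n",
              sum(object@included), length(object@perParticle)))
})

setMethod("show", "DisorderEstimate", function(object) {
  cat(sprintf("DisorderEstimate (%d interior cells)\n", object@nInterior))
  cat(sprintf("  <2 r_hex^vor> = %.6g\n", object@meanSpacing))
  cat(sprintf("  delta-r: %.6g (variance form), %.6g (error propagation)\n",
              object@deltaRVariance, object@deltaRPropagated))
})

setMethod("show", "ValenceMap", function(object) {
  cat(sprintf("ValenceMap %dx%d over [-%g, %g]^2, %d particles%s%s\n",
              nrow(object@grid), ncol(object@grid), object@halfWidth,
              object@halfWidth, object@nContributing,
              if (object@oriented)
                sprintf(", oriented (%s)", object@orientationRule) else "",
              if (!is.na(object@coordinationFilter))
                sprintf(", coordination = %d", object@coordinationFilter)
              else ""))
  if (object@nOutOfRange > 0L)
    cat(sprintf("  %d endpoint(s) out of range\n", object@nOutOfRange))
})

setMethod("show", "OrderReport", function(object) {
  cat(sprintf("OrderReport: %d sample(s)\n", nrow(object@summary)))
  print(object@summary, digits = 4)
})
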