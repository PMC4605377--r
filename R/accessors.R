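# Accessor and show methods for the package classes.

## ---- accessors ----

#' @describeIn BScanImage-class intensity matrix of a B-scan
#' @param y ignored
#' @export
setMethod("imageData", "BScanImage", function(y) y@image)

#' @export
setMethod("axialPitch", "BScanImage", function(x) x@axialPitch)
#' @export
setMethod("axialPitch", "SurfaceSet", function(x) x@axialPitch)
#' @export
setMethod("axialPitch", "CorrectedSurfaceSet", function(x) x@axialPitch)
#' @export
setMethod("lateralPitch", "BScanImage", function(x) x@lateralPitch)
#' @export
setMethod("frameTime", "BScanImage", function(x) x@timestamp)
#' @export
setMethod("framePhase", "BScanImage", function(x) x@phase)

#' @export
setMethod("surfaceTraces", "SurfaceSet", function(x) x@traces)
#' @export
setMethod("surfaceTraces", "CorrectedSurfaceSet", function(x) x@traces)
#' @export
setMethod("apAxis", "SurfaceSet", function(x) x@apAxis)
#' @export
setMethod("apAxis", "CorrectedSurfaceSet", function(x) x@apAxis)
#' @export
setMethod("vertexPoint", "SurfaceSet", function(x) x@vertex)
#' @export
setMethod("surfaceFailures", "SurfaceSet", function(x) x@failures)
#' @export
setMethod("interfaceArcs", "CorrectedSurfaceSet", function(x) x@arcs)
#' @export
setMethod("indexStack", "CorrectedSurfaceSet", function(x) x@indices)

#' @export
setMethod("eyeSurfaces", "EyeGeometry", function(x) x@surfaces)
#' @export
setMethod("pupilRadius", "EyeGeometry", function(x) x@pupilRadius)
#' @export
setMethod("irisSag", "EyeGeometry", function(x) x@irisSag)
#' @export
setMethod("refractiveIndices", "TissueOptics", function(x) x@indices)
#' @export
setMethod("scenarioPhases", "OsmoticScenario", function(x) x@phases)
#' @export
setMethod("totalDuration", "OsmoticScenario",
          function(x) sum(x@phases$duration))

## ---- show methods ----

setMethod("show", "EyeGeometry", function(object) {
  ap <- object@surfaces$apex
  cat("EyeGeometry\n")
  cat(sprintf("  CCT %.1f  ACD %.1f  LT %.1f  CRD %.1f um\n",
              ap[2] - ap[1], ap[3] - ap[2], ap[4] - ap[3], ap[5] - ap[2]))
  cat(sprintf("  pupil radius %.0f um, iris sag %+.1f um, field +/-%.0f um\n",
              object@pupilRadius, object@irisSag, object@lateralExtent))
})

setMethod("show", "TissueOptics", function(object) {
  cat("TissueOptics\n  n:",
      paste(sprintf("%s=%.3f", names(object@indices), object@indices),
            collapse = " "), "\n")
  cat(sprintf("  lens opacity x%.3f to front depth %.2f of LT\n",
              object@lensOpacityMultiplier, object@opacityFrontDepth))
})

setMethod("show", "OsmoticScenario", function(object) {
  cat(sprintf("OsmoticScenario '%s' (%s eye): %d phase(s), %d baseline repeats\n",
              object@name, object@geometry, nrow(object@phases),
              object@baselineRepeats))
  p <- object@phases
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %d. %-10s %4d mOsmol/kg, %4.0f min, %.2f frames/min, tau %.1f min\n",
                i, p$label[i], p$osmolality[i], p$duration[i],
                p$framesPerMin[i], object@tau[i]))
})

setMethod("show", "BScanImage", function(object) {
  cat(sprintf("BScanImage %d x %d (axial x lateral), pitch %.1f/%.1f um, t = %.1f min [%s]\n",
              nrow(object@image), ncol(object@image), object@axialPitch,
              object@lateralPitch, object@timestamp, object@phase))
})

setMethod("show", "SurfaceSet", function(object) {
  n <- table(factor(object@traces$label, levels = .ALL_SURFACES))
  cat("SurfaceSet (optical-path coordinates)\n")
  cat(sprintf("  AP axis at x = %.1f um, vertex z = %.1f um\n",
              object@apAxis, object@vertex[2]))
  cat("  points:", paste(sprintf("%s=%d", names(n), n), collapse = " "), "\n")
  if (length(object@failures))
    cat("  FAILED:", paste(object@failures, collapse = ", "), "\n")
})

setMethod("show", "CorrectedSurfaceSet", function(object) {
  cat("CorrectedSurfaceSet (geometric coordinates)\n")
  cat(sprintf("  %d points over %d surfaces, %d excluded; indices: %s\n",
              nrow(object@traces), length(unique(object@traces$label)),
              nrow(object@excluded),
              paste(sprintf("%s=%.2f", names(object@indices), object@indices),
                    collapse = " ")))
})
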