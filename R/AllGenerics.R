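#' @import methods
NULL

#' @describeIn BScanImage-class axial pixel pitch in micrometres of optical
#'   path per pixel
#' @export
setGeneric("axialPitch", function(x) standardGeneric("axialPitch"))

#' @describeIn BScanImage-class lateral pixel pitch in micrometres per pixel
#' @export
setGeneric("lateralPitch", function(x) standardGeneric("lateralPitch"))

#' @describeIn BScanImage-class acquisition timestamp in minutes
#' @export
setGeneric("frameTime", function(x) standardGeneric("frameTime"))

#' @describeIn BScanImage-class phase label of the acquisition
#' @export
setGeneric("framePhase", function(x) standardGeneric("framePhase"))

#' @describeIn SurfaceSet-class detected surface traces as a data.frame with
#'   columns \code{label}, \code{x}, \code{z}
#' @export
setGeneric("surfaceTraces", function(x) standardGeneric("surfaceTraces"))

#' @describeIn SurfaceSet-class lateral position (micrometres) of the
#'   anteroposterior axis
#' @export
setGeneric("apAxis", function(x) standardGeneric("apAxis"))

#' @describeIn SurfaceSet-class corneal vertex point \code{c(x, z)}
#' @export
setGeneric("vertexPoint", function(x) standardGeneric("vertexPoint"))

#' @describeIn SurfaceSet-class per-surface failure report (character vector
#'   of missing or rejected surface labels)
#' @export
setGeneric("surfaceFailures", function(x) standardGeneric("surfaceFailures"))

#' @describeIn CorrectedSurfaceSet-class fitted interface arc models used by
#'   the correction
#' @export
setGeneric("interfaceArcs", function(x) standardGeneric("interfaceArcs"))

#' @describeIn CorrectedSurfaceSet-class refractive index stack applied during
#'   the correction
#' @export
setGeneric("indexStack", function(x) standardGeneric("indexStack"))

#' @describeIn EyeGeometry-class data.frame of axial surfaces (label, apex
#'   position, signed radius of curvature)
#' @export
setGeneric("eyeSurfaces", function(x) standardGeneric("eyeSurfaces"))

#' @describeIn EyeGeometry-class pupil radius in micrometres
#' @export
setGeneric("pupilRadius", function(x) standardGeneric("pupilRadius"))

#' @describeIn EyeGeometry-class signed iris sag amplitude in micrometres
#'   (positive = anterior bowing)
#' @export
setGeneric("irisSag", function(x) standardGeneric("irisSag"))

#' @describeIn TissueOptics-class named refractive indices of the ocular media
#' @export
setGeneric("refractiveIndices", function(x) standardGeneric("refractiveIndices"))

#' @describeIn OsmoticScenario-class phase table (label, osmolality, duration,
#'   frames per minute)
#' @export
setGeneric("scenarioPhases", function(x) standardGeneric("scenarioPhases"))

#' @describeIn OsmoticScenario-class total scheduled duration in minutes
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))
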