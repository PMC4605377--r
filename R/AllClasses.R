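# Central S4 classes. Conventions used throughout the package:
#  - z: axial coordinate in micrometres, increasing posteriorly.
#    Geometric micrometres in EyeGeometry / CorrectedSurfaceSet,
#    optical-path micrometres in BScanImage / SurfaceSet.
#  - x: lateral coordinate in micrometres, 0 on the instrument axis
#    (image centre).
#  - Signed radius of curvature: positive when the centre of curvature lies
#    posterior to the surface (anterior-convex, e.g. the corneal surfaces),
#    negative when anterior (e.g. the posterior lens surface, the retina).
#    Inf encodes a flat surface.

.AXIAL_SURFACES <- c("cornea_anterior", "cornea_posterior",
                     "lens_anterior", "lens_posterior", "ilm")
.IRIS_SURFACES <- c("iris_ipe_left", "iris_ipe_right")
.ALL_SURFACES <- c(.AXIAL_SURFACES, .IRIS_SURFACES)
.PARAMETERS <- c("cct", "acd", "lt", "crd", "lsi", "iris_sag")

#' Ground-truth geometric description of the ocular surfaces
#'
#' An \code{EyeGeometry} holds the geometric state of a schematic eye at one
#' time instant: the five axial interfaces (anterior/posterior cornea,
#' anterior/posterior crystalline lens, retinal inner limiting membrane)
#' modelled as circular arcs (apex axial position plus signed radius of
#' curvature), and an iris model per wing given by a root point, the
#' iris--lens contact point (derived from the anterior lens arc at the pupil
#' margin) and a signed sag amplitude (positive = anterior bowing,
#' i.e. a convex iris).
#'
#' @slot surfaces data.frame with columns \code{label}, \code{apex} (geometric
#'   micrometres) and \code{radius} (signed micrometres, \code{Inf} = flat)
#'   for the five axial surfaces.
#' @slot pupilRadius pupil radius, micrometres.
#' @slot irisRootX,irisRootZ iris root point of the nasal/temporal wings
#'   (mirror symmetric), micrometres.
#' @slot irisSag signed sag of the iris pigment epithelium at the chord
#'   midpoint, micrometres; positive bows toward the cornea.
#' @slot irisThickness iris body thickness, micrometres.
#' @slot lateralExtent half-width of the modelled field, micrometres.
#'
#' @seealso [mouseEye()], [modelEye()], [eyeAtTime()], [renderBScan()]
#' @export
setClass("EyeGeometry",
  representation(surfaces = "data.frame",
                 pupilRadius = "numeric",
                 irisRootX = "numeric",
                 irisRootZ = "numeric",
                 irisSag = "numeric",
                 irisThickness = "numeric",
                 lateralExtent = "numeric"))

setValidity("EyeGeometry", function(object) {
  s <- object@surfaces
  msg <- character()
  if (!identical(s$label, .AXIAL_SURFACES))
    return(sprintf("surfaces$label must be exactly: %s",
                   paste(.AXIAL_SURFACES, collapse = ", ")))
  if (any(!is.finite(s$apex)))
    msg <- c(msg, "surface apex positions must be finite")
  if (any(diff(s$apex) <= 0))
    msg <- c(msg, paste("apex positions must be strictly ordered along the",
                        "AP axis (cornea ant < cornea post < lens ant <",
                        "lens post < ILM)"))
  ap <- s$apex
  cct <- ap[2] - ap[1]; acd <- ap[3] - ap[2]
  lt <- ap[4] - ap[3]; crd <- ap[5] - ap[2]
  if (any(c(cct, acd, lt, crd) <= 0))
    msg <- c(msg, "derived thicknesses (CCT, ACD, LT, CRD) must all be > 0")
  if (crd <= acd + lt)
    msg <- c(msg, "CRD must exceed ACD + LT (vitreous depth must be > 0)")
  if (any(s$radius == 0)) msg <- c(msg, "radii must be non-zero (use Inf for flat)")
  if (object@pupilRadius <= 0) msg <- c(msg, "pupilRadius must be > 0")
  if (object@irisRootX <= object@pupilRadius)
    msg <- c(msg, "iris root must be lateral to the iris-lens contact point")
  if (object@lateralExtent <= object@irisRootX)
    msg <- c(msg, "lateralExtent must exceed the iris root position")
  if (object@irisThickness <= 0) msg <- c(msg, "irisThickness must be > 0")
  if (!is.finite(object@irisSag)) msg <- c(msg, "irisSag must be finite")
  if (length(msg)) msg else TRUE
})

#' Optical properties of the ocular media
#'
#' Refractive indices of the four ocular media (defaults 1.40 cornea, 1.33
#' aqueous humor, 1.57 crystalline lens, 1.33 vitreous), refractive indices of
#' the tonicity drops keyed by osmolality, per-layer mean backscatter
#' intensities (linear, arbitrary units) and the lens opacification model
#' (intensity multiplier applied anterior to an opacification front expressed
#' as a fraction of the optical lens thickness).
#'
#' @slot indices named numeric: \code{cornea}, \code{aqueous}, \code{lens},
#'   \code{vitreous}; all >= 1.
#' @slot dropIndices named numeric, names are osmolalities in mOsmol/kg.
#' @slot intensities named numeric, linear backscatter per layer
#'   (\code{background}, \code{cornea}, \code{aqueous}, \code{lens},
#'   \code{vitreous}, \code{retina}, \code{iris}, \code{shadow}).
#' @slot lensOpacityMultiplier intensity multiplier for the opacified
#'   anterior lens region (1 = clear lens).
#' @slot opacityFrontDepth opacification front depth as a fraction of the
#'   optical lens thickness, in [0, 1].
#'
#' @seealso [tissueOptics()], [dropIndexSpread()]
#' @export
setClass("TissueOptics",
  representation(indices = "numeric",
                 dropIndices = "numeric",
                 intensities = "numeric",
                 lensOpacityMultiplier = "numeric",
                 opacityFrontDepth = "numeric"))

setValidity("TissueOptics", function(object) {
  msg <- character()
  need <- c("cornea", "aqueous", "lens", "vitreous")
  if (!all(need %in% names(object@indices)))
    msg <- c(msg, paste("indices must name:", paste(need, collapse = ", ")))
  if (any(object@indices < 1)) msg <- c(msg, "all refractive indices must be >= 1")
  if (length(object@dropIndices) && any(object@dropIndices < 1))
    msg <- c(msg, "drop indices must be >= 1")
  needI <- c("background", "cornea", "aqueous", "lens", "vitreous",
             "retina", "iris", "shadow")
  if (!all(needI %in% names(object@intensities)))
    msg <- c(msg, paste("intensities must name:", paste(needI, collapse = ", ")))
  if (any(object@intensities < 0)) msg <- c(msg, "intensities must be >= 0")
  if (object@lensOpacityMultiplier < 0)
    msg <- c(msg, "lensOpacityMultiplier must be >= 0")
  if (object@opacityFrontDepth < 0 || object@opacityFrontDepth > 1)
    msg <- c(msg, "opacityFrontDepth must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Osmotic challenge schedule and per-parameter response model
#'
#' Ordered study phases (agent osmolality, duration, imaging frequency) plus,
#' per phase, the asymptotic fractional change and exponential relaxation time
#' constant of each biometric parameter. Phase responses are piecewise
#' exponential relaxations, continuous across phase boundaries; isotonic
#' reversal phases have zero asymptotic change, i.e. relax back toward
#' baseline.
#'
#' @slot name scenario name.
#' @slot phases data.frame with columns \code{label}, \code{osmolality}
#'   (mOsmol/kg), \code{duration} (min), \code{framesPerMin}.
#' @slot amplitudes numeric matrix, one row per phase, columns
#'   \code{cct, acd, lt, crd, lsi, iris_sag}; asymptotic fractional change of
#'   each parameter relative to baseline (e.g. -0.207 = 20.7\% decrease).
#' @slot tau numeric, relaxation time constant per phase, minutes.
#' @slot baselineRepeats number of repeat baseline acquisitions before the
#'   first phase (default 5).
#' @slot geometry which baseline geometry the scenario applies to
#'   (\code{"mouse"} or \code{"model_eye"}).
#'
#' @seealso [osmoticScenario()], [readScenario()], [osmoticResponse()],
#'   [renderTimeSeries()]
#' @export
setClass("OsmoticScenario",
  representation(name = "character",
                 phases = "data.frame",
                 amplitudes = "matrix",
                 tau = "numeric",
                 baselineRepeats = "numeric",
                 geometry = "character"))

setValidity("OsmoticScenario", function(object) {
  msg <- character()
  p <- object@phases
  if (nrow(p) < 1) return("phase list must be non-empty")
  if (!all(c("label", "osmolality", "duration", "framesPerMin") %in% names(p)))
    msg <- c(msg, "phases needs columns label, osmolality, duration, framesPerMin")
  else {
    if (any(p$duration <= 0)) msg <- c(msg, "phase durations must be > 0")
    if (any(p$framesPerMin <= 0)) msg <- c(msg, "imaging frequencies must be > 0")
  }
  if (nrow(object@amplitudes) != nrow(p))
    msg <- c(msg, "amplitudes must have one row per phase")
  if (!identical(colnames(object@amplitudes), .PARAMETERS))
    msg <- c(msg, sprintf("amplitude columns must be: %s",
                          paste(.PARAMETERS, collapse = ", ")))
  if (length(object@tau) != nrow(p) || any(object@tau <= 0))
    msg <- c(msg, "tau must be one positive time constant per phase")
  if (object@baselineRepeats < 1) msg <- c(msg, "baselineRepeats must be >= 1")
  if (!object@geometry %in% c("mouse", "model_eye"))
    msg <- c(msg, "geometry must be 'mouse' or 'model_eye'")
  if (length(msg)) msg else TRUE
})

#' A 2D OCT intensity cross-section in optical-path coordinates
#'
#' Rows are axial samples (depth measured in optical-path length: geometric
#' distance times the local refractive index accumulates along each A-scan),
#' columns are lateral A-scan positions. Intensities are linear and
#' non-negative.
#'
#' @slot image numeric matrix (rows axial, columns lateral), intensities >= 0.
#' @slot axialPitch micrometres of optical path (in air) per pixel.
#' @slot lateralPitch micrometres per pixel.
#' @slot timestamp acquisition time, minutes.
#' @slot phase phase label.
#'
#' @seealso [renderBScan()], [detectSurfaces()]
#' @export
setClass("BScanImage",
  representation(image = "matrix",
                 axialPitch = "numeric",
                 lateralPitch = "numeric",
                 timestamp = "numeric",
                 phase = "character"))

setValidity("BScanImage", function(object) {
  msg <- character()
  if (object@axialPitch <= 0 || object@lateralPitch <= 0)
    msg <- c(msg, "pixel pitches must be > 0")
  if (any(object@image < 0)) msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Segmented surface traces in optical-path image coordinates
#'
#' Per-surface point traces (lateral position x, axial optical-path depth z,
#' both micrometres), the located AP-axis lateral position and corneal vertex
#' point, and a per-surface failure report. Within every A-scan column the
#' axial surfaces preserve anatomical order; this is enforced by the class
#' validity, not merely assumed.
#'
#' @slot traces data.frame with columns \code{label}, \code{x}, \code{z}.
#' @slot apAxis lateral position of the AP axis, micrometres.
#' @slot vertex corneal vertex point \code{c(x, z)}.
#' @slot failures character vector naming surfaces that could not be detected.
#' @slot axialPitch axial pitch of the source image (micrometres/pixel),
#'   carried along for pixel-scale tolerances.
#'
#' @seealso [detectSurfaces()], [dewarp()]
#' @export
setClass("SurfaceSet",
  representation(traces = "data.frame",
                 apAxis = "numeric",
                 vertex = "numeric",
                 failures = "character",
                 axialPitch = "numeric"))

setValidity("SurfaceSet", function(object) {
  tr <- object@traces
  if (!all(c("label", "x", "z") %in% names(tr)))
    return("traces needs columns label, x, z")
  if (nrow(tr) && !all(tr$label %in% .ALL_SURFACES))
    return("unknown surface label in traces")
  ax <- tr[tr$label %in% .AXIAL_SURFACES, ]
  if (nrow(ax)) {
    # anatomical order within each A-scan column
    ord <- match(ax$label, .AXIAL_SURFACES)
    bad <- vapply(split(seq_len(nrow(ax)), ax$x), function(i) {
      is.unsorted(ax$z[i][order(ord[i])], strictly = TRUE)
    }, logical(1))
    if (any(bad))
      return("anatomical surface order violated within an A-scan column")
    dup <- vapply(split(ax$x, ax$label), anyDuplicated, integer(1))
    if (any(dup > 0))
      return("surface traces must be single-valued in lateral position")
  }
  TRUE
})

#' Refraction-corrected surface coordinates in geometric micrometres
#'
#' Result of the layer-by-layer Snell's-law correction: the same surface
#' labels as [SurfaceSet-class] with coordinates in geometric micrometres,
#' the fitted interface arc models used to evaluate surface normals, the
#' refractive index stack applied, and any points excluded (e.g. total
#' internal reflection, missing shallower surface).
#'
#' @slot traces data.frame with columns \code{label}, \code{x}, \code{z}
#'   (geometric micrometres).
#' @slot arcs named list of arc models (see [fitInterface()]).
#' @slot indices named refractive index stack applied.
#' @slot apAxis AP-axis lateral position, micrometres.
#' @slot excluded data.frame of excluded points (\code{label}, \code{x},
#'   \code{reason}).
#' @slot axialPitch axial pitch of the source image, micrometres/pixel.
#'
#' @seealso [dewarp()], [measureAxial()]
#' @export
setClass("CorrectedSurfaceSet",
  representation(traces = "data.frame",
                 arcs = "list",
                 indices = "numeric",
                 apAxis = "numeric",
                 excluded = "data.frame",
                 axialPitch = "numeric"))

setValidity("CorrectedSurfaceSet", function(object) {
  if (!all(c("label", "x", "z") %in% names(object@traces)))
    return("traces needs columns label, x, z")
  TRUE
})
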