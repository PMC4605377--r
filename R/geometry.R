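# Schematic-eye geometry constructors and evaluation helpers.

#' Construct an eye geometry from axial biometry
#'
#' Builds an [EyeGeometry-class] from the four axial biometric parameters and
#' per-surface radii of curvature. Surfaces are circular arcs (apex + signed
#' radius); iris wings are quadratic arcs through the iris root, the sag apex
#' and the iris--lens contact point at the pupil margin.
#'
#' @param cct,acd,lt,crd central corneal thickness, anterior chamber depth,
#'   lens thickness and cornea--retina distance, geometric micrometres.
#' @param radii named numeric, signed radii of curvature (micrometres) for
#'   \code{cornea_anterior}, \code{cornea_posterior}, \code{lens_anterior},
#'   \code{lens_posterior}, \code{ilm}; \code{Inf} = flat.
#' @param apexOffset axial position of the anterior corneal apex
#'   (micrometres), i.e. the air gap above the eye.
#' @param pupilRadius pupil radius, micrometres.
#' @param irisRootX lateral position of the iris root, micrometres.
#' @param irisRootZOffset axial offset of the iris root posterior to the
#'   iris--lens contact point, micrometres.
#' @param irisSag signed iris sag, micrometres (+ = anterior bowing).
#' @param irisThickness iris body thickness, micrometres.
#' @param lateralExtent modelled half-field, micrometres.
#' @return A validated [EyeGeometry-class].
#' @examples
#' g <- eyeGeometry(cct = 119, acd = 404, lt = 1860, crd = 3080)
#' eyeSurfaces(g)
#' @export
eyeGeometry <- function(cct, acd, lt, crd,
                        radii = c(cornea_anterior = 1450,
                                  cornea_posterior = 1400,
                                  lens_anterior = 1000,
                                  lens_posterior = -1050,
                                  ilm = -1600),
                        apexOffset = 150,
                        pupilRadius = 500,
                        irisRootX = 1100,
                        irisRootZOffset = 90,
                        irisSag = 0,
                        irisThickness = 40,
                        lateralExtent = 1200) {
  stopifnot(all(.AXIAL_SURFACES %in% names(radii)))
  apex <- c(apexOffset,
            apexOffset + cct,
            apexOffset + cct + acd,
            apexOffset + cct + acd + lt,
            apexOffset + cct + crd)
  geom <- new("EyeGeometry",
              surfaces = data.frame(label = .AXIAL_SURFACES, apex = apex,
                                    radius = unname(radii[.AXIAL_SURFACES])),
              pupilRadius = pupilRadius,
              irisRootX = irisRootX,
              irisRootZ = NA_real_,  # set below from the lens arc
              irisSag = irisSag,
              irisThickness = irisThickness,
              lateralExtent = lateralExtent)
  geom@irisRootZ <- .irisContact(geom)[2] + irisRootZOffset
  validObject(geom)
  geom
}

#' Default mouse baseline eye geometry
#'
#' Baseline biometry of the adult mouse eye: CCT 119, ACD 404, LT 1860,
#' CRD 3080 micrometres, with an isotonic iris sag of +28.6 micrometres.
#' Curvature radii are plausible documented defaults for the mouse (the
#' corneal and lens radii are free configuration, not measured values).
#'
#' @param irisSag signed iris sag, micrometres.
#' @param ... passed to [eyeGeometry()].
#' @return An [EyeGeometry-class].
#' @examples
#' mouseEye()
#' @export
mouseEye <- function(irisSag = 28.6, ...) {
  eyeGeometry(cct = 119, acd = 404, lt = 1860, crd = 3080,
              irisSag = irisSag, ...)
}

#' Schematic model-eye geometry (manufacturer dimensions)
#'
#' A physical calibration model eye with CCT 0.55 mm, ACD 3.03 mm and
#' LT 3.9 mm. The vitreous depth is a documented default of 6 mm (the
#' manufacturer specifies only the anterior segment) so the retinal surface is
#' present for the full segmentation chain; radii are human-scale defaults.
#'
#' @param vitreousDepth vitreous depth behind the lens, micrometres.
#' @return An [EyeGeometry-class].
#' @examples
#' modelEye()
#' @export
modelEye <- function(vitreousDepth = 6000) {
  eyeGeometry(cct = 550, acd = 3030, lt = 3900,
              crd = 3030 + 3900 + vitreousDepth,
              radii = c(cornea_anterior = 7800, cornea_posterior = 6500,
                        lens_anterior = 10200, lens_posterior = -6000,
                        ilm = -12000),
              apexOffset = 400,
              pupilRadius = 1500,
              irisRootX = 4600,
              irisRootZOffset = 100,
              irisSag = 0,
              irisThickness = 120,
              lateralExtent = 5200)
}

# Evaluate a circular-arc surface z(x) given apex position and signed radius.
# Positive radius: centre posterior to the apex (anterior-convex).
# Returns NA outside the arc's lateral support.
.surfZ <- function(apex, radius, x) {
  if (!is.finite(radius)) return(rep(apex, length(x)))
  d2 <- radius^2 - x^2
  z <- rep(NA_real_, length(x))
  ok <- d2 >= 0
  z[ok] <- apex + radius - sign(radius) * sqrt(d2[ok])
  z
}

#' Evaluate an axial surface of an eye geometry
#'
#' @param geometry an [EyeGeometry-class].
#' @param label one of the five axial surface labels.
#' @param x lateral positions, micrometres.
#' @return Axial geometric positions z(x), micrometres (NA beyond the arc's
#'   lateral support).
#' @examples
#' surfaceZ(mouseEye(), "cornea_anterior", c(-500, 0, 500))
#' @export
surfaceZ <- function(geometry, label, x) {
  s <- geometry@surfaces
  i <- match(label, s$label)
  if (is.na(i)) stop("unknown surface label: ", label)
  .surfZ(s$apex[i], s$radius[i], x)
}

# Iris-lens contact point on the right wing: the point of the anterior lens
# arc at the pupil margin. Returns c(x, z).
.irisContact <- function(geometry) {
  s <- geometry@surfaces
  i <- match("lens_anterior", s$label)
  z <- .surfZ(s$apex[i], s$radius[i], geometry@pupilRadius)
  if (is.na(z))
    stop("pupil margin lies beyond the anterior lens arc support")
  c(geometry@pupilRadius, z)
}

#' Iris pigment epithelium curve of one wing
#'
#' The IPE is a quadratic arc from the iris--lens contact point (pupil margin
#' on the anterior lens surface) to the iris root, displaced perpendicular to
#' the root--contact chord by \code{4 * sag * u * (1 - u)} so the maximum
#' perpendicular distance from the chord equals the signed sag (positive
#' toward the cornea).
#'
#' @param geometry an [EyeGeometry-class].
#' @param wing \code{"right"} (x > 0) or \code{"left"}.
#' @param n number of sample points.
#' @return Matrix with columns \code{x}, \code{z} (geometric micrometres),
#'   ordered from contact point to root.
#' @examples
#' head(irisTrace(mouseEye(), "right"))
#' @export
irisTrace <- function(geometry, wing = c("right", "left"), n = 121) {
  wing <- match.arg(wing)
  ct <- .irisContact(geometry)
  rt <- c(geometry@irisRootX, geometry@irisRootZ)
  u <- seq(0, 1, length.out = n)
  chord <- rt - ct
  len <- sqrt(sum(chord^2))
  tang <- chord / len
  # perpendicular with negative z-component points anterior (toward cornea)
  norm <- c(tang[2], -tang[1])
  if (norm[2] > 0) norm <- -norm
  off <- 4 * geometry@irisSag * u * (1 - u)
  xz <- cbind(x = ct[1] + u * chord[1] + off * norm[1],
              z = ct[2] + u * chord[2] + off * norm[2])
  if (wing == "left") xz[, "x"] <- -xz[, "x"]
  xz
}

#' Ground-truth biometry of a geometry
#'
#' The six biometric parameters implied directly by an [EyeGeometry-class]
#' and [TissueOptics-class], used as the reference for recovery tests:
#' CCT, ACD, LT, CRD from the apex positions, LSI as the mean lens backscatter
#' in the anterior sampling window, and IC as the iris sag.
#'
#' @param geometry an [EyeGeometry-class].
#' @param optics a [TissueOptics-class].
#' @param lsiFraction anterior fraction of the optical lens thickness averaged
#'   for LSI.
#' @return One-row data.frame with columns \code{cct, acd, lt, crd, lsi, ic}.
#' @examples
#' trueBiometry(mouseEye(), tissueOptics())
#' @export
trueBiometry <- function(geometry, optics, lsiFraction = 0.15) {
  ap <- geometry@surfaces$apex
  mult <- optics@lensOpacityMultiplier
  front <- optics@opacityFrontDepth
  base <- unname(optics@intensities["lens"])
  # mean over the anterior window [0, lsiFraction] of optical LT
  opac <- min(front, lsiFraction) / lsiFraction
  lsi <- base * (opac * mult + (1 - opac))
  data.frame(cct = ap[2] - ap[1], acd = ap[3] - ap[2], lt = ap[4] - ap[3],
             crd = ap[5] - ap[2], lsi = lsi, ic = geometry@irisSag)
}
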