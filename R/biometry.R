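# The six biometric parameters: CCT, ACD, LT, CRD (axial distances along the
# AP axis, geometric micrometres), LSI (mean lens backscatter from the
# anterior capsule toward the anterior nucleus, linear units, measured on the
# raw A-scan), and IC (signed iris curvature, micrometres, positive =
# anterior/convex bowing).

#' Axial biometric distances on the AP axis
#'
#' CCT = anterior to posterior corneal surface; ACD = corneal endothelium to
#' anterior lens surface; LT = anterior to posterior lens surface; CRD =
#' corneal endothelium to the retinal inner limiting membrane. Each surface's
#' axial position at the AP axis is evaluated from its fitted arc model
#' (falling back to trace interpolation when no arc is available), which
#' pools the whole corrected trace and is exact on noiseless phantoms.
#'
#' @param surfaces a [CorrectedSurfaceSet-class].
#' @param apAxisX AP-axis lateral position; defaults to the one stored with
#'   the surfaces.
#' @return Named numeric \code{c(cct, acd, lt, crd)}, micrometres.
#' @examples
#' b <- renderBScan(mouseEye(), tissueOptics())
#' measureAxial(dewarp(detectSurfaces(b), tissueOptics()))
#' @export
measureAxial <- function(surfaces, apAxisX = apAxis(surfaces)) {
  stopifnot(is(surfaces, "CorrectedSurfaceSet"))
  if (!is.finite(apAxisX)) stop("AP-axis position is undefined")
  tr <- surfaceTraces(surfaces)
  arcs <- interfaceArcs(surfaces)
  zAt <- vapply(.AXIAL_SURFACES, function(l) {
    s <- tr[tr$label == l, ]
    if (nrow(s) < 2) return(NA_real_)
    span <- diff(range(s$x))
    if (span < 150) {
      # focused region (e.g. the retina near the beam focus): corrected
      # points collapse laterally, so arc extrapolation is meaningless --
      # use the robust centre of the point cluster instead
      return(stats::median(s$z))
    }
    if (!is.null(arcs[[l]])) {
      z <- evalArc(arcs[[l]], apAxisX)
      if (is.finite(z)) return(z)
    }
    stats::approx(s$x, s$z, xout = apAxisX, rule = 1)$y
  }, numeric(1))
  if (anyNA(zAt))
    stop("surface(s) missing at the AP axis: ",
         paste(.AXIAL_SURFACES[is.na(zAt)], collapse = ", "))
  zAt <- unname(zAt)
  out <- c(cct = zAt[2] - zAt[1], acd = zAt[3] - zAt[2],
           lt = zAt[4] - zAt[3], crd = zAt[5] - zAt[2])
  if (any(out <= 0))
    stop("non-positive axial distance (degenerate layer): ",
         paste(names(out)[out <= 0], collapse = ", "))
  out
}

#' Lens scattering intensity (LSI)
#'
#' Mean linear backscatter intensity of the lens from the anterior capsule to
#' the anterior nuclear region: the A-scan samples from the anterior lens
#' boundary down to \code{region} of the optical lens thickness. The average
#' is taken on the uncorrected image (optical-path sampling, since the
#' average runs along the A-scan) over a narrow lateral band centred on the
#' AP axis.
#'
#' @param image the raw [BScanImage-class].
#' @param surfaces the uncorrected [SurfaceSet-class] for the same image.
#' @param region anterior fraction of the optical lens thickness to average,
#'   in (0, 1]; default 0.15 (anterior capsule-to-nucleus span).
#' @param lateralHalfWidth half-width of the lateral averaging band, columns.
#' @param marginPx rows skipped below the boundary to avoid the interface
#'   partial-volume pixels.
#' @return Mean linear intensity (arbitrary units).
#' @examples
#' b <- renderBScan(mouseEye(), tissueOptics())
#' measureLSI(b, detectSurfaces(b))
#' @export
measureLSI <- function(image, surfaces, region = 0.15,
                       lateralHalfWidth = 10, marginPx = 2) {
  stopifnot(is(image, "BScanImage"), is(surfaces, "SurfaceSet"))
  if (region <= 0 || region > 1) stop("region fraction must be in (0, 1]")
  im <- imageData(image)
  ap <- axialPitch(image); lp <- lateralPitch(image)
  nL <- ncol(im)
  xs <- (seq_len(nL) - (nL + 1) / 2) * lp
  tr <- surfaceTraces(surfaces)
  la <- tr[tr$label == "lens_anterior", ]
  lpo <- tr[tr$label == "lens_posterior", ]
  if (nrow(la) < 1 || nrow(lpo) < 1)
    stop("lens surfaces not available for LSI")
  x0 <- apAxis(surfaces)
  cols <- which(abs(xs - x0) <= lateralHalfWidth * lp)
  vals <- c()
  for (j in cols) {
    zla <- la$z[match(xs[j], la$x)]
    zlp <- lpo$z[match(xs[j], lpo$x)]
    if (is.na(zla) || is.na(zlp)) next
    r0 <- ceiling(zla / ap) + marginPx
    r1 <- floor((zla + region * (zlp - zla)) / ap)
    if (r1 >= r0 && r1 <= nrow(im)) vals <- c(vals, im[r0:r1, j])
  }
  if (!length(vals)) stop("empty LSI sampling window")
  mean(vals)
}

#' Iris curvature (IC)
#'
#' Per wing: the chord joins the iris root (the most peripheral detected iris
#' point) and the most peripheral point of iris--lens contact (the central
#' end of the iris trace at the pupil margin); IC is the signed maximum
#' perpendicular distance of the iris pigment epithelium from that chord,
#' positive toward the cornea (anterior/convex bowing). A quadratic is fitted
#' to the perpendicular offsets to suppress trace noise, and the two wings
#' are averaged. If the central iris end does not meet the anterior lens
#' surface (no contact), the iris tip is used as the landmark and the result
#' is flagged.
#'
#' @param surfaces a [CorrectedSurfaceSet-class] containing iris traces (and
#'   the anterior lens arc, used to verify contact).
#' @param contactTol maximum distance (um) between the central iris end and
#'   the anterior lens surface still counted as contact.
#' @return Signed IC in micrometres; attribute \code{"flag"} is TRUE when a
#'   fallback landmark was used.
#' @examples
#' b <- renderBScan(mouseEye(), tissueOptics())
#' measureIC(dewarp(detectSurfaces(b), tissueOptics()))
#' @export
measureIC <- function(surfaces, contactTol = 25) {
  stopifnot(is(surfaces, "CorrectedSurfaceSet"))
  tr <- surfaceTraces(surfaces)
  arcs <- interfaceArcs(surfaces)
  flag <- FALSE
  wingIC <- function(lab) {
    s <- tr[tr$label == lab, ]
    if (nrow(s) < 6) return(NA_real_)
    s <- s[order(abs(s$x)), ]
    sgn <- sign(s$x[nrow(s)])
    ax <- abs(s$x)
    # smooth quadratic model of the wing (the iris is a shallow arc); if the
    # trace is clearly not quadratic (large fit residual), fall back to
    # linear interpolation of the raw points so strongly curved traces keep
    # their true extreme
    qf <- stats::lm.fit(cbind(1, ax, ax^2), s$z)
    cf <- qf$coefficients
    irisF <- if (sqrt(mean(qf$residuals^2)) <= 3)
      function(a) cf[1] + cf[2] * a + cf[3] * a^2
    else stats::approxfun(ax, s$z, rule = 2)
    root <- c(ax[length(ax)], irisF(ax[length(ax)]))  # most peripheral point
    # contact landmark: where the (extrapolated) iris meets the anterior
    # lens surface, searched just inside the central trace end
    tip <- c(ax[1], irisF(ax[1]))
    if (!is.null(arcs[["lens_anterior"]])) {
      gfun <- function(a) {
        zl <- evalArc(arcs[["lens_anterior"]], sgn * a)
        if (!is.finite(zl)) return(NA_real_)
        irisF(a) - zl
      }
      lo <- max(ax[1] - 100, 1); hi <- ax[1] + 150
      glo <- gfun(lo); ghi <- gfun(hi)
      if (is.finite(glo) && is.finite(ghi) && glo * ghi < 0) {
        cx <- stats::uniroot(gfun, c(lo, hi), tol = 1e-4)$root
        tip <- c(cx, irisF(cx))
      } else if (abs(gfun(ax[1])) > contactTol) flag <<- TRUE
    } else flag <<- TRUE
    chord <- root - tip
    len <- sqrt(sum(chord^2))
    if (len < 1e-6) return(NA_real_)
    u <- chord / len
    anterior <- c(u[2], -u[1])
    if (anterior[2] > 0) anterior <- -anterior
    aa <- seq(tip[1], root[1], length.out = 201)
    rel <- cbind(aa - tip[1], irisF(aa) - tip[2])
    d <- rel %*% anterior
    d[which.max(abs(d))]
  }
  ics <- c(wingIC("iris_ipe_left"), wingIC("iris_ipe_right"))
  if (all(is.na(ics))) stop("no iris trace available for IC")
  out <- mean(ics, na.rm = TRUE)
  attr(out, "flag") <- flag
  out
}

#' Full biometry of one B-scan
#'
#' Runs the whole measurement chain on a single frame: surface detection,
#' Snell's-principle distortion correction, and the six parameters.
#'
#' @param image a [BScanImage-class].
#' @param optics a [TissueOptics-class] (index stack).
#' @param lsiFraction LSI sampling fraction of the optical lens thickness.
#' @param seeds optional segmentation seed points (see [detectSurfaces()]).
#' @return One-row data.frame: \code{time, phase, cct, acd, lt, crd, lsi,
#'   ic, flags}.
#' @examples
#' measureBiometry(renderBScan(mouseEye(), tissueOptics()), tissueOptics())
#' @export
measureBiometry <- function(image, optics = tissueOptics(),
                            lsiFraction = 0.15, seeds = NULL) {
  surf <- detectSurfaces(image, seeds = seeds)
  flags <- character()
  if (length(surfaceFailures(surf)))
    flags <- paste0("missing:", paste(surfaceFailures(surf), collapse = "+"))
  corr <- dewarp(surf, optics)
  ax <- tryCatch(measureAxial(corr), error = function(e) {
    flags <<- c(flags, conditionMessage(e))
    c(cct = NA_real_, acd = NA_real_, lt = NA_real_, crd = NA_real_)
  })
  lsi <- tryCatch(measureLSI(image, surf, region = lsiFraction),
                  error = function(e) { flags <<- c(flags, "lsi_failed"); NA_real_ })
  ic <- tryCatch({
    v <- measureIC(corr)
    if (isTRUE(attr(v, "flag"))) flags <- c(flags, "ic_fallback")
    as.numeric(v)
  }, error = function(e) { flags <<- c(flags, "ic_failed"); NA_real_ })
  data.frame(time = frameTime(image), phase = framePhase(image),
             cct = ax[["cct"]], acd = ax[["acd"]], lt = ax[["lt"]],
             crd = ax[["crd"]], lsi = lsi, ic = ic,
             flags = paste(flags, collapse = ";"))
}

#' Biometry of a frame stack
#'
#' @param frames list of [BScanImage-class] objects.
#' @param ... passed to [measureBiometry()].
#' @return data.frame with one row per frame.
#' @export
measureStack <- function(frames, ...) {
  out <- do.call(rbind, lapply(frames, measureBiometry, ...))
  rownames(out) <- NULL
  out
}
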