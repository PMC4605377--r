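# Optical distortion correction: layer-by-layer Snell's-law ray tracing.
#
# OCT images depth in optical-path length, so every structure behind a
# refracting interface appears displaced. The correction proceeds anterior to
# posterior: the corneal anterior trace is geometric already (air, n = 1);
# each deeper surface point is relocated along the refracted probing ray with
# geometric segment length = optical-path increment / n of the traversed
# layer, using surface normals from circular arcs fitted to the already
# corrected shallower interface.

#' Fit a circular arc (or flat) model to a surface trace
#'
#' Algebraic least-squares circle fit with optional robustness (iterated
#' trimming of residuals beyond 3 median absolute deviations). Collinear
#' points, or a fitted radius beyond \code{flatRadiusBound}, fall back to a
#' flat (straight-line) model rather than failing.
#'
#' @param x,z trace coordinates, micrometres.
#' @param robust iterate outlier trimming (3 rounds, 3 MAD).
#' @param flatRadiusBound radius (um) beyond which the surface is treated as
#'   flat.
#' @return list with elements \code{type} ("arc" or "flat"); for arcs
#'   \code{cx}, \code{cz}, \code{radius} (signed: positive = centre posterior
#'   = anterior-convex); for flats \code{intercept}, \code{slope}; and
#'   \code{rms}, the RMS residual.
#' @examples
#' th <- seq(-0.3, 0.3, length.out = 25)
#' fitInterface(1500 * sin(th), 1700 - 1500 * cos(th))$radius
#' @export
fitInterface <- function(x, z, robust = TRUE, flatRadiusBound = 1e5) {
  stopifnot(length(x) == length(z))
  if (length(x) < 3) stop("at least 3 points are required to fit an interface")
  flatFit <- function(x, z) {
    lf <- stats::lm.fit(cbind(1, x), z)
    list(type = "flat", intercept = lf$coefficients[[1]],
         slope = lf$coefficients[[2]],
         rms = sqrt(mean(lf$residuals^2)))
  }
  # osculating-circle fallback from a quadratic fit: stable when the direct
  # algebraic circle fit degenerates on a shallow noisy arc
  quadFit <- function(x, z) {
    x0 <- mean(range(x))
    q <- stats::lm.fit(cbind(1, x - x0, (x - x0)^2), z)$coefficients
    if (abs(q[[3]]) < 1e-12) return(flatFit(x, z))
    zp <- q[[2]]
    r <- (1 + zp^2)^1.5 / (2 * q[[3]])     # signed radius (sign of curvature)
    if (abs(r) > flatRadiusBound) return(flatFit(x, z))
    nrm <- c(-zp, 1) / sqrt(1 + zp^2)       # toward the centre for r > 0
    ctr <- c(x0, q[[1]]) + r * nrm
    mod <- list(type = "arc", cx = ctr[1], cz = ctr[2], radius = r, rms = NA)
    mod$rms <- sqrt(mean((z - evalArc(mod, x))^2, na.rm = TRUE))
    mod
  }
  fit1 <- function(x, z) {
    span <- diff(range(x))
    A <- cbind(x, z, 1)
    b <- -(x^2 + z^2)
    sol <- tryCatch(qr.solve(A, b, tol = 1e-12), error = function(e) NULL)
    if (!is.null(sol)) {
      cx <- -unname(sol[1]) / 2; cz <- -unname(sol[2]) / 2
      r2 <- cx^2 + cz^2 - unname(sol[3])
      if (r2 > 0) {
        r <- sqrt(r2)
        if (r > flatRadiusBound) return(flatFit(x, z))
        # a real arc seen over lateral span L must have |R| >= L/2
        if (r >= 0.6 * span) {
          sgn <- if (cz >= stats::median(z)) 1 else -1
          res <- sqrt((x - cx)^2 + (z - cz)^2) - r
          return(list(type = "arc", cx = cx, cz = cz, radius = sgn * r,
                      rms = sqrt(mean(res^2))))
        }
      }
    }
    quadFit(x, z)
  }
  mod <- fit1(x, z)
  if (robust && length(x) >= 6) {
    n0 <- length(x)
    for (it in 1:3) {
      res <- z - evalArc(mod, x)
      md <- stats::mad(res, na.rm = TRUE)
      if (!is.finite(md) || md < 1e-9) break
      keep <- abs(res - stats::median(res, na.rm = TRUE)) <= 3 * md
      keep[!is.finite(res)] <- FALSE
      if (all(keep, na.rm = TRUE) || sum(keep) < max(5, 0.6 * n0)) break
      x <- x[keep]; z <- z[keep]
      mod <- fit1(x, z)
    }
  }
  mod
}

#' Evaluate an interface model at lateral positions
#'
#' @param model an arc/flat model from [fitInterface()].
#' @param x lateral positions, micrometres.
#' @return Axial positions z(x); NA beyond an arc's lateral support.
#' @examples
#' evalArc(list(type = "flat", intercept = 100, slope = 0), 0)
#' @export
evalArc <- function(model, x) {
  if (model$type == "flat") return(model$intercept + model$slope * x)
  d2 <- model$radius^2 - (x - model$cx)^2
  z <- rep(NA_real_, length(x))
  ok <- d2 >= 0
  z[ok] <- model$cz - sign(model$radius) * sqrt(d2[ok])
  z
}

# Unit surface normal of a model at points P (2-column matrix), oriented
# against incoming directions D (normal . d < 0).
.modelNormal <- function(model, P, D) {
  if (model$type == "flat") {
    n0 <- c(-model$slope, 1) / sqrt(1 + model$slope^2)
    N <- matrix(n0, nrow(P), 2, byrow = TRUE)
  } else {
    N <- cbind(P[, 1] - model$cx, P[, 2] - model$cz)
    N <- N / sqrt(rowSums(N^2))
  }
  flip <- rowSums(N * D) > 0
  flip[is.na(flip)] <- FALSE
  N[flip, ] <- -N[flip, ]
  N
}

# Vectorized Snell refraction; rows with TIR return NA.
.refractRows <- function(D, N, eta) {
  cosI <- -rowSums(D * N)
  sin2T <- eta^2 * (1 - cosI^2)
  bad <- sin2T > 1
  k <- eta * cosI - sqrt(pmax(1 - sin2T, 0))
  Dt <- eta * D + k * N
  Dt <- Dt / sqrt(rowSums(Dt^2))
  Dt[bad, ] <- NA_real_
  Dt
}

#' Correct optical distortion of segmented surfaces (Snell's principle)
#'
#' Converts a [SurfaceSet-class] from optical-path image coordinates to
#' geometric coordinates by per-A-scan ray tracing through the fitted
#' interface arcs with the tissue refractive index stack (cornea 1.40,
#' aqueous 1.33, lens 1.57, vitreous 1.33 by default). On the AP axis each
#' corrected thickness equals the optical thickness divided by the layer's
#' index exactly (normal incidence). Points that hit total internal
#' reflection, or whose shallower surfaces are missing, are excluded and
#' reported, and the correction continues.
#'
#' @param surfaces a [SurfaceSet-class].
#' @param optics a [TissueOptics-class] supplying the index stack.
#' @return A [CorrectedSurfaceSet-class].
#' @examples
#' b <- renderBScan(mouseEye(), tissueOptics())
#' cs <- dewarp(detectSurfaces(b), tissueOptics())
#' cs
#' @export
dewarp <- function(surfaces, optics) {
  stopifnot(is(surfaces, "SurfaceSet"))
  validObject(optics)
  tr <- surfaceTraces(surfaces)
  if (!any(tr$label == "cornea_anterior"))
    stop("cannot correct without the corneal anterior surface")
  nI <- refractiveIndices(optics)
  media <- c(1, unname(nI[c("cornea", "aqueous", "lens", "vitreous")]))
  xs <- sort(unique(tr$x))
  nX <- length(xs)
  zOpt <- sapply(.AXIAL_SURFACES, function(l) {
    s <- tr[tr$label == l, ]
    s$z[match(xs, s$x)]
  })
  zIris <- sapply(.IRIS_SURFACES, function(l) {
    s <- tr[tr$label == l, ]
    s$z[match(xs, s$x)]
  })

  out <- list()
  excl <- list()
  arcs <- list()
  note <- function(lab, x, reason)
    data.frame(label = lab, x = x, reason = reason)

  # stage 1: corneal anterior is geometric already (air, n = 1)
  alive <- !is.na(zOpt[, 1])
  P <- cbind(xs, zOpt[, 1])
  D <- matrix(rep(c(0, 1), each = nX), nX, 2)
  out[["cornea_anterior"]] <- data.frame(label = "cornea_anterior",
                                         x = xs[alive], z = P[alive, 2])
  arcs[["cornea_anterior"]] <- fitInterface(xs[alive], P[alive, 2])

  refractAt <- function(model, P, D, eta, alive) {
    N <- .modelNormal(model, P, D)
    D2 <- .refractRows(D, N, eta)
    tir <- alive & is.na(D2[, 1])
    list(D = D2, tir = tir)
  }

  st <- refractAt(arcs[["cornea_anterior"]], P, D, media[1] / media[2], alive)
  D <- st$D
  irisDone <- FALSE

  for (k in 2:5) {
    lab <- .AXIAL_SURFACES[k]
    dOpt <- zOpt[, k] - zOpt[, k - 1]
    ok <- alive & !is.na(dOpt) & !is.na(D[, 1])
    if (any(alive & !is.na(zOpt[, k]) & !ok))
      excl[[length(excl) + 1]] <-
        note(lab, xs[alive & !is.na(zOpt[, k]) & !ok],
             "shallower surface missing or ray lost")
    Pk <- P + D * (dOpt / media[k])
    newAlive <- ok
    if (sum(newAlive) >= 3) {
      out[[lab]] <- data.frame(label = lab, x = Pk[newAlive, 1],
                               z = Pk[newAlive, 2])
      arcs[[lab]] <- fitInterface(Pk[newAlive, 1], Pk[newAlive, 2])
    }
    # iris: corrected through cornea only, lives in the aqueous like the
    # anterior lens surface
    if (k == 3 && !irisDone) {
      for (il in .IRIS_SURFACES) {
        dI <- zIris[, il] - zOpt[, 2]
        okI <- alive & !is.na(dI) & !is.na(D[, 1])
        if (sum(okI) >= 3) {
          Pi <- P + D * (dI / media[3])
          out[[il]] <- data.frame(label = il, x = Pi[okI, 1], z = Pi[okI, 2])
        }
      }
      irisDone <- TRUE
    }
    if (k < 5) {
      if (is.null(arcs[[lab]])) { alive <- rep(FALSE, nX); next }
      P <- Pk
      st <- refractAt(arcs[[lab]], P, D, media[k] / media[k + 1], newAlive)
      if (any(st$tir)) {
        excl[[length(excl) + 1]] <-
          note(lab, xs[st$tir], "total internal reflection")
        newAlive <- newAlive & !st$tir
      }
      D <- st$D
      alive <- newAlive
    }
  }

  traces <- do.call(rbind, out)
  rownames(traces) <- NULL
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(label = character(), x = numeric(), reason = character())
  new("CorrectedSurfaceSet", traces = traces, arcs = arcs,
      indices = nI, apAxis = surfaces@apAxis, excluded = excluded,
      axialPitch = surfaces@axialPitch)
}

#' Axial refraction correction at normal incidence
#'
#' On the AP axis the probing ray is undeviated, so the geometric thickness of
#' a layer is simply its optical thickness divided by the layer's refractive
#' index.
#'
#' @param opticalThickness optical-path thickness, micrometres (>= 0).
#' @param n refractive index (>= 1).
#' @return Geometric thickness, micrometres.
#' @examples
#' axialCorrect(166.6, 1.40)  # 119 um
#' @export
axialCorrect <- function(opticalThickness, n) {
  if (any(n < 1)) stop("refractive index must be >= 1")
  if (any(opticalThickness < 0)) stop("optical thickness must be >= 0")
  opticalThickness / n
}
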