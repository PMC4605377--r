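# Forward model: ray-traced synthetic OCT B-scans of a schematic eye.
#
# Each image column is one A-scan: a probing ray entering vertically from
# the top. The ray is traced anterior -> posterior; at every curved interface
# Snell's law is applied using the local arc normal, and the optical path
# (sum of refractive index x geometric segment) accumulates. Each layer's
# backscatter is deposited in the launch column between the optical-path
# depths of its interface crossings, which is exactly the distortion a real
# OCT system exhibits.

# Refract unit direction d at unit normal nrm (oriented against d),
# eta = n1/n2. Returns NULL on total internal reflection.
.snell2d <- function(d, nrm, eta) {
  cosI <- -sum(d * nrm)
  sin2T <- eta^2 * (1 - cosI^2)
  if (sin2T > 1) return(NULL)
  dt <- eta * d + (eta * cosI - sqrt(1 - sin2T)) * nrm
  dt / sqrt(sum(dt^2))
}

# First crossing of ray (p, d) with the arc (apex, signed radius) centred on
# the instrument axis. Returns list(point, normal, dist) or NULL.
.rayArc <- function(p, d, apex, radius) {
  if (!is.finite(radius)) {                    # flat surface z = apex
    if (abs(d[2]) < 1e-12) return(NULL)
    t1 <- (apex - p[2]) / d[2]
    if (t1 <= 1e-9) return(NULL)
    q <- p + t1 * d
    nrm <- c(0, -sign(d[2]))
    return(list(point = q, normal = nrm, dist = t1))
  }
  ctr <- c(0, apex + radius)
  r <- abs(radius)
  oc <- p - ctr
  b <- sum(oc * d)
  cc <- sum(oc * oc) - r^2
  disc <- b^2 - cc
  if (disc < 0) return(NULL)
  sq <- sqrt(disc)
  roots <- c(-b - sq, -b + sq)
  roots <- roots[roots > 1e-9]
  if (!length(roots)) return(NULL)
  t1 <- min(roots)
  q <- p + t1 * d
  nrm <- (q - ctr) / r
  if (sum(nrm * d) > 0) nrm <- -nrm
  list(point = q, normal = nrm, dist = t1)
}

# Average a piecewise-constant depth profile into pixels (exact partial
# volumes). bounds: ascending boundary depths (um); values: length(bounds)+1
# segment intensities (before first boundary, between, after last).
.rasterizeColumn <- function(bounds, values, n, pitch) {
  keep <- is.finite(bounds)
  bounds <- bounds[keep]
  values <- values[c(TRUE, keep)]
  if (is.unsorted(bounds))
    stop("interface depths are not monotone along an A-scan; ",
         "the geometry is inconsistent (overlapping structures)")
  k <- c(0, pmax(bounds, 0))
  cf <- c(0, cumsum(values[seq_along(bounds)] * diff(c(k, Inf))[seq_along(bounds)]))
  FF <- function(z) {
    j <- findInterval(z, k)
    cf[j] + values[j] * (z - k[j])
  }
  e <- (0:n) * pitch
  diff(FF(e)) / pitch
}

# Trace one A-scan through the axial interface stack. Returns the optical-path
# depth of every crossed interface plus the ray state after each, or NULL
# entries where tracing stopped.
.traceAxial <- function(x, surf, nMedia, nSurf = nrow(surf)) {
  p <- c(x, 0); d <- c(0, 1); opl <- 0
  depths <- rep(NA_real_, nSurf)
  pts <- vector("list", nSurf)
  dirs <- vector("list", nSurf)
  for (k in seq_len(nSurf)) {
    hit <- .rayArc(p, d, surf$apex[k], surf$radius[k])
    if (is.null(hit)) break
    opl <- opl + nMedia[k] * hit$dist
    depths[k] <- opl
    p <- hit$point
    if (k + 1 <= length(nMedia)) {
      d2 <- .snell2d(d, hit$normal, nMedia[k] / nMedia[k + 1])
      if (is.null(d2)) break
      d <- d2
    }
    pts[[k]] <- p; dirs[[k]] <- d
  }
  list(depths = depths, pts = pts, dirs = dirs, p = p, d = d, opl = opl)
}

#' Render a synthetic OCT B-scan
#'
#' Forward-models a [BScanImage-class] from a ground-truth geometry and
#' optics: per A-scan Snell's-law ray tracing through the circular-arc
#' interfaces, optical-path accumulation, anti-aliased deposition of layer
#' backscatter, an opacified anterior lens region, the iris band with its
#' shadow, and optional seeded noise (multiplicative gamma speckle of unit
#' mean plus an additive Gaussian floor). With \code{noiseSeed = NULL} the
#' output is deterministic and on the AP axis every interface lies at
#' optical-path depth \eqn{\sum n_i t_i} exactly (to pixel quantization).
#'
#' @param geometry an [EyeGeometry-class].
#' @param optics a [TissueOptics-class].
#' @param axialPitch,lateralPitch pixel pitches, micrometres (optical path /
#'   lateral); defaults scale with the eye (3/10 for mouse-sized eyes,
#'   12/40 for the model eye).
#' @param nAxial,nLateral image size; defaults fit the full eye plus margins.
#'   An image too shallow to contain the retinal surface is an error
#'   (truncation), not silent clipping.
#' @param noiseSeed integer seed for the noise draw, or \code{NULL} for a
#'   noiseless image.
#' @param speckleLooks shape of the gamma speckle (number of incoherently
#'   averaged looks; larger = lower contrast; contrast = 1/sqrt(looks)).
#' @param additiveSd standard deviation of the additive noise floor.
#' @param timestamp,phase frame metadata.
#' @return A [BScanImage-class].
#' @examples
#' b <- renderBScan(mouseEye(), tissueOptics())
#' b
#' @export
renderBScan <- function(geometry, optics,
                        axialPitch = NULL, lateralPitch = NULL,
                        nAxial = NULL, nLateral = NULL,
                        noiseSeed = NULL, speckleLooks = 4, additiveSd = 1,
                        timestamp = 0, phase = "baseline") {
  validObject(geometry); validObject(optics)
  s <- geometry@surfaces
  depthSpan <- s$apex[5] - s$apex[1]
  big <- depthSpan > 6000
  if (is.null(axialPitch)) axialPitch <- if (big) 12 else 3
  if (is.null(lateralPitch)) lateralPitch <- if (big) 40 else 10
  if (is.null(nLateral))
    nLateral <- 2 * floor(geometry@lateralExtent / lateralPitch) + 1
  nI <- refractiveIndices(optics)
  nMedia <- c(1, nI["cornea"], nI["aqueous"], nI["lens"], nI["vitreous"])
  oplIlmAxis <- s$apex[1] +
    sum(diff(s$apex) * nMedia[2:5])
  if (is.null(nAxial))
    nAxial <- ceiling((oplIlmAxis + 200) / axialPitch)
  if (oplIlmAxis > nAxial * axialPitch)
    stop("image too shallow: retinal surface at optical depth ",
         round(oplIlmAxis), " um exceeds image depth ",
         nAxial * axialPitch, " um (truncation)")
  ii <- optics@intensities
  mult <- optics@lensOpacityMultiplier
  front <- optics@opacityFrontDepth
  xs <- (seq_len(nLateral) - (nLateral + 1) / 2) * lateralPitch
  img <- matrix(ii["background"], nAxial, nLateral)
  bottom <- nAxial * axialPitch

  irR <- irisTrace(geometry, "right", n = 201)
  irisZ <- stats::approxfun(irR[, "x"], irR[, "z"], rule = 2)
  thick <- geometry@irisThickness
  pr <- geometry@pupilRadius
  rootX <- geometry@irisRootX

  crossCurve <- function(p, d, fz) {
    # first crossing of ray with curve z = fz(|x|); robust bisection
    g <- function(t) { q <- p + t * d; q[2] - fz(abs(q[1])) }
    tmax <- (bottom - p[2]) / d[2]
    if (g(0) >= 0 || g(tmax) <= 0) return(NULL)
    stats::uniroot(g, c(0, tmax), tol = 1e-6)$root
  }

  for (j in seq_len(nLateral)) {
    x <- xs[j]
    ax <- abs(x)
    if (ax < pr) {                         # pupil: full axial stack
      tr <- .traceAxial(x, s, nMedia)
      dp <- tr$depths
      if (!anyNA(dp)) {
        frontZ <- dp[3] + front * (dp[4] - dp[3])
        bounds <- c(dp[1], dp[2], dp[3], frontZ, dp[4], dp[5])
        vals <- c(ii["background"], ii["cornea"], ii["aqueous"],
                  ii["lens"] * mult, ii["lens"], ii["vitreous"], ii["retina"])
      } else {
        k <- which(is.na(dp))[1] - 1
        bounds <- dp[seq_len(k)]
        vals <- c(ii["background"], ii["cornea"], ii["aqueous"],
                  ii["lens"], ii["vitreous"])[seq_len(k + 1)]
        vals[k + 1] <- ii["shadow"]
      }
    } else {                               # iris or limbus column
      tr <- .traceAxial(x, s, nMedia, nSurf = 2)
      dp <- tr$depths[1:2]
      if (anyNA(dp)) { next }              # outside corneal support
      # the refracted ray decides whether this A-scan meets the iris band:
      # membership is judged where the ray meets the pigment epithelium
      p <- tr$p; d <- tr$d
      t2 <- crossCurve(p, d, irisZ)
      q <- if (!is.null(t2)) p + t2 * d else NULL
      onIris <- !is.null(q) && abs(q[1]) <= rootX + 1e-6 &&
        abs(q[1]) >= pr - 1e-6
      if (onIris) {
        t1 <- crossCurve(p, d, function(a) irisZ(a) - thick)
        oplIpe <- tr$opl + nI["aqueous"] * t2
        oplTop <- if (is.null(t1)) oplIpe - thick * nI["aqueous"]
                  else tr$opl + nI["aqueous"] * t1
        bounds <- c(dp, oplTop, oplIpe)
        vals <- c(ii["background"], ii["cornea"], ii["aqueous"],
                  ii["iris"], ii["shadow"])
      } else {
        bounds <- dp
        vals <- c(ii["background"], ii["cornea"], ii["shadow"])
      }
    }
    img[, j] <- .rasterizeColumn(bounds, vals, nAxial, axialPitch)
  }

  if (!is.null(noiseSeed)) {
    img <- .withSeed(noiseSeed, {
      n <- length(img)
      sp <- matrix(stats::rgamma(n, shape = speckleLooks,
                                 rate = speckleLooks), nAxial, nLateral)
      pmax(img * sp + matrix(stats::rnorm(n, sd = additiveSd),
                             nAxial, nLateral), 0)
    })
  }
  new("BScanImage", image = img, axialPitch = axialPitch,
      lateralPitch = lateralPitch, timestamp = timestamp, phase = phase)
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render a full osmotic-challenge time series
#'
#' Renders one B-scan per scheduled frame (baseline repeats at t = 0, then
#' each phase at its imaging frequency) of the eye state given by
#' [eyeAtTime()], together with the ground-truth biometry table. All
#' randomness derives from the single \code{seed} (per-frame noise seeds are
#' drawn from it), so a fixed seed reproduces the image stack bitwise.
#'
#' @param scenario an [OsmoticScenario-class].
#' @param geometry baseline [EyeGeometry-class]; default chosen by the
#'   scenario's \code{geometry} field ([mouseEye()] or [modelEye()]).
#' @param optics baseline [TissueOptics-class].
#' @param seed master seed for the noise draws.
#' @param noise logical; \code{FALSE} renders noiseless frames.
#' @param ... further arguments to [renderBScan()] (pitches, sizes, noise
#'   model parameters).
#' @return \code{list(frames = <list of BScanImage>, truth = <data.frame>)}
#'   where \code{truth} has one row per frame (frame, time, phase, cct, acd,
#'   lt, crd, lsi, ic).
#' @examples
#' ts <- renderTimeSeries(scenarioControl(), seed = 1, noise = FALSE)
#' length(ts$frames)
#' @export
renderTimeSeries <- function(scenario, geometry = NULL,
                             optics = tissueOptics(), seed = 1,
                             noise = TRUE, ...) {
  validObject(scenario)
  if (is.null(geometry))
    geometry <- if (scenario@geometry == "model_eye") modelEye() else mouseEye()
  sched <- frameSchedule(scenario)
  nF <- nrow(sched)
  frameSeeds <- .withSeed(seed, sample.int(.Machine$integer.max - 1, nF))
  frames <- vector("list", nF)
  truth <- vector("list", nF)
  for (i in seq_len(nF)) {
    st <- eyeAtTime(scenario, geometry, optics, sched$time[i])
    frames[[i]] <- renderBScan(st$geometry, st$optics,
                               noiseSeed = if (noise) frameSeeds[i] else NULL,
                               timestamp = sched$time[i],
                               phase = sched$phase[i], ...)
    truth[[i]] <- cbind(sched[i, , drop = FALSE],
                        trueBiometry(st$geometry, st$optics))
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(frames = frames, truth = truth)
}
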