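# Semiautomatic surface segmentation in optical-path image coordinates.
#
# Per A-scan column: box smoothing, tissue runs above an Otsu-derived
# intensity threshold, ordered anatomical assignment of the runs (optionally
# constrained by user seed points), sub-pixel boundary refinement by the
# centroid of the axial gradient, then robust per-surface arc fitting with
# outlier rejection at 3 median absolute deviations.

# Separable box smoothing with edge replication.
.boxSmooth <- function(m, axial = 7, lateral = 7) {
  pad <- function(v, w) c(rep(v[1], w), v, rep(v[length(v)], w))
  smooth1 <- function(v, w) {
    if (w <= 1) return(v)
    h <- (w - 1) / 2
    f <- stats::filter(pad(v, h), rep(1 / w, w), sides = 2)
    as.numeric(f[(h + 1):(h + length(v))])
  }
  m <- apply(m, 2, smooth1, w = axial)
  t(apply(m, 1, smooth1, w = lateral))
}

# Signed axial gradient with lag 6 (sm[i+3] - sm[i-3]), centred at row i;
# the lag matches the smoothing width so nearly the full step height is seen.
.axialGradient <- function(sm) {
  n <- nrow(sm)
  g <- matrix(0, n, ncol(sm))
  g[4:(n - 3), ] <- sm[7:n, ] - sm[1:(n - 6), ]
  g
}

# Tissue runs of one smoothed column: contiguous stretches above the
# intensity threshold, after suppressing runs shorter than minRun (speckle
# flips). Returns data.frame(start, end, meanI).
.columnRuns <- function(colSm, thrI, minRun = 5) {
  above <- colSm > thrI
  for (pass in 1:2) {                   # absorb short flips both ways
    r <- rle(above)
    short <- r$lengths < minRun
    if (!any(short)) break
    r$values[short] <- !r$values[short]
    above <- inverse.rle(r)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) return(NULL)
  data.frame(start = starts[keep], end = ends[keep],
             meanI = vapply(which(keep), function(i)
               mean(colSm[starts[i]:ends[i]]), numeric(1)))
}

# Refine an approximate boundary row to sub-pixel: strongest gradient peak of
# the required sign within +/- win rows, localized by the centroid of |g|
# over its contiguous support above 0.3 x peak height.
.refineEdge <- function(g, row0, sgn, win = 10) {
  n <- length(g)
  lo <- max(4, round(row0) - win); hi <- min(n - 3, round(row0) + win)
  if (hi <= lo) return(row0)
  seg <- g[lo:hi] * sgn
  i <- which.max(seg)
  if (seg[i] <= 0) return(row0)
  i <- lo + i - 1
  a <- abs(g)
  l <- i; h <- i; cut <- 0.3 * a[i]
  while (l > 1 && a[l - 1] >= cut && a[l - 1] <= a[l]) l <- l - 1
  while (h < n && a[h + 1] >= cut && a[h + 1] <= a[h]) h <- h + 1
  w <- a[l:h]
  sum((l:h) * w) / sum(w)
}

# Assign the tissue runs of one column to anatomical labels and refine each
# boundary on the gradient. The first run is the cornea; a deeper run whose
# mean intensity exceeds irisCut is the iris body (its posterior edge is the
# pigment epithelium and everything below is shadowed); otherwise the first
# deep run is the lens (the opacification front never crosses the
# tissue/background threshold, so the lens is one run) and the last run is
# the retina, whose anterior edge is the ILM.
.assignRuns <- function(runs, colSm, g, irisCut) {
  out <- c()
  if (is.null(runs) || !nrow(runs)) return(out)
  out["cornea_anterior"] <- .refineEdge(g, runs$start[1], +1)
  out["cornea_posterior"] <- .refineEdge(g, runs$end[1], -1)
  deep <- runs[-1, , drop = FALSE]
  if (!nrow(deep)) return(out)
  if (any(deep$meanI > irisCut)) {       # iris column
    i <- which(deep$meanI > irisCut)[1]
    out["iris_top"] <- .refineEdge(g, deep$start[i], +1)
    out["iris_ipe"] <- .refineEdge(g, deep$end[i], -1)
  } else {                               # pupil column: lens, then retina
    out["lens_anterior"] <- .refineEdge(g, deep$start[1], +1)
    out["lens_posterior"] <- .refineEdge(g, deep$end[1], -1)
    if (nrow(deep) >= 2)
      out["ilm"] <- .refineEdge(g, deep$start[nrow(deep)], +1)
  }
  out
}

# Robust outlier rejection on a trace: residuals to a robust arc fit beyond
# 3 MAD are dropped. The floor keeps sub-pixel systematic deviations (e.g.
# steep peripheral columns on noiseless images, where the MAD itself is
# almost zero) from being treated as outliers. Returns logical keep vector.
.traceInliers <- function(x, z, nmad = 3, floor = 0) {
  if (length(x) < 5) return(rep(TRUE, length(x)))
  fit <- fitInterface(x, z, robust = TRUE)
  res <- z - evalArc(fit, x)
  md <- stats::mad(res, na.rm = TRUE)
  if (!is.finite(md) || md < 1e-9) md <- 1e-9
  ok <- abs(res - stats::median(res, na.rm = TRUE)) <= max(nmad * md, floor)
  ok & is.finite(res)  # points beyond the model's lateral support go too
}

#' Detect ocular surfaces in a B-scan
#'
#' Semiautomatic segmentation of the six boundary labels (anterior/posterior
#' cornea, anterior/posterior lens, retinal inner limiting membrane, and the
#' iris pigment epithelium per wing) in optical-path image coordinates.
#' Per A-scan column the smoothed intensity profile is split into tissue
#' runs above an Otsu-derived background threshold; the run sequence is read
#' anatomically (cornea first; a deep high-intensity run is the iris body,
#' otherwise lens then retina), and every boundary is refined to sub-pixel
#' precision on the axial gradient. Optional seed points constrain the
#' assignment (the gradient peak nearest the seeded depth wins). Surfaces
#' that cannot be detected are reported in the failure slot, never silently
#' omitted, and anatomical ordering is enforced on the output.
#'
#' @param image a [BScanImage-class].
#' @param seeds optional data.frame of per-surface hints with columns
#'   \code{label}, \code{x} (um), \code{z} (um, optical path).
#' @param required surface labels whose absence constitutes a failure.
#' @param thresholdScale scale applied to the Otsu tissue/background
#'   intensity threshold.
#' @return A [SurfaceSet-class] (coordinates in micrometres: lateral x with 0
#'   at the image centre, axial z = optical-path depth).
#' @examples
#' b <- renderBScan(mouseEye(), tissueOptics())
#' detectSurfaces(b)
#' @export
detectSurfaces <- function(image, seeds = NULL,
                           required = c(.AXIAL_SURFACES, "iris_ipe"),
                           thresholdScale = 1) {
  stopifnot(is(image, "BScanImage"))
  im <- imageData(image)
  if (any(im < 0)) stop("image intensities must be >= 0")
  ap <- axialPitch(image); lp <- lateralPitch(image)
  nL <- ncol(im)
  xs <- (seq_len(nL) - (nL + 1) / 2) * lp
  sm <- .boxSmooth(im, axial = 7, lateral = 3)
  g <- .axialGradient(sm)
  mx <- max(sm)
  if (mx <= 0 || max(abs(g)) <= 0)
    stop("no detectable structure in image (flat intensity)")
  thrI <- thresholdScale * EBImage::otsu(sm / mx, range = c(0, 1)) * mx

  allRuns <- lapply(seq_len(nL), function(j) .columnRuns(sm[, j], thrI))
  corneaI <- stats::median(unlist(lapply(allRuns, function(r)
    if (!is.null(r)) r$meanI[1])), na.rm = TRUE)
  irisCut <- 1.3 * corneaI   # iris backscatter well above any other layer

  seedFun <- NULL
  if (!is.null(seeds) && nrow(seeds)) {
    stopifnot(all(c("label", "x", "z") %in% names(seeds)))
    seedFun <- lapply(split(seeds, seeds$label), function(s) {
      if (nrow(s) == 1) function(x) rep(s$z, length(x))
      else stats::approxfun(s$x, s$z, rule = 2)
    })
  }

  rows <- list()
  for (j in seq_len(nL)) {
    lab <- .assignRuns(allRuns[[j]], sm[, j], g[, j], irisCut)
    if (!is.null(seedFun)) {
      for (sl in names(seedFun)) {
        zSeed <- seedFun[[sl]](xs[j]) / ap
        sgn <- if (sl %in% c("cornea_posterior", "lens_posterior",
                             "iris_ipe")) -1 else 1
        lab[sl] <- .refineEdge(g[, j], zSeed, sgn, win = 15)
      }
    }
    if (!length(lab)) next
    wing <- if (xs[j] < 0) "left" else "right"
    nm <- names(lab)
    nm[nm == "iris_ipe"] <- paste0("iris_ipe_", wing)
    nm[nm == "iris_top"] <- NA  # internal helper label, not reported
    keep <- !is.na(nm)
    if (!any(keep)) next
    rows[[j]] <- data.frame(label = nm[keep], x = xs[j],
                            z = (lab[keep] - 0.5) * ap)
  }
  tr <- do.call(rbind, rows)
  if (is.null(tr)) tr <- data.frame(label = character(), x = numeric(),
                                    z = numeric())
  rownames(tr) <- NULL

  # robust per-surface outlier rejection (3 MAD about an arc fit)
  tr <- do.call(rbind, lapply(split(tr, tr$label), function(s) {
    if (nrow(s) >= 5) s[.traceInliers(s$x, s$z, floor = 0.75 * ap), ] else s
  }))
  if (is.null(tr)) tr <- data.frame(label = character(), x = numeric(),
                                    z = numeric())
  rownames(tr) <- NULL

  # enforce anatomical order per column: drop columns that violate it
  ax <- tr$label %in% .AXIAL_SURFACES
  if (any(ax)) {
    ord <- match(tr$label, .AXIAL_SURFACES)
    badCols <- unique(unlist(lapply(split(which(ax), tr$x[ax]), function(i) {
      if (is.unsorted(tr$z[i][order(ord[i])], strictly = TRUE)) tr$x[i][1]
    })))
    if (length(badCols)) tr <- tr[!(ax & tr$x %in% badCols), ]
  }

  counts <- table(factor(tr$label, levels = .ALL_SURFACES))
  failures <- character()
  for (r in required) {
    present <- if (r == "iris_ipe") sum(counts[.IRIS_SURFACES]) else counts[r]
    if (is.na(present) || present < 3) failures <- c(failures, r)
  }

  vx <- .vertexFromTrace(tr)
  new("SurfaceSet", traces = tr, apAxis = vx$apAxis, vertex = vx$vertex,
      failures = failures, axialPitch = ap)
}

# Vertex of the corneal anterior trace; ties broken at the lateral midpoint.
.vertexFromTrace <- function(tr) {
  ca <- tr[tr$label == "cornea_anterior", ]
  if (nrow(ca) < 1)
    return(list(apAxis = NA_real_, vertex = c(NA_real_, NA_real_)))
  ca <- ca[order(ca$x), ]
  zs <- if (nrow(ca) >= 9) stats::runmed(ca$z, 9) else ca$z
  zmin <- min(zs)
  tied <- which(zs <= zmin + 1e-6)
  i <- tied[ceiling(length(tied) / 2)]
  list(apAxis = ca$x[i], vertex = c(ca$x[i], ca$z[i]))
}

#' Locate the corneal vertex and AP axis
#'
#' The vertex is the minimal-axial-depth point of the corneal anterior trace;
#' the anteroposterior (AP) axis is the vertical line through it. Ties (a
#' flat or tilted-flat cornea) are broken at the lateral midpoint of the tied
#' set.
#'
#' @param surfaces a [SurfaceSet-class].
#' @return \code{list(apAxis = <x um>, vertex = c(x, z))}.
#' @examples
#' b <- renderBScan(mouseEye(), tissueOptics())
#' locateVertex(detectSurfaces(b))
#' @export
locateVertex <- function(surfaces) {
  stopifnot(is(surfaces, "SurfaceSet"))
  tr <- surfaceTraces(surfaces)
  if (!any(tr$label == "cornea_anterior"))
    stop("corneal anterior trace not present")
  .vertexFromTrace(tr)
}

#' Select the meridian slice containing the corneal vertex
#'
#' From a stack of B-scans (e.g. a thin 3D raster), returns the slice whose
#' corneal anterior apex is shallowest, i.e. the slice through the corneal
#' vertex; ties go to the lowest slice index.
#'
#' @param volume list of [BScanImage-class] objects.
#' @return The selected [BScanImage-class] (attribute \code{"slice"} holds
#'   its index).
#' @examples
#' b <- renderBScan(mouseEye(), tissueOptics())
#' selectMeridianSlice(list(b, b))
#' @export
selectMeridianSlice <- function(volume) {
  stopifnot(is.list(volume), length(volume) >= 1)
  depths <- vapply(volume, function(b) {
    stopifnot(is(b, "BScanImage"))
    sm <- .boxSmooth(imageData(b), axial = 7, lateral = 3)
    mx <- max(sm)
    if (mx <= 0) return(NA_real_)
    thrI <- EBImage::otsu(sm / mx, range = c(0, 1)) * mx
    apex <- Inf
    for (j in seq_len(ncol(sm))) {
      r <- .columnRuns(sm[, j], thrI)
      if (!is.null(r)) apex <- min(apex, r$start[1])
    }
    if (is.finite(apex)) apex * axialPitch(b) else NA_real_
  }, numeric(1))
  if (all(is.na(depths)))
    stop("no detectable cornea in any slice")
  i <- which.min(depths)
  out <- volume[[i]]
  attr(out, "slice") <- i
  out
}
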