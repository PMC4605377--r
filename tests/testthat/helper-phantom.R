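# Shared fixtures built in code: default eyes/optics and an independent
# interface-depth oracle used to check rendered images without going through
# the package's own segmentation.

defaultOptics <- function() tissueOptics()

# Independent oracle: expected optical-path depth of each axial interface on
# the AP axis, from the geometry and index stack alone (sum of n_i * t_i).
axisInterfaceOPL <- function(geometry, optics = defaultOptics()) {
  s <- eyeSurfaces(geometry)
  n <- refractiveIndices(optics)
  unname(cumsum(c(s$apex[1], diff(s$apex) * n[c("cornea", "aqueous", "lens",
                                                "vitreous")])))
}

# Independent oracle: interface depths in one image column found by scanning
# the raw intensity profile for level transitions (no package code).
columnTransitions <- function(column, pitch, minJump = 1) {
  d <- which(abs(diff(column)) > minJump)
  # merge adjacent rows belonging to one partial-volume transition
  grp <- cumsum(c(1, diff(d) > 2))
  vapply(split(d, grp), function(i) mean(i) * pitch, numeric(1))
}

# Laterally translate a B-scan by k columns, padding with the background
# level, to probe equivariance.
shiftBScan <- function(b, k) {
  im <- imageData(b)
  bg <- min(im)
  n <- ncol(im)
  if (k > 0) im2 <- cbind(matrix(bg, nrow(im), k), im[, 1:(n - k)])
  else im2 <- cbind(im[, (1 - k):n], matrix(bg, nrow(im), -k))
  new("BScanImage", image = im2, axialPitch = axialPitch(b),
      lateralPitch = lateralPitch(b), timestamp = frameTime(b),
      phase = framePhase(b))
}

# Full measurement chain on one frame; returns the axial parameters.
measureFrame <- function(b, optics = defaultOptics()) {
  measureAxial(dewarp(detectSurfaces(b), optics))
}

# A tiny two-phase scenario for fast pipeline tests.
tinyScenario <- function() {
  osmoticScenario(
    "tiny",
    data.frame(label = c("isotonic", "hypertonic"),
               osmolality = c(250, 1000),
               duration = c(5, 10), framesPerMin = c(0.4, 0.4)),
    rbind(c(cct = 0, acd = 0, lt = 0, crd = 0, lsi = 0, iris_sag = 0),
          c(cct = -0.1, acd = -0.05, lt = 0, crd = -0.01, lsi = 0.1,
            iris_sag = 0)),
    tau = c(1, 2), baselineRepeats = 2)
}
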