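# Biometry: the six parameters from corrected surfaces and raw images.

test_that("model-eye phantom returns the manufacturer dimensions", {
  o <- defaultOptics()
  b <- renderBScan(modelEye(), o)
  ax <- measureFrame(b, o)
  p <- axialPitch(b)
  expect_equal(ax[["cct"]] / 1000, 0.55, tolerance = 2 * p / 550)
  expect_equal(ax[["acd"]] / 1000, 3.03, tolerance = 3 * p / 3030)
  expect_equal(ax[["lt"]] / 1000, 3.9, tolerance = 4 * p / 3900)
})

test_that("mouse baseline phantom returns the baseline biometry", {
  o <- defaultOptics()
  b <- renderBScan(mouseEye(), o)
  ax <- measureFrame(b, o)
  expect_equal(ax[["cct"]], 119, tolerance = 6 / 119)
  expect_equal(ax[["acd"]], 404, tolerance = 9 / 404)
  expect_equal(ax[["lt"]], 1860, tolerance = 12 / 1860)
  expect_equal(ax[["crd"]], 3080, tolerance = 15 / 3080)
  expect_gt(ax[["crd"]], ax[["acd"]] + ax[["lt"]])  # positive vitreous depth
})

test_that("degenerate zero-thickness layers are a validation error", {
  xs <- seq(-300, 300, by = 30)
  tr <- rbind(data.frame(label = "cornea_anterior", x = xs, z = 100),
              data.frame(label = "cornea_posterior", x = xs, z = 220),
              data.frame(label = "lens_anterior", x = xs, z = 600),
              data.frame(label = "lens_posterior", x = xs, z = 600),
              data.frame(label = "ilm", x = xs, z = 3000))
  cs <- new("CorrectedSurfaceSet", traces = tr, arcs = list(),
            indices = refractiveIndices(defaultOptics()), apAxis = 0,
            excluded = data.frame(label = character(), x = numeric(),
                                  reason = character()),
            axialPitch = 3)
  expect_error(measureAxial(cs), "degenerate")
})

test_that("LSI: constant field, linearity, and window preconditions", {
  g <- mouseEye(); o <- defaultOptics()
  b <- renderBScan(g, o)
  s <- detectSurfaces(b)
  # uniform clear lens: LSI equals the lens backscatter level for any window
  expect_equal(measureLSI(b, s, region = 0.15), 25, tolerance = 0.02)
  expect_equal(measureLSI(b, s, region = 0.5), 25, tolerance = 0.02)
  # doubling the image doubles LSI
  b2 <- new("BScanImage", image = 2 * imageData(b), axialPitch = axialPitch(b),
            lateralPitch = lateralPitch(b), timestamp = 0, phase = "t")
  expect_equal(measureLSI(b2, s), 2 * measureLSI(b, s), tolerance = 1e-9)
  expect_error(measureLSI(b, s, region = 0), "region")
  expect_error(measureLSI(b, s, region = 1.2), "region")
})

test_that("opacified lens raises LSI by the scenario's calibrated ratio", {
  g <- mouseEye(); o <- defaultOptics()
  base <- measureLSI(renderBScan(g, o), detectSurfaces(renderBScan(g, o)))
  st <- eyeAtTime(scenarioGroupI(), g, o, 23)   # end of hypertonic phase
  bH <- renderBScan(st$geometry, st$optics)
  lsiH <- measureLSI(bH, detectSurfaces(bH))
  target <- 1 + 0.288 * (1 - exp(-13 / 2.5))
  expect_equal(lsiH / base, target, tolerance = 0.01)
  expect_equal(lsiH / base, 1.288, tolerance = 0.015)
})

test_that("IC geometry oracles: flat iris, semicircle, antisymmetry", {
  mkCS <- function(tr) new("CorrectedSurfaceSet", traces = tr, arcs = list(),
                           indices = refractiveIndices(defaultOptics()),
                           apAxis = 0,
                           excluded = data.frame(label = character(),
                                                 x = numeric(),
                                                 reason = character()),
                           axialPitch = 3)
  # perfectly flat iris
  flat <- mkCS(data.frame(label = "iris_ipe_right",
                          x = seq(500, 1100, by = 10), z = 900))
  expect_equal(as.numeric(measureIC(flat)), 0, tolerance = 1e-9)
  # semicircular arc of radius R over a chord of length 2R: IC = R
  R <- 250
  th <- seq(0, pi, length.out = 121)
  semi <- mkCS(data.frame(label = "iris_ipe_right",
                          x = 500 + R + R * cos(th), z = 900 - R * sin(th)))
  expect_equal(as.numeric(measureIC(semi)), R, tolerance = 1e-3)
  # mirroring the sag about the chord flips the sign
  xs <- seq(500, 1100, by = 10)
  u <- (xs - 500) / 600
  bump <- 4 * 30 * u * (1 - u)
  up <- mkCS(data.frame(label = "iris_ipe_right", x = xs, z = 900 - bump))
  dn <- mkCS(data.frame(label = "iris_ipe_right", x = xs, z = 900 + bump))
  expect_equal(as.numeric(measureIC(up)), -as.numeric(measureIC(dn)),
               tolerance = 1e-9)
  expect_gt(as.numeric(measureIC(up)), 0)   # anterior bowing is positive
})

test_that("pipeline IC follows the iris sag with the documented sign", {
  g <- mouseEye(); o <- defaultOptics()
  icBase <- measureIC(dewarp(detectSurfaces(renderBScan(g, o)), o))
  expect_equal(as.numeric(icBase), 28.6, tolerance = 3 / 28.6)
  gDown <- mouseEye(irisSag = -28.6)
  icDown <- measureIC(dewarp(detectSurfaces(renderBScan(gDown, o)), o))
  expect_lt(as.numeric(icDown), 0)
  expect_equal(as.numeric(icDown), -as.numeric(icBase), tolerance = 0.1)
})

test_that("measureAxial is invariant to translation and intensity rescaling", {
  g <- mouseEye(); o <- defaultOptics()
  b <- renderBScan(g, o)
  ref <- measureFrame(b, o)
  shifted <- measureFrame(shiftBScan(b, 12), o)
  expect_equal(unname(shifted), unname(ref), tolerance = 5e-3)
  b3 <- new("BScanImage", image = 3 * imageData(b),
            axialPitch = axialPitch(b), lateralPitch = lateralPitch(b),
            timestamp = 0, phase = "t")
  expect_equal(unname(measureFrame(b3, o)), unname(ref), tolerance = 1e-4)
})

test_that("measureBiometry produces a complete flagged record per frame", {
  g <- mouseEye(); o <- defaultOptics()
  rec <- measureBiometry(renderBScan(g, o, timestamp = 7, phase = "iso"), o)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$time, 7)
  expect_equal(rec$phase, "iso")
  expect_true(all(c("cct", "acd", "lt", "crd", "lsi", "ic") %in% names(rec)))
  expect_gt(rec$crd, rec$acd + rec$lt)
  expect_identical(rec$flags, "")
})
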