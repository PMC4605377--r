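# Refraction: interface fitting, Snell dewarp, axial correction.

test_that("fitInterface recovers circles, falls flat on lines, needs 3 points", {
  th <- seq(-0.4, 0.4, length.out = 41)
  x <- 1500 * sin(th); z <- 1700 - 1500 * cos(th)    # anterior-convex
  fit <- fitInterface(x, z)
  expect_equal(fit$type, "arc")
  expect_equal(fit$radius, 1500, tolerance = 1 / 1500)
  # concave (centre anterior): negative signed radius
  fit2 <- fitInterface(x, 3000 + 1500 * cos(th))
  expect_equal(fit2$radius, -1500, tolerance = 1 / 1500)
  # collinear points: flat model, not a failure
  fit3 <- fitInterface(0:10 * 50, 100 + 0.2 * (0:10) * 50)
  expect_equal(fit3$type, "flat")
  expect_equal(fit3$slope, 0.2, tolerance = 1e-9)
  expect_error(fitInterface(c(0, 1), c(0, 1)), "3 points")
})

test_that("axialCorrect is the division oracle", {
  expect_equal(axialCorrect(166.6, 1.40), 119, tolerance = 1e-12)
  expect_equal(axialCorrect(123.4, 1), 123.4)
  expect_equal(axialCorrect(0, 1.57), 0)
  expect_error(axialCorrect(100, 0.9), ">= 1")
  expect_error(axialCorrect(-1, 1.4), ">= 0")
})

test_that("index perturbation scales corrected thickness by 1/(1 + d/n)", {
  opt <- 166.6; n <- 1.40
  for (d in c(-0.05, 0.01, 0.1)) {
    expect_equal(axialCorrect(opt, n + d),
                 axialCorrect(opt, n) / (1 + d / n), tolerance = 1e-12)
  }
})

test_that("the drop-index spread stays below the 0.82% bound", {
  spread <- dropIndexSpread()
  expect_equal(spread, (1.344 - 1.333) / 1.344, tolerance = 1e-12)
  expect_lt(spread, 0.0082)
  # corrections with any drop index therefore agree within 1%
  expect_lt(abs(axialCorrect(100, 1.344) / axialCorrect(100, 1.333) - 1),
            0.01)
})

test_that("dewarp with unit indices is the identity transform", {
  xs <- seq(-300, 300, by = 20)
  mkTrace <- function(label, z) data.frame(label = label, x = xs, z = z)
  tr <- rbind(mkTrace("cornea_anterior", 300 + xs^2 / 3000),
              mkTrace("cornea_posterior", 500 + xs^2 / 3200),
              mkTrace("lens_anterior", 900 + xs^2 / 2000),
              mkTrace("lens_posterior", 2800 - xs^2 / 2100),
              mkTrace("ilm", 4000 - xs^2 / 3200))
  s <- new("SurfaceSet", traces = tr, apAxis = 0, vertex = c(0, 300),
           failures = character(), axialPitch = 3)
  unitOptics <- tissueOptics(indices = c(cornea = 1, aqueous = 1,
                                         lens = 1, vitreous = 1))
  cs <- dewarp(s, unitOptics)
  m <- merge(tr, surfaceTraces(cs), by = c("label", "x"),
             suffixes = c("O", "C"))
  expect_equal(nrow(m), nrow(tr))
  expect_lt(max(abs(m$zC - m$zO)), 1e-6)
})

test_that("oblique rays through a tilted flat interface match a hand trace", {
  b <- 0.3                        # surface slope
  n2 <- 1.40
  xs <- seq(-200, 200, by = 25)
  tr <- rbind(data.frame(label = "cornea_anterior", x = xs, z = 300 + b * xs),
              data.frame(label = "cornea_posterior", x = xs,
                         z = 300 + b * xs + 140))
  s <- new("SurfaceSet", traces = tr, apAxis = 0, vertex = c(-200, 240),
           failures = character(), axialPitch = 3)
  cs <- dewarp(s, defaultOptics())
  got <- surfaceTraces(cs)
  got <- got[got$label == "cornea_posterior", ]
  # independent trace by rotation: in the frame where the surface is
  # horizontal the vertical ray arrives at angle a = atan(b); Snell gives
  # the refracted angle; rotating back yields the geometric displacement
  a <- atan(b)
  bt <- asin(sin(a) / n2)
  L <- 140 / n2                   # geometric path in the cornea
  dirRot <- c(sin(bt), cos(bt))   # refracted, surface-horizontal frame
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  dirLab <- as.numeric(R %*% dirRot)
  x0 <- 0; z0 <- 300
  expP <- c(x0, z0) + L * dirLab
  i <- which.min(abs(got$x - expP[1]))
  expect_lt(abs(got$x[i] - expP[1]), 1e-6)
  expect_lt(abs(got$z[i] - expP[2]), 1e-6)
})

test_that("total internal reflection excludes points but keeps the rest", {
  xs <- seq(0, 60, by = 6)
  tr <- rbind(data.frame(label = "cornea_anterior", x = xs, z = 100),
              data.frame(label = "cornea_posterior", x = xs, z = 240),
              data.frame(label = "lens_anterior", x = xs, z = 600),
              data.frame(label = "lens_posterior", x = xs, z = 3000 + 3 * xs),
              data.frame(label = "ilm", x = xs, z = 4200))
  s <- new("SurfaceSet", traces = tr, apAxis = 0, vertex = c(0, 100),
           failures = character(), axialPitch = 3)
  cs <- dewarp(s, defaultOptics())
  excl <- cs@excluded
  expect_true(any(excl$reason == "total internal reflection"))
  # shallower surfaces are still corrected
  expect_true(all(c("cornea_posterior", "lens_anterior", "lens_posterior")
                  %in% surfaceTraces(cs)$label))
})

test_that("forward-inverse round trip holds over a geometry grid", {
  o <- defaultOptics()
  grid <- list(
    mouseEye(),
    eyeGeometry(cct = 100, acd = 360, lt = 1700, crd = 2900,
                radii = c(cornea_anterior = 1300, cornea_posterior = 1250,
                          lens_anterior = 900, lens_posterior = -950,
                          ilm = -1500),
                irisRootX = 950, lateralExtent = 1100),
    eyeGeometry(cct = 140, acd = 450, lt = 2000, crd = 3300,
                radii = c(cornea_anterior = 1600, cornea_posterior = 1550,
                          lens_anterior = 1100, lens_posterior = -1150,
                          ilm = -1700)))
  for (g in grid) {
    b <- renderBScan(g, o)
    ax <- measureFrame(b, o)
    truth <- trueBiometry(g, o)
    p <- axialPitch(b)
    expect_lt(abs(ax[["cct"]] - truth$cct), 2 * p)
    expect_lt(abs(ax[["acd"]] - truth$acd), 3 * p)
    expect_lt(abs(ax[["lt"]] - truth$lt), 4 * p)
    expect_lt(abs(ax[["crd"]] - truth$crd), 5 * p)
  }
})
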