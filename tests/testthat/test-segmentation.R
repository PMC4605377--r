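# Segmentation: surface detection, vertex location, meridian selection.

test_that("noiseless traces sit within one pixel of the rendered interfaces", {
  g <- mouseEye(); o <- defaultOptics()
  b <- renderBScan(g, o)
  s <- detectSurfaces(b)
  expect_length(surfaceFailures(s), 0)
  tr <- surfaceTraces(s)
  # on the AP axis, compare against the independent optical-path oracle
  expected <- axisInterfaceOPL(g, o)
  labs <- c("cornea_anterior", "cornea_posterior", "lens_anterior",
            "lens_posterior", "ilm")
  for (i in seq_along(labs)) {
    z0 <- tr$z[tr$label == labs[i] & tr$x == 0]
    expect_length(z0, 1)
    expect_lt(abs(z0 - expected[i]), axialPitch(b))
  }
})

test_that("detection degrades gracefully with speckle (median error <= 2 px)", {
  g <- mouseEye(); o <- defaultOptics()
  ref <- surfaceTraces(detectSurfaces(renderBScan(g, o)))
  noisy <- surfaceTraces(detectSurfaces(renderBScan(g, o, noiseSeed = 0)))
  m <- merge(ref, noisy, by = c("label", "x"), suffixes = c("0", "1"))
  expect_gt(nrow(m), 500)
  medErr <- median(abs(m$z1 - m$z0)) / 3   # axial pitch 3 um
  expect_lte(medErr, 2)
})

test_that("surface error is non-decreasing as speckle contrast increases", {
  g <- mouseEye(); o <- defaultOptics()
  ref <- surfaceTraces(detectSurfaces(renderBScan(g, o)))
  err <- vapply(c(16, 4, 1), function(looks) {
    noisy <- surfaceTraces(detectSurfaces(
      renderBScan(g, o, noiseSeed = 1, speckleLooks = looks)))
    m <- merge(ref, noisy, by = c("label", "x"), suffixes = c("0", "1"))
    mean(abs(m$z1 - m$z0))
  }, numeric(1))
  expect_true(all(diff(err) >= 0))
})

test_that("missing structures produce a failure report, not silence", {
  # synthetic cornea-only image: one bright band in a dim background
  im <- matrix(0.5, 400, 101)
  im[60:110, ] <- 40
  b <- new("BScanImage", image = im, axialPitch = 3, lateralPitch = 10,
           timestamp = 0, phase = "test")
  s <- detectSurfaces(b)
  expect_setequal(
    surfaceFailures(s),
    c("lens_anterior", "lens_posterior", "ilm", "iris_ipe"))
  expect_gt(sum(surfaceTraces(s)$label == "cornea_anterior"), 50)
})

test_that("flat images and all-zero volumes are detection failures", {
  im <- matrix(1, 200, 50)
  b <- new("BScanImage", image = im, axialPitch = 3, lateralPitch = 10,
           timestamp = 0, phase = "t")
  expect_error(detectSurfaces(b), "flat intensity")
  z <- new("BScanImage", image = matrix(0, 200, 50), axialPitch = 3,
           lateralPitch = 10, timestamp = 0, phase = "t")
  expect_error(selectMeridianSlice(list(z, z)), "no detectable cornea")
})

test_that("meridian selection returns the vertex-containing slice", {
  o <- defaultOptics()
  mk <- function(offset) renderBScan(
    eyeGeometry(cct = 119, acd = 404, lt = 1860, crd = 3080,
                apexOffset = offset), o, nAxial = 1700)
  stack <- list(mk(210), mk(150), mk(210))
  sel <- selectMeridianSlice(stack)
  expect_equal(attr(sel, "slice"), 2)
  one <- selectMeridianSlice(stack[1])
  expect_equal(attr(one, "slice"), 1)
})

test_that("vertex and AP axis: symmetry, decentring, flat tie-break", {
  g <- mouseEye(); o <- defaultOptics()
  b <- renderBScan(g, o)
  s <- detectSurfaces(b)
  v <- locateVertex(s)
  expect_equal(v$apAxis, 0, tolerance = 1e-9)
  expect_equal(v$vertex[2], 150, tolerance = axialPitch(b))

  # decentred by +200 um (20 columns)
  s2 <- detectSurfaces(shiftBScan(b, 20))
  expect_equal(locateVertex(s2)$apAxis, 200, tolerance = 10)

  # flat cornea: no unique minimum, midpoint rule applies
  gf <- eyeGeometry(cct = 119, acd = 404, lt = 1860, crd = 3080,
                    radii = c(cornea_anterior = Inf, cornea_posterior = Inf,
                              lens_anterior = Inf, lens_posterior = Inf,
                              ilm = Inf))
  sf <- detectSurfaces(renderBScan(gf, o))
  expect_equal(locateVertex(sf)$apAxis, 0, tolerance = 10)
})

test_that("lateral translation translates all traces equally (equivariance)", {
  g <- mouseEye(); o <- defaultOptics()
  b <- renderBScan(g, o)
  t0 <- surfaceTraces(detectSurfaces(b))
  t1 <- surfaceTraces(detectSurfaces(shiftBScan(b, 15)))
  t1$x <- t1$x - 150
  m <- merge(t0, t1, by = c("label", "x"), suffixes = c("0", "1"))
  expect_gt(nrow(m), 0.8 * nrow(t0))
  expect_lt(max(abs(m$z1 - m$z0)), 1.5)   # half an axial pixel
})

test_that("anatomical ordering is enforced by the SurfaceSet class", {
  bad <- data.frame(label = c("cornea_anterior", "cornea_posterior"),
                    x = c(0, 0), z = c(500, 400))   # inverted order
  expect_error(new("SurfaceSet", traces = bad, apAxis = 0,
                   vertex = c(0, 400), failures = character(),
                   axialPitch = 3),
               "order")
})

test_that("seed points steer the assignment of a surface", {
  g <- mouseEye(); o <- defaultOptics()
  b <- renderBScan(g, o)
  auto <- surfaceTraces(detectSurfaces(b))
  la <- auto[auto$label == "lens_anterior", ]
  seeds <- data.frame(label = "lens_anterior",
                      x = la$x, z = la$z + 2)     # hint near the truth
  seeded <- surfaceTraces(detectSurfaces(b, seeds = seeds))
  laS <- seeded[seeded$label == "lens_anterior", ]
  m <- merge(la, laS, by = "x", suffixes = c("A", "S"))
  expect_gt(nrow(m), 50)
  expect_lt(median(abs(m$zS - m$zA)), 1.5)
})
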