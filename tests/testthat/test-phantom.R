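# Phantom module: response model, time-dependent geometry, forward rendering.

test_that("osmotic response is piecewise exponential with the closed form", {
  sc <- osmoticScenario(
    "t", data.frame(label = c("iso", "hyper"), osmolality = c(250, 1000),
                    duration = c(10, 30), framesPerMin = c(1, 1)),
    rbind(c(cct = 0, acd = 0, lt = 0, crd = 0, lsi = 0, iris_sag = 0),
          c(cct = -0.207, acd = 0, lt = 0, crd = 0, lsi = 0, iris_sag = 0)),
    tau = c(2, 2.5))
  # zero-amplitude isotonic phase: constant at baseline
  expect_equal(osmoticResponse(119, sc, "cct", c(0, 3, 7, 10)),
               rep(119, 4))
  # closed-form relaxation: at t - t0 = 3 tau the normalized change is
  # -20.7% * (1 - exp(-3))
  t3 <- 10 + 3 * 2.5
  expected <- 119 * (1 - 0.207 * (1 - exp(-3)))
  expect_equal(osmoticResponse(119, sc, "cct", t3), expected,
               tolerance = 1e-12)
  expect_equal(100 * (expected - 119) / 119, -20.7 * (1 - exp(-3)),
               tolerance = 1e-9)
})

test_that("reversal phases relax back toward baseline", {
  sc <- osmoticScenario(
    "t", data.frame(label = c("hyper", "reversal"),
                    osmolality = c(1000, 250),
                    duration = c(15, 400), framesPerMin = c(1, 1)),
    rbind(c(cct = -0.2, acd = 0, lt = 0, crd = 0, lsi = 0, iris_sag = 0),
          c(cct = 0, acd = 0, lt = 0, crd = 0, lsi = 0, iris_sag = 0)),
    tau = c(2, 5))
  atEnd <- osmoticResponse(100, sc, "cct", 15)
  expect_lt(atEnd, 85)                      # challenge took effect
  late <- osmoticResponse(100, sc, "cct", 415)
  expect_equal(late, 100, tolerance = 1e-8) # normalized change returns to 0
})

test_that("response model edge cases: tiny tau steps, out-of-range time", {
  sc <- osmoticScenario(
    "t", data.frame(label = "h", osmolality = 1000, duration = 10,
                    framesPerMin = 1),
    rbind(c(cct = -0.2, acd = 0, lt = 0, crd = 0, lsi = 0, iris_sag = 0)),
    tau = 1e-6)
  expect_equal(osmoticResponse(100, sc, "cct", 1), 80, tolerance = 1e-6)
  expect_error(osmoticResponse(100, sc, "cct", 11), "schedule")
  expect_error(osmoticResponse(100, sc, "cct", -1), "schedule")
})

test_that("eyeAtTime is the identity at t = 0 and maps signs correctly", {
  g <- mouseEye(); o <- defaultOptics()
  st0 <- eyeAtTime(scenarioGroupI(), g, o, 0)
  expect_equal(eyeSurfaces(st0$geometry)$apex, eyeSurfaces(g)$apex)
  expect_equal(st0$geometry@irisSag, g@irisSag)
  expect_equal(st0$optics@lensOpacityMultiplier, 1)

  # end of the strong hypertonic phase: cornea thinner, chamber shallower,
  # lens thickness unchanged, iris bowed anterior, lens opacified
  stH <- eyeAtTime(scenarioGroupI(), g, o, 23)
  b0 <- trueBiometry(g, o); bH <- trueBiometry(stH$geometry, stH$optics)
  expect_lt(bH$cct, b0$cct)
  expect_lt(bH$acd, b0$acd)
  expect_equal(bH$lt, b0$lt)
  expect_lt(bH$crd, b0$crd)
  expect_gt(stH$geometry@irisSag, g@irisSag)
  expect_gt(stH$optics@lensOpacityMultiplier, 1.25)

  # hypotonic phase: inward (concave) iris bowing
  stL <- eyeAtTime(scenarioGroupIII(), g, o, 34)
  expect_lt(stL$geometry@irisSag, 0)
})

test_that("a response violating surface ordering fails validation", {
  sc <- osmoticScenario(
    "bad", data.frame(label = "h", osmolality = 1000, duration = 10,
                      framesPerMin = 1),
    rbind(c(cct = 0, acd = -2, lt = 0, crd = 0, lsi = 0, iris_sag = 0)),
    tau = 0.5)
  expect_error(eyeAtTime(sc, mouseEye(), defaultOptics(), 10), "ordered|> 0")
})

test_that("rendered interfaces sit at summed optical-path depths (flat case)", {
  o <- defaultOptics()
  g <- eyeGeometry(cct = 119, acd = 404, lt = 1860, crd = 3080,
                   radii = c(cornea_anterior = Inf, cornea_posterior = Inf,
                             lens_anterior = Inf, lens_posterior = Inf,
                             ilm = Inf))
  b <- renderBScan(g, o)
  col <- imageData(b)[, (ncol(imageData(b)) + 1) / 2]
  found <- columnTransitions(col, axialPitch(b))
  expected <- axisInterfaceOPL(g, o)
  # every expected interface is matched by a transition within one pixel
  for (e in expected)
    expect_lt(min(abs(found - e)), axialPitch(b))
})

test_that("curved-geometry axial column obeys optical-path additivity", {
  o <- defaultOptics()
  g <- mouseEye()
  b <- renderBScan(g, o)
  col <- imageData(b)[, (ncol(imageData(b)) + 1) / 2]
  found <- columnTransitions(col, axialPitch(b))
  expected <- axisInterfaceOPL(g, o)   # includes 119 * 1.40 = 166.6 cornea
  expect_equal(expected[2] - expected[1], 166.6, tolerance = 1e-9)
  for (e in expected)
    expect_lt(min(abs(found - e)), axialPitch(b))
})

test_that("rendering is deterministic and seeds change only the noise", {
  g <- mouseEye(); o <- defaultOptics()
  b1 <- renderBScan(g, o, noiseSeed = 5)
  b2 <- renderBScan(g, o, noiseSeed = 5)
  b3 <- renderBScan(g, o, noiseSeed = 6)
  clean1 <- renderBScan(g, o)
  clean2 <- renderBScan(g, o)
  expect_identical(imageData(b1), imageData(b2))
  expect_false(identical(imageData(b1), imageData(b3)))
  expect_identical(imageData(clean1), imageData(clean2))
})

test_that("too-shallow images raise a truncation error", {
  expect_error(renderBScan(mouseEye(), defaultOptics(), nAxial = 500),
               "truncation")
})

test_that("time series follow the scheduled imaging frequencies", {
  ctrl <- frameSchedule(scenarioControl())
  expect_equal(nrow(ctrl), 5 + 12)          # 5 baseline repeats + 60 min / 5
  expect_equal(sum(ctrl$phase == "baseline"), 5)
  g1 <- frameSchedule(scenarioGroupI())
  expect_equal(nrow(g1), 5 + 2 + 13 + 8)
  expect_equal(g1$time[g1$phase == "hypertonic"], 11:23)
  g4 <- frameSchedule(scenarioGroupIV())
  expect_equal(sum(g4$phase == "hypertonic"), 1)  # single acquisition
})

test_that("renderTimeSeries is reproducible under a fixed seed", {
  sc <- tinyScenario()
  ts1 <- renderTimeSeries(sc, seed = 3, noise = TRUE)
  ts2 <- renderTimeSeries(sc, seed = 3, noise = TRUE)
  expect_identical(lapply(ts1$frames, imageData),
                   lapply(ts2$frames, imageData))
  expect_equal(ts1$truth, ts2$truth)
  expect_equal(nrow(ts1$truth), length(ts1$frames))
})
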