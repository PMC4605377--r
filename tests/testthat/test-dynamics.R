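# Dynamics: baseline normalization, peaks, exponential fits, steady state.

test_that("baseline is the mean of the repeat acquisitions", {
  df <- data.frame(cct = c(118, 119, 120, 119, 119), acd = 404, lt = 1860,
                   crd = 3080, lsi = 25, ic = 28.6)
  bl <- computeBaseline(df, k = 5)
  expect_equal(bl$mean[bl$parameter == "cct"], 119)
  expect_equal(bl$sd[bl$parameter == "acd"], 0)
  expect_error(computeBaseline(df, k = 0), "at least one")
})

test_that("normalization is exact and invertible", {
  expect_equal(normalizeToBaseline(94.4, 119), 100 * (94.4 - 119) / 119)
  expect_equal(normalizeToBaseline(94.4, 119), -20.67227, tolerance = 1e-6)
  expect_equal(normalizeToBaseline(119, 119), 0)
  expect_error(normalizeToBaseline(100, 0), "positive")
  # round trip: de-normalizing recovers the raw value
  p0 <- 404; p <- 380
  ch <- normalizeToBaseline(p, p0)
  expect_equal(p0 * (1 + ch / 100), p)
})

test_that("peak change takes the signed extreme, earliest on ties", {
  t <- 0:5
  y <- c(0, -5, -12, -18, -20, -19)
  pk <- peakChange(t, y)
  expect_equal(pk$change, -20)
  expect_equal(pk$time, 4)
  # tie: both +8 at t = 1 and t = 3
  pk2 <- peakChange(0:4, c(0, 8, 3, 8, 2))
  expect_equal(pk2$time, 1)
  expect_error(peakChange(1, 5), "2 frames")
})

test_that("exponential fits recover amplitude and tau within 1%", {
  t <- seq(0, 12, by = 1)
  y <- -20 * (1 - exp(-t / 3))
  ft <- fitExponential(t, y)
  expect_true(ft$converged)
  expect_equal(ft$amplitude, -20, tolerance = 0.01)
  expect_equal(ft$tau, 3, tolerance = 0.01)
  # reversal segment: relaxation toward 0 from a carried-over level
  yr <- -20 * exp(-t / 3)
  fr <- fitExponential(t, yr)
  expect_equal(fr$amplitude, 20, tolerance = 0.01)
  expect_equal(fr$tau, 3, tolerance = 0.01)
  # constant series: amplitude ~ 0
  fc <- fitExponential(t, rep(2, length(t)))
  expect_true(abs(fc$amplitude) < 0.01 || !fc$converged)
  expect_error(fitExponential(0:1, c(0, 1)), "4 frames")
})

test_that("steady state matches the tau*ln(100) closed form", {
  t <- seq(0, 15, by = 0.05)
  y <- 1 - exp(-t / 2)
  ss <- steadyStateTime(t, y)
  expect_equal(ss, 2 * log(100), tolerance = 0.03)
  # constant series: reached immediately
  expect_equal(steadyStateTime(0:10, rep(4, 11)), 0)
  # linear ramp: never reached
  expect_true(is.na(steadyStateTime(0:10, 0:10)))
  expect_error(steadyStateTime(0:1, 0:1), "3 frames")
})

test_that("ground-truth series summarize to the scenario calibration", {
  sc <- scenarioGroupI()
  ts <- renderTimeSeries(sc, seed = 1, noise = FALSE)
  ser <- buildResponseSeries(ts$truth, k = 5)
  # baseline frames have zero change by construction
  expect_equal(max(abs(ser$change[ser$phase == "baseline"])), 0)
  sm <- summarizeDynamics(ser, sc)
  hyp <- sm[sm$phase == "hypertonic", ]
  target <- function(A) A * (1 - exp(-13 / 2.5))
  expect_equal(hyp$peak[hyp$parameter == "cct"], target(-20.7),
               tolerance = 1e-6)
  expect_equal(hyp$peak[hyp$parameter == "acd"], target(-11.5),
               tolerance = 1e-6)
  expect_equal(hyp$peak[hyp$parameter == "lsi"], target(28.8),
               tolerance = 1e-6)
  expect_equal(hyp$amplitude[hyp$parameter == "cct"], -20.7,
               tolerance = 0.01)
  expect_equal(hyp$tau[hyp$parameter == "cct"], 2.5, tolerance = 0.01)
  # reversal relaxes back toward baseline: final |change| below the peak
  rev <- ser[ser$parameter == "cct" & ser$phase == "reversal", ]
  expect_lt(abs(rev$change[which.max(rev$time)]), abs(target(-20.7)) / 10)
})
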