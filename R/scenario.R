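# Osmotic challenge scenarios: constructors, packaged study schedules,
# structured-text (YAML) serialization, frame schedules, and the piecewise
# exponential response model.

#' Construct an osmotic scenario
#'
#' @param name scenario name.
#' @param phases data.frame with columns \code{label}, \code{osmolality}
#'   (mOsmol/kg), \code{duration} (min), \code{framesPerMin}.
#' @param amplitudes matrix (phases x parameters \code{cct, acd, lt, crd,
#'   lsi, iris_sag}) of asymptotic fractional changes relative to baseline.
#' @param tau per-phase relaxation time constants, minutes.
#' @param baselineRepeats number of repeat baseline acquisitions (default 5).
#' @param geometry \code{"mouse"} or \code{"model_eye"}.
#' @return A validated [OsmoticScenario-class].
#' @seealso [scenarioGroupI()], [readScenario()], [osmoticResponse()]
#' @export
osmoticScenario <- function(name, phases, amplitudes, tau,
                            baselineRepeats = 5, geometry = "mouse") {
  amplitudes <- as.matrix(amplitudes)
  colnames(amplitudes) <- colnames(amplitudes) %||% .PARAMETERS
  new("OsmoticScenario", name = name, phases = phases,
      amplitudes = amplitudes[, .PARAMETERS, drop = FALSE],
      tau = tau, baselineRepeats = baselineRepeats, geometry = geometry)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.amp <- function(cct = 0, acd = 0, lt = 0, crd = 0, lsi = 0, iris_sag = 0) {
  c(cct = cct, acd = acd, lt = lt, crd = crd, lsi = lsi, iris_sag = iris_sag)
}

# Iris sag asymptotes (micrometres) observed in the isotonic / hypertonic /
# hypotonic phases, expressed as fractional change of the isotonic baseline.
.SAG_BASE <- 28.6
.SAG_HYPER <- (48.2 - .SAG_BASE) / .SAG_BASE
.SAG_HYPO <- (-24.6 - .SAG_BASE) / .SAG_BASE

#' Packaged study scenarios
#'
#' The five study schedules: a 60-min isotonic control and four challenge
#' groups (I: 250-1000-250 mOsmol/kg; II: 250-500-250; III: 250-100-250;
#' IV: 250-1000-100), with imaging frequencies as scheduled per phase and
#' 5 baseline repeats. Group-I challenge amplitudes encode the peak responses
#' of the strong hypertonic challenge (CCT -20.7\%, ACD -11.5\%, CRD -2.3\%,
#' LT 0, LSI +28.8\%, iris sag toward +48.2 um); Group II uses half the
#' magnitude with a slower time constant (only the qualitative "decreased
#' rate and magnitude" is known); Group III uses opposite-sign defaults with
#' a slower time constant and no lens scattering change; Group IV chains a
#' hypertonic and a hypotonic phase and drives the iris sag to +48.2 then
#' -24.6 um. Time constants are chosen so each phase reaches steady state
#' (rate below 1\% of the initial rate, i.e. after \code{tau * ln(100)})
#' within its scheduled duration. \code{scenarioModelEye()} is a single
#' isotonic acquisition of the model eye used for validation.
#'
#' @return An [OsmoticScenario-class].
#' @examples
#' scenarioGroupI()
#' @name scenarios
NULL

.phaseRow <- function(label, osmolality, duration, framesPerMin)
  data.frame(label = label, osmolality = osmolality, duration = duration,
             framesPerMin = framesPerMin)

#' @rdname scenarios
#' @export
scenarioControl <- function() {
  osmoticScenario("control",
                  .phaseRow("isotonic", 250, 60, 1 / 5),
                  rbind(.amp()), tau = 2)
}

#' @rdname scenarios
#' @export
scenarioGroupI <- function() {
  osmoticScenario("group1",
    rbind(.phaseRow("isotonic", 250, 10, 1 / 5),
          .phaseRow("hypertonic", 1000, 13, 1),
          .phaseRow("reversal", 250, 40, 1 / 5)),
    rbind(.amp(),
          .amp(cct = -0.207, acd = -0.115, lt = 0, crd = -0.023,
               lsi = 0.288, iris_sag = .SAG_HYPER),
          .amp()),
    tau = c(2, 2.5, 6))
}

#' @rdname scenarios
#' @export
scenarioGroupII <- function() {
  osmoticScenario("group2",
    rbind(.phaseRow("isotonic", 250, 10, 1 / 5),
          .phaseRow("hypertonic", 500, 13, 1),
          .phaseRow("reversal", 250, 40, 1 / 5)),
    rbind(.amp(),
          .amp(cct = -0.1035, acd = -0.0575, lt = 0, crd = -0.0115,
               lsi = 0.144, iris_sag = .SAG_HYPER / 2),
          .amp()),
    tau = c(2, 2.8, 7))
}

#' @rdname scenarios
#' @export
scenarioGroupIII <- function() {
  osmoticScenario("group3",
    rbind(.phaseRow("isotonic", 250, 10, 1 / 5),
          .phaseRow("hypotonic", 100, 24, 1 / 3),
          .phaseRow("reversal", 250, 24, 1 / 3)),
    rbind(.amp(),
          .amp(cct = 0.15, acd = 0.08, lt = 0, crd = 0.02,
               lsi = 0, iris_sag = .SAG_HYPO),
          .amp()),
    tau = c(2, 4.5, 4.5))
}

#' @rdname scenarios
#' @export
scenarioGroupIV <- function() {
  osmoticScenario("group4",
    rbind(.phaseRow("isotonic", 250, 10, 1 / 5),
          .phaseRow("hypertonic", 1000, 20, 1 / 20),
          .phaseRow("hypotonic", 100, 20, 1 / 20)),
    rbind(.amp(),
          .amp(cct = -0.207, acd = -0.115, lt = 0, crd = -0.023,
               lsi = 0.288, iris_sag = .SAG_HYPER),
          .amp(cct = 0.15, acd = 0.08, lt = 0, crd = 0.02,
               lsi = 0, iris_sag = .SAG_HYPO)),
    tau = c(2, 3, 3))
}

#' @rdname scenarios
#' @export
scenarioModelEye <- function() {
  osmoticScenario("model_eye",
                  .phaseRow("isotonic", 250, 1, 1),
                  rbind(.amp()), tau = 1,
                  baselineRepeats = 5, geometry = "model_eye")
}

#' Read / write a scenario configuration file
#'
#' Scenarios are serialized as YAML mirroring the study-schedule fields
#' (per-phase label, osmolality, duration, imaging frequency, time constant
#' and amplitude block). The packaged schedules live in
#' \code{system.file("extdata", "scenarios", package = "OCTbiometry")}.
#'
#' @param path file path. For [readScenario()] a bare name such as
#'   \code{"group1"} resolves to the packaged scenario file.
#' @return [readScenario()] returns an [OsmoticScenario-class];
#'   [writeScenario()] invisibly returns \code{path}.
#' @examples
#' sc <- readScenario("control")
#' totalDuration(sc)
#' @export
readScenario <- function(path) {
  if (!file.exists(path)) {
    pkg <- system.file("extdata", "scenarios",
                       paste0(sub("\\.ya?ml$", "", path), ".yaml"),
                       package = "OCTbiometry")
    if (!nzchar(pkg)) stop("scenario file not found: ", path)
    path <- pkg
  }
  y <- yaml::read_yaml(path)
  phases <- do.call(rbind, lapply(y$phases, function(p)
    .phaseRow(p$label, p$osmolality, p$duration, p$frames_per_min)))
  amp <- do.call(rbind, lapply(y$phases, function(p) {
    a <- .amp()
    got <- intersect(names(p$amplitudes), .PARAMETERS)
    a[got] <- unlist(p$amplitudes[got])
    a
  }))
  osmoticScenario(y$name, phases, amp,
                  tau = vapply(y$phases, function(p) as.numeric(p$tau),
                               numeric(1)),
                  baselineRepeats = y$baseline_repeats %||% 5,
                  geometry = y$geometry %||% "mouse")
}

#' @rdname readScenario
#' @param scenario an [OsmoticScenario-class].
#' @export
writeScenario <- function(scenario, path) {
  p <- scenario@phases
  y <- list(name = scenario@name, geometry = scenario@geometry,
            baseline_repeats = scenario@baselineRepeats,
            phases = lapply(seq_len(nrow(p)), function(i)
              list(label = p$label[i], osmolality = p$osmolality[i],
                   duration = p$duration[i],
                   frames_per_min = p$framesPerMin[i],
                   tau = scenario@tau[i],
                   amplitudes = as.list(scenario@amplitudes[i, ]))))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Imaging frame schedule of a scenario
#'
#' Baseline repeats are acquired at t = 0; within each phase frames fall at
#' the phase's imaging frequency, ending at the phase boundary.
#'
#' @param scenario an [OsmoticScenario-class].
#' @return data.frame with columns \code{frame}, \code{time} (min),
#'   \code{phase}.
#' @examples
#' nrow(frameSchedule(scenarioControl()))  # 5 baseline repeats + 12 frames
#' @export
frameSchedule <- function(scenario) {
  p <- scenario@phases
  times <- rep(0, scenario@baselineRepeats)
  labels <- rep("baseline", scenario@baselineRepeats)
  t0 <- 0
  for (i in seq_len(nrow(p))) {
    nf <- round(p$duration[i] * p$framesPerMin[i])
    if (nf > 0) {
      times <- c(times, t0 + seq_len(nf) / p$framesPerMin[i])
      labels <- c(labels, rep(p$label[i], nf))
    }
    t0 <- t0 + p$duration[i]
  }
  data.frame(frame = seq_along(times), time = times, phase = labels)
}

#' Piecewise exponential osmotic response
#'
#' Within each phase the parameter relaxes exponentially toward the phase
#' asymptote \code{baseline * (1 + amplitude)}:
#' \deqn{p(t) = p_\infty + (p(t_0) - p_\infty) e^{-(t - t_0)/\tau},}
#' continuous across phase boundaries. Isotonic phases with zero amplitude
#' relax back toward the baseline, so at long times the normalized change
#' returns to 0.
#'
#' @param baseline baseline parameter value (micrometres or intensity units).
#' @param scenario an [OsmoticScenario-class].
#' @param parameter one of \code{"cct", "acd", "lt", "crd", "lsi",
#'   "iris_sag"}.
#' @param t times in minutes (vectorized); must lie within the scenario's
#'   total duration.
#' @return Parameter values at \code{t}.
#' @examples
#' sc <- scenarioGroupI()
#' osmoticResponse(119, sc, "cct", c(0, 10, 23, 63))
#' @export
osmoticResponse <- function(baseline, scenario, parameter, t) {
  parameter <- match.arg(parameter, .PARAMETERS)
  p <- scenario@phases
  total <- sum(p$duration)
  if (any(t < 0 | t > total + 1e-9))
    stop("time outside the scenario schedule [0, ", total, "] min")
  amps <- scenario@amplitudes[, parameter]
  bounds <- cumsum(c(0, p$duration))
  starts <- numeric(nrow(p) + 1)
  starts[1] <- baseline
  pinf <- baseline * (1 + amps)
  for (i in seq_len(nrow(p)))
    starts[i + 1] <- pinf[i] +
      (starts[i] - pinf[i]) * exp(-p$duration[i] / scenario@tau[i])
  ph <- pmin(findInterval(t, bounds, left.open = TRUE), nrow(p))
  ph[t <= 0] <- 1L
  out <- numeric(length(t))
  zero <- t <= 0
  out[zero] <- baseline
  if (any(!zero)) {
    i <- ph[!zero]
    out[!zero] <- pinf[i] + (starts[i] - pinf[i]) *
      exp(-(t[!zero] - bounds[i]) / scenario@tau[i])
  }
  out
}

#' Eye state at a given time of an osmotic challenge
#'
#' Maps the six parameter responses onto the geometry and optics: the CCT
#' change moves the posterior corneal apex (the anterior cornea is the fixed
#' reference), the ACD change translates the lens, the LT change moves the
#' posterior lens apex, the CRD change translates the retinal surface, the
#' iris sag follows its own response (the iris root rides on the lens), and
#' the LSI change scales the opacified-lens intensity multiplier. Radii of
#' curvature are held fixed. At t = 0 the baseline is returned exactly; a
#' response that would violate the anatomical surface ordering fails geometry
#' validation.
#'
#' @param scenario an [OsmoticScenario-class].
#' @param geometry baseline [EyeGeometry-class].
#' @param optics baseline [TissueOptics-class].
#' @param t time, minutes.
#' @return \code{list(geometry =, optics =)} at time \code{t}.
#' @examples
#' st <- eyeAtTime(scenarioGroupI(), mouseEye(), tissueOptics(), 23)
#' trueBiometry(st$geometry, st$optics)
#' @export
eyeAtTime <- function(scenario, geometry, optics, t) {
  stopifnot(length(t) == 1)
  base <- trueBiometry(geometry, optics)
  val <- function(par, b) osmoticResponse(b, scenario, par, t)
  s <- geometry@surfaces
  radii <- stats::setNames(s$radius, s$label)
  rootOffset <- geometry@irisRootZ - .irisContact(geometry)[2]
  g <- eyeGeometry(cct = val("cct", base$cct), acd = val("acd", base$acd),
                   lt = val("lt", base$lt), crd = val("crd", base$crd),
                   radii = radii, apexOffset = s$apex[1],
                   pupilRadius = geometry@pupilRadius,
                   irisRootX = geometry@irisRootX,
                   irisRootZOffset = rootOffset,
                   irisSag = val("iris_sag", geometry@irisSag),
                   irisThickness = geometry@irisThickness,
                   lateralExtent = geometry@lateralExtent)
  o <- optics
  o@lensOpacityMultiplier <- optics@lensOpacityMultiplier *
    osmoticResponse(1, scenario, "lsi", t)
  validObject(o)
  list(geometry = g, optics = o)
}
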