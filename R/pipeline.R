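# End-to-end pipeline stages mirroring the study workflow:
# simulate -> measure -> dynamics, plus a replicate driver over all packaged
# scenarios. All randomness flows from one master seed, and every run writes
# a machine-readable JSON log (stage, parameters, seed, versions).

.writeLog <- function(outdir, stage, params) {
  log <- c(list(stage = stage,
                package = as.character(utils::packageVersion("OCTbiometry")),
                r = R.version.string,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           params)
  jsonlite::write_json(log, file.path(outdir, paste0(stage, "_log.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Simulate an osmotic-challenge acquisition
#'
#' Renders the scenario's full frame schedule and writes the image stack
#' (multi-page TIFF + metadata CSV), the ground-truth biometry CSV and a run
#' log into \code{outdir}.
#'
#' @param scenario an [OsmoticScenario-class], or a scenario name/path for
#'   [readScenario()].
#' @param outdir output directory (created if needed).
#' @param seed master seed.
#' @param noise render with the default noise model (gamma speckle +
#'   additive floor) or noiselessly.
#' @param ... passed to [renderTimeSeries()].
#' @return Invisibly, a list with the output paths and the truth table.
#' @export
runSimulate <- function(scenario, outdir, seed = 1, noise = TRUE, ...) {
  if (is.character(scenario)) scenario <- readScenario(scenario)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ts <- renderTimeSeries(scenario, seed = seed, noise = noise, ...)
  tiffPath <- file.path(outdir, "images.tif")
  writeBScanStack(ts$frames, tiffPath)
  truthPath <- file.path(outdir, "truth.csv")
  utils::write.csv(ts$truth, truthPath, row.names = FALSE)
  .writeLog(outdir, "simulate",
            list(scenario = scenario@name, seed = seed, noise = noise,
                 frames = length(ts$frames)))
  invisible(list(tiff = tiffPath, truth = truthPath, truthTable = ts$truth))
}

#' Measure biometry of a simulated (or imported) stack
#'
#' @param outdir directory holding \code{images.tif} + sidecar metadata (as
#'   written by [runSimulate()]).
#' @param optics a [TissueOptics-class] (index stack for the correction).
#' @param lsiFraction LSI window fraction.
#' @param seedsCsv optional CSV of segmentation seed points (label, x, z).
#' @return Invisibly, the biometry data.frame (also written to
#'   \code{biometry.csv}).
#' @export
runMeasure <- function(outdir, optics = tissueOptics(), lsiFraction = 0.15,
                       seedsCsv = NULL) {
  frames <- readBScanStack(file.path(outdir, "images.tif"))
  seeds <- if (!is.null(seedsCsv)) readSurfaceSet(seedsCsv) else NULL
  bio <- measureStack(frames, optics = optics, lsiFraction = lsiFraction,
                      seeds = seeds)
  utils::write.csv(bio, file.path(outdir, "biometry.csv"), row.names = FALSE)
  .writeLog(outdir, "measure",
            list(frames = length(frames), lsiFraction = lsiFraction,
                 seeds = seedsCsv %||% NA))
  invisible(bio)
}

#' Dynamics summary of a biometry table
#'
#' Normalizes the series to the baseline repeats, summarizes every phase
#' (peak change, exponential fit, steady-state time) and optionally draws
#' per-parameter response panels.
#'
#' @param biometry biometry data.frame or path to \code{biometry.csv}.
#' @param scenario the scenario (object or name) that produced it.
#' @param outdir output directory for \code{dynamics.csv} (and plots).
#' @param plot write a PNG response-curve panel per parameter.
#' @return Invisibly, list(series =, summary =).
#' @export
runDynamics <- function(biometry, scenario, outdir, plot = FALSE) {
  if (is.character(biometry)) {
    if (!file.exists(biometry)) stop("biometry CSV not found: ", biometry)
    biometry <- utils::read.csv(biometry, stringsAsFactors = FALSE)
  }
  if (nrow(biometry) < 2) stop("biometry table is empty or too short")
  if (is.character(scenario)) scenario <- readScenario(scenario)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  series <- buildResponseSeries(biometry, k = scenario@baselineRepeats)
  summary <- summarizeDynamics(series, scenario)
  utils::write.csv(summary, file.path(outdir, "dynamics.csv"),
                   row.names = FALSE)
  if (plot) plotResponseSeries(series, file.path(outdir, "response.png"))
  .writeLog(outdir, "dynamics", list(scenario = scenario@name,
                                     baselineRepeats = scenario@baselineRepeats))
  invisible(list(series = series, summary = summary))
}

#' Plot normalized response curves
#'
#' One panel per parameter (percent change vs time; IC in micrometres), in
#' the style of a multi-parameter osmotic-response figure.
#'
#' @param series long data.frame from [buildResponseSeries()].
#' @param file optional PNG path; default draws on the current device.
#' @return Invisibly NULL.
#' @export
plotResponseSeries <- function(series, file = NULL) {
  pars <- unique(series$parameter)
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 300 * ceiling(length(pars) / 2),
                   res = 120)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(ceiling(length(pars) / 2), 2),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (p in pars) {
    s <- series[series$parameter == p, ]
    ylab <- if (p == "ic") "change (um)" else "change (%)"
    graphics::plot(s$time, s$change, type = "b", pch = 16, cex = 0.6,
                   xlab = "time (min)", ylab = ylab, main = toupper(p))
    graphics::abline(h = 0, lty = 3)
  }
  invisible(NULL)
}

#' Replicate the full study: all packaged scenarios end-to-end
#'
#' Runs simulate, measure and dynamics for the control and the four
#' challenge groups under one master seed, and writes a recovery report
#' comparing the measured per-phase peak changes against the phantom's own
#' ground-truth table.
#'
#' @param outdir output root; one subdirectory per scenario.
#' @param seed master seed (per-scenario seeds derive from it).
#' @param scenarios scenario names to run.
#' @param noise render with the default noise model.
#' @return Invisibly, named list of per-scenario results (biometry, summary,
#'   recovery table).
#' @export
runReplicate <- function(outdir, seed = 1,
                         scenarios = c("control", "group1", "group2",
                                       "group3", "group4"),
                         noise = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .withSeed(seed, sample.int(.Machine$integer.max - 1,
                                      length(scenarios)))
  res <- list()
  for (i in seq_along(scenarios)) {
    nm <- scenarios[i]
    sc <- readScenario(nm)
    sub <- file.path(outdir, nm)
    sim <- runSimulate(sc, sub, seed = seeds[i], noise = noise)
    bio <- runMeasure(sub)
    dyn <- runDynamics(bio, sc, sub)
    truthSeries <- buildResponseSeries(sim$truthTable,
                                       k = sc@baselineRepeats)
    truthSummary <- summarizeDynamics(truthSeries, sc)
    rec <- merge(dyn$summary[, c("parameter", "phase", "peak")],
                 truthSummary[, c("parameter", "phase", "peak")],
                 by = c("parameter", "phase"),
                 suffixes = c("Measured", "Truth"))
    rec$error <- rec$peakMeasured - rec$peakTruth
    utils::write.csv(rec, file.path(sub, "recovery.csv"), row.names = FALSE)
    res[[nm]] <- list(biometry = bio, summary = dyn$summary, recovery = rec)
  }
  jsonlite::write_json(
    lapply(res, function(r)
      list(maxAbsPeakError = max(abs(r$recovery$error), na.rm = TRUE))),
    file.path(outdir, "replicate_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .writeLog(outdir, "replicate",
            list(seed = seed, scenarios = scenarios, noise = noise))
  invisible(res)
}
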