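# Response dynamics: baseline normalization, peak change, exponential
# relaxation fitting, and steady-state detection (the steady state is reached
# when the change rate has fallen below 1% of the initial rate).

.DYN_PARAMS <- c("cct", "acd", "lt", "crd", "lsi", "ic")

#' Baseline values from the repeat acquisitions
#'
#' The baseline of each parameter is the arithmetic mean of the first
#' \code{k} repeat acquisitions (default 5 repeats before the first
#' challenge).
#'
#' @param records biometry data.frame (rows ordered in time, baseline repeats
#'   first), with the parameter columns \code{cct, acd, lt, crd, lsi, ic}.
#' @param k number of baseline repeats (>= 1).
#' @param params parameter columns to summarize.
#' @return data.frame with columns \code{parameter}, \code{mean}, \code{sd}.
#' @examples
#' df <- data.frame(cct = c(118, 119, 120, 119, 119), acd = 404, lt = 1860,
#'                  crd = 3080, lsi = 25, ic = 28.6)
#' computeBaseline(df)
#' @export
computeBaseline <- function(records, k = 5, params = .DYN_PARAMS) {
  if (k < 1) stop("at least one baseline repeat is required")
  if (nrow(records) < k) stop("fewer records than baseline repeats")
  params <- intersect(params, names(records))
  head <- records[seq_len(k), params, drop = FALSE]
  data.frame(parameter = params,
             mean = vapply(head, mean, numeric(1)),
             sd = vapply(head, stats::sd, numeric(1)),
             row.names = NULL)
}

#' Normalize a series to its baseline
#'
#' Percent change relative to baseline: \code{100 * (p - p0) / p0}.
#'
#' @param values parameter values.
#' @param baseline baseline value p0 (> 0).
#' @return Percent change series.
#' @examples
#' normalizeToBaseline(94.4, 119)  # -20.7 percent
#' @export
normalizeToBaseline <- function(values, baseline) {
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline must be a positive finite value")
  100 * (values - baseline) / baseline
}

#' Build baseline-normalized response series from a biometry table
#'
#' @param records biometry data.frame with columns \code{time}, \code{phase}
#'   and the parameter columns.
#' @param k number of baseline repeats used for the baseline mean.
#' @param params parameters to include.
#' @return Long data.frame: \code{parameter, time, phase, value, change}
#'   (percent). Baseline frames have mean change 0 by construction.
#' @examples
#' ts <- renderTimeSeries(scenarioControl(), seed = 1, noise = FALSE)
#' head(buildResponseSeries(ts$truth, k = 5))
#' @export
buildResponseSeries <- function(records, k = 5, params = .DYN_PARAMS) {
  params <- intersect(params, names(records))
  bl <- computeBaseline(records, k, params)
  out <- lapply(params, function(p) {
    p0 <- bl$mean[bl$parameter == p]
    ch <- if (p == "ic") records[[p]] - p0  # IC reported in um, not percent
          else normalizeToBaseline(records[[p]], p0)
    data.frame(parameter = p, time = records$time, phase = records$phase,
               value = records[[p]], change = ch)
  })
  do.call(rbind, out)
}

#' Peak change within a phase window
#'
#' The signed extreme (largest absolute value) of the normalized change
#' within the window; ties are broken by the earliest time.
#'
#' @param time,change the series (>= 2 frames in the window).
#' @param window \code{c(t0, t1)} in minutes, or NULL for the whole series.
#' @return \code{list(change =, time =)}.
#' @examples
#' peakChange(0:5, c(0, -5, -12, -18, -20, -19))
#' @export
peakChange <- function(time, change, window = NULL) {
  if (!is.null(window)) {
    keep <- time > window[1] - 1e-9 & time <= window[2] + 1e-9
    time <- time[keep]; change <- change[keep]
  }
  ok <- is.finite(change)
  time <- time[ok]; change <- change[ok]
  if (length(time) < 2) stop("at least 2 frames are required in the window")
  i <- which(abs(change) >= max(abs(change)) - 1e-12)
  i <- i[which.min(time[i])]
  list(change = change[i], time = time[i])
}

#' Fit an exponential relaxation to a phase segment
#'
#' Least-squares fit of \deqn{y(t) = y_0 + A (1 - e^{-(t - t_0)/\tau})}
#' with \code{y0} fixed at the segment's starting level (0 for a challenge
#' phase starting at baseline; the carried-over level for a reversal phase,
#' which then relaxes toward 0). On noiseless exponentials the amplitude and
#' time constant are recovered essentially exactly.
#'
#' @param time,change segment series (>= 4 frames).
#' @param t0 phase onset time; default the first timestamp.
#' @param y0 starting level; default the first change value.
#' @return \code{list(amplitude, tau, rms, converged)}; a failed fit returns
#'   \code{converged = FALSE} with NA estimates (the raw series is retained
#'   by the caller).
#' @examples
#' t <- 0:12
#' fitExponential(t, -20 * (1 - exp(-t / 3)))
#' @export
fitExponential <- function(time, change, t0 = min(time), y0 = NULL) {
  ok <- is.finite(change)
  time <- time[ok]; change <- change[ok]
  if (length(time) < 4) stop("at least 4 frames are required for the fit")
  if (is.null(y0)) y0 <- change[which.min(time)]
  span <- diff(range(time))
  aStart <- change[which.max(time)] - y0
  if (abs(aStart) < 1e-9) aStart <- 1e-3
  fit <- tryCatch(
    minpack.lm::nlsLM(change ~ y0 + A * (1 - exp(-(time - t0) / tau)),
                      start = list(A = aStart, tau = max(span / 3, 0.1)),
                      lower = c(-Inf, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(amplitude = NA_real_, tau = NA_real_, rms = NA_real_,
                converged = FALSE))
  cf <- stats::coef(fit)
  list(amplitude = unname(cf["A"]), tau = unname(cf["tau"]),
       rms = sqrt(mean(stats::residuals(fit)^2)), converged = TRUE)
}

#' Steady-state time of a response segment
#'
#' The change rate is estimated by centred finite differences smoothed over a
#' 3-frame window; the initial rate is the first window's rate. The steady
#' state is the earliest time at which the absolute rate has decreased below
#' 1\% of the initial rate. For an exact exponential this equals
#' \eqn{t_0 + \tau \ln(100) \approx t_0 + 4.605 \tau}. A zero initial rate
#' (constant series) returns the segment start; a never-decaying rate (e.g. a
#' linear ramp) returns NA ("not reached").
#'
#' @param time,value segment series (>= 3 frames, time increasing).
#' @return Steady-state time in minutes, or NA if not reached.
#' @examples
#' t <- seq(0, 15, by = 0.05)
#' steadyStateTime(t, 1 - exp(-t / 2))  # ~ 2 * log(100) = 9.21
#' @export
steadyStateTime <- function(time, value) {
  ok <- is.finite(value)
  time <- time[ok]; value <- value[ok]
  n <- length(time)
  if (n < 3) stop("at least 3 frames are required")
  mid <- 2:(n - 1)
  rate <- (value[mid + 1] - value[mid - 1]) / (time[mid + 1] - time[mid - 1])
  if (length(rate) >= 3)
    rate <- stats::filter(rate, rep(1 / 3, 3), sides = 2)
  rate <- as.numeric(rate)
  tr <- time[mid]
  ok2 <- is.finite(rate)
  rate <- rate[ok2]; tr <- tr[ok2]
  if (!length(rate)) return(NA_real_)
  r0 <- abs(rate[1])
  if (r0 < 1e-12) return(time[1])
  hit <- which(abs(rate) < 0.01 * r0)
  if (!length(hit)) return(NA_real_)
  tr[hit[1]]
}

#' Per-phase dynamics summary of a response series
#'
#' For every parameter and every challenge/reversal phase: peak change and
#' its time, fitted exponential amplitude and time constant (when at least 4
#' frames are available), and the steady-state time.
#'
#' @param series long data.frame from [buildResponseSeries()].
#' @param scenario the [OsmoticScenario-class] that produced it (defines the
#'   phase windows).
#' @return data.frame: \code{parameter, phase, peak, peakTime, amplitude,
#'   tau, steadyState}.
#' @examples
#' ts <- renderTimeSeries(scenarioControl(), seed = 1, noise = FALSE)
#' summarizeDynamics(buildResponseSeries(ts$truth), scenarioControl())
#' @export
summarizeDynamics <- function(series, scenario) {
  p <- scenario@phases
  bounds <- cumsum(c(0, p$duration))
  out <- list()
  for (par in unique(series$parameter)) {
    s <- series[series$parameter == par, ]
    for (i in seq_len(nrow(p))) {
      w <- c(bounds[i], bounds[i + 1])
      keep <- s$time > w[1] - 1e-9 & s$time <= w[2] + 1e-9
      seg <- s[keep, ]
      if (nrow(seg) < 2) next
      pk <- peakChange(seg$time, seg$change)
      ft <- if (nrow(seg) >= 4)
        fitExponential(seg$time, seg$change, t0 = w[1],
                       y0 = if (i == 1) 0 else NULL)
      else list(amplitude = NA_real_, tau = NA_real_)
      ss <- if (nrow(seg) >= 3) steadyStateTime(seg$time, seg$change)
            else NA_real_
      out[[length(out) + 1]] <-
        data.frame(parameter = par, phase = p$label[i], peak = pk$change,
                   peakTime = pk$time, amplitude = ft$amplitude,
                   tau = ft$tau, steadyState = ss)
    }
  }
  do.call(rbind, out)
}
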