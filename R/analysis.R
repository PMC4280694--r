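#' Time-weighted mean over a cycle window
#'
#' Trapezoidal mean of a sampled series over its time window.
#'
#' @param x numeric series.
#' @param t time grid of the same length.
#' @return the trapezoidal time average.
#' @export
cycleMean <- function(x, t) {
  if (!length(x) || length(x) != length(t))
    tsError("series and time grid must be non-empty and of equal length",
            "talsim_domain_error")
  if (length(x) == 1L) return(x)
  dt <- diff(t)
  sum(dt * (utils::head(x, -1) + utils::tail(x, -1)) / 2) / (t[length(t)] - t[1])
}

#' End-diastolic and end-systolic volume of a ventricular volume trace
#'
#' EDV is the maximum and ESV the minimum over one full cycle (equivalent to
#' valve-event timing for ideal diode valves, and robust at flow reversal).
#'
#' @param v ventricular volume series over one cycle, ml.
#' @return named vector \code{c(EDV =, ESV =)}, ml.
#' @export
edvEsv <- function(v) {
  if (!length(v)) tsError("empty volume series", "talsim_domain_error")
  c(EDV = max(v), ESV = min(v))
}

#' Cardiac output from stroke volume and heart rate
#'
#' \code{CO = (EDV - ESV) * HR / 1000} l/min.
#'
#' @param EDV,ESV end-diastolic and end-systolic volume, ml (EDV >= ESV).
#' @param hr heart rate, bpm.
#' @return cardiac output, l/min.
#' @export
cardiacOutput <- function(EDV, ESV, hr) {
  if (any(EDV < ESV))
    tsError("EDV must be >= ESV", "talsim_domain_error")
  (EDV - ESV) * hr / 1000
}

#' Signed area of a closed x-y loop (shoelace)
#'
#' The curve is closed by joining the last sample back to the first.  The
#' sign encodes orientation (positive = counter-clockwise); take
#' \code{abs()} for the magnitude.
#'
#' @param x,y coordinate series on the same grid (>= 3 points).
#' @return signed polygon area in the product of the axis units.
#' @export
loopArea <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3L)
    tsError("loop area requires at least 3 paired points",
            "talsim_domain_error")
  j <- c(2:n, 1L)
  0.5 * sum(x * y[j] - x[j] * y)
}

#' Signed percentage change from a baseline
#'
#' \code{100 (assisted - baseline) / baseline}.
#'
#' @param baseline reference value (non-zero).
#' @param assisted new value.
#' @return signed percent change.
#' @export
percentChange <- function(baseline, assisted) {
  if (any(baseline == 0))
    tsError("percent change undefined for a zero baseline",
            "talsim_domain_error")
  100 * (assisted - baseline) / baseline
}

#' Per-cycle haemodynamic summary
#'
#' Computes, over the final converged cycle: time-weighted means of main
#' pulmonary arterial, left atrial, systemic venous and aortic pressure and
#' of coronary inflow; LV/RV end-diastolic and end-systolic volumes;
#' cardiac output from the LV stroke volume (systemic output — with a
#' left-atrial TAL return the RV output differs by the shunted volume); and
#' the magnitude of the coronary-blood-flow/aortic-pressure loop area.
#'
#' @param ss a \code{steadyState} (or \code{cvSimResult} covering one cycle).
#' @return a list of class \code{cycleSummary}.
#' @export
cycleSummary <- function(ss) {
  sim <- if (inherits(ss, "steadyState")) ss$result else ss
  stopifnot(inherits(sim, "cvSimResult"))
  ser <- sim$series
  t <- sim$time
  hr <- 60 / sim$network$period
  need <- c("Ppam", "Pla", "Pvs", "Pao", "Qcor", "Vlv", "Vrv")
  miss <- setdiff(need, colnames(ser))
  if (length(miss))
    tsError(sprintf("waveforms missing for summary: %s",
                    paste(miss, collapse = ", ")), "talsim_domain_error")
  lv <- edvEsv(ser[, "Vlv"])
  rv <- edvEsv(ser[, "Vrv"])
  out <- list(
    meanPAP = cycleMean(ser[, "Ppam"], t),
    meanLAP = cycleMean(ser[, "Pla"], t),
    meanSVP = cycleMean(ser[, "Pvs"], t),
    meanAoP = cycleMean(ser[, "Pao"], t),
    meanCBF = cycleMean(ser[, "Qcor"], t),
    LVEDV = unname(lv["EDV"]), LVESV = unname(lv["ESV"]),
    RVEDV = unname(rv["EDV"]), RVESV = unname(rv["ESV"]),
    CO = cardiacOutput(unname(lv["EDV"]), unname(lv["ESV"]), hr),
    CBFAoP = abs(loopArea(ser[, "Pao"], ser[, "Qcor"])),
    hr = hr)
  class(out) <- "cycleSummary"
  out
}

#' @export
print.cycleSummary <- function(x, ...) {
  cat("<cycleSummary>\n")
  cat(sprintf("  mean PAP %6.1f mmHg   mean LAP %6.1f mmHg   mean SVP %5.1f mmHg\n",
              x$meanPAP, x$meanLAP, x$meanSVP))
  cat(sprintf("  mean AoP %6.1f mmHg   CO       %6.2f l/min  HR %6.1f bpm\n",
              x$meanAoP, x$CO, x$hr))
  cat(sprintf("  LVEDV %5.1f  LVESV %5.1f  RVEDV %5.1f  RVESV %5.1f ml\n",
              x$LVEDV, x$LVESV, x$RVEDV, x$RVESV))
  cat(sprintf("  CBF-AoP loop area %8.1f mmHg.ml/s\n", x$CBFAoP))
  invisible(x)
}

## The nine analysed variables of the percent-change report.
.protocolVariables <- c("LVEDV", "LVESV", "RVEDV", "RVESV", "CO",
                        "meanPAP", "meanLAP", "meanSVP", "CBFAoP")

summaryVector <- function(s) {
  vapply(.protocolVariables, function(v) s[[v]], 0)
}
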