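#' Specification of the TAL training-course protocol
#'
#' Full factorial sweep: TAL modes x pulmonary arteriolar resistance
#' settings (CGS units) x inlet-graft compliance x device-chamber
#' compliance, plus one assistance-off baseline per resistance setting.
#'
#' @param modes TAL modes to sweep.
#' @param rparCgs pulmonary arteriolar resistance settings, g·cm^-4·s^-1.
#' @param ctalin inlet graft compliance values, ml/mmHg.
#' @param ctalch device chamber compliance values (applied to both inlet and
#'   outlet chambers), ml/mmHg.
#' @return a list of class \code{protocolSpec}.
#' @export
protocolSpec <- function(modes = c("parallel", "hybrid"),
                         rparCgs = c(240, 120),
                         ctalin = c(1.5, 0.4),
                         ctalch = c(2.0, 0.1)) {
  bad <- setdiff(modes, c("parallel", "series", "hybrid"))
  if (length(bad))
    tsError(sprintf("unknown TAL mode(s): %s", paste(bad, collapse = ", ")),
            "talsim_config_error")
  if (any(rparCgs < 0) || any(ctalin <= 0) || any(ctalch <= 0))
    tsError("protocol values must be positive", "talsim_domain_error")
  structure(list(modes = modes, rparCgs = rparCgs, ctalin = ctalin,
                 ctalch = ctalch),
            class = "protocolSpec")
}

#' Calibrate a pulmonary-hypertensive virtual patient
#'
#' Bisection on a common scale factor applied to the pulmonary arteriolar,
#' capillary and small-PA resistances (with the RV systolic elastance
#' reduced by a fixed fraction) until the steady-state cycle-mean pulmonary
#' arterial pressure reaches the target within 1 mmHg.  The calibrated
#' preset must also show right-ventricular dilation (RVEDV above the normal
#' preset's by at least \code{targetRVdilation}).
#'
#' @param normal the normal \code{\link{patientPreset}}.
#' @param targetPpam target steady-state mean PAP, mmHg (default 35).
#' @param targetRVdilation required fractional RVEDV increase (default 0.2).
#' @param rvEmaxReduction fractional reduction of RV Emax (default 0.3),
#'   representing RV systolic impairment under chronic pressure overload.
#' @param scaleBounds admissible resistance scale range.
#' @param tolPpam acceptance band around the target, mmHg.
#' @param dt,tol,maxCycles integration settings per evaluation.
#' @return a list of class \code{phCalibration}: \code{$preset} (calibrated),
#'   \code{$scale}, \code{$summary}, \code{$normalSummary} and \code{$log}
#'   (audit trail of bisection iterates).
#' @export
calibratePulmonaryHypertension <- function(normal, targetPpam = 35,
                                           targetRVdilation = 0.2,
                                           rvEmaxReduction = 0.3,
                                           scaleBounds = c(1, 20),
                                           tolPpam = 1, dt = 1e-4,
                                           tol = 1e-3, maxCycles = 60L) {
  stopifnot(inherits(normal, "patientPreset"))
  checkScalar(targetPpam, "targetPpam", positive = TRUE)
  baseSum <- cycleSummary(simulatePatient(normal, dt = dt, tol = tol,
                                          maxCycles = maxCycles))
  if (targetPpam < baseSum$meanPAP - tolPpam)
    tsError(sprintf(
      "target mean PAP %.1f mmHg is below the normal preset's %.1f mmHg",
      targetPpam, baseSum$meanPAP), "talsim_calibration_error")

  applyScale <- function(s) {
    p <- normal
    p$pulmonary$Rpar <- normal$pulmonary$Rpar * s
    p$pulmonary$Rpc <- normal$pulmonary$Rpc * s
    p$pulmonary$Rpas <- normal$pulmonary$Rpas * s
    p$heart$rv$Emax <- normal$heart$rv$Emax * (1 - rvEmaxReduction)
    p$label <- sprintf("pulmonary-hypertension (scale %.3f)", s)
    p
  }
  log <- data.frame(iter = integer(), scale = numeric(),
                    meanPAP = numeric(), RVEDV = numeric())
  iter <- 0L
  evalScale <- function(s) {
    sm <- cycleSummary(simulatePatient(applyScale(s), dt = dt, tol = tol,
                                       maxCycles = maxCycles))
    iter <<- iter + 1L
    log <<- rbind(log, data.frame(iter = iter, scale = s,
                                  meanPAP = sm$meanPAP, RVEDV = sm$RVEDV))
    sm
  }

  lo <- scaleBounds[1]; hi <- scaleBounds[2]
  smLo <- evalScale(lo)
  if (abs(smLo$meanPAP - targetPpam) <= tolPpam) {
    s <- lo; sm <- smLo
  } else {
    smHi <- evalScale(hi)
    if (smHi$meanPAP < targetPpam - tolPpam)
      tsError(sprintf(
        "target mean PAP %.1f mmHg unreachable within scale bounds [%g, %g] (achieved %.1f mmHg)",
        targetPpam, scaleBounds[1], scaleBounds[2], smHi$meanPAP),
        "talsim_calibration_error", achieved = smHi$meanPAP)
    sm <- smHi; s <- hi
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      smMid <- evalScale(mid)
      if (abs(smMid$meanPAP - targetPpam) <= tolPpam) {
        s <- mid; sm <- smMid; break
      }
      if (smMid$meanPAP < targetPpam) lo <- mid else hi <- mid
      s <- mid; sm <- smMid
      if (hi - lo < 1e-3) break
    }
    if (abs(sm$meanPAP - targetPpam) > tolPpam)
      tsError(sprintf(
        "bisection did not settle within %.1f mmHg of the target (achieved %.1f)",
        tolPpam, sm$meanPAP), "talsim_calibration_error",
        achieved = sm$meanPAP)
  }
  if (sm$RVEDV < (1 + targetRVdilation) * baseSum$RVEDV &&
      abs(targetPpam - baseSum$meanPAP) > tolPpam)
    tsError(sprintf(
      "calibrated RVEDV %.1f ml does not exceed the normal %.1f ml by %.0f%%",
      sm$RVEDV, baseSum$RVEDV, 100 * targetRVdilation),
      "talsim_calibration_error")

  structure(list(preset = applyScale(s), scale = s, summary = sm,
                 normalSummary = baseSum, log = log),
            class = "phCalibration")
}

#' @export
print.phCalibration <- function(x, ...) {
  cat("<phCalibration> resistance scale ", format(x$scale, digits = 4),
      ", mean PAP ", format(x$summary$meanPAP, digits = 3), " mmHg (normal ",
      format(x$normalSummary$meanPAP, digits = 3), "), RVEDV ",
      format(x$summary$RVEDV, digits = 4), " ml (normal ",
      format(x$normalSummary$RVEDV, digits = 4), "), ",
      nrow(x$log), " evaluations\n", sep = "")
  invisible(x)
}

#' Run the three-step TAL assistance protocol
#'
#' For each pulmonary arteriolar resistance setting: run the assistance-off
#' baseline to periodic steady state, then every (mode x compliance)
#' combination, and report the signed percentage change of the nine analysed
#' variables against the matching-resistance baseline (per-resistance
#' baselining isolates the TAL effect from the drug effect).
#'
#' @param patient a calibrated \code{\link{patientPreset}}.
#' @param spec a \code{\link{protocolSpec}}.
#' @param dt,tol,maxCycles integration settings per run.
#' @param verbose print progress to stderr.
#' @return a data frame of class \code{percentChangeTable}: one baseline row
#'   (all zeros) per resistance setting plus one row per assisted run, with
#'   the absolute cycle summaries attached as attribute \code{"summaries"}.
#' @export
runProtocol <- function(patient, spec = protocolSpec(), dt = 1e-4,
                        tol = 1e-3, maxCycles = 60L, verbose = FALSE) {
  stopifnot(inherits(patient, "patientPreset"),
            inherits(spec, "protocolSpec"))
  rows <- list(); sums <- list()
  talBase <- if (is.null(patient$tal)) talParams() else patient$tal

  runCell <- function(p, label) {
    if (verbose) message("  running ", label)
    tryCatch(cycleSummary(simulatePatient(p, dt = dt, tol = tol,
                                          maxCycles = maxCycles)),
             talsim_convergence_error = function(e)
               tsError(sprintf("protocol cell '%s' did not converge: %s",
                               label, conditionMessage(e)),
                       "talsim_convergence_error"))
  }

  for (rp in spec$rparCgs) {
    base <- setParameter(patient, "Rpar", rp, units = "g.cm-4.s-1")
    base$tal <- NULL
    key <- sprintf("off|%g|baseline", rp)
    baseSum <- runCell(base, key)
    sums[[key]] <- baseSum
    rows[[key]] <- data.frame(mode = "off", rparCgs = rp, CTALin = NA_real_,
                              CTALch = NA_real_,
                              t(stats::setNames(numeric(
                                length(.protocolVariables)),
                                .protocolVariables)))
    bvec <- summaryVector(baseSum)
    for (mode in spec$modes) for (cin in spec$ctalin)
      for (cch in spec$ctalch) {
        p <- base
        p$tal <- configureTal(talParams(CTALin = cin, CTALad = cch,
                                        CTALap = cch,
                                        RTALpab = talBase$RTALpab),
                              mode)
        key <- sprintf("%s|%g|Cin%g|Cch%g", mode, rp, cin, cch)
        sm <- runCell(p, key)
        sums[[key]] <- sm
        pc <- percentChange(bvec, summaryVector(sm))
        rows[[key]] <- data.frame(mode = mode, rparCgs = rp, CTALin = cin,
                                  CTALch = cch, t(pc))
      }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "summaries") <- sums
  class(tab) <- c("percentChangeTable", "data.frame")
  tab
}

#' @export
print.percentChangeTable <- function(x, digits = 2, ...) {
  cat("<percentChangeTable> ", nrow(x), " rows (signed % vs the matching",
      " assistance-off baseline)\n", sep = "")
  y <- as.data.frame(x)
  y[.protocolVariables] <- lapply(y[.protocolVariables], round,
                                  digits = digits)
  print(y, ...)
  invisible(x)
}

#' Export a percent-change table (or waveform summary table) as CSV
#'
#' One header row; columns are the protocol factors followed by the nine
#' analysed variables.
#'
#' @param table a \code{percentChangeTable}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportTable <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Check the protocol results against the expected response directions
#'
#' For parallel assistance at the high pulmonary arteriolar resistance
#' setting (240 g·cm^-4·s^-1), every compliance combination must show:
#' LVEDV and LVESV increased, RVEDV and RVESV decreased, CO increased, mean
#' PAP decreased, CBF-AoP loop area increased and mean LAP increased (the
#' right ventricle is unloaded into the left heart).  Additionally the
#' best-case hybrid mean-PAP reduction must exceed the best-case parallel
#' reduction at the same resistance.
#'
#' @param table a \code{percentChangeTable} from \code{\link{runProtocol}}.
#' @param rparCgs the resistance setting to examine, g·cm^-4·s^-1.
#' @return a list of class \code{directionalCheck} with a per-comparison
#'   data frame (\code{$checks}) and \code{$passed}.
#' @export
directionalCheck <- function(table, rparCgs = 240) {
  stopifnot(inherits(table, "percentChangeTable"))
  par <- table[table$mode == "parallel" & table$rparCgs == rparCgs, ]
  hyb <- table[table$mode == "hybrid" & table$rparCgs == rparCgs, ]
  if (!nrow(par))
    tsError("table contains no parallel-mode rows at the requested setting",
            "talsim_domain_error")
  expected <- c(LVEDV = 1, LVESV = 1, RVEDV = -1, RVESV = -1, CO = 1,
                meanPAP = -1, CBFAoP = 1, meanLAP = 1)
  checks <- do.call(rbind, lapply(names(expected), function(v) {
    vals <- par[[v]]
    data.frame(check = sprintf("parallel %s %s", v,
                               if (expected[[v]] > 0) "increases"
                               else "decreases"),
               min = min(vals), max = max(vals),
               pass = all(sign(vals) == expected[[v]]))
  }))
  if (nrow(hyb)) {
    hRed <- max(-hyb$meanPAP); pRed <- max(-par$meanPAP)
    checks <- rbind(checks, data.frame(
      check = "hybrid mean-PAP reduction exceeds parallel",
      min = pRed, max = hRed, pass = hRed > pRed))
  }
  structure(list(checks = checks, passed = all(checks$pass),
                 rparCgs = rparCgs),
            class = "directionalCheck")
}

#' @export
print.directionalCheck <- function(x, ...) {
  cat("<directionalCheck> at Rpar ", x$rparCgs, " g.cm-4.s-1: ",
      if (x$passed) "all checks pass" else "FAILURES present", "\n",
      sep = "")
  df <- x$checks
  df$min <- round(df$min, 2); df$max <- round(df$max, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
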