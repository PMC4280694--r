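#' Convert a CGS vascular resistance to internal units
#'
#' Converts g·cm^-4·s^-1 (identically dyn·s/cm^5) to mmHg·s/ml using
#' 1 mmHg = 1333.22 dyn/cm^2.
#'
#' @param Rcgs resistance in g·cm^-4·s^-1 (>= 0).
#' @return resistance in mmHg·s/ml.
#' @export
cgsResistance <- function(Rcgs) {
  if (any(!is.finite(Rcgs)) || any(Rcgs < 0))
    tsError("CGS resistance must be finite and >= 0", "talsim_domain_error")
  Rcgs / 1333.22
}

#' Intramyocardial squeezing pressure
#'
#' The external pressure compressing the intramyocardial compliance in the
#' intramyocardial-pump coronary model: \code{P_im = gamma * P_lv}, so
#' coronary inflow is impeded during systole.
#'
#' @param Plv instantaneous left-ventricular pressure, mmHg.
#' @param gamma coupling coefficient in [0, 1].
#' @return squeezing pressure, mmHg.
#' @export
intramyocardialPressure <- function(Plv, gamma) {
  if (any(gamma < 0 | gamma > 1))
    tsError("'gamma' must be in [0, 1]", "talsim_domain_error")
  gamma * Plv
}

#' Systemic circulation parameters
#'
#' Three-element windkessel afterload (characteristic resistance Rcs in
#' series with the arterial compliance Cas in parallel with the peripheral
#' resistance Ras) plus an RC venous compartment.
#'
#' @param Rcs characteristic (proximal aortic) resistance, mmHg·s/ml.
#' @param Cas systemic arterial compliance, ml/mmHg.
#' @param Ras systemic peripheral arterial resistance, mmHg·s/ml (settable).
#' @param Rvs systemic venous resistance, mmHg·s/ml (settable).
#' @param Cvs systemic venous compliance, ml/mmHg.
#' @return a list of class \code{systemicParams}.
#' @export
systemicParams <- function(Rcs = 0.05, Cas = 1.3, Ras = 0.9, Rvs = 0.05,
                           Cvs = 80) {
  for (v in c(Rcs, Cas, Ras, Rvs, Cvs)) checkScalar(v, "systemic parameter",
                                                    positive = TRUE)
  structure(list(Rcs = Rcs, Cas = Cas, Ras = Ras, Rvs = Rvs, Cvs = Cvs),
            class = "systemicParams")
}

#' Pulmonary circulation parameters
#'
#' RLC main and small pulmonary artery segments, a single lumped arteriolar
#' and capillary resistance, and an RC pulmonary venous compartment.
#'
#' @param Rpam,Lpam,Cpam main pulmonary artery resistance (mmHg·s/ml),
#'   inertance (mmHg·s^2/ml) and compliance (ml/mmHg).
#' @param Rpas,Lpas,Cpas the same for the small pulmonary artery segment.
#' @param Rpar pulmonary arteriolar resistance, mmHg·s/ml.
#' @param Rpc pulmonary capillary resistance, mmHg·s/ml.
#' @param Rvp,Cvp pulmonary venous resistance and compliance.
#' @return a list of class \code{pulmonaryParams}.
#' @export
pulmonaryParams <- function(Rpam = 0.01, Lpam = 5e-4, Cpam = 2.0,
                            Rpas = 0.01, Lpas = 5e-4, Cpas = 2.0,
                            Rpar = 0.04, Rpc = 0.02, Rvp = 0.01, Cvp = 15) {
  for (v in c(Rpam, Lpam, Cpam, Rpas, Lpas, Cpas, Rpar, Rpc, Rvp, Cvp))
    checkScalar(v, "pulmonary parameter", positive = TRUE)
  structure(list(Rpam = Rpam, Lpam = Lpam, Cpam = Cpam, Rpas = Rpas,
                 Lpas = Lpas, Cpas = Cpas, Rpar = Rpar, Rpc = Rpc,
                 Rvp = Rvp, Cvp = Cvp),
            class = "pulmonaryParams")
}

#' Coronary circulation parameters (intramyocardial pump)
#'
#' The coronary branch taps the systemic arterial node, fills an
#' intramyocardial compliance squeezed by \code{gamma * Plv}, and drains to
#' the right atrium.
#'
#' @param Rcorin coronary inflow resistance, mmHg·s/ml.
#' @param Ccor intramyocardial compliance, ml/mmHg.
#' @param Rcorout coronary outflow resistance, mmHg·s/ml.
#' @param gamma intramyocardial coupling coefficient in [0, 1].
#' @return a list of class \code{coronaryParams}.
#' @export
coronaryParams <- function(Rcorin = 12, Ccor = 0.15, Rcorout = 8,
                           gamma = 0.75) {
  for (v in c(Rcorin, Ccor, Rcorout)) checkScalar(v, "coronary parameter",
                                                  positive = TRUE)
  checkScalar(gamma, "gamma", nonneg = TRUE)
  if (gamma > 1) tsError("'gamma' must be in [0, 1]", "talsim_domain_error")
  structure(list(Rcorin = Rcorin, Ccor = Ccor, Rcorout = Rcorout,
                 gamma = gamma),
            class = "coronaryParams")
}

#' Assemble a complete virtual-patient preset
#'
#' @param label preset name.
#' @param heart a \code{\link{heartParams}}.
#' @param systemic a \code{\link{systemicParams}}.
#' @param pulmonary a \code{\link{pulmonaryParams}}.
#' @param coronary a \code{\link{coronaryParams}}.
#' @param Pt mean intrathoracic pressure, mmHg.
#' @param bloodVolume total blood volume, ml (bookkeeping: the systemic
#'   venous unstressed volume absorbs the slack so that the initial stored
#'   volume equals this value).
#' @param tal optional \code{\link{talParams}} block.
#' @return a list of class \code{patientPreset}.
#' @export
patientPreset <- function(label = "custom", heart = heartParams(),
                          systemic = systemicParams(),
                          pulmonary = pulmonaryParams(),
                          coronary = coronaryParams(), Pt = -4,
                          bloodVolume = 5300, tal = NULL) {
  checkScalar(Pt, "Pt")
  checkScalar(bloodVolume, "bloodVolume", positive = TRUE)
  if (!is.null(tal) && !inherits(tal, "talParams"))
    tsError("'tal' must be NULL or a talParams object", "talsim_domain_error")
  p <- structure(list(label = label, heart = heart, systemic = systemic,
                      pulmonary = pulmonary, coronary = coronary, Pt = Pt,
                      bloodVolume = bloodVolume, tal = tal),
                 class = "patientPreset")
  attr(p, "changeLog") <- data.frame(symbol = character(),
                                     value = numeric(),
                                     units = character(),
                                     stringsAsFactors = FALSE)
  p
}

#' Built-in virtual patient: normal adult
#'
#' Calibration values placing the resting preset in textbook ranges
#' (mean aortic pressure 70-105 mmHg, cardiac output 4-6.5 l/min at 75 bpm).
#'
#' @return a \code{\link{patientPreset}}.
#' @export
normalPreset <- function() {
  patientPreset(label = "normal")
}

#' @export
print.patientPreset <- function(x, ...) {
  cat("<patientPreset> '", x$label, "': HR ", x$heart$hr, " bpm, Pt ",
      x$Pt, " mmHg, blood volume ", x$bloodVolume, " ml, TAL ",
      if (is.null(x$tal)) "none" else x$tal$mode, "\n", sep = "")
  n <- nrow(attr(x, "changeLog"))
  if (!is.null(n) && n > 0) cat("  parameter changes logged:", n, "\n")
  invisible(x)
}

## Default initial node pressures (mmHg) and chamber volumes (ml) used to
## seed the integration; overridable through initialState().
defaultInitialPressures <- function(preset) {
  pam <- 16
  list(sa = 80, vs = 4.5, pam = pam, pas = 14, vp = 8, cor = 50,
       talin = pam, talad = pam, talap = pam)
}

defaultInitialVolumes <- function(preset) {
  list(LA = 55, LV = 130, RA = 55, RV = 130)
}

## Fixed unstressed volumes (ml); the systemic venous compartment absorbs the
## remainder so that the implied initial stored volume equals bloodVolume.
unstressedVolumes <- function(preset) {
  pr <- defaultInitialPressures(preset)
  vol <- defaultInitialVolumes(preset)
  sy <- preset$systemic; pu <- preset$pulmonary; co <- preset$coronary
  Pt <- preset$Pt
  fixed <- c(sa = 600, pam = 30, pas = 30, vp = 350, cor = 5,
             talin = 0, talad = 0, talap = 0)
  stressed <- c(sa = sy$Cas * pr$sa,
                vs = sy$Cvs * pr$vs,
                pam = pu$Cpam * (pr$pam - Pt),
                pas = pu$Cpas * (pr$pas - Pt),
                vp = pu$Cvp * (pr$vp - Pt),
                cor = co$Ccor * pr$cor)
  ## the TAL adds its own priming volume on top of the patient's blood
  ## volume, so its stressed volume is not budgeted against Cvs
  used <- sum(fixed[c("sa", "pam", "pas", "vp", "cor")]) + sum(stressed) +
    sum(unlist(vol))
  vuVs <- preset$bloodVolume - used
  if (vuVs < 0)
    tsError(sprintf(
      "total blood volume %g ml is below the stressed volume implied by the initial pressures (%g ml)",
      preset$bloodVolume, used), "talsim_domain_error")
  c(fixed, vs = unname(vuVs))
}

#' Build the full cardiovascular network from a preset
#'
#' Creates the complete electrical analogue: four variable-elastance
#' chambers with diode valves, three-element windkessel systemic arterial
#' section, RC systemic venous section, RLC main/small pulmonary artery
#' segments, lumped arteriolar+capillary resistance, RC pulmonary venous
#' section, the intramyocardial-pump coronary branch, and (when configured)
#' the thoracic artificial lung.  Heart chambers, pulmonary compartments and
#' TAL chambers reference intrathoracic pressure; systemic compliances
#' reference ambient.
#'
#' @param preset a \code{\link{patientPreset}}.
#' @return a \code{\link{cvNetwork}} whose waveform names follow the standard
#'   symbols (Pla, Plv, Ppam, Qli, Qro, ...).  Aortic pressure \code{Pao} is
#'   the systemic arterial storage-node pressure.
#' @export
buildNetwork <- function(preset) {
  stopifnot(inherits(preset, "patientPreset"))
  h <- preset$heart; sy <- preset$systemic; pu <- preset$pulmonary
  co <- preset$coronary
  period <- h$period
  vu <- unstressedVolumes(preset)
  aOnset <- period - h$prDelay

  els <- list(
    chamberElement("LA", "la", h$la$Emax, h$la$Emin, h$la$V0, aOnset,
                   h$TsysA, volumeName = "Vla"),
    chamberElement("LV", "lv", h$lv$Emax, h$lv$Emin, h$lv$V0, 0, h$TsysV,
                   volumeName = "Vlv"),
    chamberElement("RA", "ra", h$ra$Emax, h$ra$Emin, h$ra$V0, aOnset,
                   h$TsysA, volumeName = "Vra"),
    chamberElement("RV", "rv", h$rv$Emax, h$rv$Emin, h$rv$V0, 0, h$TsysV,
                   volumeName = "Vrv"),
    capacitorElement("Cas", "sa", sy$Cas, ext = "ambient", Vu = vu[["sa"]],
                     volumeName = "Vas"),
    capacitorElement("Cvs", "vs", sy$Cvs, ext = "ambient", Vu = vu[["vs"]],
                     volumeName = "Vvs"),
    capacitorElement("Cpam", "pam", pu$Cpam, ext = "intrathoracic",
                     Vu = vu[["pam"]], volumeName = "Vpam"),
    capacitorElement("Cpas", "pas", pu$Cpas, ext = "intrathoracic",
                     Vu = vu[["pas"]], volumeName = "Vpas"),
    capacitorElement("Cvp", "vp", pu$Cvp, ext = "intrathoracic",
                     Vu = vu[["vp"]], volumeName = "Vvp"),
    capacitorElement("Ccor", "cor", co$Ccor, ext = "intramyocardial",
                     Vu = vu[["cor"]], volumeName = "Vcor"),
    resistorElement("Rli", "la", "lv", h$Rli, sub = "diode",
                    flowName = "Qli"),
    ## aortic valve in series with the windkessel characteristic resistance
    resistorElement("Rlo", "lv", "sa", h$Rlo + sy$Rcs, sub = "diode",
                    flowName = "Qlo"),
    resistorElement("Rri", "ra", "rv", h$Rri, sub = "diode",
                    flowName = "Qri"),
    resistorElement("Rro", "rv", "pam", h$Rro, sub = "diode",
                    flowName = "Qro"),
    resistorElement("Ras", "sa", "vs", sy$Ras, flowName = "Qas"),
    resistorElement("Rvs", "vs", "ra", sy$Rvs, flowName = "Qria"),
    resistorElement("Rvp", "vp", "la", pu$Rvp, flowName = "Qlia"),
    resistorElement("Rcorin", "sa", "cor", co$Rcorin, flowName = "Qcor"),
    resistorElement("Rcorout", "cor", "ra", co$Rcorout,
                    sub = "waterfall", flowName = "QcorOut"),
    inductorElement("Lpam", "pam", "pas", pu$Lpam, R = pu$Rpam,
                    flowName = "Qpam"),
    ## small PA segment lumped with the arteriolar + capillary resistances
    inductorElement("Lpas", "pas", "vp", pu$Lpas,
                    R = pu$Rpas + pu$Rpar + pu$Rpc, flowName = "Qpas"))

  pn <- c(la = "Pla", lv = "Plv", ra = "Pra", rv = "Prv", sa = "Pao",
          vs = "Pvs", pam = "Ppam", pas = "Ppas", vp = "Pvp", cor = "Pcor",
          talin = "PTALin", talad = "PTALad", talap = "PTALap")
  net <- cvNetwork(els, period = period, Pt = preset$Pt, gamma = co$gamma,
                   septal = h$septal, pressureNames = pn)
  if (!is.null(preset$tal)) net <- attachTal(net, preset$tal, vu = vu)
  net
}

#' Initial state for a preset's network
#'
#' Builds the state vector from the default (or overridden) initial node
#' pressures and chamber volumes; the total stored volume matches the
#' preset's blood volume within 1 ml by construction.
#'
#' @param preset a \code{\link{patientPreset}}.
#' @param network the network built from the preset (rebuilt if omitted).
#' @param pressures named list of initial node-pressure overrides, mmHg.
#' @param volumes named list of initial chamber-volume overrides, ml.
#' @return named numeric state vector.
#' @export
initialState <- function(preset, network = buildNetwork(preset),
                         pressures = list(), volumes = list()) {
  pr <- utils::modifyList(defaultInitialPressures(preset), pressures)
  vol <- utils::modifyList(defaultInitialVolumes(preset), volumes)
  stateTemplate(network, pressures = pr, volumes = vol)
}

#' Simulate a virtual patient to periodic steady state
#'
#' Convenience wrapper: builds the network, seeds the initial state and runs
#' \code{\link{runToSteadyState}}.
#'
#' @param preset a \code{\link{patientPreset}}.
#' @param dt,tol,maxCycles,divergenceBound passed to
#'   \code{\link{runToSteadyState}}.
#' @param pressures,volumes initial-condition overrides, see
#'   \code{\link{initialState}}.
#' @return a \code{steadyState} object with the preset attached.
#' @export
simulatePatient <- function(preset, dt = 1e-4, tol = 1e-3, maxCycles = 60L,
                            divergenceBound = 1e5, pressures = list(),
                            volumes = list()) {
  net <- buildNetwork(preset)
  s0 <- initialState(preset, net, pressures = pressures, volumes = volumes)
  ss <- runToSteadyState(net, s0, dt = dt, tol = tol, maxCycles = maxCycles,
                         divergenceBound = divergenceBound)
  ss$preset <- preset
  ss
}

## symbol -> (component, field) map for set/get of preset parameters
.symbolMap <- local({
  m <- rbind(
    c("Rli", "heart", "Rli", "R"), c("Rlo", "heart", "Rlo", "R"),
    c("Rri", "heart", "Rri", "R"), c("Rro", "heart", "Rro", "R"),
    c("HR", "heart", "hr", "bpm"),
    c("Rcs", "systemic", "Rcs", "R"), c("Cas", "systemic", "Cas", "C"),
    c("Ras", "systemic", "Ras", "R"), c("Rvs", "systemic", "Rvs", "R"),
    c("Cvs", "systemic", "Cvs", "C"),
    c("Rpam", "pulmonary", "Rpam", "R"),
    c("Lpam", "pulmonary", "Lpam", "L"),
    c("Cpam", "pulmonary", "Cpam", "C"),
    c("Rpas", "pulmonary", "Rpas", "R"),
    c("Lpas", "pulmonary", "Lpas", "L"),
    c("Cpas", "pulmonary", "Cpas", "C"),
    c("Rpar", "pulmonary", "Rpar", "R"),
    c("Rpc", "pulmonary", "Rpc", "R"),
    c("Rvp", "pulmonary", "Rvp", "R"),
    c("Cvp", "pulmonary", "Cvp", "C"),
    c("Rcorin", "coronary", "Rcorin", "R"),
    c("Ccor", "coronary", "Ccor", "C"),
    c("Rcorout", "coronary", "Rcorout", "R"),
    c("gamma", "coronary", "gamma", "1"),
    c("Pt", ".", "Pt", "mmHg"),
    c("bloodVolume", ".", "bloodVolume", "ml"),
    c("RTALin", "tal", "RTALin", "R"), c("LTALin", "tal", "LTALin", "L"),
    c("CTALin", "tal", "CTALin", "C"), c("CTALad", "tal", "CTALad", "C"),
    c("CTALap", "tal", "CTALap", "C"),
    c("RTALad", "tal", "RTALad0", "R"),
    c("RTALap", "tal", "RTALap0", "R"),
    c("RTALala", "tal", "RTALala", "R"),
    c("LTALala", "tal", "LTALala", "L"),
    c("RTALan", "tal", "RTALan", "R"), c("LTALan", "tal", "LTALan", "L"),
    c("RTALpab", "tal", "RTALpab", "R"))
  data.frame(symbol = m[, 1], component = m[, 2], field = m[, 3],
             unitClass = m[, 4], stringsAsFactors = FALSE)
})

.unitAliases <- list(
  R = c("mmHg.s/ml", "mmHg.s.ml-1"),
  C = c("ml/mmHg", "ml.mmHg-1"),
  L = c("mmHg.s2/ml", "mmHg.s2.ml-1"),
  bpm = "bpm", mmHg = "mmHg", ml = "ml", `1` = c("1", "dimensionless"))

#' Set a model parameter on a preset by symbol
#'
#' Returns an updated copy of the preset; the original is untouched and the
#' change is appended to the preset's change log.  Resistances may be given
#' in CGS units (\code{units = "g.cm-4.s-1"}), in which case they are
#' converted on assignment.
#'
#' @param preset a \code{\link{patientPreset}}.
#' @param symbol parameter symbol, e.g. \code{"Rpar"}, \code{"Cvs"},
#'   \code{"CTALin"}, \code{"HR"}.
#' @param value new value.
#' @param units optional unit string; must be compatible with the symbol.
#' @return the updated preset.
#' @export
setParameter <- function(preset, symbol, value, units = NULL) {
  stopifnot(inherits(preset, "patientPreset"))
  i <- match(symbol, .symbolMap$symbol)
  if (is.na(i))
    tsError(sprintf("unknown parameter symbol '%s'; valid symbols: %s",
                    symbol, paste(.symbolMap$symbol, collapse = ", ")),
            "talsim_config_error")
  uc <- .symbolMap$unitClass[i]
  if (!is.null(units)) {
    if (uc == "R" && units %in% c("g.cm-4.s-1", "dyn.s/cm5", "CGS")) {
      value <- cgsResistance(value)
    } else if (!(units %in% .unitAliases[[uc]])) {
      tsError(sprintf("units '%s' are not valid for '%s' (expected %s)",
                      units, symbol,
                      paste(.unitAliases[[uc]], collapse = " or ")),
              "talsim_unit_error")
    }
  }
  checkScalar(value, symbol)
  comp <- .symbolMap$component[i]; field <- .symbolMap$field[i]
  if (comp == ".") {
    preset[[field]] <- value
  } else {
    if (comp == "tal" && is.null(preset$tal))
      tsError(sprintf("cannot set '%s': preset has no TAL block", symbol),
              "talsim_config_error")
    preset[[comp]][[field]] <- value
    if (symbol == "HR") preset$heart$period <- 60 / value
  }
  log <- attr(preset, "changeLog")
  attr(preset, "changeLog") <- rbind(log, data.frame(
    symbol = symbol, value = value,
    units = if (is.null(units)) NA_character_ else units,
    stringsAsFactors = FALSE))
  preset
}

#' Read a model parameter from a preset by symbol
#'
#' @inheritParams setParameter
#' @return the current value (internal units).
#' @export
getParameter <- function(preset, symbol) {
  i <- match(symbol, .symbolMap$symbol)
  if (is.na(i))
    tsError(sprintf("unknown parameter symbol '%s'", symbol),
            "talsim_config_error")
  comp <- .symbolMap$component[i]; field <- .symbolMap$field[i]
  if (comp == ".") preset[[field]] else preset[[comp]][[field]]
}
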