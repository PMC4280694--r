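.configKeys <- c("preset", "parameters", "tal", "rparCgs", "dt", "tol",
                 "maxCycles", "divergenceBound", "recordEvery", "output")
.talConfigKeys <- c("mode", "RTALin", "LTALin", "CTALin", "CTALad",
                    "RTALad0", "kad", "CTALap", "RTALap0", "kap", "RTALala",
                    "LTALala", "RTALan", "LTALan", "RTALpab", "disabled")
.outputKeys <- c("waveforms", "summary", "table", "log")

#' Load a run configuration file
#'
#' YAML configuration describing one run: a preset reference (built-in name
#' or inline parameter overrides keyed by model symbol), an optional TAL
#' block, the pulmonary arteriolar resistance in CGS units, and solver
#' settings.  Unknown keys are rejected; defaults are filled in.
#'
#' @param path path to a YAML file.
#' @return a list of class \code{runConfig} with a resolved
#'   \code{\link{patientPreset}} in \code{$preset}.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path))
    tsError(sprintf("config file '%s' does not exist", path),
            "talsim_config_error")
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), .configKeys)
  if (length(bad))
    tsError(sprintf("unknown config key(s): %s (valid keys: %s)",
                    paste(bad, collapse = ", "),
                    paste(.configKeys, collapse = ", ")),
            "talsim_config_error")
  presetRef <- raw$preset
  if (is.null(presetRef)) presetRef <- "normal"
  preset <- if (is.character(presetRef)) {
    getPreset(presetRef)
  } else if (inherits(presetRef, "patientPreset")) presetRef else {
    tsError("'preset' must name a built-in preset", "talsim_config_error")
  }
  for (sym in names(raw$parameters)) {
    spec <- raw$parameters[[sym]]
    if (is.list(spec)) {
      preset <- setParameter(preset, sym, spec$value, units = spec$units)
    } else preset <- setParameter(preset, sym, spec)
  }
  if (!is.null(raw$rparCgs))
    preset <- setParameter(preset, "Rpar", raw$rparCgs,
                           units = "g.cm-4.s-1")
  if (!is.null(raw$tal)) {
    bad <- setdiff(names(raw$tal), .talConfigKeys)
    if (length(bad))
      tsError(sprintf("unknown TAL config key(s): %s (valid keys: %s)",
                      paste(bad, collapse = ", "),
                      paste(.talConfigKeys, collapse = ", ")),
              "talsim_config_error")
    preset$tal <- do.call(talParams, raw$tal)
  }
  out <- raw$output
  if (!is.null(out)) {
    bad <- setdiff(names(out), .outputKeys)
    if (length(bad))
      tsError(sprintf("unknown output key(s): %s",
                      paste(bad, collapse = ", ")), "talsim_config_error")
  }
  cfg <- list(preset = preset,
              dt = if (is.null(raw$dt)) 1e-4 else raw$dt,
              tol = if (is.null(raw$tol)) 1e-3 else raw$tol,
              maxCycles = if (is.null(raw$maxCycles)) 60L
                          else as.integer(raw$maxCycles),
              divergenceBound = if (is.null(raw$divergenceBound)) 1e5
                                else raw$divergenceBound,
              recordEvery = if (is.null(raw$recordEvery)) 1L
                            else as.integer(raw$recordEvery),
              output = out, source = normalizePath(path))
  checkScalar(cfg$dt, "dt", positive = TRUE)
  checkScalar(cfg$tol, "tol", nonneg = TRUE)
  class(cfg) <- "runConfig"
  cfg
}

#' Built-in presets
#'
#' \code{listPresets()} names the presets shipped with the package;
#' \code{getPreset()} instantiates one.  The pathological preset is the
#' pulmonary-hypertensive patient produced by
#' \code{\link{calibratePulmonaryHypertension}} with its default targets.
#'
#' @param name preset name.
#' @return a character vector, or a \code{\link{patientPreset}}.
#' @export
listPresets <- function() c("normal", "pulmonary-hypertension")

#' @rdname listPresets
#' @export
getPreset <- function(name) {
  switch(name,
         "normal" = normalPreset(),
         "pulmonary-hypertension" =
           calibratePulmonaryHypertension(normalPreset())$preset,
         tsError(sprintf("unknown preset '%s'; built-ins: %s", name,
                         paste(listPresets(), collapse = ", ")),
                 "talsim_config_error"))
}

#' Serialise a preset to YAML (and read it back)
#'
#' The file is keyed by the model's parameter symbols, grouped by section.
#'
#' @param preset a \code{\link{patientPreset}}.
#' @param path output path.
#' @return \code{writePreset}: the path, invisibly; \code{readPreset}: the
#'   preset.
#' @export
writePreset <- function(preset, path) {
  stopifnot(inherits(preset, "patientPreset"))
  h <- preset$heart
  doc <- list(
    label = preset$label,
    heart = list(HR = h$hr,
                 lv = h$lv, rv = h$rv, la = h$la, ra = h$ra,
                 Rli = h$Rli, Rlo = h$Rlo, Rri = h$Rri, Rro = h$Rro,
                 septal = h$septal, TsysV = h$TsysV, prDelay = h$prDelay),
    systemic = unclass(preset$systemic),
    pulmonary = unclass(preset$pulmonary),
    coronary = unclass(preset$coronary),
    Pt = preset$Pt, bloodVolume = preset$bloodVolume)
  if (!is.null(preset$tal)) doc$tal <- unclass(preset$tal)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname writePreset
#' @export
readPreset <- function(path) {
  if (!file.exists(path))
    tsError(sprintf("preset file '%s' does not exist", path),
            "talsim_config_error")
  doc <- yaml::read_yaml(path)
  h <- doc$heart
  tal <- if (!is.null(doc$tal)) {
    doc$tal$disabled <- as.character(unlist(doc$tal$disabled))
    do.call(talParams, doc$tal)
  }
  patientPreset(
    label = doc$label,
    heart = heartParams(hr = h$HR, lv = h$lv, rv = h$rv, la = h$la,
                        ra = h$ra, Rli = h$Rli, Rlo = h$Rlo, Rri = h$Rri,
                        Rro = h$Rro, septal = h$septal, TsysV = h$TsysV,
                        prDelay = h$prDelay),
    systemic = do.call(systemicParams, doc$systemic),
    pulmonary = do.call(pulmonaryParams, doc$pulmonary),
    coronary = do.call(coronaryParams, doc$coronary),
    Pt = doc$Pt, bloodVolume = doc$bloodVolume, tal = tal)
}

#' Export simulated waveforms as CSV
#'
#' Plain comma-separated values with a dot decimal separator: first column
#' the time in s, then one column per named waveform.  Values are written
#' with 17 significant digits so the file round-trips losslessly.
#'
#' @param result a \code{cvSimResult} or \code{steadyState}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportWaveforms <- function(result, path) {
  sim <- if (inherits(result, "steadyState")) result$result else result
  stopifnot(inherits(sim, "cvSimResult"))
  con <- tryCatch(file(path, "w"),
                  error = function(e)
                    tsError(sprintf("cannot write '%s': %s", path,
                                    conditionMessage(e)), "talsim_io_error"))
  on.exit(close(con))
  header <- c("time", colnames(sim$series))
  writeLines(paste(header, collapse = ","), con)
  if (!length(sim$time)) {
    warning("result contains no samples; header-only file written")
    return(invisible(path))
  }
  m <- cbind(sim$time, sim$series)
  lines <- apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, con)
  invisible(path)
}

#' Re-import waveforms written by \code{exportWaveforms}
#'
#' @param path CSV path.
#' @return a data frame with the time column and one column per waveform.
#' @export
importWaveforms <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
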