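# Shared fixtures.  Steady-state runs are deterministic, so expensive objects
# are computed once per session and reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixtures, inherits = FALSE))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures, inherits = FALSE)
}

steadyNormal <- function() fixture("normal", simulatePatient(normalPreset()))

phCalibrated <- function() fixture("ph",
  calibratePulmonaryHypertension(normalPreset()))

# pathological patient at the high arteriolar-resistance setting, TAL off
phBaseline240 <- function() fixture("base240", {
  p <- setParameter(phCalibrated()$preset, "Rpar", 240, units = "g.cm-4.s-1")
  p$tal <- NULL
  p
})

steadyTal <- function(mode, ...) {
  key <- paste0("tal_", mode, "_", paste(unlist(list(...)), collapse = "_"))
  fixture(key, {
    p <- phBaseline240()
    p$tal <- configureTal(talParams(...), mode)
    simulatePatient(p)
  })
}

protocolTable <- function() fixture("protocol",
  runProtocol(phCalibrated()$preset))

# closed RC loop: unit compliance charged to 10 mmHg discharging through R = 1
# into a near-infinite reservoir held at 0 mmHg
rcNetwork <- function(C = 1, R = 1, Cres = 1e9) {
  cvNetwork(list(
    capacitorElement("C1", "a", C),
    capacitorElement("Cres", "b", Cres),
    resistorElement("R1", "a", "b", R)),
    period = 1, Pt = 0)
}

rcState <- function(net, V = 10) stateTemplate(net, pressures = list(a = V))
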