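# cycle means of the waveforms two configurations share
sharedCycleMeans <- function(a, b) {
  simA <- a$result; simB <- b$result
  cols <- intersect(colnames(simA$series), colnames(simB$series))
  list(a = vapply(cols, function(j) cycleMean(simA$series[, j], simA$time), 0),
       b = vapply(cols, function(j) cycleMean(simB$series[, j], simB$time), 0))
}

relDiff <- function(a, b) abs(a - b) / pmax(abs(a), 1)

test_that("the flow-dependent pressure drop is linear plus sign-preserving quadratic", {
  expect_equal(flowDependentDrop(0, 0.02, 1e-4), 0)
  expect_equal(flowDependentDrop(50, 0.02, 0), 1.0)
  expect_equal(flowDependentDrop(-50, 0.02, 1e-4), -1.25)
  expect_error(flowDependentDrop(1, -0.1, 0), class = "talsim_domain_error")
})

test_that("the stepper inverts the flow-dependent drop exactly", {
  # the solver computes Q from dP; pushing Q back through the drop law must
  # recover dP
  net <- cvNetwork(list(
    capacitorElement("Ca", "a", 1), capacitorElement("Cb", "b", 1),
    resistorElement("Rf", "a", "b", 0.1, sub = "flowdep", k = 2e-3)),
    period = 1, Pt = 0)
  f <- assembleDerivative(net)
  for (dp in c(-20, -1, 0.5, 12)) {
    d <- f(0, stateTemplate(net, pressures = list(a = dp, b = 0)))
    expect_equal(flowDependentDrop(d$flows[["Q_Rf"]], 0.1, 2e-3), dp,
                 tolerance = 1e-12)
  }
})

test_that("attachment modes disable exactly the stated branches", {
  net <- buildNetwork(normalPreset())
  wf <- function(mode, ...) colnames(
    simulateNetwork(attachTal(net, configureTal(talParams(...), mode)),
                    stateTemplate(attachTal(net, configureTal(talParams(...),
                                                              mode)),
                                  pressures = list(sa = 80)),
                    duration = 0)$series)
  expect_false("QTALan" %in% wf("parallel"))   # distal-PA return removed
  expect_true("QTALala" %in% wf("parallel"))
  expect_false("QTALala" %in% wf("series"))    # LA return removed
  expect_false("Qpam" %in% wf("series"))       # native (banded) path removed
  expect_true(all(c("QTALala", "QTALan", "Qpam") %in% wf("hybrid")))
  expect_error(configureTal(talParams(), "sideways"),
               class = "talsim_config_error")
  expect_error(attachTal(attachTal(net, talParams()), talParams()),
               class = "talsim_topology_error")
})

test_that("an attached TAL in off mode leaves the haemodynamics untouched", {
  p <- phBaseline240()
  pOff <- p; pOff$tal <- talParams(mode = "off")
  m <- sharedCycleMeans(simulatePatient(p), simulatePatient(pOff))
  expect_lt(max(relDiff(m$a, m$b)), 1e-6)
})

test_that("hybrid limits reproduce parallel and series exactly", {
  p <- phBaseline240()

  pPar <- p; pPar$tal <- talParams(mode = "parallel")
  pLim <- p; pLim$tal <- configureTal(talParams(RTALpab = 0),
                                      "hybrid", disabled = "paReturn")
  m <- sharedCycleMeans(simulatePatient(pPar), simulatePatient(pLim))
  expect_lt(max(relDiff(m$a, m$b)), 1e-9)

  pSer <- p; pSer$tal <- talParams(mode = "series")
  pLim2 <- p; pLim2$tal <- configureTal(talParams(), "hybrid",
                                        disabled = c("native", "laReturn"))
  m2 <- sharedCycleMeans(simulatePatient(pSer), simulatePatient(pLim2))
  expect_lt(max(relDiff(m2$a, m2$b)), 1e-9)
})

test_that("TAL mass balance closes over a converged cycle", {
  for (mode in c("parallel", "hybrid")) {
    ss <- steadyTal(mode)
    ser <- ss$result$series; t <- ss$result$time
    inlet <- cycleMean(ser[, "QTALin"], t)
    returns <- cycleMean(ser[, "QTALala"], t) +
      (if ("QTALan" %in% colnames(ser)) cycleMean(ser[, "QTALan"], t) else 0)
    expect_lt(abs(inlet - returns) / abs(inlet), 0.005)
  }
})

test_that("parallel TAL decompresses the hypertensive pulmonary artery", {
  base <- cycleSummary(simulatePatient(phBaseline240()))
  par <- cycleSummary(steadyTal("parallel"))
  expect_lt(par$meanPAP, base$meanPAP)
  expect_gt(par$meanLAP, base$meanLAP)
})

test_that("a tighter band shifts pulmonary inflow towards the left-atrial return", {
  # fraction of the total flow leaving the main PA that reaches the left
  # atrium through the device rather than through the natural lung
  share <- vapply(c(0.05, 0.15, 0.30), function(pab) {
    ss <- steadyTal("hybrid", RTALpab = pab)
    ser <- ss$result$series; t <- ss$result$time
    cycleMean(ser[, "QTALala"], t) /
      (cycleMean(ser[, "Qpam"], t) + cycleMean(ser[, "QTALin"], t))
  }, 0)
  expect_true(all(diff(share) > 0))
})
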