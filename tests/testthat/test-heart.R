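test_that("raised-cosine activation has the stated landmarks and period", {
  Tsys <- 0.3; period <- 0.8
  expect_equal(activationFraction(0, 0, Tsys, period), 0)
  expect_equal(activationFraction(Tsys / 2, 0, Tsys, period), 1)
  expect_equal(activationFraction(0.25 * Tsys, 0, Tsys, period), 0.5)
  expect_equal(activationFraction(Tsys, 0, Tsys, period), 0)

  t <- seq(0, period, by = 0.01)
  expect_equal(activationFraction(t, 0.1, Tsys, period),
               activationFraction(t + 7 * period, 0.1, Tsys, period))
})

test_that("elastance interpolates between Emin and Emax", {
  expect_equal(chamberElastance(0, 2.5, 0.1), 0.1)
  expect_equal(chamberElastance(1, 2.5, 0.1), 2.5)
  expect_equal(chamberElastance(0.5, 2.5, 0.1), 1.3)
  expect_error(chamberElastance(1.2, 2.5, 0.1),
               class = "talsim_domain_error")
})

test_that("chamber pressure follows the elastance law including suction", {
  expect_equal(chamberPressure(15, 1.7, 15, Pref = -4), -4)
  expect_equal(chamberPressure(65, 2, 15, Pref = 0), 100)
  expect_equal(chamberPressure(-5 + 15, 0.1, 15, Pref = -4), -4.5)
})

test_that("diode valves conduct forward only", {
  expect_equal(valveFlow(100, 80, 0.005), 4000)
  expect_equal(valveFlow(80, 100, 0.005), 0)
  expect_equal(valveFlow(90, 90, 0.005), 0)
  expect_error(valveFlow(1, 0, 0), class = "talsim_domain_error")
})

test_that("valve flows are non-negative throughout a converged cycle", {
  ser <- steadyNormal()$result$series
  for (q in c("Qli", "Qlo", "Qri", "Qro"))
    expect_gte(min(ser[, q]), 0)
})

test_that("stroke volume responds to contractility and preload (Starling)", {
  sv <- function(emax = 2.5, pvs = 4.5) {
    p <- normalPreset()
    p$heart$lv$Emax <- emax
    s <- cycleSummary(simulatePatient(p, pressures = list(vs = pvs)))
    s$LVEDV - s$LVESV
  }
  svs <- vapply(c(2.0, 2.5, 3.0), sv, 0)
  expect_true(all(diff(svs) >= 0))
  expect_gt(sv(pvs = 6.5), sv(pvs = 4.5))
})
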