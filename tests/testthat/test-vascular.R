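test_that("CGS resistances convert through the mmHg/dyn identity", {
  expect_equal(cgsResistance(1333.22), 1)
  expect_equal(signif(cgsResistance(240), 4), 0.1800)
  expect_equal(signif(cgsResistance(120), 4), 0.09001)
  expect_error(cgsResistance(-1), class = "talsim_domain_error")
})

test_that("setParameter round-trips, converts units and logs changes", {
  p0 <- normalPreset()
  p1 <- setParameter(p0, "Rpar", 240, units = "g.cm-4.s-1")
  expect_equal(signif(getParameter(p1, "Rpar"), 4), 0.1800)
  expect_equal(getParameter(p0, "Rpar"), 0.04)  # original untouched
  expect_equal(nrow(attr(p1, "changeLog")), 1L)

  p2 <- setParameter(p1, "Cvs", 75)
  expect_equal(getParameter(p2, "Cvs"), 75)
  expect_error(setParameter(p0, "Rxx", 1), class = "talsim_config_error")
  expect_error(setParameter(p0, "Rpar", 1, units = "ml/mmHg"),
               class = "talsim_unit_error")
  err <- tryCatch(setParameter(p0, "Rxx", 1), talsim_config_error = identity)
  expect_match(conditionMessage(err), "Rpar")  # lists valid symbols
})

test_that("the full network carries the expected bill of materials", {
  net <- buildNetwork(normalPreset())
  expect_length(net$elements, 21L)
  expect_setequal(net$nodes, c("la", "lv", "ra", "rv", "sa", "vs", "pam",
                               "pas", "vp", "cor"))
  p <- normalPreset(); p$tal <- talParams(mode = "parallel")
  expect_length(buildNetwork(p)$elements, 29L)
})

test_that("initial stored volume matches the preset blood volume", {
  p <- normalPreset()
  net <- buildNetwork(p)
  s0 <- initialState(p, net)
  cn <- talsim:::compileNetwork(net)
  expect_lt(abs(sum(s0[seq_len(cn$ns)]) - p$bloodVolume), 1)
})

test_that("the normal preset rests in textbook haemodynamic ranges", {
  ss <- steadyNormal()
  s <- cycleSummary(ss)
  expect_lte(ss$cycles, 60L)
  expect_gt(s$meanAoP, 70); expect_lt(s$meanAoP, 105)
  expect_gt(s$CO, 4); expect_lt(s$CO, 6.5)
  expect_lt(s$meanPAP, 20)
  expect_gt(s$LVEDV, s$LVESV)
})

test_that("raising the arteriolar resistances loads the right ventricle", {
  sweep <- lapply(c(1, 2, 4), function(k) {
    p <- normalPreset()
    p$pulmonary$Rpar <- p$pulmonary$Rpar * k
    cycleSummary(simulatePatient(p))
  })
  pap <- vapply(sweep, `[[`, 0, "meanPAP")
  rvesv <- vapply(sweep, `[[`, 0, "RVESV")
  expect_true(all(diff(pap) > 0))
  expect_true(all(diff(rvesv) > 0))
})

test_that("afterload monotonicity: higher Ras raises AoP and lowers CO", {
  sweep <- lapply(c(0.7, 0.9, 1.2), function(r) {
    p <- normalPreset()
    p$systemic$Ras <- r
    cycleSummary(simulatePatient(p))
  })
  aop <- vapply(sweep, `[[`, 0, "meanAoP")
  co <- vapply(sweep, `[[`, 0, "CO")
  expect_true(all(diff(aop) > 0))
  expect_true(all(diff(co) < 0))
})

test_that("the coronary loop closes and the intramyocardial pump throttles systolic inflow", {
  ss <- steadyNormal()
  ser <- ss$result$series; t <- ss$result$time
  inFlow <- cycleMean(ser[, "Qcor"], t)
  outFlow <- cycleMean(ser[, "QcorOut"], t)
  expect_lt(abs(inFlow - outFlow) / inFlow, 0.005)

  # systolic inflow dips below the diastolic peak
  net <- ss$network
  sys <- (t - t[1]) < 0.3 * sqrt(net$period)
  expect_lt(min(ser[sys, "Qcor"]), 0.5 * max(ser[!sys, "Qcor"]))

  # removing the squeeze (gamma = 0) raises cycle-mean coronary flow
  p <- normalPreset(); p$coronary$gamma <- 0
  s0g <- cycleSummary(simulatePatient(p))
  expect_gt(s0g$meanCBF, inFlow)

  expect_equal(intramyocardialPressure(120, 0), 0)
  expect_equal(intramyocardialPressure(120, 1), 120)
  expect_error(intramyocardialPressure(120, 1.5),
               class = "talsim_domain_error")
})
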