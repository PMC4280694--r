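test_that("pulmonary-hypertension calibration hits its pressure and dilation targets", {
  cal <- phCalibrated()
  expect_gte(cal$summary$meanPAP, 34)
  expect_lte(cal$summary$meanPAP, 36)
  expect_gte(cal$summary$RVEDV, 1.2 * cal$normalSummary$RVEDV)
  expect_gt(nrow(cal$log), 1L)          # audit trail of the bisection
  expect_true(all(diff(cal$log$iter) == 1L))
})

test_that("a target already satisfied by the normal preset needs no scaling", {
  cal0 <- calibratePulmonaryHypertension(
    normalPreset(), targetPpam = phCalibrated()$normalSummary$meanPAP,
    targetRVdilation = 0)
  expect_lte(cal0$scale, 1.05)
})

test_that("unreachable calibration targets raise a calibration error", {
  expect_error(calibratePulmonaryHypertension(normalPreset(),
                                              targetPpam = 300),
               class = "talsim_calibration_error")
})

test_that("the course protocol emits the full factorial table", {
  tab <- protocolTable()
  expect_s3_class(tab, "percentChangeTable")
  expect_equal(nrow(tab), 18L)
  expect_equal(sum(tab$mode == "off"), 2L)
  base <- tab[tab$mode == "off",
              c("LVEDV", "LVESV", "RVEDV", "RVESV", "CO", "meanPAP",
                "meanLAP", "meanSVP", "CBFAoP")]
  expect_true(all(as.matrix(base) == 0))

  empty <- runProtocol(phCalibrated()$preset,
                       protocolSpec(modes = character(), rparCgs = 240))
  expect_equal(nrow(empty), 1L)
  expect_true(all(empty$mode == "off"))
})

test_that("the protocol is deterministic", {
  spec1 <- protocolSpec(modes = "parallel", rparCgs = 240, ctalin = 1.5,
                        ctalch = 2.0)
  t1 <- runProtocol(phCalibrated()$preset, spec1)
  t2 <- runProtocol(phCalibrated()$preset, spec1)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("lowering the arteriolar resistance (drug effect) unloads the right ventricle", {
  sums <- attr(protocolTable(), "summaries")
  b240 <- sums[["off|240|baseline"]]
  b120 <- sums[["off|120|baseline"]]
  expect_lt(b120$meanPAP, b240$meanPAP)
  expect_lt(b120$RVESV, b240$RVESV)
})

test_that("parallel assistance at high resistance reproduces the expected directions", {
  chk <- directionalCheck(protocolTable())
  expect_true(chk$passed)
  expect_equal(nrow(chk$checks), 9L)
})

test_that("parallel assistance boosts cardiac output more than hybrid in every compliance combination", {
  tab <- protocolTable()
  par <- tab[tab$mode == "parallel" & tab$rparCgs == 240, ]
  hyb <- tab[tab$mode == "hybrid" & tab$rparCgs == 240, ]
  key <- function(d) paste(d$CTALin, d$CTALch)
  hyb <- hyb[match(key(par), key(hyb)), ]
  expect_true(all(par$CO > hyb$CO))
})
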