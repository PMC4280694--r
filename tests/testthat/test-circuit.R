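test_that("assembled state equations reproduce elementary circuit behaviour", {
  # an isolated compliance exchanges no volume
  lone <- cvNetwork(list(capacitorElement("C1", "a", 1)), period = 1, Pt = 0)
  f <- assembleDerivative(lone)
  d <- f(0, stateTemplate(lone, pressures = list(a = 10)))
  expect_identical(unname(d$dstate), 0)

  # Ohmic discharge: 10 mmHg across 1 mmHg.s/ml drains 10 ml/s
  net <- rcNetwork()
  f <- assembleDerivative(net)
  d <- f(0, rcState(net))
  expect_equal(unname(d$dstate[["V_C1"]]), -10)
  expect_equal(unname(d$flows[["Q_R1"]]), 10)

  # an inductor with equal end pressures and zero flow stays at rest
  ind <- cvNetwork(list(
    capacitorElement("Ca", "a", 1), capacitorElement("Cb", "b", 1),
    inductorElement("L1", "a", "b", L = 0.01)), period = 1, Pt = 0)
  d <- assembleDerivative(ind)(0, stateTemplate(ind,
    pressures = list(a = 5, b = 5)))
  expect_equal(unname(d$dstate[["Q_L1"]]), 0)
})

test_that("nodes without a pressure-defining storage element are rejected", {
  err <- tryCatch(
    cvNetwork(list(
      capacitorElement("C1", "a", 1),
      resistorElement("R1", "a", "mid", 1),
      resistorElement("R2", "mid", "a", 1)), period = 1),
    talsim_topology_error = identity)
  expect_s3_class(err, "talsim_topology_error")
  expect_match(conditionMessage(err), "mid")
})

test_that("the Euler update follows x + dt * f", {
  expect_equal(eulerStep(1, 2, 0.5), 2)
  x <- c(a = 3, b = -1)
  expect_equal(eulerStep(x, c(0, 0), 0.1), x)
  expect_equal(eulerStep(10, -10, 0.01), 9.9)
  expect_error(eulerStep(c(V = 1), c(NaN), 0.1),
               class = "talsim_instability_error")
  expect_error(eulerStep(1, 1, dt = 0), class = "talsim_domain_error")
})

test_that("zero-duration simulation returns exactly the initial sample", {
  net <- rcNetwork()
  s0 <- rcState(net)
  sim <- simulateNetwork(net, s0, duration = 0)
  expect_equal(nrow(sim$series), 1L)
  expect_equal(unname(sim$series[1, "V_C1"]), 10)
  expect_equal(sim$time, 0)
})

test_that("RC discharge matches the closed form with first-order convergence", {
  net <- rcNetwork()
  s0 <- rcState(net)
  exact <- 10 * exp(-1)
  errAt <- function(dt) {
    sim <- simulateNetwork(net, s0, duration = 1, dt = dt)
    abs(sim$series[nrow(sim$series), "V_C1"] - exact)
  }
  e1 <- errAt(2e-4)
  e2 <- errAt(1e-4)
  expect_lt(e2, 1e-3)           # O(dt) accuracy at dt = 1e-4
  expect_gt(e1 / e2, 1.6)       # halving dt halves the error (+/- 20%)
  expect_lt(e1 / e2, 2.4)
})

test_that("closed loops conserve total stored volume", {
  net <- cvNetwork(list(
    capacitorElement("Ca", "a", 1), capacitorElement("Cb", "b", 2),
    resistorElement("R1", "a", "b", 0.5)), period = 1, Pt = 0)
  s0 <- stateTemplate(net, pressures = list(a = 10, b = 0))
  sim <- simulateNetwork(net, s0, duration = 10, dt = 1e-3)
  tot <- rowSums(sim$series[, c("V_Ca", "V_Cb")])
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-4)  # < 0.01 %
})

test_that("compiled and reference steppers agree to rounding error", {
  ss <- steadyNormal()
  net <- ss$network
  simC <- simulateNetwork(net, ss$state, duration = 0.1, dt = 1e-4,
                          engine = "cpp")
  simR <- simulateNetwork(net, ss$state, duration = 0.1, dt = 1e-4,
                          engine = "r")
  expect_lt(max(abs(simC$series - simR$series)), 1e-8)
})

test_that("divergent integrations fail fast naming the state slot", {
  stiff <- cvNetwork(list(
    capacitorElement("Ca", "a", 1e-6), capacitorElement("Cb", "b", 1e-6),
    resistorElement("R1", "a", "b", 1e-3)), period = 1, Pt = 0)
  s0 <- stateTemplate(stiff, pressures = list(a = 10, b = 0))
  err <- tryCatch(simulateNetwork(stiff, s0, duration = 0.1, dt = 1e-4),
                  talsim_instability_error = identity)
  expect_s3_class(err, "talsim_instability_error")
  expect_match(conditionMessage(err), "smaller dt")
})

test_that("steady-state detection needs a chamber, honours tol = 0, and is fast on a periodic orbit", {
  expect_error(runToSteadyState(rcNetwork(), rcState(rcNetwork())),
               class = "talsim_convergence_error")

  ss <- steadyNormal()
  expect_true(ss$converged)
  expect_lte(ss$cycles, 60L)
  # restarting from the periodic orbit converges in the minimum four cycles
  again <- runToSteadyState(ss$network, ss$state)
  expect_equal(again$cycles, 4L)
  # an impossible tolerance must exhaust the cycle budget
  expect_error(runToSteadyState(ss$network, ss$state, tol = 0,
                                maxCycles = 6L),
               class = "talsim_convergence_error")
})
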