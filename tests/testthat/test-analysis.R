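test_that("cycle means are time-weighted", {
  t <- seq(0, 1, by = 1e-3)
  expect_equal(cycleMean(rep(7, length(t)), t), 7)
  expect_equal(cycleMean(sin(2 * pi * t), t), 0, tolerance = 1e-6)
  expect_equal(cycleMean(t, t), 0.5)
  expect_error(cycleMean(numeric(), numeric()),
               class = "talsim_domain_error")
})

test_that("EDV/ESV are the volume extrema", {
  expect_equal(edvEsv(rep(80, 10)), c(EDV = 80, ESV = 80))
  th <- seq(0, 2 * pi, length.out = 501)   # grid hits both extrema exactly
  expect_equal(edvEsv(60 + 30 * cos(th)), c(EDV = 90, ESV = 30))
})

test_that("cardiac output arithmetic", {
  expect_equal(cardiacOutput(120, 50, 75), 5.25)
  expect_equal(cardiacOutput(100, 100, 80), 0)
  expect_equal(cardiacOutput(140, 60, 60), 4.8)
  expect_error(cardiacOutput(50, 60, 75), class = "talsim_domain_error")
})

test_that("shoelace loop area matches closed forms and a triangulation oracle", {
  th <- seq(0, 2 * pi, length.out = 1e4 + 1)[-1]
  expect_equal(abs(loopArea(cos(th), sin(th))), pi, tolerance = 1e-3)
  expect_equal(loopArea(c(0, 1, 2), c(0, 1, 2)), 0)
  expect_equal(abs(loopArea(c(0, 1, 1, 0), c(0, 0, 1, 1))), 1)
  expect_error(loopArea(1:2, 1:2), class = "talsim_domain_error")

  # fan triangulation from the centroid as an independent area computation
  fanArea <- function(x, y) {
    cx <- mean(x); cy <- mean(y); n <- length(x); a <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      a <- a + 0.5 * abs((x[i] - cx) * (y[j] - cy) -
                           (x[j] - cx) * (y[i] - cy))
    }
    a
  }
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    ang <- sort(stats::runif(n, 0, 2 * pi))
    r <- stats::runif(1, 0.5, 3)
    x <- r * cos(ang) + stats::rnorm(1)
    y <- r * sin(ang) + stats::rnorm(1)   # convex (points on a circle)
    expect_equal(abs(loopArea(x, y)), fanArea(x, y), tolerance = 1e-9)
  }
})

test_that("percent change is signed and guards the zero baseline", {
  expect_equal(percentChange(100, 110), 10)
  expect_equal(percentChange(50, 40), -20)
  expect_equal(percentChange(3.7, 3.7), 0)
  expect_error(percentChange(0, 5), class = "talsim_domain_error")
})

test_that("stroke volume agrees with the aortic-flow integral per beat", {
  ss <- steadyNormal()
  ser <- ss$result$series; t <- ss$result$time
  sv <- max(ser[, "Vlv"]) - min(ser[, "Vlv"])
  ejected <- cycleMean(ser[, "Qlo"], t) * ss$network$period
  expect_lt(abs(sv - ejected) / sv, 0.02)
})

test_that("LV and RV stroke volumes agree at periodic steady state", {
  # in a closed loop the per-beat throughput of the two ventricles matches;
  # a left-atrial TAL return re-routes flow around the lung but cannot make
  # the periodic totals differ
  for (ss in list(steadyNormal(), steadyTal("parallel"))) {
    ser <- ss$result$series
    svL <- max(ser[, "Vlv"]) - min(ser[, "Vlv"])
    svR <- max(ser[, "Vrv"]) - min(ser[, "Vrv"])
    expect_lt(abs(svL - svR) / svL, 0.02)
  }
})

test_that("cycle summaries satisfy their invariants", {
  s <- cycleSummary(steadyNormal())
  expect_gte(s$LVEDV, s$LVESV)
  expect_gte(s$RVEDV, s$RVESV)
  expect_gte(s$CO, 0)
  expect_gt(s$CBFAoP, 0)
})
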