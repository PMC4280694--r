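#' Integrate a network over time
#'
#' Explicit-Euler integration of the network's state equations on a uniform
#' grid.  All node pressures and branch flows are reported alongside the state
#' variables, not only the states themselves.
#'
#' @param network a \code{\link{cvNetwork}}.
#' @param state initial state vector (see \code{\link{stateTemplate}}).
#' @param duration simulated time in s (>= 0); \code{duration = 0} yields
#'   exactly the initial sample.
#' @param dt integration step, s (default 1e-4).
#' @param t0 start time, s.
#' @param recordEvery store every n-th step (output decimation); the final
#'   sample is always stored.
#' @param divergenceBound abort when any state magnitude exceeds this bound.
#' @param engine \code{"cpp"} (compiled, default) or \code{"r"} (reference
#'   implementation used for cross-checking).
#' @return an object of class \code{cvSimResult}: uniform time grid,
#'   waveform matrix (volumes, node pressures, branch flows), cardiac-cycle
#'   start indices, and the final state.
#' @export
simulateNetwork <- function(network, state, duration, dt = 1e-4, t0 = 0,
                            recordEvery = 1L, divergenceBound = 1e5,
                            engine = c("cpp", "r")) {
  stopifnot(inherits(network, "cvNetwork"))
  engine <- match.arg(engine)
  checkScalar(duration, "duration", nonneg = TRUE)
  checkScalar(dt, "dt", positive = TRUE)
  recordEvery <- max(1L, as.integer(recordEvery))
  nsteps <- as.integer(round(duration / dt))
  cn <- compileNetwork(network)
  if (length(state) != length(cn$stateNames))
    tsError(sprintf("state has %d entries; network expects %d",
                    length(state), length(cn$stateNames)),
            "talsim_domain_error")
  if (!all(is.finite(state)))
    tsError("initial state contains non-finite entries",
            "talsim_domain_error")

  if (engine == "cpp") {
    out <- .eulerRunCpp(cn, as.numeric(state), t0, nsteps, dt, recordEvery,
                        divergenceBound)
  } else {
    out <- eulerRunR(network, cn, as.numeric(state), t0, nsteps, dt,
                     recordEvery, divergenceBound)
  }
  if (out$badSlot > 0) {
    nm <- cn$stateNames[out$badSlot]
    tsError(sprintf(
      paste0("simulation diverged at t = %.6g s (state '%s' exceeded %g); ",
             "try a smaller dt"),
      t0 + out$badStep * dt, nm, divergenceBound),
      "talsim_instability_error", slot = nm)
  }
  rows <- seq_len(out$rows)
  series <- out$series[rows, , drop = FALSE]
  colnames(series) <- cn$seriesNames
  time <- out$time[rows]
  cyc <- which(abs(((time - t0) / network$period) -
                     round((time - t0) / network$period)) < dt / 10 &
                 (time - t0) / network$period > -0.5)
  structure(list(time = time, series = series,
                 state = stats::setNames(out$state, cn$stateNames),
                 cycleStarts = cyc, dt = dt, recordEvery = recordEvery,
                 network = network),
            class = "cvSimResult")
}

## Pure-R mirror of the compiled stepper (used in tests / as an oracle host).
eulerRunR <- function(network, cn, state, t0, nsteps, dt, recordEvery,
                      divergenceBound) {
  f <- assembleDerivative(network)
  recIdx <- unique(c(seq(0L, nsteps, by = recordEvery), nsteps))
  nrec <- length(recIdx)
  series <- matrix(NA_real_, nrec, length(cn$seriesNames))
  time <- numeric(nrec)
  row <- 0L; badSlot <- -1L; badStep <- -1L
  x <- state
  for (i in 0:nsteps) {
    t <- t0 + i * dt
    d <- f(t, x)
    if (i %in% recIdx) {
      row <- row + 1L
      time[row] <- t
      series[row, ] <- c(x[seq_len(cn$ns)], d$pressures, d$flows)
    }
    if (i == nsteps) break
    x <- x + dt * d$dstate
    if (any(!is.finite(x) | abs(x) > divergenceBound)) {
      badSlot <- which(!is.finite(x) | abs(x) > divergenceBound)[1L]
      badStep <- i + 1L
      break
    }
  }
  list(time = time, series = series, state = x, rows = row,
       badSlot = badSlot, badStep = badStep)
}

#' @export
print.cvSimResult <- function(x, ...) {
  cat("<cvSimResult> ", length(x$time), " samples, t = [",
      format(min(x$time)), ", ", format(max(x$time)), "] s, dt = ", x$dt,
      " s, ", ncol(x$series), " waveforms, ", length(x$cycleStarts),
      " cycle starts\n", sep = "")
  invisible(x)
}

#' Run a network to periodic steady state
#'
#' Integrates whole cardiac cycles until the relative change of the
#' cycle-mean monitors (all node pressures plus each chamber's stroke volume)
#' stays below \code{tol} for three consecutive cycles, with a minimum of
#' four cycles.  For quantities of magnitude below 1 the change is measured
#' in absolute units (denominator floored at 1) to avoid division blow-up
#' near zero-mean signals.
#'
#' @param network a \code{\link{cvNetwork}} containing at least one elastance
#'   chamber (which defines the cardiac cycle).
#' @param state initial state vector.
#' @param dt integration step, s.
#' @param tol relative convergence tolerance (default 1e-3).
#' @param maxCycles abort with a non-convergence error after this many cycles.
#' @param divergenceBound passed to \code{\link{simulateNetwork}}.
#' @return an object of class \code{steadyState}: the last cycle's full
#'   waveforms (\code{$result}), the number of cycles used, the final state
#'   and the last residuals.
#' @export
runToSteadyState <- function(network, state, dt = 1e-4, tol = 1e-3,
                             maxCycles = 60L, divergenceBound = 1e5) {
  stopifnot(inherits(network, "cvNetwork"))
  kinds <- vapply(network$elements, `[[`, "", "kind")
  if (!any(kinds == "chamber"))
    tsError("periodic steady state requires at least one elastance chamber",
            "talsim_convergence_error")
  checkScalar(tol, "tol", nonneg = TRUE)
  period <- network$period
  cn <- compileNetwork(network)
  chCols <- which(cn$stor_type == 1L)

  monitors <- function(sim) {
    tt <- sim$time
    pcols <- cn$ns + seq_len(cn$nn)
    m <- apply(sim$series[, pcols, drop = FALSE], 2L, cycleMean, t = tt)
    sv <- vapply(chCols, function(j) {
      v <- sim$series[, j]
      max(v) - min(v)
    }, 0)
    c(m, sv)
  }

  x <- state
  prev <- NULL
  consec <- 0L
  resid <- NULL
  for (cyc in seq_len(maxCycles)) {
    sim <- simulateNetwork(network, x, period, dt = dt,
                           t0 = (cyc - 1L) * period,
                           divergenceBound = divergenceBound)
    x <- sim$state
    cur <- monitors(sim)
    if (!is.null(prev)) {
      resid <- abs(cur - prev) / pmax(abs(prev), 1)
      consec <- if (max(resid) < tol) consec + 1L else 0L
      if (consec >= 3L && cyc >= 4L) {
        return(structure(list(result = sim, cycles = cyc, state = x,
                              residuals = resid, network = network,
                              converged = TRUE),
                         class = "steadyState"))
      }
    }
    prev <- cur
  }
  tsError(sprintf(
    "no periodic steady state within %d cycles (max residual %.3g, tol %g)",
    maxCycles, if (is.null(resid)) NA_real_ else max(resid), tol),
    "talsim_convergence_error", residuals = resid)
}

#' @export
print.steadyState <- function(x, ...) {
  cat("<steadyState> converged in ", x$cycles, " cycles (max residual ",
      format(max(x$residuals), digits = 3), ")\n", sep = "")
  print(x$result)
  invisible(x)
}
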