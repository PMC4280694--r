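#' @useDynLib talsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.extCodes <- c(ambient = 0L, intrathoracic = 1L, intramyocardial = 2L)

tsError <- function(msg, class, ...) {
  stop(errorCondition(msg, class = c(class, "talsim_error"), ...))
}

checkScalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    tsError(sprintf("'%s' must be a finite numeric scalar", name),
            "talsim_domain_error")
  if (positive && x <= 0)
    tsError(sprintf("'%s' must be > 0 (got %g)", name, x),
            "talsim_domain_error")
  if (nonneg && x < 0)
    tsError(sprintf("'%s' must be >= 0 (got %g)", name, x),
            "talsim_domain_error")
  x
}

#' Capacitor (compliance) storage element
#'
#' A compliance attached to one circuit node and referenced to an external
#' pressure.  Its pressure is \code{P = (V - Vu)/C + P_ref}, where \code{Vu}
#' is an unstressed volume used for blood-volume bookkeeping (it does not
#' alter the dynamics).
#'
#' @param id element identifier (unique within a network).
#' @param node name of the node the compliance defines the pressure of.
#' @param C compliance in ml/mmHg; must be positive.
#' @param ext external pressure reference: \code{"ambient"} (0 mmHg),
#'   \code{"intrathoracic"} (the network's Pt) or \code{"intramyocardial"}
#'   (gamma times left-ventricular pressure; see \code{\link{cvNetwork}}).
#' @param Vu unstressed volume in ml.
#' @param volumeName column name used for this element's volume waveform.
#' @return an object of class \code{circuitElement}.
#' @export
capacitorElement <- function(id, node, C, ext = "ambient", Vu = 0,
                             volumeName = paste0("V_", id)) {
  checkScalar(C, "C", positive = TRUE)
  checkScalar(Vu, "Vu", nonneg = TRUE)
  ext <- match.arg(ext, names(.extCodes))
  structure(list(kind = "capacitor", id = id, node = node, C = C, Vu = Vu,
                 ext = ext, volumeName = volumeName),
            class = "circuitElement")
}

#' Variable-elastance chamber element
#'
#' A heart chamber whose stiffness follows a raised-cosine activation between
#' \code{Emin} (diastole) and \code{Emax} (peak systole):
#' \code{P = e(t) (V - V0) + P_ref}.
#'
#' @inheritParams capacitorElement
#' @param Emax,Emin end-systolic and end-diastolic elastance, mmHg/ml.
#' @param V0 unstressed chamber volume, ml.
#' @param onset activation onset offset within the cardiac cycle, s.
#' @param Tsys active (systolic) duration, s.
#' @return an object of class \code{circuitElement}.
#' @export
chamberElement <- function(id, node, Emax, Emin, V0, onset, Tsys,
                           ext = "intrathoracic",
                           volumeName = paste0("V_", id)) {
  checkScalar(Emax, "Emax", positive = TRUE)
  checkScalar(Emin, "Emin", positive = TRUE)
  if (Emax < Emin)
    tsError("chamber requires Emax >= Emin", "talsim_domain_error")
  checkScalar(V0, "V0", nonneg = TRUE)
  checkScalar(onset, "onset", nonneg = TRUE)
  checkScalar(Tsys, "Tsys", positive = TRUE)
  ext <- match.arg(ext, names(.extCodes))
  structure(list(kind = "chamber", id = id, node = node, Emax = Emax,
                 Emin = Emin, V0 = V0, onset = onset, Tsys = Tsys, ext = ext,
                 volumeName = volumeName),
            class = "circuitElement")
}

#' Resistive branch (linear, diode valve, or flow-dependent)
#'
#' Algebraic branch between two nodes.  \code{sub = "diode"} gives an ideal
#' valve in series with R (forward flow only); \code{sub = "flowdep"} uses the
#' pressure drop \code{dP = R*Q + k*Q*|Q|}, inverted for Q at each step.
#'
#' @inheritParams capacitorElement
#' @param up,down upstream and downstream node names (positive flow up->down).
#' @param R resistance, mmHg·s/ml.
#' @param sub one of \code{"linear"}, \code{"diode"}, \code{"flowdep"},
#'   \code{"waterfall"} (drains against the larger of the downstream and the
#'   intramyocardial pressure, never backwards).
#' @param k quadratic loss coefficient, mmHg·s^2/ml^2 (flow-dependent only).
#' @param enabled logical; disabled branches are removed from the dynamics
#'   (this is how "infinite resistance" is realised).
#' @param flowName column name for this branch's flow waveform.
#' @return an object of class \code{circuitElement}.
#' @export
resistorElement <- function(id, up, down, R,
                            sub = c("linear", "diode", "flowdep",
                                    "waterfall"), k = 0,
                            enabled = TRUE, flowName = paste0("Q_", id)) {
  sub <- match.arg(sub)
  if (enabled) {
    checkScalar(R, "R", nonneg = TRUE)
    if (R == 0 && sub != "flowdep")
      tsError("enabled resistive branch requires R > 0", "talsim_domain_error")
  }
  checkScalar(k, "k", nonneg = TRUE)
  if (identical(up, down))
    tsError(sprintf("branch '%s' must join two distinct nodes", id),
            "talsim_topology_error")
  structure(list(kind = "resistor", id = id, up = up, down = down, R = R,
                 sub = sub, k = k, enabled = isTRUE(enabled),
                 flowName = flowName),
            class = "circuitElement")
}

#' Inductive branch (inertance with optional series resistance)
#'
#' Carries a flow state Q with \code{dQ/dt = (P_up - P_down - R*Q)/L}.
#'
#' @inheritParams resistorElement
#' @param L inertance, mmHg·s^2/ml; must be positive.
#' @param R series resistance, mmHg·s/ml (may be 0).
#' @return an object of class \code{circuitElement}.
#' @export
inductorElement <- function(id, up, down, L, R = 0, enabled = TRUE,
                            flowName = paste0("Q_", id)) {
  checkScalar(L, "L", positive = TRUE)
  checkScalar(R, "R", nonneg = TRUE)
  if (identical(up, down))
    tsError(sprintf("branch '%s' must join two distinct nodes", id),
            "talsim_topology_error")
  structure(list(kind = "inductor", id = id, up = up, down = down, L = L,
                 R = R, enabled = isTRUE(enabled), flowName = flowName),
            class = "circuitElement")
}

#' Assemble a lumped-parameter circuit network
#'
#' Collects circuit elements into a validated network.  Every node must be
#' owned by exactly one storage element (capacitor or chamber): node pressures
#' are algebraic functions of the stored volumes, so a node with only
#' resistive/inductive attachments has no pressure definition and is rejected.
#'
#' @param elements list of \code{circuitElement} objects.
#' @param period cardiac period in s (drives chamber activation).
#' @param Pt mean intrathoracic pressure, mmHg (reference for elements with
#'   \code{ext = "intrathoracic"}).
#' @param gamma intramyocardial coupling coefficient in [0, 1]; elements with
#'   \code{ext = "intramyocardial"} are squeezed by \code{gamma * Plv}.
#' @param septal optional linear septal coupling coefficient (0 = decoupled).
#' @param pressureNames optional named character vector mapping node names to
#'   pressure waveform column names.
#' @return an object of class \code{cvNetwork} with a state registry mapping
#'   each state slot to a storage volume or an inductive flow.
#' @export
cvNetwork <- function(elements, period, Pt = -4, gamma = 0.75, septal = 0,
                      pressureNames = NULL) {
  checkScalar(period, "period", positive = TRUE)
  checkScalar(Pt, "Pt")
  checkScalar(gamma, "gamma", nonneg = TRUE)
  if (gamma > 1) tsError("'gamma' must be in [0, 1]", "talsim_domain_error")
  if (!length(elements) || !all(vapply(elements, inherits, TRUE,
                                       "circuitElement")))
    tsError("'elements' must be a non-empty list of circuit elements",
            "talsim_topology_error")
  ids <- vapply(elements, `[[`, "", "id")
  if (anyDuplicated(ids))
    tsError(sprintf("duplicated element id(s): %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            "talsim_topology_error")

  kinds <- vapply(elements, `[[`, "", "kind")
  storage <- elements[kinds %in% c("capacitor", "chamber")]
  branches <- elements[kinds %in% c("resistor", "inductor")]
  storNodes <- vapply(storage, `[[`, "", "node")
  if (anyDuplicated(storNodes))
    tsError(sprintf("node(s) %s have more than one storage element",
                    paste(unique(storNodes[duplicated(storNodes)]),
                          collapse = ", ")),
            "talsim_topology_error")
  branchNodes <- unlist(lapply(branches, function(e) c(e$up, e$down)))
  nodes <- unique(c(storNodes, branchNodes))
  orphan <- setdiff(nodes, storNodes)
  if (length(orphan))
    tsError(sprintf(
      paste0("node(s) %s have no storage element defining their pressure ",
             "(only resistive/inertial attachments)"),
      paste(orphan, collapse = ", ")), "talsim_topology_error")

  if (any(vapply(storage, `[[`, "", "ext") == "intramyocardial") &&
      !any(ids == "LV"))
    tsError("intramyocardial pressure reference requires an 'LV' chamber",
            "talsim_topology_error")

  enabledInd <- vapply(branches, function(e)
    e$kind == "inductor" && e$enabled, TRUE)
  registry <- data.frame(
    slot = seq_len(length(storage) + sum(enabledInd)),
    kind = c(rep("volume", length(storage)), rep("flow", sum(enabledInd))),
    element = c(vapply(storage, `[[`, "", "id"),
                vapply(branches[enabledInd], `[[`, "", "id")),
    stringsAsFactors = FALSE)

  if (is.null(pressureNames)) {
    pressureNames <- paste0("P_", nodes)
    names(pressureNames) <- nodes
  }
  structure(list(elements = elements, nodes = nodes, period = period,
                 Pt = Pt, gamma = gamma, septal = septal,
                 registry = registry, pressureNames = pressureNames),
            class = "cvNetwork")
}

#' @export
print.cvNetwork <- function(x, ...) {
  kinds <- vapply(x$elements, `[[`, "", "kind")
  en <- vapply(x$elements, function(e) is.null(e$enabled) || e$enabled, TRUE)
  cat("<cvNetwork> ", length(x$nodes), " nodes, ", length(x$elements),
      " elements (", sum(!en), " disabled), ", nrow(x$registry),
      " states, period ", x$period, " s, Pt ", x$Pt, " mmHg\n", sep = "")
  cat("  storage:", sum(kinds %in% c("capacitor", "chamber")),
      " resistive:", sum(kinds == "resistor"),
      " inertial:", sum(kinds == "inductor"), "\n")
  invisible(x)
}

## Flat integer/numeric representation consumed by the C++ stepper and the
## R derivative mirror.
compileNetwork <- function(net) {
  stopifnot(inherits(net, "cvNetwork"))
  els <- net$elements
  kinds <- vapply(els, `[[`, "", "kind")
  storage <- els[kinds %in% c("capacitor", "chamber")]
  res <- Filter(function(e) e$enabled, els[kinds == "resistor"])
  ind <- Filter(function(e) e$enabled, els[kinds == "inductor"])

  nodes <- net$nodes
  nodeIdx <- stats::setNames(seq_along(nodes), nodes)
  storIds <- vapply(storage, `[[`, "", "id")
  storNode <- vapply(storage, `[[`, "", "node")
  storIdx <- stats::setNames(seq_along(storIds), storNode)

  num <- function(x, f, d = 0) vapply(x, function(e)
    if (is.null(e[[f]])) d else e[[f]], 0)
  isCh <- vapply(storage, `[[`, "", "kind") == "chamber"

  lv <- match("LV", storIds, nomatch = 0L) - 1L
  rv <- match("RV", storIds, nomatch = 0L) - 1L

  list(
    stor_node = unname(nodeIdx[storNode] - 1L),
    stor_type = as.integer(isCh),
    stor_C = unname(num(storage, "C", 1)),
    stor_Vu = unname(num(storage, "Vu")),
    stor_Emax = unname(num(storage, "Emax")),
    stor_Emin = unname(num(storage, "Emin")),
    stor_V0 = unname(num(storage, "V0")),
    stor_onset = unname(num(storage, "onset")),
    stor_Tsys = unname(num(storage, "Tsys", 1)),
    stor_ext = unname(.extCodes[vapply(storage, `[[`, "", "ext")]),
    res_up = unname(nodeIdx[vapply(res, `[[`, "", "up")] - 1L),
    res_down = unname(nodeIdx[vapply(res, `[[`, "", "down")] - 1L),
    res_type = unname(c(linear = 0L, diode = 1L, flowdep = 2L,
                        waterfall = 3L)[vapply(res, `[[`, "", "sub")]),
    res_R = unname(num(res, "R")),
    res_k = unname(num(res, "k")),
    ind_up = unname(nodeIdx[vapply(ind, `[[`, "", "up")] - 1L),
    ind_down = unname(nodeIdx[vapply(ind, `[[`, "", "down")] - 1L),
    ind_R = unname(num(ind, "R")),
    ind_L = unname(num(ind, "L", 1)),
    node_stor = unname(storIdx[nodes] - 1L),
    Pt = net$Pt, gamma = net$gamma, septal = net$septal,
    period = net$period, lv_stor = lv, rv_stor = rv,
    stateNames = c(vapply(storage, `[[`, "", "volumeName"),
                   vapply(ind, `[[`, "", "flowName")),
    seriesNames = c(vapply(storage, `[[`, "", "volumeName"),
                    unname(net$pressureNames[nodes]),
                    vapply(res, `[[`, "", "flowName"),
                    vapply(ind, `[[`, "", "flowName")),
    ns = length(storage), nn = length(nodes), nr = length(res),
    ni = length(ind))
}

#' Assemble the state equations of a network
#'
#' Returns the derivative function of the network's ODE system.  At any state
#' and time it computes node pressures algebraically (capacitor pressures from
#' \code{(V - Vu)/C + P_ref}, chamber pressures from the elastance law),
#' resistive and valve flows from the pressure gradients, and the state
#' derivatives: \code{dV/dt} = net inflow per storage element and
#' \code{dQ/dt = (dP - R Q)/L} per inductive branch.
#'
#' @param network a \code{\link{cvNetwork}}.
#' @return a function \code{f(t, state)} returning a list with components
#'   \code{dstate} (named derivative vector), \code{pressures} (named node
#'   pressures, mmHg) and \code{flows} (named branch flows, ml/s).
#' @export
assembleDerivative <- function(network) {
  cn <- compileNetwork(network)
  ns <- cn$ns; ni <- cn$ni
  isCh <- cn$stor_type == 1L
  chExtPt <- cn$stor_ext[isCh] == 1L
  capExt <- cn$stor_ext[!isCh]
  rUpS <- cn$node_stor[cn$res_up + 1L] + 1L
  rDnS <- cn$node_stor[cn$res_down + 1L] + 1L
  iUpS <- cn$node_stor[cn$ind_up + 1L] + 1L
  iDnS <- cn$node_stor[cn$ind_down + 1L] + 1L
  flowNames <- cn$seriesNames[(cn$ns + cn$nn + 1L):length(cn$seriesNames)]
  if (cn$nr + cn$ni == 0L) flowNames <- character()
  pNames <- cn$seriesNames[(cn$ns + 1L):(cn$ns + cn$nn)]

  function(t, state) {
    V <- state[seq_len(ns)]
    Pst <- numeric(ns)
    if (any(isCh)) {
      a <- activationFraction(t, cn$stor_onset[isCh], cn$stor_Tsys[isCh],
                              cn$period)
      e <- cn$stor_Emin[isCh] + (cn$stor_Emax[isCh] - cn$stor_Emin[isCh]) * a
      Pst[isCh] <- e * (V[isCh] - cn$stor_V0[isCh]) +
        ifelse(chExtPt, cn$Pt, 0)
    }
    if (cn$septal != 0 && cn$lv_stor >= 0 && cn$rv_stor >= 0) {
      l <- cn$lv_stor + 1L; r <- cn$rv_stor + 1L
      pl <- Pst[l]; pr <- Pst[r]
      Pst[l] <- pl + cn$septal * (pr - cn$Pt)
      Pst[r] <- pr + cn$septal * (pl - cn$Pt)
    }
    plv <- if (cn$lv_stor >= 0) Pst[cn$lv_stor + 1L] else 0
    if (any(!isCh)) {
      pext <- numeric(sum(!isCh))
      pext[capExt == 1L] <- cn$Pt
      pext[capExt == 2L] <- cn$gamma * plv
      Pst[!isCh] <- (V[!isCh] - cn$stor_Vu[!isCh]) / cn$stor_C[!isCh] + pext
    }
    Pn <- Pst[cn$node_stor + 1L]

    dV <- numeric(ns)
    q <- numeric(cn$nr)
    if (cn$nr) {
      dp <- Pn[cn$res_up + 1L] - Pn[cn$res_down + 1L]
      lin <- cn$res_type == 0L
      dio <- cn$res_type == 1L
      fdp <- cn$res_type == 2L
      wf <- cn$res_type == 3L
      q[lin] <- dp[lin] / cn$res_R[lin]
      q[dio] <- pmax(dp[dio], 0) / cn$res_R[dio]
      if (any(wf)) {
        back <- pmax(Pn[cn$res_down[wf] + 1L], cn$gamma * plv)
        q[wf] <- pmax(Pn[cn$res_up[wf] + 1L] - back, 0) / cn$res_R[wf]
      }
      if (any(fdp)) {
        R0 <- cn$res_R[fdp]; k <- cn$res_k[fdp]; d <- dp[fdp]
        qf <- ifelse(k <= 0, d / R0,
                     sign(d) * (-R0 + sqrt(R0^2 + 4 * k * abs(d))) /
                       (2 * pmax(k, .Machine$double.xmin)))
        q[fdp] <- qf
      }
      for (j in seq_len(cn$nr)) {
        dV[rUpS[j]] <- dV[rUpS[j]] - q[j]
        dV[rDnS[j]] <- dV[rDnS[j]] + q[j]
      }
    }
    dQ <- numeric(ni)
    if (ni) {
      qi <- state[ns + seq_len(ni)]
      for (j in seq_len(ni)) {
        dV[iUpS[j]] <- dV[iUpS[j]] - qi[j]
        dV[iDnS[j]] <- dV[iDnS[j]] + qi[j]
      }
      dQ <- (Pn[cn$ind_up + 1L] - Pn[cn$ind_down + 1L] - cn$ind_R * qi) /
        cn$ind_L
      q <- c(q, qi)
    }
    list(dstate = stats::setNames(c(dV, dQ), cn$stateNames),
         pressures = stats::setNames(Pn, pNames),
         flows = stats::setNames(q, flowNames))
  }
}

#' One explicit-Euler update
#'
#' \code{x_{t+dt} = x_t + dt * f}.  The derivative may be supplied either as a
#' numeric vector (already evaluated at the current state) or as a function
#' \code{f(t, state)} returning such a vector (or a list whose first element
#' is one), in which case \code{t} must be given.
#'
#' @param state numeric state vector.
#' @param derivative numeric vector or derivative function.
#' @param dt step size in s; must be positive.
#' @param t current time (used only when \code{derivative} is a function).
#' @return the updated state vector.
#' @export
eulerStep <- function(state, derivative, dt, t = 0) {
  checkScalar(dt, "dt", positive = TRUE)
  d <- if (is.function(derivative)) derivative(t, state) else derivative
  if (is.list(d)) d <- d[[1L]]
  if (length(d) != length(state))
    tsError("derivative length does not match state", "talsim_domain_error")
  bad <- which(!is.finite(d))
  if (length(bad)) {
    nm <- names(state)[bad[1L]]
    tsError(sprintf("non-finite derivative in state slot %s",
                    if (is.null(nm) || !nzchar(nm)) bad[1L] else nm),
            "talsim_instability_error")
  }
  state + dt * d
}

#' Build a state vector for a network
#'
#' Storage volumes are derived from target node pressures (capacitors:
#' \code{V = Vu + C (P - P_ref)}) or given directly (chambers); inductive
#' flows default to zero.  The intramyocardial external reference is taken at
#' its diastolic value (gamma contribution omitted) for initialisation.
#'
#' @param network a \code{\link{cvNetwork}}.
#' @param pressures named list/vector of node pressures in mmHg (capacitor
#'   nodes).
#' @param volumes named list/vector of chamber volumes in ml, keyed by element
#'   id.
#' @param flows named list/vector of initial inductive-branch flows, ml/s.
#' @return named numeric state vector matching the network's state registry.
#' @export
stateTemplate <- function(network, pressures = list(), volumes = list(),
                          flows = list()) {
  cn <- compileNetwork(network)
  x <- numeric(length(cn$stateNames))
  names(x) <- cn$stateNames
  kinds <- vapply(network$elements, `[[`, "", "kind")
  storage <- network$elements[kinds %in% c("capacitor", "chamber")]
  for (i in seq_along(storage)) {
    e <- storage[[i]]
    if (e$kind == "capacitor") {
      p <- pressures[[e$node]]
      pref <- switch(e$ext, ambient = 0, intrathoracic = network$Pt,
                     intramyocardial = 0)
      x[i] <- e$Vu + e$C * ((if (is.null(p)) pref else p) - pref)
    } else {
      v <- volumes[[e$id]]
      x[i] <- if (is.null(v)) e$V0 else v
    }
  }
  for (nm in names(flows)) {
    j <- match(nm, cn$stateNames)
    if (!is.na(j)) x[j] <- flows[[nm]]
  }
  x
}

totalVolume <- function(network, state) {
  cn <- compileNetwork(network)
  sum(state[seq_len(cn$ns)])
}
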