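#' Thoracic artificial lung parameter block
#'
#' A pumpless TAL modelled as an inlet graft (R, L, C), two compliant device
#' chambers joined by flow-dependent resistances, and two return grafts: one
#' to the left atrium and one to the distal pulmonary artery.  The native
#' pulmonary-artery band \code{RTALpab} sits on the natural PA segment
#' between the two anastomoses and governs the flow split in hybrid mode.
#'
#' Attachment modes ("infinite resistance" is realised by branch removal):
#' \describe{
#'   \item{off}{all TAL branches disabled; the simulation matches the
#'     unattached network.}
#'   \item{parallel}{distal-PA return disabled; blood is routed from the
#'     pulmonary artery through the TAL and back to the left atrium, with
#'     the banded native path still open.}
#'   \item{series}{left-atrial return and the native (banded) PA path
#'     disabled; all flow passes through the TAL to the distal PA.}
#'   \item{hybrid}{all three paths active; \code{RTALpab} divides the flow
#'     between the natural lung and the left atrium.}
#' }
#'
#' @param mode attachment mode: \code{"off"}, \code{"parallel"},
#'   \code{"series"} or \code{"hybrid"}.
#' @param RTALin,LTALin,CTALin inlet graft resistance (mmHg·s/ml), inertance
#'   (mmHg·s^2/ml) and compliance (ml/mmHg).
#' @param CTALad,CTALap inlet and outlet device-chamber compliances,
#'   ml/mmHg.
#' @param RTALad0,kad,RTALap0,kap linear and quadratic coefficients of the
#'   flow-dependent inlet/outlet resistances (dP = R0 Q + k Q |Q|).
#' @param RTALala,LTALala left-atrial return graft resistance and inertance.
#' @param RTALan,LTALan distal-PA return graft resistance and inertance.
#' @param RTALpab native pulmonary-artery band resistance, mmHg·s/ml.
#' @param disabled character vector of branches to disable on top of the
#'   mode (any of \code{"inlet"}, \code{"laReturn"}, \code{"paReturn"},
#'   \code{"native"}); used to realise mode-limit configurations.
#' @return a list of class \code{talParams}.
#' @export
talParams <- function(mode = c("off", "parallel", "series", "hybrid"),
                      RTALin = 0.05, LTALin = 1e-4, CTALin = 1.5,
                      CTALad = 2.0, RTALad0 = 0.10, kad = 2e-3,
                      CTALap = 2.0, RTALap0 = 0.10, kap = 2e-3,
                      RTALala = 0.05, LTALala = 1e-4,
                      RTALan = 0.15, LTALan = 1e-4,
                      RTALpab = 0.15, disabled = character()) {
  mode <- match.arg(mode)
  for (v in c(CTALin, CTALad, CTALap))
    checkScalar(v, "TAL compliance", positive = TRUE)
  for (v in c(LTALin, LTALala, LTALan))
    checkScalar(v, "TAL inertance", positive = TRUE)
  for (v in c(RTALin, RTALad0, kad, RTALap0, kap, RTALala, RTALan, RTALpab))
    checkScalar(v, "TAL resistance", nonneg = TRUE)
  bad <- setdiff(disabled, c("inlet", "laReturn", "paReturn", "native"))
  if (length(bad))
    tsError(sprintf("unknown TAL branch name(s): %s",
                    paste(bad, collapse = ", ")), "talsim_config_error")
  structure(list(mode = mode, RTALin = RTALin, LTALin = LTALin,
                 CTALin = CTALin, CTALad = CTALad, RTALad0 = RTALad0,
                 kad = kad, CTALap = CTALap, RTALap0 = RTALap0, kap = kap,
                 RTALala = RTALala, LTALala = LTALala, RTALan = RTALan,
                 LTALan = LTALan, RTALpab = RTALpab, disabled = disabled),
            class = "talParams")
}

#' Configure the attachment mode of a TAL block
#'
#' Returns a copy of the parameter block with the requested mode; the
#' branch-disabling pattern implied by the mode is applied when the TAL is
#' attached to a network.
#'
#' @param params a \code{\link{talParams}}.
#' @param mode one of \code{"off"}, \code{"parallel"}, \code{"series"},
#'   \code{"hybrid"}.
#' @param disabled optional extra branch disables (see
#'   \code{\link{talParams}}).
#' @return the updated \code{talParams}.
#' @export
configureTal <- function(params, mode, disabled = params$disabled) {
  stopifnot(inherits(params, "talParams"))
  if (!mode %in% c("off", "parallel", "series", "hybrid"))
    tsError(sprintf("unknown TAL mode '%s'", mode), "talsim_config_error")
  params$mode <- mode
  bad <- setdiff(disabled, c("inlet", "laReturn", "paReturn", "native"))
  if (length(bad))
    tsError(sprintf("unknown TAL branch name(s): %s",
                    paste(bad, collapse = ", ")), "talsim_config_error")
  params$disabled <- disabled
  params
}

## Which TAL paths are active for a given configuration, and the band
## resistance added to the native PA segment.
talBranchPlan <- function(params) {
  mode <- params$mode
  act <- list(
    inlet = mode != "off",
    internal = mode != "off",
    laReturn = mode %in% c("parallel", "hybrid"),
    paReturn = mode %in% c("series", "hybrid"),
    native = mode != "series",
    band = if (mode == "hybrid") params$RTALpab else 0)
  for (d in params$disabled) {
    if (d == "native") act$native <- FALSE else act[[d]] <- FALSE
  }
  act
}

#' Pressure drop of a flow-dependent TAL resistance
#'
#' \code{dP = R0 Q + k Q |Q|}: linear plus sign-preserving quadratic loss;
#' \code{k = 0} recovers a linear resistance.
#'
#' @param Q flow, ml/s (vectorised).
#' @param R0 linear resistance coefficient, mmHg·s/ml (>= 0).
#' @param k quadratic coefficient, mmHg·s^2/ml^2 (>= 0).
#' @return pressure drop, mmHg.
#' @export
flowDependentDrop <- function(Q, R0, k) {
  if (any(R0 < 0) || any(k < 0))
    tsError("'R0' and 'k' must be >= 0", "talsim_domain_error")
  R0 * Q + k * Q * abs(Q)
}

#' Attach a thoracic artificial lung to a cardiovascular network
#'
#' Anastomoses the TAL inlet to the main pulmonary artery node, splits the
#' outlet towards the distal small-PA node and the left atrium, and places
#' the band resistance on the native PA segment between the two anastomoses.
#' Three storage states (inlet graft and the two device chambers, all
#' referenced to intrathoracic pressure) and up to three inertial states are
#' registered.  Branches excluded by the mode are disabled, i.e. removed
#' from the dynamics.
#'
#' @param network a \code{\link{cvNetwork}} built by
#'   \code{\link{buildNetwork}} (must contain nodes \code{pam}, \code{pas},
#'   \code{la} and the native branch \code{Lpam}).
#' @param params a configured \code{\link{talParams}}.
#' @param vu optional named unstressed-volume vector (internal use).
#' @return the extended network.
#' @export
attachTal <- function(network, params, vu = NULL) {
  stopifnot(inherits(network, "cvNetwork"), inherits(params, "talParams"))
  ids <- vapply(network$elements, `[[`, "", "id")
  if ("CTALin" %in% ids)
    tsError("a TAL is already attached to this network",
            "talsim_topology_error")
  need <- c("pam", "pas", "la")
  if (!all(need %in% network$nodes))
    tsError("network lacks the pulmonary/left-atrial nodes required for TAL attachment",
            "talsim_topology_error")
  plan <- talBranchPlan(params)
  vuT <- if (is.null(vu)) c(talin = 0, talad = 0, talap = 0) else vu

  add <- list(
    capacitorElement("CTALin", "talin", params$CTALin,
                     ext = "intrathoracic", Vu = vuT[["talin"]],
                     volumeName = "VTALin"),
    capacitorElement("CTALad", "talad", params$CTALad,
                     ext = "intrathoracic", Vu = vuT[["talad"]],
                     volumeName = "VTALad"),
    capacitorElement("CTALap", "talap", params$CTALap,
                     ext = "intrathoracic", Vu = vuT[["talap"]],
                     volumeName = "VTALap"),
    resistorElement("RTALad", "talin", "talad", params$RTALad0,
                    sub = "flowdep", k = params$kad,
                    enabled = plan$internal, flowName = "QTALad"),
    resistorElement("RTALap", "talad", "talap", params$RTALap0,
                    sub = "flowdep", k = params$kap,
                    enabled = plan$internal, flowName = "QTALap"),
    inductorElement("LTALin", "pam", "talin", params$LTALin,
                    R = params$RTALin, enabled = plan$inlet,
                    flowName = "QTALin"),
    inductorElement("LTALala", "talap", "la", params$LTALala,
                    R = params$RTALala, enabled = plan$laReturn,
                    flowName = "QTALala"),
    inductorElement("LTALan", "talap", "pas", params$LTALan,
                    R = params$RTALan, enabled = plan$paReturn,
                    flowName = "QTALan"))

  els <- network$elements
  iN <- which(ids == "Lpam")
  if (!length(iN))
    tsError("network lacks the native pulmonary branch 'Lpam'",
            "talsim_topology_error")
  els[[iN]]$R <- els[[iN]]$R + plan$band
  els[[iN]]$enabled <- plan$native
  cvNetwork(c(els, add), period = network$period, Pt = network$Pt,
            gamma = network$gamma, septal = network$septal,
            pressureNames = network$pressureNames)
}
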