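#' Activation fraction of a heart chamber
#'
#' Single-lobe raised cosine: for phase \code{tau = (t - onset) mod period}
#' within the active window \code{[0, Tsys)},
#' \code{a = (1 - cos(2 pi tau / Tsys)) / 2}; zero otherwise.  Continuous,
#' peaking at exactly 1 at \code{tau = Tsys/2}.  Vectorised over all
#' arguments.
#'
#' @param t time, s.
#' @param onset activation onset within the cycle, s.
#' @param Tsys active duration, s.
#' @param period cardiac period, s.
#' @return activation in [0, 1].
#' @export
activationFraction <- function(t, onset, Tsys, period) {
  tau <- (t - onset) %% period
  ifelse(tau < Tsys, 0.5 * (1 - cos(2 * pi * tau / Tsys)), 0)
}

#' Instantaneous chamber elastance
#'
#' Linear interpolation between diastolic and systolic stiffness:
#' \code{e = Emin + (Emax - Emin) a}.
#'
#' @param a activation fraction in [0, 1].
#' @param Emax,Emin systolic and diastolic elastance, mmHg/ml.
#' @return elastance, mmHg/ml.
#' @export
chamberElastance <- function(a, Emax, Emin) {
  if (any(a < 0 | a > 1)) tsError("activation must lie in [0, 1]",
                                  "talsim_domain_error")
  Emin + (Emax - Emin) * a
}

#' Chamber pressure from the elastance law
#'
#' \code{P = e (V - V0) + P_ref}.  Negative transmural pressures are
#' permitted (diastolic suction).
#'
#' @param V chamber volume, ml.
#' @param e instantaneous elastance, mmHg/ml.
#' @param V0 unstressed volume, ml.
#' @param Pref external reference pressure, mmHg (intrathoracic for the
#'   heart).
#' @return pressure, mmHg.
#' @export
chamberPressure <- function(V, e, V0, Pref = 0) {
  e * (V - V0) + Pref
}

#' Ideal diode valve flow
#'
#' An ideal diode in series with a resistance: forward flow
#' \code{(P_up - P_down)/R} when the upstream pressure exceeds the
#' downstream pressure, zero otherwise.  Never negative.
#'
#' @param Pup,Pdown upstream and downstream pressures, mmHg.
#' @param R valve resistance, mmHg·s/ml (> 0).
#' @return flow, ml/s.
#' @export
valveFlow <- function(Pup, Pdown, R) {
  if (any(R <= 0)) tsError("valve resistance must be > 0",
                           "talsim_domain_error")
  pmax(Pup - Pdown, 0) / R
}

#' Heart parameter set
#'
#' Four variable-elastance chambers and four diode valves, plus the timing
#' constants of the activation clock.  Ventricular systole defaults to
#' \code{0.3 sqrt(period)} s; atrial contraction lasts \code{prDelay} s and
#' ends exactly at ventricular onset.
#'
#' @param hr heart rate, bpm.
#' @param lv,rv,la,ra lists with \code{Emax}, \code{Emin} (mmHg/ml) and
#'   \code{V0} (ml) for each chamber.
#' @param Rli,Rlo,Rri,Rro mitral, aortic, tricuspid and pulmonary valve
#'   resistances, mmHg·s/ml.
#' @param septal optional linear septal coupling coefficient (default 0,
#'   decoupled ventricles).
#' @param TsysV ventricular systolic duration, s (NULL = Bazett-style
#'   default).
#' @param prDelay atrio-ventricular activation delay, s.
#' @return a list of class \code{heartParams}.
#' @export
heartParams <- function(hr = 75,
                        lv = list(Emax = 2.5, Emin = 0.08, V0 = 15),
                        rv = list(Emax = 0.7, Emin = 0.04, V0 = 15),
                        la = list(Emax = 0.25, Emin = 0.15, V0 = 10),
                        ra = list(Emax = 0.25, Emin = 0.15, V0 = 10),
                        Rli = 0.005, Rlo = 0.008, Rri = 0.005, Rro = 0.008,
                        septal = 0, TsysV = NULL, prDelay = 0.16) {
  checkScalar(hr, "hr", positive = TRUE)
  for (ch in list(lv, rv, la, ra)) {
    checkScalar(ch$Emax, "Emax", positive = TRUE)
    checkScalar(ch$Emin, "Emin", positive = TRUE)
    if (ch$Emax < ch$Emin)
      tsError("chamber requires Emax >= Emin", "talsim_domain_error")
  }
  for (r in c(Rli, Rlo, Rri, Rro)) checkScalar(r, "valve R", positive = TRUE)
  period <- 60 / hr
  if (is.null(TsysV)) TsysV <- 0.3 * sqrt(period)
  if (TsysV >= period || prDelay >= period)
    tsError("systolic duration and PR delay must be shorter than the period",
            "talsim_domain_error")
  structure(list(hr = hr, period = period, lv = lv, rv = rv, la = la,
                 ra = ra, Rli = Rli, Rlo = Rlo, Rri = Rri, Rro = Rro,
                 septal = septal, TsysV = TsysV, TsysA = prDelay,
                 prDelay = prDelay),
            class = "heartParams")
}
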