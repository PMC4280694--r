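---
title: "Modelling heart-lung interaction under thoracic artificial lung assistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heart-lung interaction under thoracic artificial lung assistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(talsim)
```

`talsim` is a modular lumped-parameter (0D) simulator of the circulation
built to study how a pumpless thoracic artificial lung (TAL) interacts with
a pressure-overloaded right heart.  This vignette is the package's own
account of the model: the equations, the assumptions behind them, the
parameters that matter, how the virtual patients are calibrated, and what
the simulations can and cannot say about real patients.

## The circuit

Every compartment is one of four element types attached to named nodes:

* **Compliances** store volume and define their node's pressure
  algebraically, `P = (V - Vu)/C + P_ref`.  `Vu` is an unstressed volume
  used purely for blood-volume bookkeeping; it cancels from the dynamics.
* **Variable-elastance chambers** are compliances whose stiffness cycles
  between a diastolic `Emin` and a systolic `Emax`:
  `P = [Emin + (Emax - Emin) a(t)] (V - V0) + P_ref`.  The activation
  `a(t)` is a single-lobe raised cosine over the systolic duration —
  continuous, peaking at exactly 1 — which is the simplest waveform that
  produces smooth pressure-volume loops.  Because chamber pressure rises
  with filling, the model exhibits the Frank-Starling behaviour: more
  venous return or a higher `Emax` yields a larger stroke volume (both are
  verified in the test suite).
* **Resistive branches** carry algebraic flows: linear (`Q = dP/R`), ideal
  diode valves (`Q = max(dP, 0)/R`), flow-dependent TAL resistances
  (`dP = R0 Q + k Q|Q|`, inverted in closed form at every step), and a
  vascular-waterfall variant used by the coronary outflow (below).
* **Inductive branches** carry a flow state,
  `dQ/dt = (P_up - P_down - R Q)/L`, modelling blood inertia in the
  pulmonary artery segments and the TAL grafts.

Node pressures are always owned by exactly one storage element, so no
implicit solve is ever needed; a topology in which a node has only
resistive/inertial attachments is rejected with an error naming the node.
Pressure references follow anatomy: heart chambers, pulmonary compartments
and the TAL chambers sit in the thorax and reference the mean intrathoracic
pressure `Pt` (default −4 mmHg); the systemic arterial and venous
compliances reference ambient pressure.

The full virtual patient (`buildNetwork()`) comprises the four chambers and
valves, a three-element windkessel systemic arterial section (characteristic
resistance `Rcs` in series with `Cas ∥ Ras`; `Rcs` is lumped into the aortic
valve branch, which is exact because the diode makes that branch
unidirectional), an RC systemic venous section, RLC main and small pulmonary
artery segments, a single lumped arteriolar + capillary resistance
(`Rpar + Rpc`, folded into the small-PA branch), an RC pulmonary venous
section, and the coronary branch.  The arteriolar resistance is settable in
clinical CGS units; `cgsResistance()` divides by 1333.22
(1 mmHg = 1333.22 dyn/cm²).

## The coronary model

The coronary branch taps the aortic node, fills an intramyocardial
compliance, and drains to the right atrium.  Systolic compression is the
"intramyocardial pump": the compliance is squeezed by an external pressure
`γ·Plv` (default γ = 0.75), which throttles inflow during systole — the
computed inflow dips sharply at each beat and can transiently reverse, as
arterial coronary flow does.  A subtlety worth recording: with purely linear
elements the squeeze redistributes flow within the beat but leaves the
cycle mean unchanged (the compartment's mean pressure re-equilibrates), so
compression would have no net perfusion cost.  The outflow is therefore a
**vascular waterfall**: it drains against `max(Pra, γ·Plv)` and never runs
backwards.  With the waterfall in place, raising γ strictly lowers mean
coronary flow, which is the physiologically expected behaviour of
subendocardial compression.  The coronary perfusion index reported by
`cycleSummary()` is the magnitude of the loop traced by instantaneous
coronary inflow against aortic pressure over one cycle (shoelace area);
total arterial inflow is used, as the branch is not subdivided.

## The thoracic artificial lung

The TAL is a pumpless oxygenator: an inlet graft (R, L, C), two compliant
device chambers joined by flow-dependent resistances, and two return
grafts.  Only haemodynamics are modelled — no gas exchange.  Attachment
modes, with "infinite resistance" realised by removing the branch from the
dynamics rather than by a large number (which would only add stiffness):

* **parallel** — pulmonary artery → TAL → left atrium; the distal-PA return
  is removed and the native pulmonary path stays fully open.
* **series** — proximal PA → TAL → distal PA; the left-atrial return and
  the native PA segment between the anastomoses are removed.
* **hybrid** — all paths active; a band resistance `RTALpab` on the native
  PA segment between the two anastomoses divides the flow between the
  natural lung and the left-atrial return.

The band is interpreted as a surgical pulmonary-artery banding applied when
the flow split must be controlled, i.e. in hybrid mode; in parallel mode
the native path is untouched.  A consequence used by the tests: a hybrid
configuration with the distal-PA return disabled and `RTALpab = 0` has
*identical* equations to parallel mode, and one with the native and
left-atrial branches disabled is identical to series mode — the mode
algebra is exact to rounding error, not approximate.

Two behaviours of the calibrated device are worth flagging.  First, at
periodic steady state the two ventricles must pump the same per-beat volume
even under a left-atrial shunt — the TAL changes the *path* of pulmonary
flow, not the closed loop's totals — so LV and RV stroke volumes agree in
every mode.  Second, under hybrid assistance the distal-PA graft can carry
retrograde flow (the distal PA drains through the device); the monotone
effect of the band is therefore stated on the left-atrial share of total
pulmonary inflow, which rises strictly with `RTALpab`.

## Numerics

The state equations are integrated by an explicit Euler scheme implemented
in C++ with a default step of `dt = 1e-4` s — small enough for the stiffest
branches (valve resistances of a few 10⁻³ mmHg·s/ml) with ample margin,
while a full 60-cycle run takes well under a second.  Euler is the
reference method; the suite cross-checks it against a classical 4th-order
Runge-Kutta integration of the same derivative function (via `deSolve`) and
requires cycle-mean agreement within 1%, plus the textbook first-order
error halving on an RC discharge.  Because every branch flow moves volume
between storage elements symmetrically, closed loops conserve total stored
volume to rounding error at any step size.

Periodic steady state is declared when the relative change of the
cycle-mean monitors (all node pressures and each chamber's stroke volume,
with the denominator floored at 1 to keep near-zero means from inflating
the residual) stays below `tol = 1e-3` for three consecutive cycles, with a
minimum of four cycles and a budget of 60; a run that exhausts the budget
raises a convergence error carrying the last residuals.  Any state
magnitude exceeding 10⁵ aborts immediately with the offending slot named —
wrong parameters should fail fast, not silently.  Identical inputs give
bit-identical outputs; nothing in the core draws random numbers.

Degenerate inputs are contracts, not surprises: `tol = 0` always exhausts
the cycle budget; a zero-duration simulation returns exactly the initial
sample; disabled branches are absent from the state registry rather than
carrying zero flow.

## Virtual patients and what they stand for

No individual patient parameterisation is published for this experiment, so
the package ships a two-stage synthetic patient:

* **Normal preset.**  Chamber elastances (LV 2.5/0.08, RV 0.7/0.04, atria
  0.25/0.15 mmHg/ml), valve resistances (5–8·10⁻³ mmHg·s/ml), windkessel
  (Rcs 0.05, Cas 1.3, Ras 0.9), venous (Rvs 0.05, Cvs 80), pulmonary
  (total resistance ≈ 0.09 mmHg·s/ml, Cpam = Cpas = 2, Cvp = 15) and
  coronary values are calibration constants chosen once to put the resting
  preset in textbook ranges — mean aortic pressure 70–105 mmHg, cardiac
  output 4–6.5 l/min, mean PAP < 20 mmHg, coronary flow ≈ 200 ml/min at
  75 bpm.  Ventricular systole lasts `0.3·√period` (a Bazett-style
  scaling); atrial contraction starts 0.16 s before ventricular onset and
  ends exactly at it (the stated atrio-ventricular delay and the "ends at
  ventricular onset" requirement cannot both hold with a 0.1 s atrial
  systole, so the delay was kept and the atrial duration set equal to it).
  Total blood volume (5300 ml) is honoured through unstressed-volume
  bookkeeping — only stressed volume enters the dynamics, so preload
  interventions are expressed through the initial compartment pressures,
  and an attached TAL adds its own priming volume on top.
* **Pulmonary-hypertensive patient.**  `calibratePulmonaryHypertension()`
  bisects a common scale factor on (Rpar, Rpc, Rpas) with RV `Emax` reduced
  by 30% — chronic pressure overload with systolic impairment — until the
  steady-state mean PAP is within 1 mmHg of the 35 mmHg target, and
  verifies ≥ 20% RV dilation.  Every bisection iterate is kept in an audit
  log, so the calibrated preset is exactly reproducible.
* **TAL device values.**  The device's hydraulic constants are likewise
  calibration values, fixed once against the magnitudes reported for this
  class of experiment: bundle resistances `RTALad0 = RTALap0 = 0.10`
  mmHg·s/ml with quadratic losses `k = 2·10⁻³` mmHg·s²/ml² (≈ 15 mmHg drop
  at 6 l/min, a realistic pumpless-oxygenator figure), inlet and LA grafts
  0.05, distal-PA graft 0.15, band 0.15 mmHg·s/ml.  With these, parallel
  assistance at Rpar = 240 g·cm⁻⁴·s⁻¹ relieves mean PAP by roughly a
  quarter to a third, hybrid assistance somewhat more (best case near
  40%), and parallel raises cardiac output more than hybrid in every
  compliance combination — the pattern the protocol's directional and
  quantitative checks assert.  All values are exposed in `talParams()` and
  in the YAML configs.

## The training-course protocol

`runProtocol()` reproduces the three-step course experiment: for each
arteriolar resistance setting (240, then 120 g·cm⁻⁴·s⁻¹ — the latter
standing for pulmonary vasodilator therapy), run the assistance-off
baseline, then parallel and hybrid assistance for the four compliance
combinations `CTALin ∈ {1.5, 0.4}`, `CTALad = CTALap ∈ {2.0, 0.1}` ml/mmHg
(18 steady-state runs in all).  Percentage changes of the nine analysed
variables — LVEDV, LVESV, RVEDV, RVESV, CO, mean PAP, mean LAP, mean SVP
and the CBF-AoP loop area — are signed and computed against the
*same-resistance* baseline, which isolates the device effect from the drug
effect (the alternative, baselining everything at the original resistance,
would conflate the two).  CO is reported from the LV stroke volume, the
clinical convention.  EDV and ESV are volume extrema over the cycle, which
for ideal diode valves coincides with valve-event timing and is robust when
flows reverse.

## Known limitations

* No baroreflex or autonomic control: Ras, Rvs and heart rate are constants
  per run, so the model cannot show reflex compensation.
* No gas exchange: the TAL and lung are hydraulic elements only; nothing
  can be said about oxygenation benefit.
* Ventricles are decoupled by default; a linear septal coupling coefficient
  exists as an extension knob (off by default) but no pericardium is
  modelled.
* The virtual patient is a single calibrated individual, not a population;
  passing checks demonstrate that the implemented physics reproduces the
  reported response *pattern*, not that magnitudes transfer to any real
  patient.
* Explicit Euler at a fixed step is the deliberate reference integrator;
  extremely stiff parameterisations (e.g. near-zero compliances) will fail
  the divergence guard rather than integrate slowly.
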