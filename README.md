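# talsim

Lumped-parameter (0D) simulation of the human circulation with a pumpless
**thoracic artificial lung (TAL)** attachable to the pulmonary circulation in
parallel, series or hybrid mode.

Patients with severely elevated pulmonary vascular resistance develop right
ventricular pressure overload: the right ventricle dilates (RVEDV and RVESV
rise), pulmonary arterial pressure climbs, and systemic output falls.  A
pumpless TAL anastomosed to the pulmonary artery offers a low-resistance
bypass for right ventricular output.  How much it decompresses the pulmonary
artery — and at what cost to left-heart loading — depends on where the device
returns the blood (left atrium, distal pulmonary artery, or both) and on its
graft and chamber compliances.  `talsim` is aimed at physiologists, device
modellers and educators who want to explore exactly these trade-offs on a
reproducible virtual patient.

## The model

The circulation is an electrical analogue: pressure ↔ voltage, flow ↔
current, with resistances R (mmHg·s/ml), compliances C (ml/mmHg) and
inertances L (mmHg·s²/ml).  Its parts:

* **Heart** — four variable-elastance chambers.  Each chamber obeys
  `P(t) = e(t)·(V − V0) + Pt` with `e(t) = Emin + (Emax − Emin)·a(t)` and a
  single-lobe raised-cosine activation `a(t)`.  Valves are ideal diodes in
  series with a resistance: `Q = max(P_up − P_down, 0)/R`.
* **Systemic circulation** — three-element windkessel afterload
  (Rcs + Cas ∥ Ras) and an RC venous compartment.
* **Pulmonary circulation** — RLC main and small pulmonary artery segments,
  a lumped arteriolar + capillary resistance (Rpar, Rpc), and an RC venous
  compartment.  Rpar is settable in clinical CGS units
  (g·cm⁻⁴·s⁻¹ = dyn·s/cm⁵; divide by 1333.22 for mmHg·s/ml).
* **Coronary branch** — intramyocardial pump: an intramyocardial compliance
  squeezed by `γ·Plv`, draining through a vascular-waterfall outflow against
  `max(Pra, γ·Plv)`, so systolic compression impedes coronary perfusion.
* **TAL** — inlet graft (R, L, C), two compliant device chambers joined by
  flow-dependent resistances `ΔP = R₀Q + kQ|Q|`, a left-atrial return graft,
  a distal-pulmonary-artery return graft, and a native-PA band resistance
  (RTALpab) that divides the flow in hybrid mode.  "Infinite resistance" of
  an unused path is realised by removing the branch from the dynamics.

Node pressures are algebraic functions of the stored volumes, and the state
equations (`dV/dt` = net inflow, `dQ/dt = (ΔP − RQ)/L`) are integrated with
an explicit Euler scheme (compiled, step 0.1 ms) until the cycle means reach
a periodic steady state.

## Worked example

```r
library(talsim)

ss <- simulatePatient(normalPreset())
cycleSummary(ss)
#> <cycleSummary>
#>   mean PAP   14.1 mmHg   mean LAP    5.3 mmHg   mean SVP   5.4 mmHg
#>   mean AoP   91.0 mmHg   CO         5.90 l/min  HR   75.0 bpm
#>   LVEDV 146.1  LVESV  67.4  RVEDV 132.1  RVESV  53.4 ml
#>   CBF-AoP loop area    417.9 mmHg.ml/s
```

The resting virtual patient sits in textbook ranges: mean aortic pressure
91 mmHg, cardiac output 5.9 l/min, mean pulmonary arterial pressure
14 mmHg.  Next, make the patient pulmonary-hypertensive (bisection on the
pulmonary resistances with a weakened right ventricle until mean PAP reaches
35 mmHg) and apply parallel TAL assistance at a pulmonary arteriolar
resistance of 240 g·cm⁻⁴·s⁻¹:

```r
cal <- calibratePulmonaryHypertension(normalPreset())
cal
#> <phCalibration> resistance scale 6.344, mean PAP 35.5 mmHg (normal 14.1),
#>   RVEDV 167.7 ml (normal 132.1), 7 evaluations

assisted <- setParameter(cal$preset, "Rpar", 240, units = "g.cm-4.s-1")
assisted$tal <- talParams(mode = "parallel")
cycleSummary(simulatePatient(assisted))
#> <cycleSummary>
#>   mean PAP   22.6 mmHg   mean LAP    4.3 mmHg   mean SVP    5.5 mmHg
#>   mean AoP   80.7 mmHg   CO         5.19 l/min  HR   75.0 bpm
#>   LVEDV 130.8  LVESV  61.6  RVEDV 152.6  RVESV  83.4 ml
#>   CBF-AoP loop area    327.0 mmHg.ml/s
```

Routing pulmonary arterial blood through the device into the left atrium
decompresses the pulmonary artery and unloads the right ventricle, at the
price of higher left-heart volumes.  `runProtocol()` sweeps both assistance
modes, both resistance settings (240 and 120 g·cm⁻⁴·s⁻¹) and the four TAL
compliance combinations (CTALin ∈ {1.5, 0.4}, CTALad = CTALap ∈ {2.0, 0.1}
ml/mmHg), reporting signed percentage changes of nine haemodynamic variables
against the matching assistance-off baseline, and `directionalCheck()`
verifies the expected response directions.

A command-line wrapper is included:

```sh
Rscript inst/cli/talsim protocol --out results/
```

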