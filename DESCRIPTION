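Package: talsim
Title: Lumped-Parameter Cardiovascular Simulation with Thoracic
    Artificial Lung Assistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A modular lumped-parameter (0D) simulator of the human
    cardiovascular system: time-varying elastance heart chambers with
    ideal diode valves, a modified windkessel systemic circulation,
    RLC pulmonary arterial segments, a coronary branch based on the
    intramyocardial pump concept, and a pumpless thoracic artificial
    lung (TAL) that can be attached to the pulmonary circulation in
    parallel, in series or in hybrid mode.  The state equations are
    integrated to periodic steady state with an explicit Euler scheme
    implemented in C++.  Includes per-cycle haemodynamic analysis
    (cycle means, end-diastolic/end-systolic volumes, cardiac output,
    pressure-volume and coronary-flow/aortic-pressure loop areas), a
    calibrated pulmonary-hypertensive virtual patient, and a protocol
    runner that sweeps TAL modes, pulmonary arteriolar resistance and
    TAL compliances, reporting signed percentage changes against the
    matched assistance-off baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
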