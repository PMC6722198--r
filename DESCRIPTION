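Package: btu2d
Title: Drug Distribution in a 2D Brain Tissue Unit
Version: 0.1.0
Authors@R:
    person("btu2d", "developers", email = "btu2d@example.org", role = c("aut", "cre"))
Description: Simulates the local pharmacokinetics of a drug inside a single
    2D brain tissue unit: a 50 x 50 micrometre square of brain extracellular
    fluid (ECF) entirely surrounded by capillaries carrying the blood-brain
    barrier (BBB). Free drug in the ECF obeys an advection-diffusion equation
    coupled to two ordinary differential equations for specific (target) and
    non-specific binding; passive BBB exchange enters through Robin
    (flux-matching) boundary conditions driven by a closed-form plasma
    concentration profile after oral or intravenous dosing. Includes a
    method-of-lines solver with an adaptive TR-BDF2 stiff integrator and
    sparse analytic Jacobians, a well-mixed reduction and mass-balance /
    symmetry auditors used as verification oracles, scripted scenario suites
    (binding, kinetics, permeability, spatial maps), and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
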