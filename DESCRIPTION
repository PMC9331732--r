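Package: kvclamp
Title: Voltage-Clamp Simulation and Biophysical Characterization of Kv1.1
    Potassium Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates whole-cell voltage-clamp recordings of Kv1.1
    (KCNA1) potassium channels with Boltzmann steady-state activation,
    voltage-dependent first-order gating kinetics, bi-exponential C-type
    inactivation and exponential recovery, and analyzes such recordings
    back to the standard biophysical parameter set (activation midpoint
    and slope, activation/deactivation time constants, inactivation and
    recovery time constants) with cohort statistics. Includes a binomial
    dominant-negative subunit assembly model for wild-type/mutant
    co-expression, and trajectory geometry tools (S6 helix kink angle and
    four-fold symmetry angles) for multi-model PDB coordinate sets of
    tetrameric channel pore domains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    bio3d,
    signal
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    yaml
Config/testthat/edition: 3
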