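Package: dynred
Title: Likelihood-Based Reduction of Dynamical Scattering in Electron
    Diffraction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for correcting three-dimensional electron diffraction
    (microED) intensities for dynamical (multiple elastic) scattering.
    Fits a hyperbolic error model between observed and calculated
    structure-factor amplitudes to estimate a resolution-dependent
    dynamical error term, and down-weights overestimated weak
    reflections with a reciprocal generalized Wiener filter.  Includes
    SHELX HKLF4 reflection I/O and merging statistics, kinematic
    structure-factor calculation from CIF or PDB models with electron
    atomic scattering factors (including a refit of five-Gaussian
    parameterizations to the nine Cromer-Mann coefficients used by
    small-molecule refinement programs), restraint-based unit-cell
    refinement, and a simulator that generates reflection data with a
    known kinematic truth and a controllable dynamical perturbation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
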