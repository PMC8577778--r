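Package: rfdosim
Title: Radio-Frequency Dosimetry of Insect-Scale Bodies by FDTD Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for far-field radio-frequency (RF) dosimetry of
    insect-scale dielectric bodies between 2 and 240 GHz. Provides a
    two-relaxation Debye dielectric model with static conduction
    (evaluation, bounded least-squares fitting to coaxial-probe spectra,
    and extrapolation), STL mesh input/output and voxelization on uniform
    grids, parametric mosquito-like phantoms with labeled body parts, a
    finite-difference time-domain (FDTD) Maxwell solver with
    perfectly-matched-layer boundaries and plane-wave excitation at
    arbitrary incidence, an independent Mie-series absorption oracle for
    homogeneous spheres, and an exposure protocol (twelve standard plane
    waves, frequency sweeps, random orientations, per-body-part absorbed
    power, group comparisons, and sensitivity analyses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
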