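Package: pdcore
Title: Solution-Structure Analysis of Icosahedral Pyruvate Dehydrogenase
    Complex Cores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the multi-technique solution characterisation of
    pentagonal-dodecahedral multi-subunit assemblies such as the E2/E3BP
    core of the human pyruvate dehydrogenase complex. Builds synthetic
    icosahedral bead models with configurable E2/E3BP stoichiometry
    (substitution vs addition) and flexible N-terminal arms; computes
    small-angle scattering curves (Debye sums over spherical beads),
    Guinier fits, pair-distance distributions, regularized indirect
    Fourier transforms, Dmax estimation and normalized spatial
    discrepancy superposition; derives hydrodynamic parameters from the
    Svedberg relation (frictional ratio, Stokes radius and diameter,
    diffusion coefficient), standardizes and extrapolates sedimentation
    coefficients, coarse-grains coordinates onto cubic grids, computes
    bead-model translational friction by Rotne-Prager-Yamakawa
    supermatrix inversion or the Kirkwood approximation, and applies the
    hydration conversion factor; simulates and fits sedimentation
    equilibrium profiles for one or two species with infinite-dilution
    mass extrapolation; and fits two-state linear-extrapolation chemical
    denaturation curves with percent-change normalization and
    emission-peak-shift metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
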