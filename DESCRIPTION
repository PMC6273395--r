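Package: hopdyn
Title: Trajectory Surface Hopping with Overlap-Based Time-Derivative Couplings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale toolkit for nonadiabatic molecular dynamics on
    analytic model potentials. Implements fewest-switches trajectory surface
    hopping with time-derivative nonadiabatic couplings evaluated from
    wavefunction overlaps between consecutive time steps: the cheap
    orbital-derivative (OD) contraction for CIS-type wavefunctions and the
    reference Slater-determinant (DD) overlap method, including orbital phase
    matching. Around the hopping engine it provides harmonic-oscillator Wigner
    sampling of initial conditions, nuclear-ensemble absorption spectra with
    excitation-window filtering, Cremer-Pople ring-puckering analysis with
    Boeyens conformer classification, sequential kinetic-model fitting of
    state occupations with binomial confidence bounds, and linear
    interpolation of internal coordinates for reaction paths. A three-state,
    two-coordinate model anchored to published excited-state energies of
    thymine drives end-to-end runs without any electronic-structure code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
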