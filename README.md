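# hopdyn

Trajectory surface hopping with overlap-based time-derivative couplings,
at desk scale.

## What this is for

Nonadiabatic dynamics studies of ultrafast photorelaxation — internal
conversion of UV-excited nucleobases being the canonical example — rest
on a stack of machinery: fewest-switches surface hopping (FSSH),
nonadiabatic couplings, Wigner-sampled initial conditions,
nuclear-ensemble spectra, ring-puckering analysis of hop geometries, and
kinetic fits of state occupations. In production that stack is welded to
an electronic-structure code, which makes the algorithms themselves hard
to test, teach, or modify.

hopdyn implements the full stack in R against *analytic model
Hamiltonians*, including a three-state, two-coordinate model of a
thymine-like pyrimidine whose adiabatic energies at six anchor
configurations (state minima and the S2/S1 and S1/S0 intersections)
reproduce published ADC(2) energies to better than 0.05 eV. Every
component is validated against independent oracles: determinant algebra,
analytic mixing angles, closed-form propagators, exact round trips. The
audience is method developers, students of nonadiabatic dynamics, and
anyone who needs a transparent reference implementation of this tool
chain.

## The core methods

**Time-derivative couplings.** Hopping is driven by
$\sigma_{mn} = \langle\Psi_m|\partial_t \Psi_n\rangle$, evaluated from
wavefunction overlaps between consecutive time steps (replacing the
coupling-vector dot product $\mathbf{F}_{mn}\cdot\mathbf{v}$). For
CIS-type wavefunctions $|\Psi_m\rangle = \sum_{ia} C^m_{ia}
|\Phi_i^a\rangle$ two routes are implemented:

- `dd_sigma()` — the determinant (DD) reference: the overlap expanded
  over all pairs of singly excited determinants, one
  $N_{occ}\times N_{occ}$ determinant per pair;
- `od_sigma()` — the orbital-derivative (OD) contraction, which needs
  only the molecular-orbital overlap matrix $S_{ji}(t, t+\Delta t)$ and
  the CI coefficients, at $N_{occ} N_{virt}^2$ cost,

with orbital phase matching (`phase_match()`) restoring basis continuity
across steps. The suite holds OD and DD to within $10^{-6}$ of each
other over hundreds of random instances, and both to the analytic
mixing-angle derivative $d\theta/dt$ on model paths.

**The engine.** Velocity-Verlet nuclei (0.5 fs), 5th-order Butcher
electronic substeps (0.025 fs) on interpolated energies and couplings,
fewest-switches hopping, energy-based decoherence
($\alpha = 0.1$ Hartree), uniform velocity rescaling at hops, and the
S1/S0 gap-stop criterion (0.15 eV, configurable) that stands in for
internal conversion to the ground state where excited-state methods
break down.

**Analysis.** Cremer–Pople puckering $(Q, \theta, \phi)$ with Boeyens
conformer classification and symmetry-projected hop maps; sequential
kinetic-model fits $(f_\tau, \tau)$ per process; worst-case binomial
confidence half-widths; LIIC reaction paths; nuclear-ensemble spectra
with excitation-window filtering of initial conditions.

## A worked example

The standard protocol on the anchored model — 500-point Wigner ensemble,
spectrum, window filtering, 115 trajectories for 1 ps, puckering and
kinetics:

```r
library(hopdyn)

model <- build_thymine_model()
ic    <- sample_initial_conditions(model, 500, seed = 11)
spec  <- nea_spectrum(ic)
spec
#> <spectrum_curve: band maximum at 5.116 eV, width 0.050 eV, unit-max normalized>

sel <- filter_energy_window(ic, spec$band_max, 0.13, target_state = 2)
sel <- subsample_initial_conditions(sel, 115, seed = 11)

ens <- run_ensemble(model, sel, run_settings(seed = 11, t_max = 1000))
ens
#> <fssh_ensemble on 'thymine3s': 115 trajectories (0 failed), 169 accepted hops>

occ <- aggregate_occupations(ens)
fit <- fit_sequential_model(occ)
fit
#> Sequential kinetic fit:
#>   S2 -> S1: f = 1.000, tau = 30.9 fs
#>   S1 -> S0: f = 1.000, tau = 27.5 fs
#>   residual norm 5.9

hops <- ens$hops[ens$hops$accepted & ens$hops$from == 3 & ens$hops$to == 2, ]
map  <- hop_pucker_map(hops, ring_adapter = model$ring_adapter)
head(sort(table(map$conformer), decreasing = TRUE), 1)
#> 3,6B
#>  142

confidence_halfwidth(115, 0.90)
#> [1] 7.66917
```

Reading the numbers: the simulated absorption band peaks at 5.12 eV,
just above the model's vertical bright-state excitation (5.06 eV at the
reference geometry); 115 initial conditions inside the ±0.13 eV window
are propagated, relax S2 → S1 → S0 completely, and the S2/S1 hop
geometries cluster at the 3,6-boat — the conformation of the
minimum-energy crossing. With 115 trajectories any occupation fraction
carries at most a ±7.7 ≈ ±8 percentage-point uncertainty at 90%
confidence. The fitted time constants (about 30 fs) describe the
two-coordinate surrogate, which relaxes far faster than the real
39-dimensional molecule; see the methods vignette
(`vignettes/hopdyn-methods.Rmd`) for what the model does and does not
emulate.

A command-line driver wraps the same functions:

```sh
Rscript inst/cli/hopdyn.R propagate --model thymine3s --n 10 --seed 7 --out runs/demo
Rscript inst/cli/hopdyn.R pucker ideal-boat.xyz --out runs/pucker
```

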