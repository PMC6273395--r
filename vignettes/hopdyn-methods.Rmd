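---
title: "Models and numerics behind hopdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind hopdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopdyn)
```

hopdyn is a desk-scale toolkit for nonadiabatic molecular dynamics. It
implements the machinery of a trajectory-surface-hopping study of an
ultrafast photorelaxation — couplings, hopping, initial conditions,
spectra, ring-puckering analysis and kinetics — on analytic model
Hamiltonians, so that every component can be exercised and validated
without an electronic-structure code. This vignette explains the models,
the conventions, and the numerical choices, and states what the tests do
and do not demonstrate about real molecules.

## Units

Lengths are in Angstrom, times in fs, energies in eV, masses in amu.
`hop_units()` collects the conversion factors; in these units
1 amu A$^2$/fs$^2$ = 103.6427 eV and $\hbar$ = 0.6582 eV fs. The
decoherence parameter is accepted in Hartree (converted internally),
because that is how the quantity is conventionally quoted.

## The anchored three-state model

`build_thymine_model()` is a three-state, two-coordinate diabatic model of
a thymine-like pyrimidine. The coordinates are a C4O-stretch-like $x$ and
a ring-puckering-like $y$; the three diabats carry closed-shell,
n$\pi^*$ and $\pi\pi^*$ character. The model is *anchored*: its adiabatic
energies at six designated configurations — the S$_0$, S$_1$ and S$_2$
minima, the S$_2$/S$_1$ intersection, and the two S$_1$/S$_0$
intersections — reproduce published ADC(2) energies of thymine to better
than 0.05 eV (15 printed values in total; three of the six rows print no
S$_2$ entry).

Construction, done once at build time by exact linear solves:

* the ground diabat is the isotropic harmonic $V_1 = \tfrac12 K (x^2+y^2)$
  with $K = 20$ eV/A$^2$, zero at the S$_0$ minimum (the energy zero of
  the anchor table). Each anchor therefore sits on the radius fixed by its
  S$_0$ energy; the angles are design choices that mimic the character of
  each geometry change (stretch-dominated for the S$_1$/S$_2$ minima and
  the n$\pi^*$/S$_0$ crossing, pucker-dominated for the boat-shaped
  crossings).
* the n$\pi^*$ diabat is a full quadratic
  $a + b_1 x + b_2 y + \tfrac12 c_1 x^2 + \tfrac12 c_2 y^2$ solved exactly
  from its five anchor values.
* the $\pi\pi^*$ diabat additionally needs a cross term
  ($c_{12}xy$, curvatures fixed at 14 and 8 eV/A$^2$, remaining four
  parameters solved from its four anchors); the cross term keeps the
  quadratic positive definite while letting the surface fall toward the
  strongly puckered $\pi\pi^*$/S$_0$ crossing.
* constant diabatic couplings: 0.005 eV to the ground state (narrowly
  avoided S$_1$/S$_0$ crossings, appropriate for seams the dynamics is
  *stopped* at rather than propagated through) and 0.03 eV between the
  excited diabats (the S$_2$/S$_1$ funnel the hopping actually traverses).

With $K = 20$ eV/A$^2$ and the default 12 amu (carbon-like) masses the
ground-state vibrational period is about 50 fs (670 cm$^{-1}$), a
realistic ring-mode scale. The straight-line interpolated profile from
the S$_2$ minimum to the S$_2$/S$_1$ crossing rises by 0.06 eV — small
and positive, matching the near-barrierless picture the anchor energies
imply. One honest deviation from the real molecule: in this
two-coordinate model the S$_2$/S$_1$ seam dips slightly below the
anchored crossing point, so the upper surface funnels trajectories to the
seam faster than the 39-dimensional molecule would. Time constants
produced by the model ensemble are therefore *not* comparable to the
published ones; parameter recovery of the kinetic fit is tested on
synthetic ensembles instead (below).

`single_crossing` and `double_crossing` are one-coordinate two-state
models used as controlled testbeds, and `mixing_angle()` provides the
analytic diabatic-adiabatic rotation angle against which overlap-based
couplings are checked.

## Time-derivative couplings: OD and DD

For CIS-type wavefunctions
$|\Psi_m\rangle = \sum_{ia} C^m_{ia} |\Phi_i^a\rangle$ the coupling
$\sigma_{mn} = \langle \Psi_m | \partial_t \Psi_n \rangle$ is evaluated
between consecutive steps in two ways:

* **DD** (`dd_sigma()`): the wavefunction overlap is expanded over all
  pairs of singly excited determinants; each pair contributes the
  determinant of the occupied-block orbital overlap with the bra row and
  ket column replaced by the respective virtuals. This is exact (within
  CIS) and serves as the reference; it costs
  $N_{occ}^2 N_{virt}^2$ determinants.
* **OD** (`od_sigma()`): the cheap contraction of the CI-coefficient
  finite difference with the occupied- and virtual-block orbital overlap
  derivatives, scaling as $N_{occ} N_{virt}^2$ (`scaling_probe()` tabulates
  the operation counts).

Conventions that the printed formulas of this family of methods leave
open, fixed here and validated against DD:

* **Determinant ordering.** The virtual orbital of an excitation
  $i \to a$ occupies the position of $i$ in the determinant (in-place
  replacement). With this convention the reordering phase attached to the
  occupied-block term is $+1$ for every index pair; the alternating
  $(-1)^{i+j}$ parities of the append-at-end convention never appear.
* **Phase matching** (`phase_match()`): orbitals at $t+\Delta t$ are
  reassigned by maximum-|overlap| within the occupied and virtual blocks
  separately and sign-flipped so diagonal overlaps are non-negative; ties
  break deterministically toward lower indices. CI coefficient matrices
  are co-transformed (`align_cis_states()`), and each CI vector's global
  sign is fixed by maximizing its overlap with the earlier step.
* **Midpoint contraction.** The finite-difference coupling is naturally a
  midpoint quantity. The orbital-derivative terms are therefore
  contracted with midpoint-averaged CI coefficients, and the full matrix
  is antisymmetrized. Both choices matter: the overlap matrix of a
  rotation has no even-order antisymmetric part, so with midpoint
  averaging the OD error relative to DD starts at *third* order in the
  step-to-step change, which is what makes the 1e-6 agreement of the test
  suite achievable at realistic step sizes. The raw forward-difference
  matrix remains available (`antisymmetrize = FALSE` returns it as an
  attribute).
* Whether production codes antisymmetrize is not documented in this
  method family; antisymmetric is the default here because it enforces
  the exact skew symmetry of the continuous coupling.

`synthetic_cis_along_path()` manufactures CIS fixtures whose *physical*
state mixing follows a two-state model's rotation angle while the orbital
basis drifts by seeded intra-block rotations (the CI matrices are
co-rotated, leaving the states invariant). This gives a nontrivial
analytic oracle: whatever the orbital drift, the OD/DD coupling must
equal $d\theta/dt$.

## The surface-hopping engine

Per classical step of $\Delta t = 0.5$ fs:

1. velocity-Verlet on the active adiabatic surface (Hellmann-Feynman
   gradients of the diabatic model);
2. couplings from the adiabatic-rotation overlap
   $\sigma = (U - U^T)/(2\Delta t)$, $U = R(t)^T R(t+\Delta t)$, with
   columns sign-matched step to step to avoid spurious trivial-crossing
   artifacts;
3. electronic amplitudes integrated through the step by the 6-stage
   5th-order Butcher Runge-Kutta scheme in substeps of 0.025 fs, with
   energies interpolated linearly across the step and the
   midpoint-assigned couplings interpolated between consecutive
   intervals. Two numerical safeguards: the integration is performed
   relative to the mean electronic energy (a pure global phase, restored
   exactly afterwards), which removes most of the phase stiffness; and
   because the continuous equation conserves the norm exactly, the norm
   drift of a substep is used as a truncation-error controller that
   locally halves the substep at coupling spikes. Norm conservation per
   step is then at the 1e-10 level even through narrowly avoided
   crossings.
4. fewest-switches hop test once per classical step, from the
   accumulated amplitudes:
   $g_{l\to m} = \max(0, -2\Delta t\,\mathrm{Re}(a_m^* \sigma_{ml} a_l)/|a_l|^2)$,
   the positive part of the population flux in the convention of the
   propagator $\dot a_m = -(i/\hbar)E_m a_m - \sum_l \sigma_{ml} a_l$;
5. accepted hops rescale the velocities uniformly along the velocity
   direction (overlap-based propagation provides no coupling vector to
   rescale along); frustrated hops leave velocities unchanged;
6. energy-based decoherence damping of inactive amplitudes with
   $\tau_m = (\hbar/|E_m - E_l|)(1 + \alpha/E_{kin})$, $\alpha$ = 0.1
   Hartree by default, the active amplitude rescaled to restore the norm;
7. termination when the trajectory is on S$_1$ and the S$_1$/S$_0$ gap
   drops below 0.15 eV (configurable; 0.30 eV is the standard
   sensitivity variant) — the step time is recorded as the crossing-time
   estimate — or at 1 ps. While the gap stop is in force, couplings to
   the ground state are excluded from the amplitude propagation and from
   hopping: internal conversion to S$_0$ is represented by the stop
   criterion alone, exactly because the excited-state methods this
   protocol mirrors provide no reliable S$_1$/S$_0$ couplings. (Disable
   the gap stop to recover ordinary all-state hopping, as the two-state
   testbeds do.) Ground-state dynamics is not continued after
   termination.

Ensembles derive per-trajectory seeds from the master seed by a fixed
counter scheme, so results are bit-for-bit reproducible regardless of
evaluation order; failing trajectories are quarantined, not fatal.

## Initial conditions and spectra

`wigner_sample()` draws coordinates and momenta of each harmonic mode
from the ground-state Wigner Gaussians
($\sigma_q^2 = \hbar/2\mu\omega$, $\sigma_p^2 = \hbar\mu\omega/2$).
`model_normal_modes()` supplies modes from the mass-weighted Hessian of a
model surface. The nuclear-ensemble spectrum is the average of
oscillator-strength-weighted normalized Gaussians at the vertical
excitation energies; the default line width of 0.05 eV is a plotting
choice (the spectrum-shape tests use a 0.15 eV kernel, comparable to the
band's intrinsic spread, so the located maximum is a stable statistic at
the 500-point ensemble size). Intensities are reported in arbitrary
units normalized to unit band maximum. Oscillator strengths on the
three-state model are proportional to the $\pi\pi^*$ diabatic weight of
each adiabatic state — the bright-state character — with the protocol
value 0.2 at the reference geometry.

The excitation-window filter keeps points whose vertical excitation to
the target state lies within `center ± half_width`, boundaries inclusive;
selection down to a trajectory budget is uniform over qualifying points
by default (oscillator-strength weighting is available). The standard
protocol on the anchored model mirrors the published one: a 500-point
ensemble, a ±0.13 eV window about the band maximum, and 115 trajectories.

## Ring puckering

`cremer_pople()` follows the classic prescription: centroid origin, mean
plane fixed by the two first-order trigonometric sum conditions, then
$q_2 e^{i\phi_2}$ from the $m=2$ sums (negative-sine convention) and
$q_3$ from the alternating sum; $Q = \sqrt{q_2^2+q_3^2}$,
$\cos\theta = q_3/Q$. The reference hexagon of the inverse map is
traversed clockwise seen from $+z$; with atom 1 = N1 and traversal
N1→C2→…→C6 this makes the boat with atoms 3 and 6 above the plane come
out at exactly $(\theta,\phi) = (90^\circ, 120^\circ)$ — the anchor that
fixes the otherwise arbitrary $\phi$ origin. Cyclic relabeling by one
position advances $\phi$ by 120° and mirrors the hemisphere
($\theta \to 180^\circ - \theta$, because the alternating sum changes
sign); both are covered by property tests.

The 38 canonical Boeyens conformers are generated *geometrically* (ideal
displacement patterns for chairs, boats and twist-boats;
five-atoms-coplanar constructions for envelopes and half-chairs) and
pushed through the forward map, so the canonical vertices automatically
respect the package's sign conventions. Classification is
nearest-vertex by great-circle distance on the $(\theta,\phi)$ sphere —
a Voronoi variant of the original zone scheme, chosen because published
zone boundaries differ between sources — with deterministic tie-breaks.
Labels name the displaced atoms (superscript above, subscript below;
rendered inline as in `3,6B`, `1C4`, `1T2`).

`hop_pucker_map()` tabulates $(Q, \theta, \phi)$ at hop geometries,
mirror-projects $\phi$ into $[0^\circ, 180^\circ)$ as polar hop maps
conventionally are, and reports the correlation of the projected phase
with hop time. The three-state model embeds its abstract puckering
coordinate as a 3,6-boat deformation (amplitude proportional to the
coordinate, polar angle tilted by the stretch), which is a synthetic
adapter for exercising the analysis, not a prediction of real hop
geometries.

## Kinetics

State occupations are trajectory fractions on the common time grid;
gap-terminated trajectories count as ground-state population from their
crossing time onward, so the pools always sum to one.
`fit_sequential_model()` fits the branching sequential model

$$S_2(t) = f_{21} e^{-t/\tau_{21}} + (1 - f_{21}),$$
$$S_1(t) = f_{10}\,\frac{k_1 (e^{-k_1 t} - e^{-k_2 t})}{k_2 - k_1}
  + (f_{21} - f_{10})(1 - e^{-k_1 t}),$$

with $k_1 = 1/\tau_{21}$, $k_2 = 1/\tau_{10}$: a fraction $f_{21}$ of the
population leaves S$_2$ with constant $\tau_{21}$ (the rest is trapped),
and of the total population a fraction $f_{10} \le f_{21}$ continues to
the ground state with constant $\tau_{10}$. This is the minimal
two-step/two-trapped-fraction model consistent with reporting each
process as an (amplitude, time constant) pair; whether the trapped
excited population drains on a third, slower constant is not resolvable
from sub-picosecond occupations and is deliberately not modelled.
Optimization is bounded least squares over
$(f_{21}, \log\tau_{21}, f_{10}/f_{21}, \log\tau_{10})$; fits whose time
constants hit the bound are flagged and rejected. The returned object
behaves like a standard fitted model (`coef`, `summary`, `predict`,
`plot`, `residuals`).

`confidence_halfwidth(n, level)` is the worst-case (p = 1/2) normal
binomial half-width in percent — the maximum statistical uncertainty of
any occupation fraction from an `n`-trajectory ensemble. For n = 115 at
90% confidence it evaluates to 7.7%, i.e. about ±8%.

`liic_path()` interpolates chain bond/angle/torsion internals (torsions
along the shortest arc) and rebuilds each image, aligning the path
rigidly to the first endpoint; degenerate (collinear) internals fall
back to cartesian interpolation with a warning. Standard deviations in
`bond_distance_series()` are population (divide-by-n) standard
deviations, matching mean ± one-standard-deviation band plots.

## Problem sizes and determinism

The default study conditions are the published protocol: 500-point
Wigner ensembles, a ±0.13 eV selection window, 115 trajectories, 1 ps,
$\Delta t$ = 0.5/0.025 fs. The test suite runs these sizes directly on
the two-coordinate model (an end-to-end ensemble takes on the order of a
minute); parameter-recovery studies use 50 replicate ensembles of 115
synthetic trajectories. Every stochastic component takes an explicit
seed, and ensembles are reproducible bit for bit.

## What the tests show — and what they do not

The validation demonstrates algorithmic correctness: couplings against
determinant and analytic oracles, integrators against closed forms and
conservation laws, puckering against exact round trips, fits against
known parameters. The synthetic generators emulate smooth orbital
drift, isolated crossings, harmonic vibrations and clean sequential
kinetics. They do not emulate basis-set effects (orbitals live in a
common orthonormal basis, so the atomic-orbital overlap plumbing of a
quantum-chemistry interface is out of scope), near-singular occupied
overlaps from bond breaking, multi-state degeneracy clusters, or
anharmonic initial-state distributions — passing tests say nothing about
those regimes. Triplet states, double excitations and propagation
through the S$_1$/S$_0$ crossing itself (where single-reference
excited-state methods break down — the very reason for the gap-stop
criterion) are out of scope by design.
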