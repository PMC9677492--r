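---
title: "Driven radical-pair magnetoreception: model, methods, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driven radical-pair magnetoreception: model, methods, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpdrive)
```

## The model

`rpdrive` simulates the spin dynamics of a recombining radical pair — the
mechanism hypothesised to underlie the magnetic compass of migratory birds via
the cryptochrome FAD–tryptophan pair — when the inter-radical distance is
*driven*, i.e. modulated in time. Two unpaired electron spins interconvert
coherently between singlet and triplet configurations under hyperfine
couplings to magnetic nuclei and the Zeeman interaction with the geomagnetic
field; only the singlet recombines. Inter-radical exchange and
electron–electron dipolar (EED) couplings split the singlet and triplet
energies and, when static and larger than roughly 1 MHz, trap the pair and
suppress the directional magnetic field effect. Distance modulation makes the
exchange coupling `J(t)` sweep through the region where it matches the
hyperfine mixing element, producing repeated
Landau–Zener–Stückelberg–Majorana (LZSM) passages that release the trapped
singlet population and restore — and can even enhance — the compass
anisotropy.

The Hermitian part of the Hamiltonian contains, per geometry sample along the
trajectory:

* Zeeman terms for both electrons with equal isotropic g factor
  (`gamma_e/2pi = 0.0280 MHz/µT`; 50 µT, the geomagnetic default, gives a
  1.40 MHz Larmor frequency);
* hyperfine couplings `S_i · A_k · I_k`, one 3×3 symmetric tensor per
  nucleus (MHz);
* exchange `J(r) (1/2 + 2 S_1 · S_2)` with
  `J(r) = J0 exp(-beta (r - r0))` — the singlet–triplet splitting is `2J`;
* the point-dipole EED contraction `S_1 · D(r) · S_2`, with a traceless
  axial tensor aligned with the inter-radical unit vector whose axial
  element is `D(r) = D0 (r0/|r|)^3`.

Spin-selective recombination follows the Haberkorn prescription: the singlet
channel decays at `k_b(r) = kb0 exp(-beta (r - r0))` and every state decays
through the spin-independent forward channel at `k_f`, which together form
the anti-Hermitian part `-(i/2)(k_b(t) P_S + k_f I)` of the effective
Hamiltonian. The initial state is the fully mixed singlet manifold
`P_S / Z`, one electronic singlet per nuclear configuration.

**Units.** Couplings are entered in MHz and converted internally to angular
frequency (×2π, rad/µs). The reaction rates `k_b`, `k_f` are *linear* rates
in µs⁻¹ — no 2π — following the standard spin-chemistry convention.
Distances are in Å, times in µs, fields in µT.

## Distance trajectories

The harmonic drive applies the displacement
`delta(t) = Delta_d sin²(pi nu_d t)` along a unit direction `u` from the
reference geometry `r0 n0`, so `r(t)` starts at `r0` with zero initial
displacement, returns to `r0` at every full period `n/nu_d`, and reaches
`r0 + Delta_d` at half periods — equivalently `J(t)` oscillates between `J0`
and `J0 exp(-beta Delta_d)`. Negative amplitudes push the radicals closer
together and *increase* `|J|` and `k_b`. When `u` differs from `n0` the
dipolar axis itself rotates in time.

Two relaxations of the idealised periodic drive are provided: a *damped*
variant multiplying the displacement by `exp(-gamma t)` (the envelope decays
onto the static geometry), and a *Brownian* variant in which the displacement
follows an underdamped Langevin process (inertia, velocity friction, harmonic
confinement about `r0`), integrated by Euler–Maruyama on a fixed grid with a
recorded seed. The Brownian parameters are configuration inputs, not shipped
constants: they emulate protein-mediated stochastic motion only at the level
of a one-dimensional confined coordinate.

## Yields: exact step integrals and a geometric Floquet sum

The singlet yield is

```
Phi_S = (1/Z) sum_i  ∫ k_b(t) <psi_i(t)| P_S |psi_i(t)> dt ,
```

with one wavefunction per initial singlet ⊗ nuclear basis state propagated
under the non-Hermitian effective Hamiltonian; `Phi_f` is the analogous
forward-channel integral and `Phi_S + Phi_f = 1`.

The only discretisation in the package is the piecewise-constant sampling of
`r(t)` at step midpoints (default 256 steps per driving period — exchange
couplings can reach 100 MHz while `nu_d` is of order 1 MHz, so intra-period
resolution matters; `check_convergence = TRUE` reruns at doubled resolution
and reports the difference, typically below 1e-6). Within each step the
Hamiltonian is constant, and both the step propagator `exp(-i H_eff dt)` and
the accumulated yield integrals are evaluated *exactly* through the
eigendecomposition of `H_eff` (a φ-function in the eigenvalue differences).
A scaling-and-squaring Padé exponential with Simpson substep quadrature
stands behind an automatic fallback for the rare ill-conditioned
eigendecomposition. Because the within-step integrals are exact,
`Phi_S + Phi_f = 1` holds to roundoff rather than to quadrature error.

For periodic driving the per-period operators are assembled once, and the
stroboscopic sum over periods is evaluated in closed form: with
`U(T) = V Λ V⁻¹` (all `|λ| < 1` whenever `k_f > 0`), the infinite sum
`Σ_p Tr[U^p ρ0 U^p† M]` is a geometric series summed exactly over eigenvalue
pairs. This is the package's Floquet acceleration: it is what a truncated
stroboscopic power iteration converges to, with no truncation parameter at
all. The direct integrator steps the wavefunctions through time instead
(stopping when the survival probability falls below 1e-9, with a hard cap on
the number of periods), handles non-periodic trajectories, and doubles as the
reference path: Floquet and direct agree to better than 1e-6 on every preset.
A commutator-free fourth-order Magnus scheme (`scheme = "cf4"` in
`period_propagator()`) is available for high-accuracy checks; the test-suite
validates it at 1e-8 against adaptive complex-ODE integration. Static
trajectories (or `Delta_d = 0`) dispatch to the exact time-independent
result, so the driven code path reduces to the static one identically.

```{r yield-example}
mod <- one_nitrogen_model(J0 = 20)
spec <- trajectory_spec("harmonic", delta_d = 3, nu_d = 3)
propagate_yield_floquet(mod$system, field_spec(50, "perpendicular"),
  mod$laws, spec
)
```

## Anisotropy measures

For axially symmetric models the compass figure of merit is
`chi = (Phi_par - Phi_perp) / Phi_bar` with the orientation average
`Phi_bar = (Phi_par + 2 Phi_perp)/3` (one parallel, two equivalent
perpendicular axes). The printed form of the normalisation in the source
material is ambiguous, so it is isolated in a single internal function —
switching to another convention is a one-line change. For models without
axial symmetry the sphere measure `chi = (Phi_max - Phi_min)/<Phi>` is
evaluated over an icosphere orientation grid (`10 f² + 2` vertices;
`f = 16` gives the 2562-orientation grid, `f = 4` a 162-point grid that
resolves the same extrema structure at a fraction of the cost). Extrema are
taken over grid points without interpolation.

## Coherence

The relative entropy of coherence `C_r = S(Δ(ρ)) - S(ρ)` (log base 2, `Δ` =
diagonal truncation) is evaluated in the electronic singlet–triplet ⊗
nuclear Zeeman product basis on the normalised, decaying state. The
time-integrated average runs until the survival probability falls below
1e-3 (≈ 7/k_f; later times carry negligible population) and is averaged over
the parallel and perpendicular field orientations. `C_r` is basis-dependent
by construction and is only reported in this declared basis.

## Preset models

* **one_nitrogen** — a single spin-1 nitrogen on radical A with the axial
  flavin-N5 tensor (`A_perp = -2.6`, `A_par = 49.2` MHz); Hilbert dimension
  12. The workhorse model: with `A_perp = 0` it block-diagonalises into
  three 4×4 blocks labelled by the nuclear projection `m_I`, whose S–T0
  coupling `(A_par/2) m_I = 24.6 m_I` MHz exposes the LZSM structure.
  `block_hamiltonian()` builds these blocks by numerical projection of the
  full Hamiltonian — never by transcribing a formula — and the test-suite
  verifies the direct sum against the full operator.
* **two_level** — the further-reduced `(T0, S)` model with detuning `2J(t)`
  and constant Rabi coupling `c` (off-diagonal element `c/2`); with
  `c = A_par` it is exactly the `m_I = 1` sub-block in a parallel field.
* **four_spin_fad_trp** — N5 and N10 (spin-1) on the flavin, N1 (spin-1)
  and H1 (spin-1/2) on the tryptophan; dimension 216, `Z = 54`,
  `D(r0) = -13.7` MHz. The shipped hyperfine tensors are **synthetic axial
  placeholders** (`inst/extdata/four_spin_hyperfine_synthetic.yaml`)
  representative of literature magnitudes; refined tensors slot in through
  `four_spin_model(tensors = ...)`.

**Geometry.** The reference inter-radical axis `n0` defaults to the
hyperfine z axis. In cryptochrome the FAD–Trp separation vector makes a
substantial angle with the flavin normal, which is precisely why the pair
with EED lacks axial symmetry; since the refined relative orientation is not
shipped, `fad_trp_dipolar_axis()` provides a synthetic stand-in tilted 60°
from z. The driven-vs-static sphere-measure enhancement is insensitive to
the exact tilt (any value between roughly 30° and 90° shows it); with a
fully aligned axis the model regains axial symmetry and the enhancement at
small amplitudes disappears, which is a statement about that degenerate
geometry rather than about the mechanism.

## Optimal control of the drive

`optimize_waveform()` maximises the absolute axial anisotropy over
piecewise-constant displacement waveforms (default 64 segments over 5 µs,
`|delta| ≤ 3` Å). The piecewise-constant parameterisation matches the
propagator's piecewise-exponential structure exactly, so the objective has
no additional discretisation error; after the horizon the displacement holds
its final value and the remaining yield is integrated analytically. The
optimizer is a seeded multi-start greedy coordinate search with step halving
— the objective is cheap at dimension 12 and derivative formulas for the
non-Hermitian yield are not available in closed form — starting from the
static waveform, harmonic profiles over a frequency grid (which guarantees
the result dominates both baselines), and uniform random waveforms. At
`J0 = 10` MHz the optimized anisotropy (≈ 0.99) exceeds the best sampled
harmonic drive (≈ 0.26) by well over the threefold margin the harmonic
baseline suggests.

## Degenerate inputs, tie-breaks, tolerances

* `k_f = 0` removes the guaranteed decay: infinite-horizon yields are then
  ill-defined and both propagators stop with an explicit error.
* Eigendecomposition residuals above 1e-9 (relative) trigger the Padé +
  Simpson fallback; Hermitian checks and projector algebra are asserted at
  1e-12.
* Trajectories that would collapse the pair distance to zero error out.
* The icosphere deduplicates shared edge/corner vertices by rounding to
  1e-9 and orders vertices lexicographically by (z, x, y) for deterministic
  output.
* All stochastic components (Brownian paths, random optimizer starts) are
  seeded explicitly and restore the caller's RNG state.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run entirely from code at modest
sizes chosen to exercise every claim on the 12-dimensional one-nitrogen
model: 256 steps per period, a 162-point orientation grid for the
sphere-measure comparison, a 128-trajectory Brownian ensemble on the bare
pair for Monte-Carlo scaling, and a reduced-budget control run (32 segments,
6 starts) alongside the full-budget one (64 segments, 20 starts) in
`scripts/acceptance.R`. Four-spin runs are construction-checked (dimension,
initial-state enumeration, defaults) but full four-spin anisotropy maps are
left to the user — they are hours-scale computations and their quantitative
value depends on replacing the placeholder tensors.

## Limitations

The model is a reductionist idealisation: isotropic equal g factors, no
nuclear Zeeman or quadrupolar terms, no spin relaxation or Redfield-type
decoherence superoperators, a single one-dimensional reaction coordinate,
and phenomenological exponential/point-dipole coupling laws. Passing tests
demonstrate internal consistency and reproduction of the driven-enhancement
phenomenology on these idealised models — not a quantitative prediction for
any particular protein. Three-radical/scavenger schemes and structural
(MD-level) modelling of cryptochrome are out of scope.
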