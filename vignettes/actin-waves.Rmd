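---
title: "Methods: stochastic actin waves at three levels of description"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic actin waves at three levels of description}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and its three levels

The package implements a conceptual activator–inhibitor description of
cortical actin signalling on a one-dimensional periodic domain (a slice of
the cell membrane, hence a circle). An activator `u` — an abstraction of Ras
activity — is degraded linearly (`a1 u`) and by the inhibitor (`a2 u v`),
and produced by a saturating autocatalytic Hill term (`a3 u^2/(a4 + u^2)`)
plus a basal source (`a5`). The inhibitor `v` decays (`eps c1 v`) and is
produced in response to the activator (`eps c2 u`); `eps` separates the two
timescales. Both species diffuse, with `Du < Dv`.

Three levels of description share this reaction network:

1. **Macroscopic.** The reaction-rate equations with diffusion — an
   excitable FitzHugh–Nagumo-type PDE. `simulate_rde()` integrates it by the
   method of lines.
2. **Mesoscopic.** The chemical Langevin equation: drift as above, plus
   per-species multiplicative reaction noise whose variance is the summed
   propensities scaled by `sigma^2` (`sigma = 1/sqrt(omega)`, `omega` the
   number of molecules per unit concentration), plus a conservative
   noise-flux term `sigma * d/dx(sqrt(2 D X) dW)` from diffusion.
   `simulate_cle()` integrates it by Euler–Maruyama.
3. **Microscopic.** Exact Gillespie sampling of integer molecule counts:
   `simulate_ssa_wellmixed()` (direct method) and `simulate_rdme()` (spatial,
   with diffusion as hop events at rate `D/dx^2` per molecule).

In the limit `sigma -> 0` the mesoscopic model collapses onto the
macroscopic one — in this implementation they then agree to machine
precision because they share one stepper. As `omega` grows, the microscopic
first moments converge to the macroscopic kinetics; both properties are
under test.

## Background states and bifurcations

Spatially homogeneous equilibria satisfy the u-nullcline after eliminating
`v* = c2 u*/c1`, a quartic in `u` whose positive real roots are the
admissible states. `background_states()` finds all roots as eigenvalues of
the companion matrix, keeping those with `|Im| < 1e-9 * max(1, |Re|)` and
real part above `1e-12`. `descartes_root_bound()` reports the sign-rule
bound: exactly one positive root when `c1 (a3 + a5) < a2 a4 c2` (the
boundary case conservatively reports `"one_or_three"`).

Stability comes from the 2x2 kinetics Jacobian. One entry deserves a note:
the derivative of the Hill activation term is `+2 a3 a4 u/(a4 + u^2)^2`,
which is positive — this is the destabilising autocatalysis. With the
standard parameter set (`a1 = 0.167`, `a2 = 16.67`, `a3 = 167`,
`a4 = 1.44`, `a5 = 1.47`, `eps = 0.52`, `c2 = 3.9`) and `c1` scanned over
[0.18, 0.35], the eigenvalues are first real and negative, collide and
become complex near `c1 = 0.245`, and cross the imaginary axis (Hopf) near
`c1 = 0.288`. `eigen_scan()` locates both transitions by bisection on the
Jacobian discriminant and on the maximal real part, to `1e-6` in `c1` by
default — far tighter than the two decimals the transitions are usually
quoted to. When several positive states coexist the scan follows one branch
by nearest-neighbour continuation in `u*`.

## Discretisation choices

All numerical parameters are package choices (no reference discretisation
was available) and are exposed as arguments:

* **Grid.** Default domain `[-10, 10)` with `n = 400` cells
  (`dx = 0.05`), which resolves the deterministic pulse (width about 0.5 at
  the default detection threshold) with roughly ten points. Long-time or
  multi-pulse experiments use `[-60, 60)`: on a length-20 circle two
  separating pulses eventually annihilate through the periodic boundary and
  the global inhibitor level rises until activity collapses (by `t ~ 18`
  for the standing-wave preset), which is a domain-size artefact, not a
  property of the waves.
* **Time step.** Explicit Euler with `dt = 0.2 dx^2 / max(Du, Dv)`
  (5e-4 at the default grid); a step above the diffusive stability limit is
  rejected. The stepper is first order; a convergence-order test is part of
  the suite.
* **Noise discretisation.** Space-time white noise enters as independent
  `N(0,1)/sqrt(dx dt)` per cell and step. The diffusion noise uses one
  normal per cell *interface*; the flux differences telescope, so the
  increment conserves mass exactly on the circle. Its per-cell variance at
  constant state X is `2 (2 D X) dt/dx^3`, with correlation -1/2 between
  neighbours (one shared interface) — both verified by Monte Carlo.
* **Positivity.** The Langevin approximation does not preserve positivity;
  the multiplicative-noise modes clamp states to zero after each step and
  report the clamped fraction (about 2e-4 of cell-updates at the published
  noise levels, used as an alarm diagnostic). The additive-white-noise
  ablation is deliberately left unclamped: its solutions are allowed to go
  negative, and clamping it would rectify the noise, inflate the mean
  activator and hence the inhibitor (`v* = 39 u-bar` at the standing-wave
  preset), and suppress activation entirely.
* **Inhibitor noise amplitude.** The construction `S diag(R) S^T` gives the
  inhibitor reaction-noise variance `eps (c1 v + c2 u)` — both inhibitor
  reactions add variance — and this is the default
  (`variance_convention = "sum_of_propensities"`). A signed variant
  `eps (-c1 v + c2 u)`, which mirrors the drift and vanishes exactly at the
  background state, is exposed as `"as_printed"` for fidelity experiments;
  the two differ little away from the background state because the `c2 u`
  term dominates during events. Negative variance arguments are clamped to
  zero before the square root.
* **RNG.** The compiled steppers use a self-contained mt19937_64 +
  ziggurat normal sampler, so a run is reproducible from its integer seed
  across platforms and independent of R's RNG state. Ensembles derive run
  seeds as `base_seed + run - 1`. The pure-R generic-network stepper uses
  R's RNG; the two paths are cross-checked on moments, not trajectories.

## Wave profiles

A localised wave is a stationary profile of the co-moving equations in
`xi = x - c t`. `solve_wave_profile()` discretises them with the same
periodic central differences as the PDE solver and applies damped Newton
with an analytic sparse Jacobian. Translation invariance is removed by an
integral phase condition pinning the solution to the initial guess; with
the speed as an unknown the bordered system is square. For standing waves
(`fix_c_zero = TRUE`) the speed is held at zero and the phase condition
dropped: on the lattice the translation mode is only approximately null, so
plain Newton converges, and the clipped initial guess fixes which translate
is found. Initial guesses come from simulations (`seed_wave_profile()`
grows two counter-propagating pulses from a Gaussian bump, clips the
left-moving one, and estimates its speed from the kymograph).

Converged tails must sit near the background state. This constrains the
domain: behind a travelling wave the inhibitor recovers at spatial rate
`~eps c1/|c|` (about 0.05 for the travelling preset), so travelling-wave
solves use `[-60, 60)`. The solved speed converges as `O(dx^2)`:
-2.06 at `dx = 0.05`, -2.163 at 0.025, -2.187 at 0.0125 for the
travelling preset. The co-moving validation (a converged profile advected
by the PDE stays within L2 distance 1e-2 of its rigidly translated self
over two time units) holds at `dx = 0.00625`; at working resolutions the
lattice wave's effective speed differs from the solver's `c` by the same
`O(dx^2)`, which the unit test accounts for by comparing at the best
circular shift.

## Event detection and statistics

Activation events are connected components of the super-threshold activator
mask in the space-time lattice, 8-connected, periodic in space only.
Width is measured on the circle as the occupied span of the component's
spatial projection (domain length minus the largest empty gap); duration is
the component's frame span times the frame spacing.

The detection threshold adapts to the parameter set:
`u* + 0.25 (u_pulse_max - u*)`, where `u_pulse_max` is read from a
deterministic reference run on the large domain (about 1.57 for the
standing-wave preset, giving a threshold near 0.44). Ensemble runs sample
frames at `dx/4` in time so that travelling events (speeds up to 4) advance
at most one cell per frame and stay connected; the minimum-size filter is
rescaled so that it always corresponds to the same space-time area (8 cells
at the reference `dx = 0.05`, frame spacing 0.1 — about 0.04 space-time
units). Without this rescaling the filter, and with a coarser cadence the
connectivity, would depend on the save cadence.

Oscillation periods are estimated from the spatial mean of `u`: discard
`t < 10` (the initial relaxation), find local maxima at least 25% of the
signal range above its minimum and at least 0.5 time units apart, and
average the spacings. The deterministic oscillatory preset gives
`T = 8.14`; with `sigma = 0.01` the mean over seeds drops to about 7.9 —
noise pre-empts the slow phase of the relaxation oscillation, shortening
the period.

## What the generator emulates — and what it does not

The synthetic protocols mirror the figure-level studies: a Gaussian bump
(`u0 = u* + exp(-x^2)`, `v0 = v* + 2/cosh(5x)^2`) as the crude
localised-wave seed; a homogeneous `(u*, 4 v*)` start with a small seeded
uniform perturbation (amplitude `1e-2 u*` on `u` — enough to break
symmetry, too small to activate deterministically) for ensemble statistics;
a homogeneous `(u*, 2 v*)` start for the wild-type versus PTEN-null
comparison. These are idealisations of a membrane slice: real cortical
dynamics is two-dimensional, has many more chemical components, and couples
to membrane geometry and external signals. Passing tests show that the
three levels of description are mutually consistent and reproduce the
printed quantities of this idealised model, not that the model captures any
particular cell.

## Known limitations and open points

* The full Langevin model's diffusion-noise term is mathematically
  delicate (the square root of a distribution); no claim of a continuum
  limit is made, and the `reaction_only` mode exists precisely because the
  event statistics barely change without the term.
* The pulse-width quantity is threshold-dependent. At the default
  threshold the deterministic single standing pulse measures 0.5 wide, and
  no admissible threshold takes it beyond about 0.65 — the profile itself
  is validated independently (tails, symmetry, the inhibitor value at the
  sharp transition ~3.9, residual below 1e-8), so quoted widths from other
  implementations are only comparable given the same width convention.
* At matched noise `sigma = 0.06`, the PTEN-null parameter set produces
  about twice as many activation events as wild type, and because more
  waves collide and annihilate sooner, their *mean* duration is shorter
  (1.26 vs 1.90); only the extreme tails (longest, widest events) of the
  PTEN-null ensemble exceed wild type. The expectation that PTEN-null
  events live longer on average at matched noise is therefore not met by
  this implementation's detector; the corresponding acceptance test is
  kept and documents the discrepancy.
* The additive-white-noise ablation is cutoff-dependent (white noise gets
  rougher as `dx, dt` shrink). At this discretisation, calibrating it to
  the full model's event rate (`sigma = 0.23` vs 0.046) yields events with
  clearly weaker maxima but *not* shorter or narrower extents; the
  distributional contrast in extents evidently depends on the reference
  discretisation.
* Pulse-adding dynamics in the intermediate range `c1` in (0.25, 0.29) and
  two-dimensional membranes are out of scope.

## Problem sizes used by the acceptance script

Background states and bifurcation scans are closed-form-scale (quartic and
2x2 eigenproblems). The travelling-wave solve uses `[-60, 60)` with
`n = 4800`; the measured speed uses `[-20, 20)` with `n = 1600` over eight
time units; the width uses the standing solve at `n = 2400`; periods use
the default grid over 100 time units (one deterministic run; ten seeds at
`sigma = 0.01`); the event-rate check runs 30 seeds of 100 time units at
`sigma = 0.03`. These sizes reproduce the printed values at their stated
tolerances while keeping a desk-scale runtime.
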