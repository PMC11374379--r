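---
title: "Minima-hopping simulation of crowded protein solutions: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minima-hopping simulation of crowded protein solutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crowdhop)
```

## The model

`crowdhop` treats a crowded protein solution as a set of rigid bodies
whose pairwise interactions are known only at their docking minima. The
intermolecular energy landscape of each ordered pair is mapped once by
grid docking, and dynamics then proceed by *minima hopping*: a protein
(the ligand) jumps directly to a randomly drawn docking match on a
randomly drawn neighboring protein (the receptor). The chain never
visits high-energy intermediate configurations, which is what buys the
long time scales; it also means the method is meaningful only when
proteins are constantly within hopping range, i.e. at volume fractions
of roughly 0.1 and above. Solvent, hydrodynamics and conformational
flexibility are deliberately outside the model.

### Docking score

The score is the classic grid shape-complementarity correlation. A
structure is discretized on a cubic grid (a cell is occupied if it
contains an atom center or its own center lies inside an atom's van der
Waals sphere, Bondi radii, unknown elements 1.7 Å). For the receptor,
occupied cells within `surface_thickness` (default 1) shells of an
unoccupied cell score +1 and deeper cells score `-repulsion` (default
9.0); the ligand contributes +1 per occupied cell. The pose energy is
minus the correlation of the two grids, so good surface burial is
rewarded and core interpenetration is penalized. Orientations come from
a deterministic z-y-z Euler lattice with polar decimation (the number
of alpha samples per beta ring scales with sin beta), so the list is
identical across runs and roughly uniform over orientation space.
Translations are scanned by zero-padded FFT; when the grids hold
integers the result is rounded back, making the FFT path exactly equal
to the brute-force sliding sum (this is asserted, not assumed, in the
test suite).

Interpretation of the core penalty weight: the number multiplies the
per-cell core contribution of the correlation. This is the standard
soft-core realization of a van der Waals-like docking score; no claim
of numerical parity with any external docking program is made — the
method only needs a *ranked minima spectrum* per pair, and all
downstream physics (Boltzmann weights, hop statistics) is driven by
energy differences within that spectrum relative to the temperature
scale.

### The chain and detailed balance

From state *i*, a move proposes (ligand, receptor, pose) with
probability `1/(n * N_i * K)` where `N_i` is the ligand's neighbor
count and `K` the library size. Because `N` changes between source and
destination, a bare Metropolis rule would violate detailed balance on
the hop graph; the acceptance used is

    P = min{1, exp(-(E_j - E_i)/T) * N_i/N_j}

which restores it, and on any enumerable landscape the stationary law
is exactly the Boltzmann distribution over states, independent of the
graph degrees. The package verifies this two ways: algebraically (the
stationary eigenvector of the explicitly constructed transition matrix
equals the normalized Boltzmann weights on random toy landscapes) and
empirically (chain occupancies after 10^6 steps are within 2% total
variation of that eigenvector).

The temperature `T = 100` is a scale factor expressed in score units,
and the physical time per sweep (one attempted move per protein) is
20 ns; both are adopted as the method's published calibration. Whether
one "step" is a single attempted move or a per-protein sweep is
ambiguous in the source description; the package defaults to sweeps
(`sweep_mode = TRUE`), so that every protein moves on the 20 ns scale
regardless of system size, and retains the single-attempt mode for the
stationarity oracle.

### Choices the method description leaves open

* **Energy of undocked states.** The initial lattice configuration is
  not a docked minimum and has no defined energy; instances start at
  `E = 0` and acquire the energy of their first accepted pose. Since
  the acceptance rule only ever sees energy differences, this choice
  affects a short transient which the 2 µs MSD reference discards.
* **Clashes with third proteins.** A hop is proposed pairwise, so the
  destination may overlap a third instance. By default moves whose
  ligand bounding sphere overlaps any non-receptor instance by more
  than 0.4 of the smaller radius are rejected (`clash_check`,
  `overlap_tolerance`); the check is configurable and disabled in the
  stationarity tests, whose toy landscapes have no geometry.
* **Neighbor cutoff.** "Proximity" is realized as a per-type-pair
  cutoff: sum of bounding-sphere radii plus a 10 Å margin, large enough
  to admit every pose in the libraries (pose translations never exceed
  the radii sum at contact).

## Estimators

**Translational.** `msd_curve()` computes squared displacements of
unwrapped geometric centers, and `fit_dt()` takes the least-squares
slope through the origin divided by 6. Two averaging modes exist, and
the distinction matters. The *fixed-reference* mode (default;
displacement from the position at 2 µs) mirrors the published protocol
and discards the equilibration transient, but its relative error floor
is about `sqrt(2/(3 n_copies))` no matter how long the trajectory —
with 20 copies that is ~18%, which cannot certify a 5% estimator check.
The *sliding-origin* mode averages over all time origins and is the
statistically efficient estimator for stationary signals; it is used
wherever the package checks recovery of known constants, and the two
modes are cross-checked on synthetic data. Units are Å²/ns internally;
1 Å²/ns = 10 µm²/s exactly (`dt_to_um2s()`).

**Rotational.** Body-fixed unit vectors (toward randomly chosen
C-alpha atoms, or random directions when no structure is given) are
propagated by the recorded orientation quaternions;
`C(k) = <P2(v(t+k)·v(t))>` over vectors, origins and copies. For long
trajectories the all-origins average is computed by FFT using
`(v(t+k)·v(t))^2 = sum over coordinate products`, i.e. six scalar
autocorrelations per vector — an exact identity, tested against the
direct sum. `fit_exponential()` fits `S exp(-t/tau)` over the window
`C > 0.05` (single-exponential by design; a restricted fit window keeps
the noise floor out) and `dr_from_tau()` applies
`D_r = 1/(l(l+1)tau)`, `l = 2`. Non-decaying input is an error, never a
silent large tau.

**Concentration and size fits.** `fit_cohen_turnbull()` fits
`D_0 exp(-alpha V/(1-V))` by nonlinear least squares seeded from the
log-linear solution. `fit_power_law()` is a log-log regression.
`fit_cytoplasm()` fixes the two cytoplasm length scales
(`R_h = 420 Å`, `xi = 5.1 Å`) and the hydrodynamic-radius
parameterization `r_p = 0.0515 Mw^0.392` — the formula yields
nanometres, the only reading that gives physically sensible radii, and
is converted to Å before use — and minimizes over the single exponent
`a` on (0, 5]. The exponent placement `(xi^2/R_h^2 + xi^2/r_p^2)^(-a/2)`
follows the cited cytoplasm-scaling model; the source text's rendering
of the formula is typographically garbled at exactly this point.

## Synthetic generators and what they do (and do not) show

`make_blob_protein()` builds uniform-ball pseudo-proteins with
protein-like element composition (every 4th atom flagged C-alpha), so
geometry (Rg → radius·sqrt(3/5)), molecular weight scaling and docking
are all exercised without any external coordinates.
`make_pocket_pair()` constructs a thick-walled cup receptor and a plug
ligand whose global score optimum is known *by construction* — the wall
is kept more than three grid cells thick so erosion produces a
penalized core, which is what pins the optimum to the cavity center
(a thin all-surface wall would reward pressing the plug into it).
`ideal_trajectory()` produces exact Brownian ground truth: Gaussian
center steps of per-axis variance `2 D_t dt`, and rotations about
uniform axes with angle s.d. `sqrt(6 D_r dt)`, giving a tracked-vector
angular variance of `4 D_r dt` per step and P2 decay `exp(-6 D_r t)`.
Composing finite rotations is only diffusive to leading order: at
`4 D_r dt = 0.4` the apparent tau is ~20% above `1/(6 D_r)` (the
per-step P2 contraction is `(1 + 2 E[cos d] + 2 E[cos 2d])/5`, not
`exp(-6 D_r dt)`), so the generator refuses settings above
`4 D_r dt = 0.15`, where the bias is at or below ~2%.

Passing tests on these generators demonstrates that the estimators and
the chain are correct *given the model's assumptions* — they say
nothing about force-field realism, flexible proteins, or hydrodynamic
coupling, all of which are outside the model.

## Validation problem sizes

The package's validation study (`run_mix3_study()`, also what
`scripts/acceptance.R` runs) uses deliberately compact settings chosen
as a desk-scale reproduction: three blob proteins with radii of
gyration matched to the villin headpiece / protein G / ubiquitin
triplet (7.3 / 10.6 / 11.8 Å) and atom counts proportional to their
molecular weights; docking at rotation interval 40°, 5000 poses per
pair; a 170 Å box at V = 0.10/0.20/0.30 (plus 0.25 for the
mixture-vs-self comparison); 800 sweeps (16 µs) and 2 replicas per
condition. Estimator-recovery checks use 10^5-frame ideal trajectories
with 20 copies on a 3×3 grid of (D_t, D_r). Stationarity checks use
10^6 chain steps on landscapes of up to 12 states.

At these sizes the study reproduces the qualitative physics of the
full-scale method: diffusion slows monotonically with volume fraction
for every protein; the size ordering of D_t holds at V = 0.20 and 0.30;
and the smallest protein diffuses measurably faster in the
heterogeneous mixture than self-crowded at V = 0.25, with its
normalized slowdown at V = 0.20 close to the published 0.56. Two known
shortfalls, documented rather than hidden: at V = 0.10 the smallest
protein is *not* the fastest — the method's own description notes an
inherent unfavorable bias against small proteins in neighbor selection
at low concentrations, and the re-implemented score's depth scale
(relative to the fixed T = 100) differs from the original program's —
and the large protein's slowdown is overestimated relative to the
printed 0.81, a number whose protein assignment is moreover in tension
with the source's own figure caption stating that smaller proteins keep
the higher normalized rate.

## Numerical notes

* Pose ranking is computed in full precision; ties are broken
  deterministically (rotation index, then lexicographic translation),
  so docking output is bit-stable across runs.
* Per-rotation pruning keeps the best 1000 translations (300 in the
  scaled study) before the global top-K merge; with K well below
  rotations × kept poses this does not change the retained set.
* The largest-remainder rounding of copy counts keeps the achieved
  volume fraction within one protein volume of the target.
* Minimum-image displacements use the half-open convention
  `(-L/2, L/2]`; wrapped and unwrapped coordinates are asserted
  congruent modulo the box at every recorded frame.
* All generators snapshot and restore the caller's RNG state; engine
  draw order per attempt is ligand, receptor, pose, acceptance uniform.

## Known limitations

Single-particle moves only (no cluster moves), pairwise energies only
(no third-body terms), rigid structures, no solvent or hydrodynamics,
no electrostatics or desolvation in the score, and validity restricted
to crowded conditions. Dilute-limit rates (D_0) are obtained only by
Cohen-Turnbull extrapolation, not by direct simulation.
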