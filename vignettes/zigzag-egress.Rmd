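---
title: "Multidirectional ligand egress by differential-evolution guided pulling"
author: "depull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidirectional ligand egress by differential-evolution guided pulling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depull)
```

## The problem and the model

Steered pulling drags a bound ligand out of its receptor with a harmonic
spring attached to a moving dummy atom, and uses the non-equilibrium pulling
work $W_{\mathrm{pull}}$ (and the rupture force $F_{\max}$) as a cheap proxy
for relative binding affinity. When the pulling direction is fixed for the
whole trajectory, the ligand is frequently rammed into residues lining the
exit route; the collision shows up as a second peak in the force profile,
inflates the work, and degrades the correlation between
$W_{\mathrm{pull}}$ and experimental affinities such as
$\ln(\mathrm{IC}_{50})$.

`depull` implements a multidirectional ("zigzag") alternative. The
trajectory is split into short intervals of length $\tau$. Before each
interval, candidate rigid translations $\mathbf{v}$ of the ligand (no
rotation, no internal deformation during probing) are scored by

$$E_{\mathrm{score}}(\mathbf{v}) =
  \left(E_{\mathrm{elec}} + E_{\mathrm{vdw}}\right)^{\mathrm{probe}}
  - \left(E_{\mathrm{elec}} + E_{\mathrm{vdw}}\right)^{\mathrm{current}}
  + \alpha \left| \left(E_{\mathrm{elec}} +
    E_{\mathrm{vdw}}\right)^{\mathrm{probe}} \right|,$$

where the energies are the ligand–receptor Coulomb and 12-6 Lennard-Jones
interactions (Lorentz–Berthelot combination, plain 1.0 nm cutoff). The
first two terms reward moving to weaker interaction; the $\alpha$ term
penalizes both receptor overlap and parking in a deep energy minimum — with
$\alpha = 0$ the score is a pure energy difference and the search happily
dives into the nearest attractive well (`find_direction` has a unit test
demonstrating exactly that). The score is minimized over the ball
$\lVert\mathbf{v}\rVert \le 0.7$ nm with differential evolution
(DE/rand/1/bin, $CR = 0.9$, $F = 0.5$), and the best translation's unit
vector becomes the pulling direction for the next interval. Once the ligand
has left the receptor the last direction is kept.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| spring stiffness $k$ | 600 | kJ mol$^{-1}$ nm$^{-2}$ | AFM-scale spring |
| pulling speed $v$ | 5 | nm ns$^{-1}$ | dummy speed |
| interval $\tau$ | 20 | ps | direction-change cadence |
| DE population | 3000 | – | candidate translations per interval |
| max translation | 0.7 | nm | probe ball radius |
| DE iterations | 100 | – | generations per interval |
| $\alpha$ | 2 | – | overlap / trap penalty |
| cutoff | 1.0 | nm | nonbonded truncation |

These defaults are the method's recommended set. The fixture studies
shipped with the package run the DE at population 120 and 40 generations:
the search space is a 3-dimensional ball and the fixture landscapes are
smooth, so this resolves directions as well as the production-scale setting
while keeping a full four-fixture study under a quarter of an hour on one
CPU; the defaults of `de_config()` are unchanged. `fixture_protocol()`
returns the exact configuration the packaged studies use.

## The toy engine

Production use targets an external MD engine through the adapter contract
(a direction file per interval; coordinates and a 3-column force profile
back). For desk-scale, fully-reproducible studies the package ships an
overdamped Langevin engine:

$$\mathrm{d}\mathbf{x} = \frac{\mathbf{F}}{\gamma}\,\mathrm{d}t +
  \sqrt{\tfrac{2 k_B T}{\gamma}\,\mathrm{d}t}\; \boldsymbol{\eta},$$

per ligand atom, receptor fixed, forces from analytic derivatives of the
truncated pair potentials (the force discontinuity at the cutoff is
accepted; it only perturbs poses that are already essentially out of
contact). Three engine choices deserve explanation:

* **Intra-ligand cohesion.** The scoring energy is strictly
  ligand–receptor, but the dynamics include intra-ligand nonbonded forces.
  The spring grabs a single atom (the one nearest the ligand's centre of
  mass); without any cohesive force the other atoms would simply be left
  behind, so the Lennard-Jones attraction between ligand atoms is the
  minimal bond-free mechanism that lets a multi-atom ligand egress as a
  deformable unit. Under a hard enough obstruction it can still shear — the
  engine is honest about deformation and rupture.
* **A persistent 3-D dummy.** The dummy is a point in space advancing at
  $v$ along the current direction and connected to the pulled atom by a
  3-D harmonic spring; it is *not* re-seated at direction changes. This is
  the trajectory-wide reading of the force law $F = k(vt - x)$: if the
  ligand stalls, the spring keeps loading across intervals until the
  obstruction yields, which is what produces meaningful rupture peaks. The
  alternative (re-anchoring the dummy each interval) caps the force at
  $k v \tau = 60$ kJ mol$^{-1}$ nm$^{-1}$ forever and, at $T = 0$, opens a
  zero-force window at every direction switch during which the binding site
  recaptures the ligand; in our experiments no multidirectional trajectory
  could leave a realistic binding well under that variant. Scalar
  bookkeeping (projected displacement accumulated across intervals) fails
  for a subtler reason: a ligand wandering on a curved path accrues
  projected displacement without net motion and so never loads the spring.
* **Overdamped, not Newtonian.** Brownian dynamics removes solvent and
  thermostat machinery while preserving the pull-and-drag contract the
  protocol needs. $T = 0$ is allowed and gives deterministic dynamics, so
  ensemble variability can be attributed entirely to the stochastic
  direction search.

The integrator is plain Euler–Maruyama at 0.002 ps. On the free-ligand
problem ($\gamma \dot x = k(vt - x)$, closed form
$x(t) = vt - \frac{\gamma v}{k}(1 - e^{-kt/\gamma})$) the discrete solution
is within $10^{-4}$ nm of the exact one at 20 ps, and halving the timestep
moves the endpoint by less than $10^{-4}$ nm.

## Orchestration

`find_path()` loops: previous-pose energies, direction (DE search, or a
user-supplied fixed direction in unidirectional mode), one pulling
interval, then two checks. *Exit*: minimum ligand–receptor atom distance
above cutoff + 0.2 nm — equivalent under truncation to exactly zero
nonbonded contact — at two consecutive interval ends; after the first clear
end the direction is frozen for the confirmation intervals. A ligand that
already satisfies the criterion at the start has no energy signal for DE at
all, so the confirmation pull uses the receptor-centroid-to-ligand
direction. *Stuck*: ligand CoM net displacement below 0.01 nm per interval
for five consecutive intervals. Stuck trajectories are reported, never
silently retried.

## The synthetic fixtures

`make_system()` builds receptors with known ground truth: a
Fibonacci-sphere shell plus an interior cubic-lattice scaffold of neutral
LJ atoms (spacing below $2^{1/6}\sigma$, so the only ways out are the
designed channels), a spherical binding cavity, channels carved as
clearance cylinders around polylines, and a labeled gate sphere on each
channel mouth for ground-truth pathway classification. The binding well is
a single soft LJ ball ($\sigma = 1.2$ nm) embedded below the cavity floor.
Its softness is deliberate: a deep-but-soft well has a bounded peak
restraining force, so the spring can rupture the contact while the well
depth — the quantity the work should rank — spans a wide range
($\varepsilon_{\mathrm{site}} = 2\ldots10$ kJ/mol in the ligand series).
The ligand is a three-atom LJ triangle whose self-cohesion exceeds the
per-atom site pull at the deepest well, so it leaves as one body. Wall
atoms are nearly non-adhesive ($\varepsilon = 0.02$ kJ/mol): strongly
adhesive walls create spurious near-zero-energy cancellation poses at the
cavity surface that compete with the channel mouth for the score minimum.

Four canonical fixtures: `STRAIGHT` (one axial channel), `BENT` (an
L-shaped channel whose straight continuation is blocked by a *soft plug* —
a sparse lattice of weak LJ atoms that yields at roughly 45–55
kJ mol$^{-1}$ nm$^{-1}$ of sustained force), `TWO_CHANNEL` (a wide and a
slightly narrower channel at right angles), and `CAGE` (no channel). The
BENT fixture is the unidirectional-failure demonstrator: straight pulling
along the initial channel axis must force the plug, which costs extra work
and produces a sustained secondary force peak, while the multidirectional
protocol turns the corner. What the fixtures do *not* emulate: ligand
rotation during probing, receptor flexibility, solvent, long-range
electrostatics, and the energetic ruggedness of real binding sites —
passing the fixture studies shows the protocol's logic is right at desk
scale, not that it reproduces any particular protein system.

## Observables

`compute_work()` implements the per-step sum
$W_{\mathrm{pull}} = \sum_i F_i (x_i - x_{i-1})$ with $F_i$ the recorded
spring force along the instantaneous direction and $x_i$ the cumulative
projected pulled-atom displacement (the first sample is the integration
origin, and a trapezoidal option is available); `pearson()` squares the
product-moment correlation for the $R^2$ reported against
$\ln(\mathrm{IC}_{50})$. Pathway populations come from classifying each
trajectory by the first gate sphere its CoM track enters after leaving the
binding-site sphere (a complete-linkage angular clustering at 45° is the
labeled-heuristic fallback when no gates exist), and
`bootstrap_populations()` resamples the label list with replacement — 20000
resamples by default — reporting each label's mean and SD percentage.
`summarize_work()` warns when the ensemble SD exceeds 10% of the mean work,
the usual trajectory-count adequacy rule.

## Numerical choices and degenerate inputs

* Coulomb distances are clamped at 0.01 nm purely to guard floating-point
  range; the $\alpha$ term is the method's own overlap guard. An overlap
  deeper than the clamp aborts the interval with a diagnostic.
* DE trial vectors outside the probe ball are rescaled radially onto the
  boundary (preserves the search direction, keeps feasibility exact);
  selection ties keep the incumbent; non-finite objective values are +Inf.
* A degenerate direction search (null best vector, or a zero-spread score
  landscape, e.g. no receptor atom within the cutoff of any probe) reuses
  the previous direction; on the first interval it is an error instructing
  a reseed.
* The dielectric is configurable (default 1, vacuum); the fixture systems
  are neutral, so only the LJ part is exercised there.
* Profile time series are sampled every integrator step; downsampling is
  an analysis concern.

## Problem sizes used by the packaged studies

The acceptance studies run, at $T = 0$ and with the DE at $120 \times 40$:
20 trajectories on STRAIGHT (60-interval budget), 20 multidirectional plus
20 unidirectional on BENT (70/55), 30 on TWO_CHANNEL (60), 10 on CAGE (12),
and $5 \times 10$ across the ligand series, about 150 trajectories in
total. Interval budgets follow the $N = \tau_{\mathrm{sim}}/\tau$
convention with a simulated time generous enough for the ~2.3 nm egress
distance of the fixtures.

## Known limitations

Rigid-translation probing cannot discover routes that require ligand
reorientation; the toy engine's receptor is frozen, so transiently opening
channels are out of reach; plain truncation makes the score blind past
1.0 nm, which is also why the exit criterion is phrased in terms of zero
truncated contact; and the gate-free pathway clustering is a labeled
heuristic, not a substitute for ground-truth gates.
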