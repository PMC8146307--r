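---
title: "Methods: a looped-chromosome model of cytoplasmic subdiffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a looped-chromosome model of cytoplasmic subdiffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`featherboa` simulates a coarse-grained bacterial chromosome — the
"feather-boa" architecture — together with a single cytoplasmic tracer
nanoparticle, inside a rigid cell-wall confinement. The chromosome is a
linear backbone of beads connected by harmonic springs, with a closed side
loop attached at every backbone bead: at full scale, 200 backbone beads and
200 loops of 40 beads (8200 polymer beads), plus the tracer. Loops are
closed *through their anchor*: both loop ends bond to the backbone bead, so
every loop bead has exactly two bonds. This follows the closed-loop
architecture of the model family; an open-brush variant is available via
`build_feather_boa(closed_loops = FALSE)` for sensitivity checks.

All quantities are in reduced units: lengths in the bead diameter
$\sigma$, energies in $\epsilon$, times in $\tau$, with $k_BT = 1$.

Three interactions act:

* **Bonds**: $U_{bond} = \tfrac12 k_{bond}(r - \sigma)^2$ with
  $k_{bond} = 100\,\epsilon/\sigma^2$.
* **Pairs**: the purely repulsive Weeks–Chandler–Andersen potential,
  i.e. Lennard-Jones truncated at its minimum $2^{1/6}b$ and shifted, with
  contact distance $b = \sigma$ for bead–bead pairs and
  $b = \sigma/2 + r_p$ for bead–tracer pairs ($r_p$ = tracer radius).
* **Walls**: each wall element (lateral cylinder surface, flat end plane,
  compression plane, hemispherical cap) contributes an independent 9-3
  Lennard-Jones term
  $U_{wall}(r) = \epsilon[\tfrac{2}{15}(b/r)^9 - (b/r)^3]$ in the gap $r$
  to that surface, cut off at $2^{1/6}b$ and energy-shifted to zero there.

Two choices here deserve comment, because the model definition leaves them
open:

* **Bonded pairs are excluded from the WCA sum.** With $r_0 = b = \sigma$
  the harmonic minimum sits inside the WCA core; double-counting would
  shift the effective bond length away from $\sigma$. Exclusion matches
  common practice for this family of bead-spring models, and the package
  verifies the bond-length distribution against the one-dimensional
  Boltzmann quadrature oracle.
* **The wall cutoff is kept at $2^{1/6}b$ as specified**, which retains
  part of the attractive branch of the 9-3 form (a shallow well of depth
  ≈ 0.39 ε after shifting). A purely repulsive mode cutting at the
  potential minimum $(2/5)^{1/6}b$ is available via
  `ff_params(wall_cutoff = "repulsive")`.

## Confinement geometries

Three wall shapes, all centred at the origin with the long axis along $z$
(the "focal" observation plane is $xz$):

* `cylinder_spec(diameter, length)` — flat end caps at $z = \pm L/2$. The
  end-cap treatment is not part of the printed model definition; flat
  planes are the minimal closure that confines beads in all directions.
* `spherocylinder_spec(diameter, cyl_length)` — hemispherical caps; the
  wall gap is computed as $R$ minus the distance to the axis segment,
  which is exact for every point inside.
* `compressed_spec(width, height, length)` — intersection of a cylinder
  with a slab of two parallel planes normal to $y$ at $\pm H/2$, the
  compressed-cell geometry. Flat end planes close the axis, as for the
  cylinder.

**Constant-packing-fraction compression.** Under compression the cell
length is fixed, so fixing the cross-sectional area fixes the volume and
hence the monomer packing fraction η. The cross-section of a compressed
cell is a circle-slab intersection with area
$2[h\sqrt{R^2-h^2} + R^2\arcsin(h/R)]$ ($R = W/2$, $h = H/2$), and
`solve_width_for_height(H, 29.5)` root-finds the width $W$ whose area
equals the uncompressed circle $\pi\,29.5^2/4$, bracketing on
$[D_{ref}, 10\,D_{ref}]$ since compression always widens the cell. The
three canonical heights give widths 31.625, 37.579 and 50.148 σ. The
source material prints the third height in two variants (13.086 σ in one
place, 13.806 σ in another); only 13.806 σ reproduces the quoted width
50.15 σ, so 13.806 σ is canonical here and `preset("compressed-H13.806")`
carries it.

**A documented inconsistency.** The printed claim that the cell-like
spherocylinder (29.5 σ diameter, 45.83 σ cylindrical height) holds the
same packing fraction as the 29.5 × 50.75 σ cylinder is not geometrically
attainable: hemispherical caps add 29% volume (44 767 vs 34 687 σ³, ratio
0.7749). The presets keep the printed dimensions; the regression test
freezes the true ratio. All quantitative targets in this package use the
cylinder geometry, where no ambiguity exists. Because η's bead-volume
convention is likewise unresolved in the source (8200 beads of diameter σ
in the stated cylinder give η ≈ 12.4%, not 23.8%), `packing_fraction()`
takes the bead diameter as an explicit argument and every η-based claim is
implemented as a convention-independent *ratio*.

## Dynamics

The integrator is BAOAB-split underdamped Langevin dynamics: velocity
half-kick, half-drift, exact Ornstein–Uhlenbeck thermostat step, half-drift,
half-kick, at `dt = 0.01 τ` and `kBT = 1`. Friction γ = 1/τ and bead mass
m = 1 are adopted (they are not part of the printed model definition);
this puts the inertial crossover at $t = m/\gamma = 1\,\tau$, far below
the analysis lags, and makes the free-particle diffusion constant
$k_BT/(m\gamma) = 1\,\sigma^2/\tau$. The tracer mass defaults to 1
regardless of $r_p$ — diffusive-regime observables are mass-insensitive —
with a volumetric option (`particle_mass = "volume"`).

The thermostat noise is a counter-based stream: the three Gaussian draws
for bead $i$ at global step $s$ are a pure hash of (seed, $s$, $i$), so a
run split across restarts or checkpoints reproduces the uninterrupted
trajectory bit-exactly. This determinism contract is tested.

Pair interactions go through a linked-cell grid plus Verlet list with a
0.4 σ skin, rebuilt when any bead has moved more than half the skin.
Cell-list forces are verified against brute-force $O(N^2)$ evaluation to
10⁻¹² relative, and all forces against central differences of the energy.

**Initial configurations** place the backbone on a helix near the wall,
each closed loop on a circle of matching circumference through its anchor
lying in the radial–axial plane and extending inward (so loops fill the
interior instead of crowding a shell), and the tracer at a random interior
point with ≥ 1 σ + contact clearance from every wall. Residual overlaps
are removed by capped-force steepest descent over soft pair/wall
repulsions plus softened bonds, with the push amplitude annealed and
deterministic kicks breaking descent limit cycles. The relaxer targets
overlaps no deeper than 0.05 σ; in practice the minimum pair distance
after initialisation is ≥ 0.95 σ across all presets. Velocities are drawn
from the Maxwell–Boltzmann distribution at $k_BT = 1$.

## Run protocol and presets

The full-scale protocol is 10⁷ equilibration steps followed by 10⁸
production steps with frames every 100 steps (1 τ). The presets
`uncompressed`, `cell`, `dense` (26.93 σ diameter, a 20% packing-fraction
increase) and the three `compressed-H*` cells carry this protocol; they
are cluster workloads and are not exercised by the test suite beyond their
wiring.

`scaled-test` is the desk-scale fixture used for all quantitative checks:
50 backbone beads, 50 closed loops of 10 beads (550 polymer beads) and one
tracer, in a cylinder scaled isotropically to the same polymer-bead-count
per volume as the full cylinder (diameter 11.99 σ, length 20.62 σ), with
10⁵ equilibration + 5 × 10⁵ production steps. A full sweep of this system
runs in about a minute on one core.

## Trajectory analysis

* `msd_2d()` computes the time-averaged MSD of one tracked bead projected
  on the focal plane over all overlapping start frames (an
  independent-window mode is implicit in choosing non-overlapping lag
  grids; overlapping averaging is the default as standard practice).
  `msd_ensemble()` averages curves over replicate runs and/or equivalent
  beads.
* `fit_power_law()` fits MSD $= 4 D_{xz} t^\alpha$ by least squares in
  log–log space ("exponential regression" in the source's terminology),
  with 95% confidence bounds from the linear-fit covariance and an
  optional nonlinear refinement. The full-scale fit window is
  $t \in [10, 1000]\,\tau$. For the scaled fixture the window is
  $[10, 500]\,\tau$: its production trajectories are 5000 τ long, and
  time-averaged MSD values at lags beyond ~T/10 carry too few independent
  windows to constrain a power law.
* `displacements_1d()` collects all overlapping 1D displacements
  $\Delta z = z(t + t_m) - z(t)$ at measurement lag $t_m$, reports their
  standard deviation δ, and builds the peak-normalised histogram of
  $\Delta z/\delta$ over 41 bins on $[-5\delta, 5\delta]$. The full-scale
  lag is $t_m = 1000\,\tau$; the scaled fixture uses $t_m = 100\,\tau$,
  scaled down with the trajectory so that enough independent windows
  remain (5000 τ / 100 τ = 50, against 10⁶ τ / 1000 τ = 1000 at full
  scale).
* `fit_step_shape()` computes maximum-likelihood Gaussian and Laplace fits
  (Laplace in mean/standard-deviation form
  $P(\Delta z) = \tfrac{1}{\delta\sqrt2}e^{-|\Delta z-\mu|\sqrt2/\delta}$,
  MLE $\mu$ = median, $\delta = \sqrt2\,\mathrm{mean}|\Delta z -
  \mathrm{med}|$), their log-likelihood difference, and the excess
  kurtosis of the samples (0 for Gaussian, 3 for Laplace).

## What the scaled fixture does and does not show

The desk-scale system reproduces, at its own size, the phenomenology the
model is built for: a monomer-sized tracer and the mid-loop loci show
anomalous exponents near 1/2 (ensemble over four replicates: tracer
α ≈ 0.53, mid-loop loci α ≈ 0.40–0.47 across seed groups); the locus
mobility ordering — backbone middle slowest, backbone ends intermediate,
loop loci fastest — holds at fixed lag; the monomer-sized tracer's step
distribution is Gaussian while a mid-size (3 σ) tracer's is heavy-tailed
toward a Laplace law. Ensemble averaging over replicates is essential at
this scale: single-run locus exponents scatter by about ±0.1 because one
5000 τ trajectory holds few independent long-lag windows.

What it cannot show: absolute diffusion coefficients (γ and m are
conventions, so only ratios and exponents are meaningful), the ~80-fold
D drop across tracer sizes 1–4 σ, the α ≈ 0.7 plateau for d ≥ 1.5 σ, and
the compressed-cell panel values — those are properties of the 8201-bead
system over 10⁸ steps and are wired as the full-scale presets. The model
itself, by construction, contains no ATP-driven activity, no explicit
crowders and no hydrodynamics; it probes how much of cytoplasmic
subdiffusion follows from chromosome mechanics alone.

## Numerical choices and degenerate inputs

* Width solver: `uniroot` at 10⁻¹⁰ relative tolerance; heights at or above
  the reference diameter return the uncompressed width (no compression);
  heights too small to bracket raise an "infeasible geometry" error.
* Wall gaps ≤ 0 raise an `escaped-bead` error naming the bead and its
  coordinate; non-finite coordinates raise an integration-blowup error
  naming the bead and step.
* A drifting bead with zero displacement spread is flagged `degenerate` by
  `displacements_1d()` rather than silently dividing by zero.
* On-axis points in a cylinder have an ill-defined lateral normal; an
  arbitrary fixed unit vector is returned (the lateral gap there is R, far
  outside any interaction cutoff in every meaningful configuration).
* The free-particle check fits on lags $t \in [100, 1000]\,\tau \gg
  m/\gamma$, because the exact underdamped MSD $4D[t - (1 -
  e^{-\gamma t})/\gamma]$ biases power-law fits at shorter lags (the
  package reproduces this closed form to three digits at lag 1 τ).

## Reduced-unit summary of tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `k_bond` | 100 | ε/σ² | harmonic bond stiffness |
| `r0` | 1 | σ | equilibrium bond length |
| `epsilon` | 1 | ε | WCA / wall energy scale |
| `particle_radius` | 0.5 | σ | tracer radius $r_p$ (diameter $2r_p$) |
| `dt` | 0.01 | τ | integrator step |
| `kBT` | 1 | ε | thermostat temperature |
| `gamma` | 1 | 1/τ | Langevin friction |
| `mass` | 1 | m | bead mass |
| `skin` | 0.4 | σ | Verlet-list skin |
| `dump_every` | 100 | steps | frame interval (1 τ) |
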