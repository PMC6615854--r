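---
title: "Mechanochemical bundle dynamics and morphology classification: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanochemical bundle dynamics and morphology classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actobundle)
```

## The model

`actobundle` simulates untethered bundles of actin filaments decorated with
passive crosslinkers (alpha-actinin) and active ones (non-muscle myosin II
minifilaments), and classifies the emerging morphologies. The question the
package addresses is one of stability: a bundle whose filaments all point the
same way (unipolar) responds very differently to motor activity than a bundle
with mixed polarity (apolar), because minifilaments are unidirectional walkers
and antiparallel filament pairs slide against each other while parallel pairs
do not. Depending on the polarity, the motor and crosslinker mole ratios, and
the filament turnover (treadmilling) rate, a bundle either persists, collapses
into a polarity-sorted aster, settles into an intermediate, or — when
crosslinking cannot keep up — disintegrates ("catastrophes").

### Mechanics

Each filament is a chain of cylinders joined at hinge beads. A cylinder holds
an integer number of actin monomers; its rest length is `monomers x 2.7 nm`,
so a partially filled end cylinder has a proportionally shorter rest length
and polymerization changes the geometry smoothly. The energy is a sum of:

* **Stretching** — harmonic per cylinder, `(k_str/2)(l - l0)^2`, default
  `k_str = 100 pN/nm`.
* **Bending** — discrete worm-like chain, `k_bend (1 - cos theta)` at every
  interior hinge, with `k_bend = lp kBT / l0`. With the experimental
  persistence length `lp = 17 um`, `kBT = 4.1 pN nm` and `l0 = 108 nm` this is
  about 645 pN nm.
* **Excluded volume** — a repulsive `k_vol / r^4` kernel integrated over both
  cylinder axes (Gauss–Legendre quadrature; an analytic-gradient double line
  integral). It is what prevents filaments from passing through each other.
  Below 1 nm the kernel is clamped, so intersecting configurations have a
  large finite energy and are flagged rather than infinite.
* **Crosslinker / minifilament springs** — a bound element is a harmonic
  spring between two fractional attachment points on distinct filaments
  (alpha-actinin: rest 35 nm, 8 pN/nm; minifilament: rest 200 nm, 2.5 pN/nm).
  Its signed tension feeds the mechanochemical rate laws.
* **Boundary walls** — a harmonic penalty outside the box; the wall force on
  a filament tip is the load used by the polymerization ratchet.

Mechanical equilibration uses Polak–Ribière conjugate gradient with restarts
and an Armijo line search with quadratic interpolation, run until the largest
per-bead force component falls below the force tolerance (default 1 pN).
Non-convergence is flagged on the result, never silent. All analytic
gradients are tested against central finite differences at 1e-5 relative
accuracy.

Thermal (Langevin) fluctuations are deliberately absent: the propagation
scheme exploits the timescale separation between slow chemistry and fast
mechanical relaxation instead of resolving thermal motion.

### Stochastic chemistry

Reactions are propagated by the next reaction method: every channel keeps a
tentative firing time, the earliest channel fires, and propensity updates
rescale the remaining exponential waits (Gibson–Bruck), which keeps the
trajectory statistically equivalent to the direct stochastic simulation
algorithm — a property the test suite checks by chi-square comparison against
an independent direct-SSA implementation.

Channels and their mechanochemical couplings:

* **Filament end kinetics** — per-end polymerization (plus 11.6, minus
  1.3 uM^-1 s^-1) and depolymerization (1.4, 0.8 s^-1), the in-vitro
  constants. Growth propensity uses the instantaneous local G-actin
  concentration. The treadmilling factor `chi` multiplies all four rates;
  "non-treadmilling" mode zeroes them (the chi = 0 limit). Tips growing
  against a wall are slowed by the Brownian ratchet factor
  `exp(-F delta / kBT)` with `delta = 2.7 nm`.
* **Crosslinker (un)binding** — binding is a single-step reaction creating a
  doubly attached element; eligible pairs are site pairs (quarter, mid and
  three-quarter points of each cylinder) on distinct filaments within the
  species band: 30–40 nm for alpha-actinin, 175–225 nm for minifilaments.
  Alpha-actinin unbinds as a slip bond, `k0 exp(max(F,0) x_c / kBT)`.
* **Minifilament unbinding** — a catch bond derived from the parallel
  cluster picture: the bound-head number performs a birth–death walk (attach
  `k_a` per free head, detach `k0 exp(-F/(n_b F_c))` per bound head with the
  load shared over bound heads), and the ensemble off-rate is the inverse
  closed-form mean first-passage time to zero bound heads. We compute that
  closed form directly rather than fitting the single-exponential
  approximation suggested as a default, because the closed form is exactly
  what the parallel-cluster model prescribes, it is guaranteed monotone
  decreasing in load, and it leaves the Monte-Carlo head-chain oracle in the
  tests genuinely independent.
* **Motor walking** — a linear force–velocity law
  `v = v0 max(0, 1 - F/F_stall)` (defaults `v0 = 200 nm/s`,
  `F_stall = 100 pN`), realized as 2.7 nm steps toward the plus end at
  propensity `v / 2.7`. Walking stalls at the filament tip.

**Numerical choice — span-aggregated walking.** Between two mechanical
equilibrations (the chemistry span, default 0.05 s; the scaled test runs use
0.1 s) every tension, and therefore every walk propensity, is frozen, and a
walk event changes no other channel's propensity. The number of steps an
attachment takes over its alive interval within a span is therefore Poisson
with known rate, and the implementation draws it in one variate instead of
scheduling each step as a separate event. This is statistically identical
under the frozen-rate approximation already in force and removes the dominant
event cost at high motor density. Per-event displacement remains one step,
which the two-filament sliding test verifies by arc-length bookkeeping.

**Numerical choice — the well-mixed default.** The reaction volume is tiled
into voxels (the Kuramoto-length scale, default 500 nm) and free species hop
between face-adjacent voxels as first-order events. At realistic copy numbers
(tens of thousands of G-actin monomers) explicit hops dominate the event
budget while contributing nothing at bundle scale, so the desk-scale default
is the fast-diffusion limit: a single well-mixed voxel
(`spatial_diffusion = FALSE`). The spatial machinery is retained, exercised
by a relaxation-to-uniformity test, and enabled by one config flag.

### Protocol

A trajectory alternates: advance chemistry one span, re-equilibrate
mechanics, update mechanosensitive rates from the new tensions and tip loads,
and (optionally) update the flexible volume, which sets the box X-extent to
the filament span plus a 500 nm margin on both sides and re-tiles the voxel
field conserving every copy. Snapshots are recorded at a fixed interval;
identical (config, seed) pairs give bit-identical trajectories.

The reference initial condition is a 2 um bundle of 30 filaments on a 35 nm
hexagonal lattice (filled in concentric order), in a 4 x 1.5 x 1.5 um box at
5 uM total actin. Unipolar bundles point all plus ends toward +X; apolar
bundles alternate orientation by lattice column with a deterministic fix-up
so the two orientation counts differ by at most one (column alternation
maximizes antiparallel neighbor pairs, the arrangement most susceptible to
sliding). Free species totals follow from the mole ratios alpha:A (molecules
of alpha-actinin per actin monomer) and M:A (myosin heads per actin monomer;
one minifilament carries 2 x 16 heads).

Steady state is declared from an observable series (radius of gyration, or
mean filament length under treadmilling) when every sliding-window mean from
some onset on stays within 5% of the final window's mean, with at least two
full windows of steady data (the last guard keeps a slowly ramping series
from being called steady merely because its trailing windows resemble the
final one).

### Morphology classification

For each condition the three distributions of cross-filament end distances —
plus–plus, minus–minus and plus–minus (both ordered cross-polarity pairs per
unordered filament pair) — are pooled over steady-state snapshots into 50 nm
histograms on shared bins. Condition dissimilarity is the unweighted mean of
the three base-2 Jensen–Shannon divergences (bounded in [0, 1]; the log base
and the equal weighting are this package's choices, stated here because the
method's description fixes neither). Complete-linkage agglomeration (authored
in-package, deterministic lowest-index tie-breaking, `hclust`-compatible so
trees cut with `cutree` and export to Newick via `ape`) is cut into three
clusters, and each cluster is labeled from its medoid's order parameters:

* **BL** (bundle-like): nematic order `S >= 0.6`;
* **AL** (aster-like): polarity-sorting score `> 0.2` with asphericity
  `< 0.1` (plus ends central, near-spherical);
* **ABI** (aster–bundle intermediate): the remainder.

`S` is the largest eigenvalue of the length-weighted cylinder orientation
Q-tensor `3/2 <uu> - 1/2 I`; the polarity-sorting score is the mean
minus-end minus mean plus-end centroid distance over the radius of gyration;
asphericity is the normalized gyration-tensor measure (0 for a sphere, 1 for
a rod). All features are rigid-frame invariant to 1e-9 relative.

Catastrophe labels preempt the three classes. The filament graph (one edge
per bound element) gives: Type A if the largest connected component holds
less than `f_A = 0.6` of the filaments; otherwise Type B if the mean linker
degree `2E/N` is below `d_B`. The stated default pair (`f_A = 0.6`,
`d_B = 1.0`) is mutually unsatisfiable — a component holding 60% of N
filaments already forces `2E/N > 1` for N > 10 — so this package ships
`d_B = 1.5`, which preserves every worked example (a spanning chain has mean
degree ~1.93 and is not a catastrophe) while making Type B reachable. Both
thresholds remain configuration-exposed.

### Synthetic fixtures

`make_fixture()` generates labeled geometries — bundle, aster, intermediate,
sarcomere (apolar bundle with minifilaments confined to bands near minus-end
overlaps), fragmented (Type A ground truth) and sparse (Type B) — with
isotropic Gaussian bead jitter plus small per-filament rigid rotations
(default 10 nm, a realistic lattice disorder scale). Fixtures emulate the
geometric and connectivity structure of the terminal morphologies only; they
carry no mechanical or chemical realism. A green classifier test on fixtures
therefore establishes that the pipeline separates the morphology classes it
was built to separate — not that the simulator reaches those classes under
any particular condition, which only the (scaled) trend runs probe.

## What the scaled tests do and do not establish

The reference campaigns behind the published phase behavior are 42 mole-ratio
pairs x 8 trajectories x 2000 s plus 84 treadmilling triads x 7 trajectories
— multi-day single-CPU work that the test suite does not attempt; the
condition-grid runner implements the campaign and a reduced smoke grid proves
the plumbing. The trend tests run the stated 10-filament, 1 um, 5-seed world
for 30 s (a runtime-budget scaling, chosen from measured wall-clock before
inspecting outcomes). At that horizon the acceptance tests check that unipolar bundles at low
motor density retain `S > 0.8` and that apolar bundles at M:A 0.675
polarity-sort (positive sorting score), each in at least 4 of 5 seeds. One
caveat is recorded openly:
at M:A 0.675 *both* polarities collapse toward asters — as the reference
phase behavior itself indicates for that ratio — so the additional demand
that the apolar S be seed-wise lower than the unipolar S at a 30 s horizon is
noisy, and the corresponding acceptance clause is allowed to fail honestly
rather than being re-tuned. The robust apolar-instability signature at this
scale is the sorting score, not the S ordering.

## Known limitations

* Nucleotide states (ATP/ADP.Pi/ADP), branching, severing, capping and
  nucleation are out of scope; end kinetics are effective per-end rates.
* Motor load on a walking attachment is the rectified spring tension; the
  projection onto the walking direction is not resolved.
* Binding propensities use the species' mean concentration over the box
  (exact in the well-mixed default; an approximation in spatial mode).
* Eligible-pair enumeration is O(sites^2) per span, adequate at desk scale.
* Catastrophe thresholds and the label thresholds (`S >= 0.6`, sorting
  `> 0.2`, asphericity `< 0.1`) are calibrated on the synthetic fixtures, not
  on campaign-scale simulation output.
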