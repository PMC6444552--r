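---
title: "Mechanistic simulation of multistate movement in resistance landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic simulation of multistate movement in resistance landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverwalk)
```

## The model

riverwalk simulates the movement of an individual animal as a multistate,
locally biased correlated random walk in continuous space. The animal
carries a small set of behavioral states (say, an exploratory random walk,
a directed commuting walk, and rest); a Markov chain switches between them
with fixed per-step probabilities. Within a state, movement is governed by
three familiar movement-ecology parameters: a turning-angle concentration,
a maximum step length, and a perceptual range.

The landscape enters through a resistance raster: a grid of values in
$[0, 1]$ where 0 is freely traversable and 1 is impassable. The two
assumptions that drive everything are (a) the environment *around* the
current location biases the choice of heading for the next step, and (b)
the environment *crossed by* a step throttles its length. Both effects are
local — the walker is never given a global destination or a least-cost
path, so it cannot "know" anything beyond its perceptual range.

Each simulation step proceeds as follows:

1. Draw the next behavioral state from the transition-matrix row of the
   current state.
2. Sample the resistance raster at points regularly spaced along $K$
   radial lines centered on the current location, out to the state's
   perceptual range.
3. Sum the conductance ($1 - \text{resistance}$) of the samples on each
   line, giving an empirical distribution of desirable headings.
4. Build a discrete wrapped-normal turning kernel on the same $K$
   headings, centered on the previous step heading, with the state's
   concentration $\rho$.
5. Multiply the two distributions, weight by weight, and renormalize.
6. Draw the new heading from the product.
7. Scale the state's maximum step length by
   $1 - \tfrac{1}{2}(r_\text{start} + r_\text{end})$, the mean resistance
   of the step's endpoints: zero mean resistance realizes the full step,
   mean resistance 1 realizes no movement.
8. Move; if the scaled landing point still falls on an impassable cell, an
   explicit guard shortens the step further (see "Numerical choices").

Because headings are re-drawn at every (high-frequency) step, landscape
bias accumulates into realistic large-scale behavior: walkers funnel along
low-resistance corridors, hesitate at crossings, and — in the binary
water/land limit — remain strictly confined to a river network.

### The turning kernel

The concentration parameter is the mean resultant length
$\rho = e^{-\sigma^2/2} \in [0, 1]$ of a wrapped normal distribution: the
only standard circular parameterization bounded in $[0,1]$. The kernel is
evaluated on the discrete grid from the wrapped series

$$f(\theta) = \frac{1}{2\pi}\Big[1 + 2\sum_{p \ge 1} \rho^{p^2}
\cos p(\theta - \mu)\Big],$$

truncated once $\rho^{p^2} < 10^{-12}$, then normalized over the $K$ grid
angles. $\rho = 0$ is exactly uniform (random walk); $\rho = 1$ is a point
mass on the grid angle nearest the previous heading (straight-line limit).
A unit test cross-checks this series against an independent evaluation
that wraps the plain normal density directly.

### States, resting, and heading memory

A state with maximum step length 0 is a Resting state. Two conventions are
deliberate and documented rather than incidental:

* the "previous step heading" that centers the turning kernel is the
  direction of the last step with *nonzero displacement* — resting (or
  being fully blocked) does not randomize orientation, so a correlated
  walker resumes its old direction after a rest;
* state switching is evaluated once per step, before the heading draw, and
  the new state's kernel and perceptual range govern that same step.

## Tunable parameters

| Parameter | Units | Default | Notes |
|---|---|---|---|
| `concentration` ($\rho$) | — | per state | 0 = RW, near 1 = CRW |
| `step_length` | map units | per state | fixed per-state maximum; realized steps are shorter in resistant terrain |
| `perceptual_range` | map units | per state | radius of landscape perception |
| transition probabilities | per step | per species | row-stochastic; dwell time in a state with exit probability $p$ is geometric with mean $1/p$ |
| `K` (angular grid) | headings | 72 | 5° resolution; both perception lines and heading support |
| `samples_per_line` | — | `max(2, ceil(range / (cell/2)))` | at least half-cell-dense radial sampling |

The step length should respect the half-of-thinnest-feature rule: at most
half the width of the narrowest landscape feature the walker must resolve,
otherwise a step can jump clean across a barrier between two samples of
the attenuation rule. The bundled channel generators enforce a minimum
channel width of 2 cells for exactly this reason.

Perceptual range deserves a caveat: simulations are fairly insensitive to
it until it changes by orders of magnitude, which also makes it weakly
identifiable from data. The parameter-approximation module therefore fixes
it (user-supplied) instead of searching it.

## Numerical choices

* **Discrete headings.** Headings are drawn on the $K$-angle grid, not
  interpolated between angles; the angular machinery is genuinely
  discrete. $K$ is configurable where it matters.
* **Impassability guard.** The endpoint-averaging attenuation rule alone
  can land a walker *on* an impassable cell (e.g. start at resistance 0
  aiming into resistance 1 gives a half step ending on the barrier).
  Because resistance 1 is defined as "where the walker cannot be", the
  simulator ray-marches back along the segment in quarter-cell increments
  to the farthest passable point; if none exists the walker waits in
  place. The start cell is always passable, so the search always
  terminates.
* **Boxed-in walkers.** If every product weight in step 5 is zero (all
  perception mass on headings the kernel excludes, or vice versa), the
  draw falls back to the kernel alone and the guard then enforces a
  zero-length move. The event is counted in the trajectory's
  `trapped_steps` attribute rather than raising an error: a fish at the
  tip of a dead-end channel waits, it does not teleport.
* **Out-of-extent policy.** Any lookup outside the raster extent returns
  resistance 1, and NoData cells are read as 1. Unknown terrain is
  impassable — the conservative choice, and the mechanism that keeps
  trajectories inside the mapped world.
* **Pixel convention.** Cells are half-open,
  $[x_0, x_0 + c) \times [y_0, y_0 + c)$, row 1 at the top in file order,
  so a point on an interior edge belongs to exactly one cell and edge
  lookups are unambiguous.
* **Homogeneous fast path.** With no raster, the perception term is
  uniform, so the combined distribution *is* the kernel; and on a regular
  grid the kernel centered on a grid angle is a circular shift of the
  kernel centered on 0. Heading indices therefore perform a modular random
  walk driven by iid per-state kernel draws, which vectorizes the whole
  simulation. This is an exact reduction, not an approximation — a test
  compares the turning-angle law of the two code paths on an all-zero
  raster — and it is what makes the optimization loop (tens of thousands
  of simulations) affordable.
* **Rasterization.** Shapes are burned in list order with last-wins,
  cell-center semantics, the usual GIS overlay behavior; polylines are
  buffered by perpendicular distance into corridors of total width
  `2 * buffer`. How overlapping features *should* combine is genuinely
  open — last-wins is this package's documented choice.

## Downsampling and the observable scale

Real telemetry is far coarser than the simulation frequency.
`sample_movement()` thins a trajectory to every $m$-th location (index-
based thinning — simulation steps are the clock) and computes step
lengths, turning angles in $(-\pi, \pi]$, and accumulated resistance (the
sum over the $m-1$ skipped locations; the kept endpoints are excluded, a
convention documented here because either choice is defensible). The
fixed-step-length simplification at high frequency washes out at this
scale: downsampled step lengths are smooth, right-skewed distributions,
and a two-state RW/CRW walker shows the heavy-tailed, Lévy-like step
distribution familiar from compound walks.

## Parameter approximation from observed tracks

Given an observed low-frequency track, `adjust_model()` asks: what
high-frequency simulation parameters could have produced it? This is
pattern-oriented calibration: candidate parameter sets are simulated at
high frequency, downsampled by the frequency ratio $m$, and scored by the
L1 distances between simulated and observed turning-angle and step-length
histograms (16 angular bins; 20 step bins spanning
$[0, 1.1 \times \max]$ of the observed lengths; both configurable; the
Wasserstein distance is available as an option). These two aggregate
metrics admittedly discard much of what characterizes a trajectory — they
are the package's documented default, not a claim of sufficiency.

The search engine is an in-package NSGA-II: fast nondominated sorting,
crowding distance, binary tournament on (rank, crowding), simulated binary
crossover ($\eta = 15$), polynomial mutation ($\eta = 20$, probability
$1/n_{\text{params}}$), and $(\mu + \lambda)$ elitist survivor selection,
with defaults of 100 individuals and 50 generations. Two properties are
load-bearing and tested: parents keep their cached objective values, so
per-generation objective minima never increase; and crowding truncation
keeps per-objective extremes, so the front retains its spread.

Each candidate is scored by a single fresh stochastic simulation. The
objective surface is therefore noisy; elitism can retain a lucky
evaluation. At the problem sizes used here (10,000-step simulations,
$m = 10$, ~1,000 observed steps) the histogram noise floor is small
relative to parameter effects, and single-state recovery experiments
return front candidates within $\pm 0.05$ of the true concentration and
$\pm 20\%$ of the true step length in at least 8 of 10 seeded replicates.
Averaging repeated evaluations is supported upstream of the optimizer but
off by default: it multiplies runtime for little gain at these sizes.

Timestamped tracks are handled minimally: the track is split into
segments wherever the sampling interval exceeds 1.5 times the modal
interval, per-segment statistics are pooled, and no interpolation onto a
regular grid is attempted. Decoding of candidate vectors uses a fixed,
documented layout (per-state concentration and step length, then
row-major off-diagonal switching probabilities) whose bounds guarantee
every in-bounds vector is a valid species.

## Synthetic landscapes: what they do and do not emulate

`synthetic_landscape()` generates the study landscapes in code:
homogeneous (all zero), a meandering river corridor (the centerline is
itself a seeded correlated random walk, buffered to a fixed width — which
reuses the core machinery and guarantees a connected channel), a
dendritic network (a binary branching tree; depth $d$ gives $2^{d-1}$ leaf
channels), zero-resistance patches in a graded matrix, and a smooth
resistance gradient with seeded noise. Defaults are 300×300 cells of size
10 — ample room for 10,000-step runs at step length 10 without boundary
pinning — and all generation is deterministic given the seed.

These fixtures emulate the *geometry* classes that matter to the
algorithm (linear confinement, branching, patchiness, gradients). They do
not emulate real hydrology, DEM-derived channel widths, temporally
varying landscapes, or telemetry error — so a passing test suite shows
the mechanics are right under controlled geometry, not that any
particular real system is well described. Parameter-recovery results in
particular are demonstrated on data generated by the model itself; with
real tracks the model-mismatch term is unknowable from inside the
package.

## Problem sizes used in the checks

The validation suite exercises: 50,000-step homogeneous runs for kernel
recovery ($\rho \in \{0, 0.5, 0.95\}$, concentration recovered within
$\pm 0.02$); $10^6$-step runs for switching rates and dwell times (3
standard errors); 10,000-step confined runs on a 150×150 dendritic raster
(zero escapes tolerated); Schaffer's two-objective problem for the
optimizer (hypervolume within 2% of the analytic optimum); and ten seeded
single-state recovery replicates at population 100 × 30 generations.
These sizes were chosen so each check's sampling error is comfortably
below its tolerance while the whole suite stays desk-scale.

## Known limitations

* Transition probabilities are fixed per species; habitat- or
  time-dependent switching is out of scope.
* No inter-individual interactions, memory, or home-range mechanisms.
* Step lengths are per-state constants at the simulation frequency (by
  design; distributions emerge at the observation frequency).
* The two calibration metrics are aggregate distributions only;
  maximum-likelihood or Bayesian estimation of these models is a separate
  problem the package does not attempt.
* Rasters and shapes must share a coordinate system; the CRS tag is
  carried, never interpreted, and there is no reprojection, multi-band, or
  temporal-stack support.
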