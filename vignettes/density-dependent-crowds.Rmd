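---
title: "Density-dependent preferred velocities for microscopic crowd simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-dependent preferred velocities for microscopic crowd simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedflow)
```

## The problem

Microscopic crowd simulators usually split trajectory generation into a
global planner (which proposes a *preferred velocity* $\vec v_0$ toward the
current goal at the walker's desired speed) and a local planner (which turns
the preferred velocity into a collision-free velocity for the next time
step). Local planners such as the social force model or optimal reciprocal
collision avoidance (ORCA) are very good at not colliding, but left to
themselves they do not slow down the way people do: empirically, walking
speed falls with crowd density — the *fundamental diagram* (FD) — even when a
faster collision-free motion exists. A planner that only avoids collisions
will happily thread a 2.5 people/m² crowd at free-walking speed.

`pedflow` inserts a *density-dependent filter* between the two layers. Each
step, the filter re-aims and re-scales every agent's preferred velocity
according to the density the agent perceives around its intended heading, and
only then hands it to the local planner. The filter layer is pure: with it
disabled the pipeline is exactly the bare local planner.

## The model

**Agent state.** Agents are 2D disks with radius $r$, body width $w$
(default 0.48 m, used only in the density-to-space conversion), current
position and velocity, preferred velocity $\vec v_0$, and three
physiological/psychological parameters: the stride factor $\alpha$, the
height normalizer $H = \mathrm{height}/1.72$ and the stride buffer $\beta$.

**Stride relation.** Biomechanically, stride length and walking speed are
coupled, $L(v) = \alpha H \sqrt v$; psychologically, people keep a personal
space buffer that inflates the space they need by $(1+\beta)$. The space
needed to walk comfortably at speed $v$ is therefore
$S_{\mathrm{needed}} = \alpha H (1+\beta)\sqrt v$, and inverting gives the
natural speed for the space $S$ available ahead:

$$V(S) \;=\; \min\!\Big(\|\vec v_0\|,\ \big(\tfrac{S}{\alpha H (1+\beta)}\big)^2\Big).$$

**Perceived density.** For a probe direction $\hat v_\theta$ offset by
$\theta$ from $\vec v_0$, the agent density is an anisotropic Gaussian sum
over neighbors within `neighbor_radius` of the agent:
displacements $\vec d = \vec p - \vec p_j$ are split into the component
along $\hat v_\theta$ (kept) and the lateral remainder (stretched by
`lateral_scale`, default 2.5), so people ahead weigh more than people
abeam; each transformed displacement contributes
$\frac{1}{2\pi\sigma^2} e^{-\|\vec d\,'\|^2 / 2\sigma^2}$. The prefactor is
the unit-integral 2D normalization (the `as_printed` variant
$\frac{1}{2\pi\sigma}$ is selectable), and the exponent is negative — a true
Gaussian; the package treats these as the only dimensionally consistent
reading of the formulation.

**Obstacle discomfort.** Obstacles are rasterized on a grid of cell size
$c_b$ (default 0.1 m). For each free cell the *contiguous free space* FS is
the mass of a normalized Gaussian stencil (support radius 1 m, stencil
$\sigma$ = half the support) over the support cells that are
4-connected-reachable from the cell through free space: pockets sealed off
behind walls do not count. In the open FS is exactly 1; near walls FS < 1,
and the effective density perceived at the probe point
$\vec q_\theta = \vec p + \hat v_\theta \cdot \mathrm{lookahead}$ is
$\rho_\theta = \rho_{A\theta} / \mathrm{FS}(\vec q_\theta)$: walls make a
given crowd feel denser. The field is computed once, offline; runtime
queries are bilinear interpolations. 4-connectivity was chosen because
8-connectivity leaks through diagonal wall corners; the stencil is
renormalized after truncation so that open-space FS is exactly 1.

**Density to space.** Single-file (1D) FD measurements relate to 2D
densities by a factor equal to the inverse body width:
$\rho_{1D} = w\,\rho_{2D}$ (0.48 m width makes 1 person/m equivalent to
2.08 people/m²), so the linear space ahead is $S = 1/(w \rho)$. This
`seyfried` mapping is the package default: it is the only variant consistent
with the worked 2.08 people/m² equivalence, and the alternative printed form
$S = w/\rho$ (`eq10`, selectable) compresses $S$ by a factor $w^2 \approx
0.23$, which freezes a crowd already at about 1 person/m² under any
plausible $\alpha, \beta$.

**Arc optimization.** The filter evaluates `n_samples` (13) directions on
$[-\theta_{\max}, \theta_{\max}]$ ($\pm\pi/2$) around $\vec v_0$. Each
sample's corrected velocity is $\hat v_\theta V(S(\rho_\theta))$, and the
sample minimizing the distance to the goal after the optimization period
$\tau$ (1 s) wins; ties go to the smaller $|\theta|$, then to the negative
offset. $\tau$ must exceed the planner step `dt`: the preferred velocity is
optimized on a longer horizon than collision avoidance. An agent may pick a
longer but emptier heading when it makes more progress toward the goal.

## Local planners

*Social forces*: driving force $m(\vec v_{\mathrm{pref}} - \vec v)/\tau_H$
plus the Helbing-style exponential repulsion, body force and sliding
friction for agents and wall segments ($\tau_H = 0.5$ s, $A = 2000$ N,
$B = 0.08$ m, $k = 1.2\times10^5$ kg/s², $\kappa = 2.4\times10^5$ kg/(m s),
$m = 80$ kg). $\tau_H$ is implemented as the relaxation time of the driving
force — tying it to the integration step would make the force step-size
dependent. Semi-implicit Euler integration; speed clamped at
`max_speed_factor` (1.3) times the preferred speed.

*ORCA*: per neighbor, the truncated velocity-obstacle half-plane with
half-half responsibility (horizon $\tau^O = 2$ s; already-overlapping disks
are resolved over `dt` instead), solved by incremental 2D linear programming
over the intersection with the speed disk; if infeasible, a fallback program
minimizes the maximum constraint violation while keeping obstacle
constraints hard. Obstacle segments enter as linearized nearest-point
half-planes — an interpretation; the formulation is silent on obstacles.
Two numerical choices matter in dense packs: a nearest-`max_neighbors` cap
(10) on agent constraints, standard for this planner, and a constraint
`safety_margin` (0.04 m) added to combined radii *only inside the constraint
construction*. The fallback program can violate constraints by a few
millimeters per step in a jammed pack; the margin absorbs exactly that, so
physical disks stay disjoint. All metrics use the true radii.

## Scenarios and their defaults

The generator's defaults are the study conditions; they were fixed once and
are listed here with their reasons.

* **Disk radius 0.2 m** (width 0.48 m kept for the density mapping). At
  $r = 0.24$ m, 2.5 people/m² is a packing fraction of 0.45, where
  counterflow cannot physically sustain free-walking speeds for any planner;
  0.2 m is the conventional disk radius of velocity-obstacle crowd
  frameworks and gives packing 0.31 at the top of the density range.
* **Preferred speeds** drawn from a truncated normal, mean 1.34 m/s, sd
  0.05 m/s. Mild heterogeneity breaks symmetry; larger spreads cause
  within-lane overtaking that destabilizes bidirectional lanes at high
  density and makes the unfiltered ORCA baseline noisy.
* **Stride parameters** $\alpha = 1.57$, $H = 1$, $\beta = 1.9$. $\alpha$
  is the biomechanical stride-length factor; $\beta$ was calibrated once,
  with the bidirectional sweep, so the simulated FD has the Weidmann-like
  shape: slowdown beginning near 1 person/m² rather than a flat-then-cliff
  response. With the quadratic $V(S)$ the tail is necessarily steeper than
  the empirical curve; the package reproduces the qualitative relation, not
  the empirical point values.
* **Bidirectional corridor** (default 3.6 m x 20 m): periodic along its
  axis ("infinitely long"), seeded at the requested density on a jittered
  non-overlapping grid, with walking directions alternating between the
  placement rows (`direction_mode = "rows"`). This emulates the organized
  lanes of steady bidirectional flow; the fully mixed `"random"` mode is an
  interpenetrating initial state that drives every planner into a jam which
  anneals only after minutes of simulated time.
* **Uni-directional corridor**: open ends, Poisson inflow at a controlled
  rate, optionally a narrowed exit door. The bottleneck construction
  (inflow 4 people/s against a 1.2 m door) pushes measurement-region
  densities to roughly 2-2.8 people/m², reproducing the congested regime of
  the corridor experiments.
* **Hourglass**: two mirrored concave boundaries narrowing to a 1.2 m
  central passage; agents stage on the left and stream through (default
  200). **Kiosk**: ring spawn, walk to a central kiosk, dwell (default
  10 s), head outward — sustained opposing flows near the center. Both are
  schematic geometries that exercise the algorithm, not reproductions of a
  particular floor plan.

## Measurement protocol

FD samples come from a 2 m long, full-width central measurement region:
for each complete transit, speed = region length / transit time and density
= time-averaged center count in the region during the transit, divided by
the region area. Samples pooled over a sweep are binned by this *observed*
density — that is what an FD scatter plot is; under stop-and-go waves the
same nominal density contributes transits at several local densities, and
binning by the observed value attributes them correctly.

The collision score is the interval penetration depth — for each pair of
adjacent frames, the maximum disk overlap under linear motion within the
interval (closed form of a quadratic) — summed over pairs and intervals and
divided by the number of agent-intervals. The normalization divisor is
exposed (`per_pair_interval`, `total`) because the per-agent-per-interval
convention, while matching the scale of published per-agent scores, is one
of several defensible choices.

Smoothness is reported as finite-difference mean acceleration magnitude and
mean unsigned heading-change rate; both vanish for straight constant-speed
motion.

## Problem sizes

The shipped tests and the acceptance script use: bidirectional corridor
3.6 m x 20 m at initial densities 0.5-2.5 people/m² (36-180 agents), 60 s at
dt = 0.0625 s, three seeds; the congested uni-directional corridor at inflow
4 people/s for 60 s (about 240 agents); hourglass and kiosk runs with 60-80
agents over 40-50 s. These sizes were chosen so a full sweep completes in
minutes on one core while the densest condition still reaches the top of the
experimental density range.

## What the synthetic scenarios do and do not show

The generators emulate controlled corridor experiments: homogeneous adults,
steady goals, flat geometry, no groups, no distraction, no culture- or
age-dependent speed distributions. Passing the shipped checks shows that the
filter produces the qualitative FD response, near-zero collision scores and
smoother trajectories *under these conditions*; it does not demonstrate
calibration against any captured human trajectory set, and the FD tail
steepness in particular should not be read as an empirical prediction.

## Known limitations

* The density response is purely local (one probe per arc direction, one
  meter ahead); meso-scale anticipation (slowing before a visible jam far
  ahead) is out of scope.
* Periodic corridors at high density develop stop-and-go waves over long
  horizons; this is a real feature of the model class, but it makes
  per-initial-density averages unstable, which is why the measurement
  protocol bins by observed density.
* ORCA's obstacle handling is a nearest-point linearization; acute concave
  corners are handled conservatively by multiple segment constraints.
* `space_mapping_mode = "eq10"` is provided for comparison but is not
  usable as a walking model (see above).

## A minimal session

```{r example, eval = FALSE}
sc <- build_corridor(width = 3.6, length = 20, bidirectional = TRUE,
                     initial_density = 1.5, seed = 1)
cfg <- simulation_config(duration = 60, planner = "orca",
                         filter_enabled = TRUE, seed = 1)
traj <- simulate_crowd(sc, cfg)
fd <- fd_samples(traj, sc$measurement)
collision_score(traj)
plot(fd$density, fd$speed, xlab = "density [1/m^2]", ylab = "speed [m/s]")
```
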