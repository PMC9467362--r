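---
title: "Boundary-layer flow, vortex identification, and larval settlement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-layer flow, vortex identification, and larval settlement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

larvaflow studies a question in biophysical ecology: how does
millimeter-scale substrate topography change the wave-driven benthic
boundary layer, and can that change alone — with no biochemical cues —
make it easier for slow-swimming coral larvae to settle? The package
provides the whole computational chain: synthetic oscillatory flow fields
over flat and ridged substrates, tracer imagery and particle tracking
velocimetry (PTV), Q-criterion vortex identification and settling-window
statistics, an agent-based simulation of ellipsoidal swimmers, and the
settlement statistics.

## The flow fields

All lengths are millimeters, times seconds, velocities mm/s; `x` is
streamwise (periodic), `y` vertical with `y = 0` at the substrate base.
The free stream is a pure sinusoid `U0 sin(2 pi t / T)` with defaults
`U0 = 45` mm/s and `T = 5.5` s — wave conditions representative of
shallow reef habitats. With `phase0 = 0`, `t = 0` is a flow reversal.

**Flat substrate.** The exact oscillatory Stokes-layer solution of the
Navier-Stokes equations over a no-slip plane:

$$u(y,t) = U_0\left[\sin(\omega t) - e^{-y/\delta}\sin(\omega t - y/\delta)\right],
\qquad \delta = \sqrt{2\nu/\omega},$$

with $v = 0$. The default kinematic viscosity `nu = 0.85` mm^2/s
(seawater near 27.5 C) gives $\delta \approx 1.22$ mm. The solution is
evaluated in closed form anywhere; it satisfies no-slip exactly and its
velocity amplitude at $y=\delta$ is $|1 - e^{-(1+i)}| U_0 = 0.859\,U_0$,
which the tests verify against the independent complex-amplitude form.

**Ridged substrate.** Rectangular ridges, by default 2.5 mm tall and
7.5 mm apart edge-to-edge (spacing-to-height ratio 3). The ridge width is
not uniquely determined by that description; we take it equal to the
height (2.5 mm), which matches the appearance of the fabricated
substrates, and make it configurable. The flow is composed from a
streamfunction so it is exactly divergence-free:

* above the crest plane, the Stokes layer referenced to the crest plane;
* inside each cavity, one recirculation cell
  $\psi = A(t)\sin^2(\pi X/s)\sin^2(\pi Y/h)$ whose amplitude follows the
  forcing, $A(t) = g\,U_0 (h/\pi) \sin(\omega(t - t_{lag}))$. The
  $\sin^2$ form guarantees no-slip and zero normal flow on all four cell
  boundaries. The sign of $A$ follows the forcing so the cell reverses
  with the flow, preserving the left-right symmetry of the oscillation;
  its magnitude tracks the free-stream magnitude. The default lag is 0.
* a C1 smoothstep applied to the Stokes streamfunction regularises the
  velocity-gradient kink at the crest plane. Inside the blend band the
  smoothstep doubles the peak shear no matter how thick the band is, so
  the default thickness is deliberately thin — 0.1 mm, about two cells of
  the reference 0.05 mm grid — keeping the artifact at grid scale and the
  physical shear profile intact. (An early 0.5 mm default created an
  artificial shear barrier above the crests strong enough to suppress
  settlement there; see "Limitations".)

The cavity gain `g` is calibrated once so the peak in-cavity speed is
6 mm/s at peak forcing (`g = 6/45`), the top of the observed in-cavity
speed range over 2.5 mm ridges; settling-window durations are left fully
emergent. The 0.25 mm comparison geometry keeps the spacing-to-height
ratio of 3 (0.25 mm ridges, 0.75 mm gaps).

**Gridded sampling.** `sample_field()` materialises any analytic provider
on a uniform grid (default 0.05 mm, 64 slices per period) by
centrally differencing the sampled streamfunction. Because the discrete
central-difference operators commute, the discrete divergence at interior
fluid nodes cancels identically (measured ~1e-14 s^-1), rather than
being merely O(dx^2) small. Time interpolation is periodic and linear.

## PTV

Synthetic tracer imagery is rendered from RK4-advected passive tracers
(Gaussian spots, 31 um/px, 90 fps by default, additive non-negative
noise). Detection thresholds at a fraction of the frame maximum
(default 0.5), labels connected components (8-connectivity) and returns
intensity-weighted centroids; linking is nearest-neighbour with greedy
assignment by ascending distance and a hard displacement cap, so crossing
particles break into separate tracks rather than swap. Velocities are
finite differences placed at link midpoints, folded by the forcing period
and averaged over 40-frame phase windows (0.44 s at 90 fps) on a 0.5 mm
grid; empty cells are missing, not zero. These detection/linking defaults
are package choices (no measured-data defaults exist to inherit).
`grid_velocities(min_track_length =)` optionally drops very short tracks,
the standard guard against spurious links. The end-to-end recovery test
(advect, render, detect, link, grid against the known field) achieves
<5% RMS in cells with at least 5 samples when frame-to-frame
displacements are kept below the mean particle spacing; the test uses a
360 fps record centred on the peak phase for that reason.

## Flow analysis

Velocity gradients use second-order central differences, one-sided
second-order stencils at walls and edges, and never difference across the
solid mask. The Q-criterion is
$Q = \tfrac12(\lVert\Omega\rVert^2 - \lVert S\rVert^2)$; for 2D
divergence-free fields this equals $\det(\nabla U)$, which the tests use
as an independent oracle, and it is Galilean- and rotation-invariant.
The vortex threshold `Q_thresh` is the population standard deviation of Q
over all fluid nodes and all slices of one period of the dataset under
analysis. Vortex regions are 4-connected components above threshold with
at least 4 cells (suppressing single-cell noise). Settling windows are
maximal intervals during which the mean speed in the band within 1.5 mm
of the local surface stays below the larval threshold — by default the
mean swimming speed plus one standard deviation (3 + 1 = 4 mm/s), the
band reading of the threshold; `threshold = u_ell` gives the stricter
swimming-speed-only cutoff. Window boundaries are interpolated linearly
and the series is treated as periodic, merging the wrap-around window.
A settlement location is "under a vortex" if any fluid node in the
one-cell-wide column up to 1.5 mm above it exceeds `Q_thresh` at any
sampled time; the column extent is a documented package choice.

## The agent-based simulation

Larvae are neutrally buoyant prolate spheroids (semi-axes
`a = 0.25`, `b = 0.15` mm, shape parameter
$\alpha = (1-(b/a)^2)/(1+(b/a)^2) = 0.4706$) swimming at a constant
`u_ell = 3` mm/s along their major axis $\hat n$:

$$\dot{\mathbf r} = \mathbf U + u_\ell \hat n, \qquad
\dot\theta = \tfrac{\omega_z}{2} + \alpha\, \hat g \cdot (S \hat n),$$

with $\hat g$ the minor-axis direction — Jeffery rotation in the local
shear. In uniform shear $\gamma$ this tumbles with the closed-form period
$(2\pi/\gamma)(r + 1/r)$, which the integrator recovers within 1% at the
default `dt = 0.01` s (0.18% of the period).

Integration is explicit Euler at fixed `dt` (the step was justified in
the motivating analysis by displacement per step, implying a simple fixed
step scheme); the analytic providers are evaluated in closed form inside
a compiled loop, so the full lattice runs in seconds. The seeding lattice
is the deterministic cross product of 30 positions (at 10 mm height), 32
orientations and 20 release phases — 19,200 agents, no randomness
anywhere, so runs are bitwise reproducible. Boundaries: periodic in x,
open absorbing top at 30 mm, rigid substrate below. Contact is "centre
within `b` of a solid surface" (contact geometry is otherwise
unspecified in the source); a contacting larva settles only if its total
speed is below the gate `u_ell + sd_u = 4` mm/s, otherwise the
penetrating displacement component is projected onto the surface tangent
(sliding — bouncing was rejected as unphysical for ciliated larvae) and
integration continues. Agents still swimming after `max_time = 120` s
(~22 periods) are reported `unresolved` rather than truncated into
another class; with defaults these are almost exactly the horizontal
orientations ($\theta \in \{0, \pi\}$, 2/32 = 6.25%) that never leave the
release height.

## Statistics

Settlement proportions are arcsine-square-root transformed before
fixed-effects ANOVA (`aov`) with post-hoc Tukey HSD at alpha = 0.05,
matching the transform-then-test order of the classical treatment of settlement proportions. For
simulations the replicate grouping must be chosen explicitly; the
pipeline uses the 20 release phases as replicate groups, a choice we
document rather than inherit (no canonical grouping exists for lattice agents).
Ridge-base distances are horizontal distances to the nearest ridge flank
along the floor; the settlement-by-Q recast crosses per-run percentages
above/below `Q_thresh` with species for the two-factor ANOVA, dropping
(with a warning) runs without settlers.

## What the generator does and does not emulate

The synthetic fields reproduce: the no-slip oscillatory boundary layer
and its phase-dependent thickness; in-cavity recirculation with
supra-threshold Q confined to the cavities (flat fields have Q exactly
zero, so zero vortex regions); near-substrate settling windows that are
an order of magnitude longer between ridges than over flat substrate;
and calibrated in-cavity speeds (up to 6 mm/s).

They do not reproduce vortex shedding from ridge trailing edges or any
advective exchange through the cavity mouths: the single $\sin^2$ cell
has zero normal flow across all of its boundaries, including the open
mouth, by construction. Consequently larvae are never *advected* into
cavities — they can only swim in — and the simulated settlement
enhancement on 2.5 mm ridges is not reproduced: all three substrates
settle 10.2-10.6% of the lattice (flat 10.6%, 2.5 mm ridges 10.2%,
0.25 mm ridges 10.5%; each within 5 percentage points of the benchmark
values 7.6 / 14.2 / 7.4% from CFD-driven simulations of this system, but without the ridged > flat ordering).
Instrumented runs show why: on flat substrates every larva that ever
touches the wall settles — settlement is limited entirely by transport
through the oscillatory shear layer, which rotates swimmers (Jeffery
tumbling) and expels most of them upward — and the sealed cavity adds no
transport path. Reproducing the enhancement would need mouth-crossing
vertical velocities (shed vortices), i.e. a generator beyond the
single-cell streamfunction family; a traveling-cell extension is the
natural next step but is out of scope here.

## Numerical choices and degenerate inputs

* Explicit Euler conserves a circular orbit radius only to
  O($\omega\,dt$) per revolution (growth $e^{\pi\omega dt}$); the tests
  use rotation rates where that stays under 1%.
* Threshold crossings (settling and active windows) are located by linear
  interpolation between samples; all-below series give one full-period
  window (fraction 1), all-above give none.
* Blank frames detect zero particles (empty table, not an error); runs
  without settlers are dropped from per-run percentage tables with a
  warning, never imputed as zeros.
* Archives store all numbers as shortest-exact decimal strings
  (17 significant digits), so write/read round-trips are bitwise exact.
* Gradient stencils fall back to first-order only where a single fluid
  neighbour exists; gradients at solid nodes are `NA`.

## Problem sizes

The test suite exercises full-resolution physics on reduced domains (one
to two ridge pitches, 4-6 mm of height, 4-16 time slices) and reduced
lattices (tens to ~2,000 agents); the settlement comparison in the test
suite uses a 1,920-agent lattice (15 x 16 x 8 thinning of the default
axes). `scripts/acceptance.R` runs the full 19,200-agent lattice for all
three substrates, which completes in well under a minute per substrate.
`run_pipeline(scale =)` thins each lattice axis by `scale^(1/3)` for
smoke runs.
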