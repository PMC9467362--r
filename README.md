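# larvaflow

Coral larvae are slow swimmers (~3 mm/s) trying to settle out of
wave-driven flows an order of magnitude faster. Millimeter-scale substrate
ridges reshape the benthic boundary layer — introducing recirculation
between ridges and long near-surface windows of low speed — and that purely
hydrodynamic change can decide whether settlement happens at all.
**larvaflow** implements the full computational chain for studying this
system in R:

* **Synthetic oscillatory flow fields** — the exact oscillatory
  Stokes-layer solution over flat substrates, and a divergence-free
  streamfunction composition with recirculating cavity cells over
  rectangular ridges (2.5 mm tall, 7.5 mm apart by default), all in
  mm/s units with a sinusoidal free stream (peak 45 mm/s, period 5.5 s).
* **Particle tracking velocimetry** — synthetic tracer imagery
  (31 um/px, 90 fps), detection, greedy nearest-neighbour linking, and
  40-frame phase-averaged velocity gridding.
* **Flow analysis** — velocity gradients, the Q-criterion
  Q = (|Omega|^2 − |S|^2)/2 with its SD-based threshold, labeled vortex
  regions, near-substrate band speeds and settling windows
  (|U| < u_ell + 1 SD = 4 mm/s within 1.5 mm of the surface).
* **Agent-based settlement simulation** — 19,200 ellipsoidal swimmers
  (Jeffery rotation thetadot = omega_z/2 + alpha g.(S n), swimming speed
  u_ell along the major axis) integrated at dt = 0.01 s in a compiled
  loop, with a speed-gated settlement rule at surface contact.
* **Settlement statistics** — arcsine-square-root transforms, one/two-way
  fixed-effects ANOVA with Tukey HSD, ridge-base distance geometry, and
  the settlement-by-Q recast.

Everything is tibble-first: simulations, tracks, windows and ANOVA
results `tidy()`/`glance()` into data frames and `autoplot()` into
ggplots.

## A worked example

```r
library(larvaflow)

# flow over 2.5 mm ridges, 7.5 mm apart, driven at 45 mm/s peak / 5.5 s
ridged <- ridged_cavity_field()
sim    <- run_simulation(ridged)      # 19,200-agent lattice, dt = 0.01 s
sim
#> <settlement_sim> ridged substrate, 19200 agents: 10.2% settled,
#>   83.5% exited, 6.2% unresolved

# near-substrate flow between the ridges: settling windows
grid <- sample_field(ridged, dx = 0.05, nt = 64,
                     xlim = c(0, 10), ylim = c(0, 8))
settling_windows(band_speed(grid, band_height = 1.5, cavity_only = TRUE))
#> <settling_windows> 1 window(s), total 5.500 s (100.0% of the 5.5 s
#>   period), threshold 4 mm/s

# vortex identification: one supra-threshold region per cavity at peak flow
qa <- q_analysis(grid)
vortex_regions(qa, t = 5.5 / 4)
#> # A tibble: 1 × 6
#>       t region  area     x     y q_max
#>   <dbl>  <int> <int> <dbl> <dbl> <dbl>
#> 1  1.38      1  1187  6.25  1.25  25.1
```

The settlement percentage is the fraction of the deterministic
30 x 32 x 20 lattice (positions x orientations x release phases) that
contacts a surface while moving slower than the 4 mm/s gate; `exited`
agents left the open top, and `unresolved` ones (the purely horizontal
orientations) were still swimming at 120 s. For the flat substrate the
same pipeline gives 10.6% settled; between the ridges the mean band speed
never exceeds the larval threshold, so the settling window spans the full
period, versus two short windows (0.47 s total) over flat substrate.

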