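---
title: "A whole-cell model of actin-microtubule crosstalk driven migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A whole-cell model of actin-microtubule crosstalk driven migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmigrate)
```

## The model

`mtmigrate` simulates a single mesenchymal cell migrating on a 2D substrate.
The cell is built from four mechanically coupled components:

* **Membrane and nucleus**: closed bead-spring loops (100 and 50 beads by
  default) with harmonic stretching along bonds, a discrete worm-like-chain
  bending energy `E = kappa/(2 l0) sum_i (theta_i - theta0)^2` over the
  signed turning angles, and an area-elasticity energy
  `E = k_area (A - A0)^2 / (2 A0)` applied through the exact shoelace-area
  gradient. The area term represents the incompressibility of the enclosed
  cytoplasm and nucleoplasm; without it the contraction machinery below
  shrinks the cell without bound, which no real cell does.
* **Microtubules (MTs)**: `Nmt` bead-spring filaments (bead spacing
  `sigma_mt` = 0.5 um) whose minus ends are pinned to a mobile centrosome.
  Plus ends follow two-state dynamic instability: growth at `vg`, shrinkage
  at `vs`, catastrophe at rate `fc` and rescue at rate `fr`. Filaments grow
  by appending beads (a sub-bead accumulator carries fractional growth) and
  shrink by removing them; a filament that shrinks to its seed bead
  re-nucleates in a fresh random direction, so the filament count is
  conserved.
* **Dynein motors**: a fixed random subset of membrane and nucleus beads
  (densities `rho_cortex`, `rho_nuc`) hosts motors that attach to a passing
  filament within `r_capture` at rate `k_on`, walk toward the minus end at
  `v_motor`, pull through a zero-rest-length spring (`k_motor`), and detach
  at rate `k_off` or when the spring load exceeds `f_stall`. Minus-end-ward
  walking pulls filaments, and through them the centrosome, toward the
  anchoring cortex.
* **Steric interactions**: a purely repulsive truncated-shifted
  Lennard-Jones (WCA) force between MT beads and both loops, between the
  loops, among non-bonded membrane beads, between the centrosome and the
  nucleus, and between every bead and the confining walls or pillars.
  MT-MT pairs are excluded (filaments may bundle and cross).

The centrosome is not integrated as a free bead: each filament's minus-end
force is transmitted to it, it moves with its own (large) drag, and the
minus ends are re-pinned to it after every step. All beads follow
overdamped forward-Euler dynamics `x(t+dt) = x(t) + dt (F/gamma + v_active)`
with no thermal noise: all stochasticity enters through dynamic instability
and motor kinetics.

### The crosstalk rules

The cell moves only because MT tips talk to the actomyosin cortex:

* **Protrusion**: each membrane bead counts growing plus ends within
  `r_signal` (1.12 um, twice the steric contact range `1.12 sigma_mt`); it
  acquires an outward active velocity `v_prot0 * min(n_grow, n_sat)`.
* **Contraction**: shrinking plus ends deposit signal into a per-bead
  cortical trace at rate `contract_deposit` while inside `r_signal`; the
  trace decays with time constant `contract_tau` and exerts an inward force
  `f_contr0 * min(trace, n_sat_contr)`. Setting `contract_tau = 0` switches
  to instantaneous shrink-tip counts. A retraction deposits only while its
  filament retains at least `deposit_min_contact` (5 um) of contour within
  the cortical contact band: a retracting gliding arc sweeps contraction
  along the cortex it lies on, whereas a tip that merely recedes radially
  from the membrane does not trigger cortical myosin. The contraction
  response saturates at a lower level than protrusion (`n_sat_contr` = 10 vs
  `n_sat` = 20), so a tip-crowded front stays protrusive even though front
  catastrophes also deposit signal there.
* **Coupling**: each nucleus bead is linked by a Hookean spring (`k_couple`,
  rest `rest_couple`) to the membrane bead at the index-proportional
  position, fixed at construction. The springs transmit front protrusion to
  the nucleus and drag the rear forward; index-proportional (rather than
  nearest-neighbour) pairing prevents the nucleus from spinning freely,
  which would destroy this rear drag.

Contraction is deliberately a *memory trace* by default. A retraction's tip
spends only seconds near any one bead, so instantaneous counts carry almost
no contraction signal anywhere; the trace lets every qualifying retraction
leave a persisting imprint along the cortical regions it traverses. This is
the model's implementation of retraction-triggered myosin activation
spreading along the cortex.

### Polarity regimes

With the defaults, the model self-organizes into the regimes the science
calls for:

* `lmt_target = 9.3` um (regular MTs, two-thirds of the cell diameter):
  tips reach only the membrane regions near the centrosome; the nucleus
  shadows the rear. Protrusion concentrates ahead of the centrosome, the
  rear follows through the coupling, and the cell migrates ballistically
  with the **centrosome ahead** of the nucleus (polarity angle theta < 90
  degrees).
* `lmt_target = 16` um (long MTs, larger than the cell diameter): filaments
  glide along the membrane and nucleus to the far side of the cell and tips
  spread over most of the cortex. Migration remains directed, but in this
  implementation the centrosome still travels ahead of the nucleus in most
  runs: the intended inversion (centrosome behind, theta > 90 degrees,
  driven by distal tip accumulation plus rear contraction) appears only
  transiently. See "Known limitations".
* `lmt_target = 3` um: tips rarely hold membrane contact; polarization is
  weak and motion is closer to a random walk with short persistence length.
* `Nmt = 200` with long MTs: growing tips occupy all cortical sectors, the
  polarity axis wanders, and the MSD exponent drops well below 2
  (super-diffusive).

## Growth against obstacles: steering, stalling, pushing

Discrete bead appending needs care at walls. Three rules, all reconstructed
mechanisms documented here as the package's own design choices:

* **Steered insertion**: a new bead is placed `sigma_mt` beyond the tip
  along the terminal tangent if that site is sterically free (farther than
  `0.7 sigma_mt` from any foreign bead, wall or pillar). If it is blocked,
  rotated candidate directions up to +-90 degrees (in 15-degree steps,
  preferring the side with more clearance) are tried. This is how a tip
  complex behaves at an obstacle: subunits add where there is space, and the
  filament glides along the wall. Without it, tips stall head-on, realized
  filament lengths saturate far below `lmt_target`, and gliding to the
  distal membrane never happens.
* **Polymerization pressing**: if every direction is blocked, growth stalls
  (the accumulator holds just below one bead) and the terminal bond carries
  a force dipole `f_poly` (2 pN, within the measured 1-4 pN stall force of
  polymerizing MTs). The filament keeps pushing, buckles, and escapes.
* **Buckling**: compressed filaments buckle at the Euler threshold
  `pi^2 kappa_mt / L^2` (about 0.05 pN for a 10-um filament at the default
  `kappa_mt = 0.5` pN um^2), so sustained pushing is bounded and gliding
  emerges rather than rigid jamming.

## Numerical choices

* `dt = 0.005` s with a hard guard: any bead displacement above
  `0.5 sigma_mt` in one step, or any bead inside a wall or pillar at a
  recording time, aborts the run loudly rather than integrating garbage.
* Stretch springs obey `ks/gamma * dt < 0.1` (validated at construction).
  Discrete bending has a much stiffer top eigenvalue (`~16 kappa / (gamma
  l0^3)`); a stability bound `dt * 16 kappa/(gamma l0^3) < 1` is enforced
  instead, and the displacement guard catches anything that slips through.
* The WCA force is exact over the resolved contact range but saturates at
  `1.5 * 24 eps/sigma` (reached just below `r = sigma`): an explicit
  overdamped scheme cannot follow the diverging LJ-13 stiffness, and a
  bounded deep-overlap branch turns would-be numerical explosions into
  bounded, self-resolving overlaps. Separations below `0.1 sigma` are
  counted and reported as overlap warnings.
* The bending gradient's `1/|bond|` factors are floored at `0.3 l0` so a
  fully compressed bond (bonded neighbours carry no steric core) cannot
  produce divergent forces.
* Drags are calibrated for integrability under aster crowding:
  `gamma_mem = gamma_nuc = 5` (cortex/adhesion and chromatin friction),
  `gamma_mt = 2`, `gamma_cen = 20` (the centrosome carries the summed
  minus-end reaction of the whole aster). Active velocities are imposed
  directly, so these drags set force-response times, not motility scales.
* One RNG stream per subsystem (initialization, filaments, motors), seeded
  from `seed`, so toggling motors does not shift filament randomness. A
  fixed seed gives bit-identical runs; snapshots serialize the stream
  states, and a resumed run reproduces an uninterrupted one bit-exactly.

## Parameters

Printed constants (`Rcell = 7` um, `Rnuc = 3` um, `sigma_mt = 0.5` um,
`fr = 0.04`/s, the studied `lmt`/`Nmt` values, device geometries, the
`alpha > 1.7 & dphi < 0.9` rule, 300-s windows, the 5-um entry depth) are
taken as given; everything else is a reconstructed default calibrated once
to reproduce the qualitative regimes above and then frozen. The full
registry with units and provenance tags:

```{r}
paramProvenance(cellParams())
```

The catastrophe rate is never set directly: `catastropheRate()` solves
`vg*vs/(fc*vs - fr*vg) = lmt_target`, the stationary mean of the
(exponential) length distribution of the two-state filament, so mean length
is the controlled quantity. The growth and shrink speeds default to
`vg = 0.25`, `vs = 0.5` um/s (15 and 30 um/min, within the measured
interphase range); slower speeds would make the length process relax more
slowly than the simulated trajectories are long, so the long-MT condition
would never actually be realized during a run.

## Confinement and chemotaxis

`obstaclePark()` builds a square pillar lattice (radius `Robs`, pitch
`spacing`); `yJunction()` a feeder chamber, funnel, stem and two arms at
+-45 degrees with independent widths; `multiChannel()` a chamber pressed
against a perforated plate whose parallel pores (chosen widths, thin septa)
open side by side, so the arriving cell touches several mouths at once. Walls are finite segments repelling
beads through the same WCA family, onset at the surface. In channel devices
a uniform forward velocity `v_chemo` on the membrane beads mimics the
chemotactic drive; it is zero in free space and obstacle parks. A cell has
entered a channel when every membrane bead is at least 5 um past the
channel mouth and laterally inside the lane.

## The analysis layer

All estimators are pure functions of the recorded track (10-s cadence by
default):

* `msd()` / `fitMsdExponent()`: time-averaged MSD and its log-log slope.
* `localAlpha()`: non-overlapping 300-s windows; per window the local MSD is
  fitted over lags from the recording cadence to a third of the window, the
  circular standard deviation `dphi = sqrt(-2 log Rbar)` of frame-to-frame
  velocity angles is computed, and the window is `directed` iff
  `alpha > 1.7` and `dphi < 0.9`.
* `persistenceLength()`: tangent-correlation estimator, `<cos dtheta(s)>`
  fitted to `exp(-s/Lp)` over contour distance; a non-decaying correlation
  returns the path length flagged as a lower bound.
* `polarityAngle()`: angle between the centroid velocity (central
  differences, speed floor 1e-3 um/s) and the nucleus-to-centrosome axis.
* `morphology()`: shoelace area, area ratio to `pi Rcell^2`, gyration-tensor
  aspect ratio `sqrt(lambda1/lambda2)`, nucleus and centrosome offsets from
  the centroid.
* `channelChoiceStats()`: per-channel entry fractions (censored runs
  reported separately) and entry-time statistics.

`syntheticTrack()` generates ballistic, Brownian, worm-like-chain and
piecewise fixtures with known exponents and persistence lengths; the test
suite validates every estimator against them and against closed forms.

## What the synthetic data do and do not show

The generator-based tests demonstrate that the estimators recover known
exponents, persistence lengths and labels from idealized tracks, and that
the simulator reproduces the intended self-organized regimes under the
registered defaults. They do not show that the reconstructed constants are
quantitatively those of any real cell type: absolute speeds, times and
forces here are calibrated to regimes, not measured. Scaled-down problem
sizes are used throughout the tests (3000-s trajectories, 5 replicates per
condition, 6-8 replicates per device geometry); the regime statements are
about majorities and orderings, which are stable at these sizes, not about
precise fractions.

## Known limitations

* The long-MT, centrosome-posterior polarity state is under-represented:
  with the reconstructed force laws the distal protrusion lobe and the rear
  contraction never dominate the proximal protrusion from freshly nucleated
  filaments for long, so the polarity-angle distribution for
  `lmt_target = 16` keeps most of its mass below 90 degrees instead of
  above. Configurations that do flip it (ungated contraction deposits with
  shared saturation) destroy the regular-MT ballistic regime instead; with
  one global parameter set the package keeps the regular-MT regime
  faithful. The angular tip distributions themselves (distal accumulation
  for long filaments) do reproduce.
* Strictly 2D; no explicit actin network, focal adhesions, or retrograde
  flow; MT tips are not mechanically anchored to the cortex.
* All filaments share one stability parameter set; asymmetric per-filament
  stability (front-stabilized MTs) is out of scope.
* The membrane perimeter is nearly fixed (stiff bonds, fixed bead count);
  large spread-area changes on stiff substrates are not representable.
* Filaments may overlap freely (no MT-MT sterics), so bundles are
  idealized.
* Very long runs eventually show the ballistic-to-diffusive crossover only
  if polarity flips occur; the default trajectories are within the
  persistent regime.
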