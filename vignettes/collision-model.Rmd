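---
title: "A two-phase model of animal-vehicle collision probability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-phase model of animal-vehicle collision probability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strikepath)
```

## The model

`strikepath` models the final seconds of an encounter between an animal and a
vehicle approaching on a fixed, linear trajectory at constant speed. The
encounter is resolved in two phases.

**Phase one — can the animal clear the trajectory in time?** At the moment of
escape initiation the animal sits a lateral distance $D_{min}$ from the
nearest edge of the vehicle's swept trajectory. To be safe it must move its
entire body length $l$ past that edge, a distance

$$D_{safe} = D_{min} + l.$$

Escaping at speed $S_a$ along an angle $\theta$ (measured from the approach
axis: $0^\circ$ directly toward the vehicle, $180^\circ$ directly away,
$90^\circ$ perpendicular), only the perpendicular velocity component moves it
toward the edge, and it first loses a sensory-motor delay $\delta$
reorienting, so the time it needs is

$$T_a = \frac{D_{safe}}{\sin\theta \cdot S_a} + \delta.$$

The time it has is set by the flight-initiation distance $D_{FID}$ (its
distance to the vehicle when escape begins) and the closing speed along the
approach axis, which the escape itself modulates:

$$T_v = \frac{D_{FID}}{S_v + \cos\theta \cdot S_a}.$$

If $T_a < T_v$ the animal clears the trajectory and the collision probability
is exactly zero. The tie $T_a = T_v$ counts as collision-possible, compared
at full floating precision with no tolerance band. A non-escaping animal
($S_a = 0$, so $T_a = \infty$) is handled by an infinity sentinel that
compares greater than any finite $T_v$, keeping the predicate total.

**Phase two — where in the trajectory, and what does it hit?** The trajectory
is a 2-D plane of width $D_{width}$ and height $D_{height}$, the vehicle's
frontal extents. The animal starts at

$$D_{initial} = D_{width} - D_{min}$$

and drifts while the vehicle covers the remaining distance:

$$D_{collision} = D_{initial} + \cos\theta \cdot S_a \cdot T_v.$$

$D_{collision}$ is the midpoint of the animal's body on the trajectory's
x-axis at vehicle arrival. The collision probability is the fraction of the
body-length-wide, full-height *collision window*
$[D_{collision} - l/2,\, D_{collision} + l/2]$ covered by the vehicle's
frontal surface $A_{front}$:

$$P_{collision} = \frac{1}{D_{height} \times l}
  \int_{D_{collision} - l/2}^{D_{collision} + l/2} A_{front},$$

under the assumption that the animal may be at any altitude within the
window. $A_{front}$ is a binary pixel mask; the integral is the occupied
fraction of the window's pixel columns.

### Assumptions

1. The vehicle approaches directly (the animal is inside its trajectory);
   [threshold_angle()] quantifies when that holds, as
   $\theta_{threshold} = \sin^{-1}((D_{half} + l)/D_{mid})$.
2. Vehicle trajectory and speed are constant.
3. The animal's escape trajectory and speed are constant after initiation;
   if phase one reports an escape, the probability is exactly zero.
4. Altitude within the trajectory is uniform-random (the $D_{height}$
   denominator).
5. Under a light treatment, toward-angles pair with baseline
   flight-initiation distances and away-angles with light-extended ones.

### A deliberate asymmetry in the published equations

The clearance term of $T_a$ uses $\sin\theta$ (perpendicular progress), while
the drift term of $D_{collision}$ uses $\cos\theta$ for motion across the
same width axis. We implement the model exactly as published and expose
`eq5_term = "sin"` as a sensitivity switch (default `"cos"`); reproducing the
published behavior takes precedence over kinematic reinterpretation. The same
policy applies at the trajectory edges: a window that drifts past *either*
edge is credited only for its in-bounds columns, so the probability decays
smoothly to zero on both sides.

## Discretization of the window integral

All geometry is done in whole pixels, mirroring the digitization of a
to-scale schematic:

* the meters-per-pixel scale is `width_m / ncol(mask)`; columns are
  half-open intervals $[i \cdot s, (i+1) \cdot s)$;
* the body length maps to `round(l / scale)` columns, floored at one (for
  the reference application, 1.15 m on a 1031-column, 14.35-m grid is 83
  pixels);
* $D_{collision}$ maps to a center pixel by nearest-pixel rounding; the
  window is exactly that many columns centered there, left-biased by one
  column when the count is even;
* grayscale input masks are binarized at a configurable threshold
  (default: intensity < 0.5 is vehicle surface); anti-aliased edges are
  thresholded, not counted fractionally.

The vectorized integral uses cumulative column sums and is tested for exact
equality against a naive per-pixel loop, plus mirror-symmetry (to one-pixel
tolerance) and monotonicity under adding occupied pixels.

## Behavioral scenarios

Escape angles are a two-component uniform mixture: "toward"
$U(0.01^\circ, 89.99^\circ)$ and "away" $U(90.01^\circ, 179.99^\circ)$ —
exact $0/90/180$ are excluded by construction. The away probability is the
scenario's behavioral signature: 0.42 with no light, 0.65 under a blue
(483 nm) light, 0.11 under a red (631 nm) light, from Canada-goose
experiments and pilot-reported behavioral frequencies.

Flight-initiation distance is Normal(56.2 m, 16.5 m) at baseline, resampled
until non-negative (zero sits 3.4 SD below the mean, so the rejection rate is
about 0.03% and the induced mean shift is ~0.02 m). Under a light, an
away-bound animal instead draws $U(0,\, S_v \beta)$, where $\beta$ (seconds)
is the temporal benefit of detecting the lit aircraft earlier and $S_v \beta$
is the corresponding maximum alert distance. Two points here were genuinely
open and are resolved as configuration defaults:

* the alert-distance bound multiplies $\beta$ by the *vehicle* speed (the
  prose definition of maximum alert distance); `beta_speed = "Sa"` switches
  to the animal-speed variant;
* toward-bound draws under a light keep the baseline distribution and get no
  $\beta$ benefit (the attraction-response pairing, Assumption 5).

## The parameter sweep

The reference grid iterates escape speed (1–17 m/s, step 2), delay (0–1 s,
step 0.1), distance to safety (10 even values, 1–14.35 m), approach speed
(15 even values, 70.47–270.97 m/s), light benefit (10 even values,
0.5–8.5 s) and the three scenarios, at 500 iterations per cell:
222,750,000 predictions. $\beta$ is iterated for the no-light scenario too —
it has no effect there, but it keeps every scenario's cell count equal, and
the enumeration reproduces the full published prediction count exactly.

Each cell owns an independent random stream seeded by a Lehmer-style mix of
the master seed and the cell index, so sweeps are reproducible, cells are
order-insensitive, and any cell can be re-run alone from the seed recorded in
the output. The per-cell draw order is fixed and documented in
`simulate_cell()`.

"Number of collisions per cell" is ambiguous when phase two yields a
probability rather than an outcome, so both readings are provided:
*expectation* mode (default) accumulates the phase-two probability directly;
*bernoulli* mode draws a binary outcome from it. The two agree in
expectation, which is tested within Monte-Carlo error.

Aggregation is streamed: per-cell means (and the grand mean ± SD across cell
means, per scenario), marginal curves over each manipulated variable, and
behavioral curves binned to 0.1 degree / 0.1 m over the sampled angle and
flight-initiation distance (half-open bins, reported at midpoints; the
streaming path and the records-based aggregator share one bin definition and
are tested for exact agreement). Outputs are plain CSV (comma, period
decimal, UTF-8) written with byte-stable formatting, plus a JSON manifest
with the seed, grid, and a grid hash.

### Problem sizes

Desk-scale runs in the test suite and the acceptance script use the full
grid at 100 iterations per cell (44.55 million predictions, about a minute
on one core with the vectorized kernel) and a one-scenario, 50-iteration
stream (7.4 million predictions) to exercise the full enumeration path; the
full 500-iteration sweep is a routine overnight-scale run of the same code.

## The synthetic silhouette: what it emulates and what it does not

`silhouette_spec_737()` is a parametric, deterministic stand-in for a
digitized frontal schematic of a Boeing-737-class airliner, built once from
published front-view dimensions: a 3.76-m fuselage disk, two 1.03-m-radius
engine nacelles 4.7 m off-center, a wing band, a horizontal-stabilizer band
whose 14.35-m span sets the trajectory width, and a vertical tail to the
12.5-m tail height. Its column-occupancy profile is trimodal
(engine–fuselage–engine), and with behavior held fixed the collision
probability as a function of $D_{min}$ reproduces that profile exactly.

It is *not* the digitized schematic used in the original application, and
two consequences matter when interpreting sweep output:

* absolute probabilities scale with mask density. The synthetic mask fills
  ~18% of the trajectory plane, so grand means are correspondingly lower
  than those obtained from a denser digitized drawing; scenario orderings,
  monotonicities and relative light benefits are unaffected.
* the vertical tail makes the fuselage column about 3.7 times taller than
  the engine columns. After marginalizing over behavior, the drift term
  $\cos\theta \cdot S_a \cdot T_v$ (several meters at the grid's speeds)
  smears the position-at-arrival distribution, and the weak engine peaks can
  be absorbed into the fuselage peak's shoulders: the marginal
  $D_{min}$ curve is then unimodal for scenarios dominated by long
  flight-initiation distances, and trimodal where drift is small (e.g. the
  red-light scenario, whose away draws carry very short light-bounded
  distances). A mask with engine columns comparable in height to its
  fuselage column — as in a gear-down airport-planning drawing with pylons
  and wing roots filled — keeps all three marginal peaks. Every local
  maximum the marginal curve does have coincides with an occupancy-profile
  peak, and that correspondence is what the test suite asserts in general.

Passing tests on the synthetic mask therefore validate the geometry engine
and the direction and structure of the behavioral effects, not the absolute
probability level of any particular aircraft.

## Known limitations

* No risk-assessment delay before escape initiation is modeled, so absolute
  probabilities are conservative for animals that hesitate after detection.
* Trajectories are straight and speeds constant for both parties; no
  evasive re-orientation, stopping, or vehicle maneuvering.
* Altitude is uniform-random; no climb/dive kinematics.
* No aerodynamic effects (engine inflow, wake) around the airframe.
* The white-light case is not parameterized: no avoidance-probability data
  exist for it.
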