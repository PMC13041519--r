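# strikepath

Collisions between wildlife and vehicles — bird strikes on aircraft in
particular — hinge on what the animal does in the final seconds of the
approach. `strikepath` implements a two-phase probabilistic model of that
moment for ecologists and wildlife-hazard analysts: it predicts whether an
escape response clears the vehicle's swept trajectory in time and, when it
does not, how likely the animal is to actually hit the vehicle given where
it ends up relative to the vehicle's frontal silhouette. The bundled
application is a Canada goose (*Branta canadensis*) in the path of a
Boeing-737-class aircraft, with and without onboard lights tuned to the
avian visual system.

## The model

**Phase one (kinematics).** The animal, at lateral distance `Dmin` from the
nearest trajectory edge, must clear `Dsafe = Dmin + l` (its body length `l`
included). Escaping at speed `Sa` along angle `θ` (0° = toward the vehicle,
180° = away) after a sensory-motor delay `δ`, it needs

    Ta = Dsafe / (sin θ · Sa) + δ

while the vehicle, at flight-initiation distance `DFID` and speed `Sv`,
arrives in

    Tv = DFID / (Sv + cos θ · Sa).

`Ta < Tv` is a clean escape (probability exactly 0); `Ta ≥ Tv` sends the
encounter to phase two.

**Phase two (geometry).** The animal starts at `Dinitial = Dwidth − Dmin`
on the trajectory plane and drifts to
`Dcollision = Dinitial + cos θ · Sa · Tv`. The collision probability is the
occupied fraction of the body-length-wide, full-height *collision window* of
the vehicle's binary frontal silhouette:

    Pcollision = 1 / (Dheight · l) ∫ Afront  over [Dcollision − l/2, Dcollision + l/2]

computed in whole pixels on a scaled mask.

Escape angle and flight-initiation distance are stochastic: a toward/away
uniform-mixture angle (away probability 0.42 with no light, 0.65 blue,
0.11 red) and Normal(56.2, 16.5) m baseline distances, replaced for
away-bound animals under a light by `U(0, Sv·β)`, where `β` is the light's
temporal detection benefit. A seeded Monte-Carlo engine sweeps escape speed,
delay, position, approach speed, `β` and scenario (222,750,000 predictions
at the default 500 iterations/cell) with streaming aggregation.

## Worked example

```r
library(strikepath)

# synthetic 737-like frontal silhouette, 1031 columns over 14.35 m
sil <- generate_silhouette(silhouette_spec_737(), resolution = 1031)
sil
#> Frontal silhouette: 898 x 1031 pixels
#>   extent: 14.350 m wide x 12.499 m high (0.013919 m/pixel)
#>   occupied: 162984 pixels = 31.574 m^2 (17.6% of trajectory plane)

goose <- animal_params(l = 1.15, Sa = 5, delta = 0.2, d_fid = 56.2,
                       theta = 45, d_min = 7)
b737  <- vehicle_params(Sv = 70.47, silhouette = sil)
(p1 <- phase_one(goose, b737))
#> Phase one: Ta = 2.505 s, Tv = 0.7594 s -> collision possible
collision_probability(goose, b737, p1)
#> Phase two: d_collision = 10.035 m, p_collision = 0.0635
```

The goose needs 2.5 s to clear the trajectory but has only 0.76 s, so a
collision is possible; drifting to x = 10.0 m puts its collision window in a
sparse region between fuselage and engine, an 6.4% chance of contact.

A sweep of the full default grid at 50 iterations per cell:

```r
g  <- build_grid(list(iterations = 50L))
sw <- run_sweep(g, sil, seed = 1)
sw
#> Monte-Carlo sweep: 22,275,000 predictions over 445,500 cells
#>   mode expectation, seed 1, grid hash 0497777597
#> Grand means (across cell means):
#>   none  0.1516 +/- 0.0831 (148500 cells)
#>   blue  0.0993 +/- 0.0692 (148500 cells)
#>   red   0.1472 +/- 0.0945 (148500 cells)
```

Averaged over every parameter combination, a goose inside the trajectory of
this synthetic silhouette collides ~15% of the time with no light; a blue
onboard light (which promotes escaping away and earlier) cuts that by about
a third, a red light only slightly. Absolute levels scale with the mask's
density — a denser digitized schematic gives proportionally higher means —
while the orderings and parameter effects are mask-robust (see the methods
vignette). `marginal_curves()`, `sw$angle_curve` and `sw$fid_curve` expose
the per-variable and behavioral response curves; `write_outputs(sw, dir)`
writes everything as CSV plus a JSON manifest.

A command-line interface wraps the same functions:

```sh
Rscript exec/strikepath generate-silhouette --out mask.txt
Rscript exec/strikepath run-sweep --out out/ --seed 1 --iterations 50
Rscript exec/strikepath aggregate --records out/records.csv --by angle --out angle.csv
```

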