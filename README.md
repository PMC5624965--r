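# woodknock

Models for two periodic-and-transient motions of large woodpeckers, for
bioacousticians and ornithologists reasoning about drumming, *Campephilus*
double knocks, and cruising flap rates.

## The models

**Drumming as a vibro-impact oscillator.** A perched woodpecker anchors with
feet and tail; tension through neck and body is a restoring force that
accelerates the head toward the wood. The displacement *x* (positive toward
the wood) obeys a damped, forced harmonic oscillator

    x'' + p x' + q x = R(t)

with a rigid wall at *x = x₀* where the bill strikes and rebounds with a
coefficient of restitution: *x' → −α x'*, α < 1. The reference configuration
is *p* = 0.2, *q* = 0.3, *α* = 0.8, *x₀* = 0.2 (dimensionless throughout).
Two forcings are studied: a periodic drive, sin *t* on the open window
(2π, 20π), which produces an onset transient, a steady near-periodic impact
train while forcing is on, and a few decaying impacts after turn-off — the
drum roll; and an impulsive Gaussian pulse, exp[−(*t* − 20π)²], a single
body thrust whose response is only the short decaying transient — the
hypothesised mechanism of the *Campephilus* double knock.

**Flap rate from vortex shedding.** The intrinsic cruising flap rate is

    f = St · U / (b · sin(33.5 · b^−0.24))

with Strouhal number St = 0.25 for intermittent flight, flight speed *U*
(m/s), wingspan *b* (m), and the amplitude angle 33.5·b^−0.24 in degrees.
For birds that pause with wings folded mid-upstroke, the raw rate f̃
(flaps per elapsed second) relates to the intrinsic rate by the duty
fraction f̃/f = 0.714 (Pileated Woodpecker).

The package also ships seeded synthetic-data generators (knock trains,
rendered knock audio with onset detection, frame-indexed flap sequences)
so every analysis stage can be validated against known ground truth.

## Worked example

```r
library(woodknock)

cfg <- fig2_preset("fig2-impulsive")
traj <- simulate_oscillator(cfg$params, cfg$forcing, cfg$ic, cfg$settings)
traj$impacts
#>       time  speed_in speed_out
#> 1 62.42925 0.4420276 0.3536221
#> 2 63.19346 0.3391852 0.2713482
#> 3 64.08097 0.1550044 0.1240035

train <- extract_impact_train(traj)
classify_regime(summarize_cadence(train, cfg$forcing))
#> [1] "transient"

flap_report()
#>        species predicted_hz observed_hz percent_diff
#> 1 ivory-billed     8.377513    9.254803     9.405405
#> 2     pileated     5.702525    5.200000     9.615385
```

A single body thrust yields three impacts of strictly decreasing speed —
a double knock (the third rebound is weak enough to be inaudible at a
distance; see `count_audible_knocks()`). The flap table compares the
Strouhal prediction against the observed cruising rates: 8.38 Hz predicted
vs 9.25 Hz video-derived for the Ivory-billed Woodpecker (9.4% apart),
5.70 Hz predicted vs 5.20 Hz observed for the Pileated (9.6% apart).

The `analysis/` scripts run the full workflow and write tables under
`results/`: `01_fig2_oscillator.R` (trajectories and impact trains for both
forcing regimes), `02_knock_cadence.R` (cadence statistics, regime
classification, audible-knock sweep), `03_flap_rates.R` (flap-rate report
and frame conversions), `04_synthetic_recovery.R` (generate → render →
detect round trips and flap-rate recovery).

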