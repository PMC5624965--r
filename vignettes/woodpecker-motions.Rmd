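---
title: "Impact-oscillator drumming and Strouhal flap rates: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Impact-oscillator drumming and Strouhal flap rates: models and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woodknock)
```

## The drumming model

A drumming woodpecker is modelled as a damped harmonic oscillator with a
one-sided rigid wall. The displacement $x$ of the head/bill (positive
toward the wood) obeys

$$\ddot x + p\,\dot x + q\,x = R(t),$$

where $p$ is a damping rate, $q$ sets the natural frequency
($\omega_0 = \sqrt q$), and $R(t)$ is the muscular forcing. When $x$
reaches the wall at $x_0$ the bill strikes the wood and rebounds with a
coefficient of restitution $\alpha$:

$$\dot x \to -\alpha\,\dot x, \qquad \alpha < 1.$$

Everything is dimensionless: the model is an illustration of the two
qualitative regimes, not a dimensional mechanics of a real bill, and no
estimation of $p$, $q$, $\alpha$ from recordings is attempted. The
reference configuration used throughout is $p = 0.2$, $q = 0.3$,
$\alpha = 0.8$, $x_0 = 0.2$ (`oscillator_params()` defaults), with two
forcings:

* **periodic** — $R(t) = \sin t$ on the open window $2\pi < t < 20\pi$,
  zero outside (`forcing_periodic()`). Driven at the resonant timescale,
  the response is an onset transient, then a steady train of one impact
  per forcing cycle (intervals $\approx 2\pi$), then a few decaying
  impacts after turn-off: drumming, with the turn-off transient the bird's
  final weaker blows.
* **impulsive** — $R(t) = \exp[-(t - 20\pi)^2]$ (`forcing_impulsive()`),
  a single thrust of the body. The response is only the decaying
  transient; with the reference parameters it contains three impacts of
  strictly decreasing speed. This is the double-knock hypothesis: a
  *Campephilus* double knock is one thrust plus one (audible) rebound,
  not two deliberate blows.

### Initial conditions and span

The reproduction of the two regimes needs a start state, which the
qualitative description leaves open. We use rest at the origin at
$t = 0$ — the only parameter-free choice, and consistent with the forcing
being zero before $2\pi$. The integration span is $[0, 30\pi]$: the
periodic window plus enough tail for the turn-off transient to die out
(the Gaussian pulse is negligible before $20\pi - 5$).

### Event handling, chattering, and sticking

Between impacts the system is integrated with `deSolve`'s `lsodar`
(adaptive BDF/Adams with root finding); the wall crossing $x = x_0$ with
$v > 0$ is located by the solver's root finder and the velocity reset
applied exactly there, so impact times are accurate to solver precision —
mislocated events would corrupt every downstream cadence statistic.
Defaults: `rel_tol` $10^{-9}$, `abs_tol` $10^{-12}$, dense output every
0.01 time units. The maximum internal step is capped at 1 so the solver
cannot step over the width-1 Gaussian pulse from a quiescent state (and an
explicit initial step is supplied: from exact rest with zero forcing an
adaptive solver cannot size its first step from the derivative norm).
Each integration segment restarts a nudge ($10\times$ `abs_tol`) inside
the wall so the root just handled is not re-detected.

A restitution law $\alpha < 1$ admits Zeno chattering: infinitely many
ever-smaller bounces in finite time. Contacts arriving slower than
`chatter_speed_eps` ($10^{-6}$) are treated as the bill settling onto the
wood: the velocity is zeroed and no impact is recorded (recording one
would violate the exact $\alpha$-restitution property of real impacts).
If, at such a contact, the net force still presses the bill into the wood
($R(t) - q x_0 > 0$ at $v = 0$), the state is held at the wall — a
sticking phase, resolved on the output grid — until the forcing releases
it. Runs of more than 100 settling contacts raise a warning. This mirrors
the physical bird: when the drive dies, the bill simply rests.

### Verification

The adaptive path is pinned to an independent fixed-step classical RK4
integrator with bisection event location (test suite,
`helper-oracle.R`); at step $10^{-3}$ the RK4 global error
($\sim \mathrm{d}t^4$) is orders of magnitude below the $10^{-5}$
agreement tolerance, and the measured disagreement on both reference
configurations is below $10^{-7}$. Halving the adaptive tolerances moves
every impact time by less than $10^{-6}$. Energy
$E = \tfrac12 v^2 + \tfrac12 q x^2$ is non-increasing under free damped
motion and its kinetic part drops by exactly $\alpha^2$ across impacts.

## Cadence statistics and regime classification

`summarize_cadence()` reduces an impact train to counts, inter-impact
intervals (population CV — a descriptive statistic on the complete train,
not a sample estimate), speed-decay ratios, and the split of impacts
around the forcing window (periodic: at or before $t_\mathrm{off}$;
impulsive: at or before the pulse maximum, the dashed-line convention of
the trajectory figure).

`classify_regime()` labels a train **periodic** when the during-forcing
impacts contain a run of at least `min_periodic_impacts` (default 5)
consecutive impacts whose intervals have CV at most `max_periodic_cv`
(default 0.1). The run-based rule matters: the onset transient of the
periodic regime contributes two short intervals ($\approx 0.83$) before
the steady $\approx 2\pi$ train, so a CV over *all* during-forcing
intervals ($\approx 0.43$ here) would misclassify textbook drumming; the
steady run is the drumming signature. A train is **transient**
(double-knock-like) when it has at most `max_transient_impacts` (default
4) impacts, all of strictly decreasing speed; anything else is
**mixed**. The defaults are conventions — the underlying hypothesis is
qualitative — and all three are exposed.

"Detected at a distance" is modelled purely as a speed threshold on
impacts (`count_audible_knocks()`); no acoustic propagation is modelled.
This captures the monotonicities that matter: more knocks clear any fixed
threshold as the thrust intensifies, and fewer clear it as the listener's
effective threshold rises.

## The flap-rate model

The intrinsic cruising flap rate follows the vortex-shedding relation

$$f = \frac{St \cdot U}{b\,\sin(33.5\,b^{-0.24})},$$

with $St = 0.25$ for intermittent flight. The amplitude angle
$33.5\,b^{-0.24}$ is interpreted in **degrees**: direct evaluation shows
only the degree convention reproduces the reported predictions from the
reported inputs (radians gives negative rates for these wingspans). With
$U = 15.2$ m/s, $b = 0.78$ m (mean of the 0.76–0.80 m span range):
8.38 Hz; with $U = 9.55$ m/s, $b = 0.705$ m: 5.70 Hz.

Raw vs intrinsic: the raw rate $\tilde f$ is flaps per elapsed second,
pauses included; the duty fraction $\tilde f / f$ (0.714 for the Pileated
Woodpecker) converts between them. All chained computations use unrounded
intermediates — $15/2.27 = 6.6079$ Hz, divided by 0.714 gives 9.2548,
displayed as 9.25 Hz; rounding the intermediate first would not.
Percent differences in `flap_report()` are computed from the
two-decimal-rounded rates with the observed rate as denominator
($|8.38 - 9.25|/9.25 = 9.4\%$, $|5.70 - 5.20|/5.20 = 9.6\%$) — the only
convention that reproduces both reported comparisons. Video frame
arithmetic uses 60 fps by default, the single frame rate consistent with
all the frames-per-flap ↔ rate pairs used (6 → 10 Hz, 8 → 7.5 Hz,
12 → 5 Hz); it is overridable everywhere. The frames-to-rate reports are
left unrounded (7 frames → 8.571 Hz).

## What the synthetic generators emulate

No field audio or video ships with the package; seeded generators stand in
with controlled ground truth.

* `generate_impact_train()` emits knock times on a nominal grid (double
  knock: two knocks, second at amplitude ratio 0.8; drum roll: default
  period 60 ms with gentle per-knock decay 0.95) plus Gaussian timing
  jitter.
* `render_audio()` renders each knock as an exponentially decaying
  sinusoid (default ring 1200 Hz, decay 10 ms) — the minimal
  resonant-impact model — plus white Gaussian noise; `detect_onsets()`
  recovers onsets via a causal 5 ms moving-RMS envelope, a threshold at a
  fraction of the envelope maximum, a minimum onset gap, and a hysteresis
  re-arm (the envelope must fall below half the threshold before the next
  onset can fire — without it a knock's own ring-down can re-cross the
  threshold under noise). Round trips recover knock counts exactly and
  intervals within 5 ms for noise RMS up to 0.05 and spacings of 50 ms or
  more.
* `generate_flap_sequence()` lays flap start frames on the raw-rate cycle
  grid ($1/(f \cdot \mathrm{duty})$ seconds per cycle; the active flap
  spans $1/f$ seconds) with per-event jitter in frames.
  `estimate_flap_rates()` recovers the raw rate from the flap starts as
  $(n-1)/\Delta t$ over the first-to-last start — the flaps-per-elapsed-
  time definition with the elapsed interval covering whole cycles — and
  the intrinsic rate via the duty fraction. Over 100 seeded sequences of
  200 flaps with 1-frame jitter, the mean recovered intrinsic rate is
  within 2% of truth.

These emulate timing structure, amplitude decay, and additive noise. They
do **not** emulate reverberation, propagation loss, wind or overlapping
sounds in field recordings, observer error in judging when a flap begins
on video, or species-specific double-knock timing (no published per-species
inter-knock intervals are modelled). Passing tests therefore validate the
analysis chain's correctness on clean, known-truth signals, not its
robustness to raw field media.

## Problem sizes and interfaces

The simulations here are desk-scale by design: two oscillator runs over
$[0, 30\pi]$ (about 94 time units, 14 and 3 impacts), audio round trips
under a second of 22.05 kHz signal, and 100 flap sequences of 200 flaps.
The package is driven from R — the `analysis/` scripts are the workflow
interface, and run configurations can be given as flat YAML
(`read_oscillator_config()`, with the two reference presets shipped as
both code (`fig2_preset()`) and YAML under `inst/extdata/`) — so no shell
command-line wrapper is provided. WAV output is mono 16-bit PCM via the
package's own minimal RIFF writer; all tables are plain CSV with `.`
decimal separators.

## Known limitations

* The oscillator is qualitative: no parameter inference from real
  drumming/double-knock recordings, and the regime thresholds are
  conventions, not fitted quantities.
* Sticking release times are resolved on the dense output grid (default
  0.01), not root-located; sub-grid forcing sign changes during a
  sticking phase are missed.
* The species z-score utility requires a user-supplied reference standard
  deviation; none is bundled.
* Onset detection assumes impulsive attacks well above the noise floor;
  it is not a general-purpose audio onset detector.
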