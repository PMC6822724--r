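---
title: "Delay-coupled oscillator simulations of anticipatory synchronization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delay-coupled oscillator simulations of anticipatory synchronization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sappa)
```

## The model

When people tap along with a metronome their taps tend to precede the
stimulus — the negative mean asynchrony of the sensorimotor
synchronization literature. `sappa` simulates this anticipation with a
single canonical Hopf oscillator that receives, besides its stimulus, its
own *delayed* activity as recurrent feedback:

$$\frac{1}{f}\dot z \;=\; z\!\left(\alpha + i2\pi + \beta_1 |z|^2\right)
  + F \;-\; \frac{D}{f}\, z(t-\tau),$$

with $\alpha = 1$, $\beta_1 = -1$ so that, unforced and without feedback,
$z$ settles on the unit circle and rotates at its natural frequency $f$
(Hz). The full constructor `oscillator_params()` also exposes the
higher-order nonlinearity $\epsilon \beta_2 |z|^4 / (1 - \epsilon|z|^2)$
of the generalized canonical oscillator; the anticipation model sets
$\beta_2 = \epsilon = 0$ and the code guards the singular denominator
$\epsilon |z|^2 \ge 1$.

The delayed feedback term is what produces anticipation: the feedback
signal $z(t-\tau)$ is phase-shifted relative to $z$, and adding it with a
negative amplitude shifts the oscillator's locked phase ahead of the
stimulus. Two parameters control its strength: the amplitude `D`
(dimensionless) and the delay `tau` (seconds). Because the term enters
the normalized equation as $D/f$, its influence grows as the stimulus
slows — which is exactly the behavioural signature: anticipation grows
with the metronome period. Two behavioural profiles are built in as
`sappa_params()`: a *musician* profile with `D = 0.05` and a
*non-musician* profile with `D = 0.36`, both with `tau = 0.222` s and
input coefficient `A = -0.5`.

## Inputs

`stimulus_spec()` describes the input $F$:

* a unit sinusoid $e^{i2\pi f_s t}$ (or its negation for the anti-phase
  role in duets, or a square wave `sign(cos)` aligned peak-for-peak with
  the sinusoid);
* optionally combined with the oscillator's own instantaneous activity,
  $F = (e^{i2\pi f_s t} + A z) / |e^{i2\pi f_s t} + A z|$ — the
  unit-magnitude normalization reflects the observation that stimulus
  loudness does not change synchronization;
* pure self- or partner-input forms $F = A z$ used in turn-taking runs.

Conventions adopted where the defining material leaves room:

* **Sign of the feedback term.** The combined form is always written
  $+A z$ with $A$ carrying its own (negative) sign, $A = -0.5$
  everywhere. The occasionally seen $-A z$ variant is the same model
  with relabelled sign, and an asymmetric sign for the second oscillator
  in turn-taking runs is available behind the
  `literal_joiner_sign` switch but off by default (symmetry is the more
  plausible reading).
* **Half-cycle feedback boundary.** In the alternating-tap task the
  model hears itself only during the half cycle in which it taps. The
  switch is defined on the stimulus phase: bare carrier on $[0, \pi)$,
  combined form on $[\pi, 2\pi)$. The stimulus phase is the only clock
  shared by all configurations.
* **Normalization scope.** The unit-magnitude normalization is applied
  whenever a sinusoidal carrier is combined with an oscillator signal
  (solo constant feedback, half-cycle feedback, duet alternation);
  pure-$z$ inputs in turn-taking runs are not normalized. A `normalize`
  flag makes the un-normalized combination available.
* **Degenerate point.** With $A = -1$ and $z$ equal to the carrier the
  normalized combination is $0/0$. The user-facing `stimulus_input()`
  reports this as a degenerate-input error; the integrator, which can
  hit the point only on a measure-zero set (e.g. the very first stage
  when $|z_0| = 1$, phase 0), uses a zero input for that stage and
  continues.

## Integration

The model is a delay differential equation, so the integrator
(`sappa_integrate()`, with `sappa_integrate_duet()` and
`sappa_integrate_turns()` for coupled pairs advancing jointly on one
grid) keeps the full state history and evaluates $z(t-\tau)$ — and, for
coupled runs, the partner's latency-delayed state — by linear
interpolation into that history. Numerical choices:

* fixed step `dt = 1 ms` by default; `tau` and the transmission latency
  are snapped to the nearest grid multiple (snap error at most 0.5 ms,
  below the 1 ms reporting resolution of the asynchrony tables);
* classical 4th-order Runge–Kutta with interpolated delayed values at
  half steps. The linear interpolation caps the observable global order
  near 2, which step-halving tests confirm; at 1 ms steps and
  frequencies at or below 1.5 Hz the terminal-state error is below
  $10^{-6}$ in modulus against an eighth-step reference, and the
  trajectory agrees with an independent general-purpose DDE solver
  (`deSolve::dede`) to better than $10^{-3}$;
* constant pre-history: $z(t) = z(0)$ for $t < 0$, the standard
  convention for delay equations;
* initial state on the unforced limit cycle (magnitude 1, phase 0)
  unless stated otherwise — starting on the cycle shortens transients;
* no randomness anywhere: identical inputs give byte-identical
  trajectories.

A delay of zero (or one snapped to zero) is treated as instantaneous
feedback using the current Runge–Kutta stage value, so the `tau = 0`
column of parameter sweeps is exact rather than extrapolated.
Divergent trajectories raise an error naming the failure time.

## Measurement

Asynchrony is measured on events, the way tapping data are scored:

* `find_peaks()` locates local maxima of $\mathrm{Re}\,z$ and refines
  each by a three-point parabola (never moving a peak by more than one
  sample);
* stimulus reference events are analytic — peaks of the carrier at
  multiples of the period, valleys at half-period offsets (used for the
  anti-phase duet role);
* each stimulus event up to the last model peak is paired with its
  nearest model peak; the per-cycle difference is *model minus
  stimulus*, so anticipation is negative, reported in ms;
* `assess_synchrony()` declares steady state from the first index after
  which every window of 5 consecutive differences spans less than 1 ms,
  and requires at least 5 post-onset cycles; the mean and SD are
  computed over the steady part only. Runs that never settle are
  *mode-locking* and carry no asynchrony value. The 1 ms / 5-cycle
  criterion is this package's choice (no quantitative criterion is
  fixed by the task itself) and both knobs are exposed.

For turn-taking runs the per-turn lead/lag statistic
$L = (a_1 - b_1) + (b_2 - a_2)$ sums the handover lags at the two turn
boundaries flanking a turn, and is converted to a fraction of a 90 bpm
beat as $-90 L_{\mathrm{ms}} / 60000$ (a `percent` column is also
emitted, since the fraction is usually plotted as a percentage).
Negative fractions mean the passive oscillator lags the active one.

Two event-level choices matter here:

* **Turn boundary.** A turn ends when the active oscillator completes
  its cycle — its phase crosses zero upward, at least half a cycle into
  the turn. An alternative rule, "unwrapped phase advanced by $2\pi$
  since the turn began", looks equivalent but is not: the incoming
  oscillator takes over mid-phase, so that rule lets the turn clock
  drift steadily away from the oscillators' cycle endpoints
  (about 35 ms per turn at a 78 ms latency) and decouples turns from
  claps. The cycle-completion rule keeps boundaries locked to the
  events being compared.
* **Claps.** Each oscillator's "claps" are its cycle-completion times
  (`cycle_completions()`, the upward zero-crossings of $\arg z$) rather
  than raw $\mathrm{Re}\,z$ maxima: the input switches discontinuously
  at handovers, and the resulting amplitude kinks can split one crest
  into two local maxima ~30 ms apart, which would corrupt first/last
  clap selection. At constant amplitude the two definitions coincide.

## The experiment drivers

All drivers run at the study conditions and are deterministic.

* `run_experiment1()` — one oscillator, periodic drive at periods
  1000–3500 ms in steps of 250 ms, `f = f_s`, with (`A z` combined) or
  without auditory feedback. Each period is simulated for 20 stimulus
  cycles (20 s at 1 Hz, 70 s at the slowest tempo), enough for the
  steady-state criterion with margin. Unsynchronized runs are kept as
  flagged rows.
* `run_experiment2_solo()` / `run_experiment2_duet()` — the alternating
  tapping task at `f = f_s = 1` Hz, 20 s. In the solo task feedback is
  present only during the second half of each stimulus cycle. In the
  duet, oscillator 1 receives $+e^{i2\pi f_s t}$ and oscillator 2 the
  negated carrier; with feedback on, each receives $A z(k)$ with $k$
  toggling self → partner every half cycle (self first, so each model
  "hears itself" on its own tapping half-cycle). The anti-phase
  oscillator is scored against stimulus valleys.
* `run_experiment3()` — two oscillators at 1.5 Hz (90 bpm), no external
  stimulus, 30 s per trial, latencies 0–78 ms. The active oscillator
  receives $A z_{\mathrm{self}}$; the passive receives the active
  oscillator's state delayed by the transmission latency with
  coefficient 1 (one hears oneself instantly, the partner through the
  link; the latency is never applied to self-feedback). The first three
  turns are excluded from the per-turn statistics as warm-up. The
  summary reports the mean beat fraction per latency and its
  least-squares slope.

### Frequency detuning

`delta` adds a constant offset to the effective frequency,
$\hat f = f + \Delta$, intended to mimic performers who run slightly
fast to compensate transmission delays. Applied symmetrically to both
oscillators its effect on their *relative* timing largely cancels: the
lead/lag curve shifts upward only marginally while
$2\pi\hat f \tau < \pi$. Once the detuning pushes the delay angle past
$\pi$ (at $\tau = 0.222$ s and $f = 1.5$ Hz this needs
$\Delta \gtrsim 0.75$ Hz) the recurrent feedback becomes
phase-advancing and the zero-latency fraction crosses into positive
values. The detuned-variant runs in the test-suite use $\Delta = 1$ Hz,
which sits in that regime; the sign of the effect, not its magnitude,
is the reproducible quantity, since no specific $\Delta$ value is fixed
by the task.

## Parameter analysis

`sweep_asynchrony()` maps the steady-state asynchrony over a
$(D, \tau)$ grid at fixed $A$ and $f$ — default grids: $D$ from 0 to 1
in steps of 0.05, and 27 $\tau$ points on $[0, 0.5]$ s so that 0.222 s
lies exactly on the grid. Cells that never reach steady state are
flagged `failed` and carry no value; `sweep_matrix()` reshapes the long
table into the conventional $D \times \tau$ matrix with integer-ms
entries (full precision stays in the long table). Each cell is exactly
the standalone integrate-and-measure run with those parameters — the
sweep takes no shortcuts, which is tested.

`fit_parameters()` is an exhaustive grid search minimizing the squared
deviation between the simulated asynchrony-versus-period curve and a
user-supplied target regression line (slope in ms of asynchrony per ms
of period, intercept in ms — behavioural regression lines are exactly
this shape). Ties break toward the smallest `D`, then the smallest
`tau`, then the `A` closest to zero. Self-consistency (recovering an
on-grid parameter set from its own curve, also under small target
perturbations) is the recovery test, since published anticipation
slopes exist only as figure overlays, not printed numbers.

`classify_attractor()` distinguishes phase-locking from mode-locking:
from at least eight initial phases it integrates the driven oscillator
and inspects the relative phase $\arg(z e^{-i2\pi f_s t})$. If every
run settles (excursion over the last 10 cycles below 0.1 rad) and all
terminal phases agree within $10^{-2}$ rad, the attractor is a fixed
point of the relative phase; a run whose relative phase keeps
traversing a loop is a limit cycle. Mixed outcomes are reported as
`limit_cycle` with a multistability warning. Both thresholds are
package choices, exposed as arguments.

## What the simulations do and do not show

All inputs are generated internally — this is a simulation package, and
the "data" are the model's own trajectories under the stated task
configurations. The drivers emulate task *structure* (periods,
feedback schedules, alternation, latencies), not behavioural
variability: there is no noise model, so the simulations reproduce mean
anticipatory tendencies, never the wide inter-trial and inter-subject
variability of real tapping (including mean-positive asynchronies of
some individuals at long periods). Passing tests therefore show that
the deterministic mechanism produces the published *orderings and
trends* — anticipation negative and growing with period, stronger for
the larger-`D` profile, weaker with feedback, lag growing with
latency — not that it fits any individual's data. Frequency detuning is
a constant offset, not an adaptive process; oscillator networks larger
than two are out of scope.

## Problem sizes

The test-suite and the bundled analysis scripts run at the study
conditions themselves (1 ms steps; 20 cycles per solo run; 30 s
turn-taking trials; coarse sweep grids for the property checks),
chosen so the full suite completes in well under a minute while leaving
every steady-state window at least 15 cycles long. The default sweep
grids (21 × 27 cells) run in a few seconds each.
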