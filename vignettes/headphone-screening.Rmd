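---
title: "Screening for headphone use with dichotic stimuli: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for headphone use with dichotic stimuli: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headscreen)
```

## The screening problem

Online auditory experiments have no control over the participant's
playback equipment. Whether a participant wears stereo headphones --
delivering the left and right channels independently to the left and
right ears -- or listens over loudspeakers -- where the two channels mix
acoustically before reaching either ear -- changes what stimuli can be
presented faithfully. `headscreen` implements a family of short
three-alternative forced-choice (3AFC) screening tests whose targets are
audible only (or only *not* audible) when the two channels reach the two
ears independently, together with the statistical machinery to evaluate
such screens and to estimate how many members of an unscreened cohort
actually wore headphones.

The three tests are:

* **HP (Huggins Pitch)** -- detection. Three intervals of white noise; in
  the target interval the right channel is the same noise with the phase
  of a narrow band (±6% around 600 Hz) inverted. Neither channel alone
  contains any spectral or temporal cue: the faint tonal percept at
  600 Hz arises centrally from the interaural comparison, so it survives
  headphone listening and collapses when the channels mix. The listener
  reports which noise contained the hidden tone.
* **AP (anti-phase)** -- discrimination. Three 200-Hz tones: a diotic
  standard, a diotic target at −6 dB, and a "foil" with the standard's
  amplitude but opposite polarity across channels. Over headphones the
  foil is as loud as the standard and the quiet target is obvious; over
  loudspeakers the foil partially cancels in the air and is mistaken for
  the quiet target.
* **BT (beat test)** -- discrimination. Three intervals of tone pairs
  separated by 30 Hz, with the lower frequency drawn from 1800--2500 Hz.
  The two standards carry both tones in each channel and beat audibly at
  30 Hz; the target puts one tone in each channel. Above the binaural
  phase-locking limit and at a 30-Hz separation no binaural beat is
  perceived, so over headphones the target sounds smooth -- but
  loudspeaker mixing recreates the monaural beat and the target becomes
  indistinguishable.

AP and BT are passable over a single channel (e.g. one earbud) and work
by *failing* loudspeaker users through acoustic interference; HP is the
only one that genuinely requires dichotic delivery. Combining HP with AP
or BT ("Both" rule: pass only if both pass) trades hit rate for a much
lower false-alarm rate.

## Stimulus synthesis

All stimuli are generated at 44.1 kHz as `stereo_waveform` objects and
can be written as 16-bit PCM WAV with a JSON answer key
(`write_trial_pool()`).

Parameters, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `center_hz`, `band_fraction` | 600 Hz, 0.06 | phase-inverted band spans 564--636 Hz (band edges inclusive) |
| `duration_s` | 1.0 s | interval duration, all tests |
| HP `onset_ramp_s` | 5 ms | raised-cosine gate on the noise; suppresses onset clicks, configurable to 0 |
| AP `tone_hz`, `target_level_db`, `ramp_s` | 200 Hz, −6 dB, 100 ms | the standard/target/foil recipe |
| BT `f1_min_hz`--`f1_max_hz`, `beat_hz`, `ramp_s` | 1800--2500 Hz, 30 Hz, 5 ms | tone-pair recipe |
| BT `rove_db_max` | 4 dB | independent per-interval attenuation drawn from [0, 4] dB, removing overall level as a cue |
| `gap_s` | 0.5 s | silent gap between intervals (unconstrained by the protocol; any comfortable value works) |
| `rms_level` | 0.05 full scale | per-interval RMS before AP/BT level offsets; absolute level belongs to a volume-calibration step outside this package |

Implementation choices worth knowing:

* **Phase inversion is a sign flip.** The 180° shift is implemented by
  multiplying the in-band complex spectrum by −1 and mirroring the
  conjugate bins, which is numerically exact and leaves every magnitude
  untouched. A bin is "in band" when its center frequency falls in
  [564, 636] Hz inclusive; a zero-width band is a no-op.
* **Ramps are applied to the noise before the dichotic transform.**
  Windowing *after* the transform would convolve the spectrum with the
  window and smear the band edges, breaking the exact left/right
  magnitude-spectrum identity. Ramping first keeps the identity exact;
  the residual onset energy of the filtered right channel is narrowband
  and far below the click threshold the ramp exists to prevent.
* **BT channel levels.** The paper-level recipe leaves the target's
  per-channel level open; the single tone is scaled by √2 so every
  interval has the same per-channel RMS before the rove, keeping level
  uninformative beyond the intended 0--4 dB rove. Which ear receives f1
  is randomized per trial.
* **AP slot assignment.** Only the target's position statistics are
  protocol-constrained; the foil and standard are assigned to the two
  remaining slots uniformly at random per trial.
* **Reproducibility.** One master seed per pool; trial *i* uses
  `child_seed(seed, i)` (a fixed multiplicative derivation, exact in
  doubles), so any single trial can be regenerated in isolation. Pools
  hold 12 trials with each target position occurring exactly 4 times.

The diotic **example trials** (`make_example_trial()`) that precede each
block sound identical on any equipment: a diotic 600-Hz tone in noise
(HP), two standards plus a softer diotic target (AP), and -- an extension
defined here, since the beat test's example is not otherwise specified --
two diotic beating pairs plus one diotic single tone (BT). Failure on the
example marks a participant for exclusion; the package records the flag
rather than enforcing an interactive flow.

## Protocol and scoring

Each screening block draws 6 of the pool's 12 trials without replacement
(`sample_block()`), scores responses as matches to the target position
(`score_block()`), and applies a pass threshold (`classify_pass()`).
Chance performance is 2 of 6. Only above-chance thresholds (3--6) are
meaningful; the recommended deployment threshold is 6/6, and the "Both"
rule (`combine_both()`) conjoins two tests. Block order over the four
test × equipment conditions is counterbalanced with a cyclic 4×4 Latin
square (`latin_square_order()`), row = participant index mod 4; the
protocol fixes only that *some* Latin square is used, and the cyclic one
is the simplest that satisfies the column property.

## Signal-detection evaluation

Hits and false alarms are properties of the *screen*: the probability of
passing a true headphone user, and of passing a loudspeaker user, at a
given threshold. Sweeping the threshold over 6, 5, 4, 3 yields four ROC
points; the degenerate accept-none (0, 0) and accept-all (1, 1) policies
anchor the curve, and `auc()` integrates it trapezoidally (the points are
monotone by construction, so the trapezoid is exact for the polygonal
curve). Sensitivity at a single threshold is
`d' = qnorm(hit) − qnorm(false_alarm)`; rates of exactly 0 or 1 are
clipped to 1/(2N) and 1 − 1/(2N) before inversion.

Two resampling procedures assess AUC differences between tests:

* `bootstrap_auc_diff()` resamples whole subjects (all four condition
  scores together) with replacement and reports the proportion of
  resampled differences on each side of zero.
* `permutation_auc_diff()` builds the null by relabeling: per permutation
  and per subject, the two tests' headphone scores are swapped or kept by
  a fair coin, and independently the two loudspeaker scores.

Both report a two-tailed p equal to `2 × (1 − max(directional support))`,
where the support proportions count *strict* inequalities: a result is
significant at α = 0.05 exactly when one direction's support exceeds
97.5%. This convention makes the degenerate case (identical tests, all
differences zero) come out maximally non-significant (p = 1) rather than
spuriously significant, keeps boundary ties conservative, and floors
reported p at 1/iterations rather than 0. Defaults are 10,000 iterations;
the counts are overridable for publication-grade runs. Calibration of the
permutation test (type-I error 0.05 under a simulated null) is part of
the test suite.

## Headphone-proportion estimation

For a cohort screened once over claimed headphones, the observed score
distribution of each test is modeled as a convex mixture of reference
distributions measured in a trusted cohort over both kinds of equipment:

    modeled = propH × reference_headphones + (1 − propH) × reference_loudspeakers

with a single `propH` shared across tests. The loudspeaker component's
(1 − propH) weight is the only reading that keeps the model
one-parameter and the distributions normalized. `estimate_prop_h()`
minimizes the sum of squared errors over all tests and all 7 score bins
on the grid 0, 0.01, …, 1. Histograms are compared as proportions, tests
weighted equally. Exact grid ties break toward the smaller `propH` --
conservative about claiming headphone use -- with a flag. An optional
parametric bootstrap (multinomial resampling of the unknown histograms)
produces an interval; it is off by default as an extension beyond the
core estimator.

## The virtual listener

No human data ship with the package; the listener simulator exists so
that every downstream statistic can be validated end-to-end on synthetic
cohorts with known ground truth.

**Playback models** are 2×2 mixing matrices from channels to ears:
`headphone_model()` (identity), `full_mix_model()` (both ears receive
(L+R)/2 -- the centered-listener idealization in which anti-phase content
cancels exactly), `crosstalk_model(c)` (each ear gets 1−c of its own
channel and c of the other, 0 ≤ c ≤ 0.5), and `delayed_mix_model(c, d)`
(crosstalk with a d-sample delay on the cross paths, emulating off-center
positions). Mixing is linear and sample-wise.

**Decision statistics** are the simplest physics-faithful detectors of
each cue, computed per interval and perturbed by zero-mean Gaussian
internal noise before an argmax/argmin choice:

* HP: power of (left ear − right ear) within 564--636 Hz, divided by the
  broadband power of the left ear; choose the maximum.
* AP: mean of the two per-ear RMS levels; choose the minimum
  ("quietest").
* BT: modulation depth of the analytic-signal envelope at 30 Hz
  (single-bin DFT normalized by the envelope mean, averaged over ears,
  ramps trimmed first); choose the minimum ("smoothest").

Noise is injected at the statistic level, not the waveform level, which
keeps the decision behavior analytically checkable. Exact ties -- and
floating-point near-ties within 10⁻⁹ relative, such as the identical
intervals of a fully mixed BT trial -- are broken uniformly at random.
Two numerical details matter for the BT statistic: the envelope window is
truncated to a whole number of beat periods and mean-centered before the
single-bin DFT, otherwise the envelope's DC component leaks into the
30-Hz bin and a perfectly smooth tone acquires a spurious percent-level
"depth".

These statistics make the qualitative regimes exact: identity playback
with zero noise yields 100% accuracy on all three tests; full mixing
erases the HP and BT cues entirely (uniform guessing, accuracy 1/3) and
silences the AP foil, which is then *always* chosen -- accuracy 0,
the below-chance trough characteristic of anti-phase screens over
loudspeakers.

**Cohort generation** (`simulate_cohort()`): each subject draws a
headphone crosstalk c ~ U(0, 0.35), a loudspeaker model (full mix by
default), and a sensitivity factor s ~ U(0.02, 0.2) that sets their
internal-noise SD to s × the test's nominal cue margin (the mean
identity-playback margin between target and best competitor, computed
from the pool). These defaults were chosen from the margin arithmetic of
the statistics to reproduce the qualitative score signatures of real
screening cohorts: channel bleed above c = 0.25 makes the anti-phase foil
quieter than the −6 dB target, so such subjects score 0/6 on AP over
headphones -- producing the bimodal AP headphone distribution and an AP
hit rate below HP's -- while the HP cue degrades smoothly as (1−2c)²,
giving the "all-or-nothing" HP headphone distribution concentrated at
6/6. Full-mix loudspeakers produce the chance-shaped HP distribution
peaking at 2 and the AP trough at 0. Consequently HP separates equipment
better than AP (higher AUC) on essentially every simulated cohort, which
is the ordering the screen is designed around.

For delay-free mixing the HP and AP statistics are exact quadratic forms
in six cached per-interval moments, and the BT depth depends only on the
per-ear tone-amplitude ratio (interpolated from a cached grid), so
cohorts simulate in milliseconds once a pool is built; models with
cross-path delay fall back to the waveform route. Equivalence of the two
routes is covered by tests (10⁻¹² for HP/AP; interpolation tolerance for
BT).

What the simulator does **not** model: room acoustics (no HRTFs,
reverberation, or head shadow), hearing impairment, attention lapses, or
any claim that a given crosstalk level maps onto a given human pass rate.
Passing the simulator-based tests shows the pipeline is self-consistent
under the stated playback physics, not that human cohorts will produce
particular numbers.

## Problem sizes used in validation

The shipped test-suite and acceptance runs use: pools of 12 trials at the
deployment rate (44.1 kHz) where the assertion concerns deployment
parameters and reduced rates (8.82 kHz, 0.5 s) elsewhere; 10,000 guessing
blocks for the chance level; 10,000 simulated trials for the full-mix
binomial checks; 100-subject cohorts for score signatures; 30 cohort
seeds for the AUC-ordering check; 500 null tables × 1,000 permutations
for type-I calibration; and ~200 multinomial draws at n = 100 for
mixture recovery. These sizes are the package's validation choices;
publication-grade inference should raise the resampling counts (the
functions accept up to millions of iterations).

## Known limitations

* The simulator's listener is an ideal observer with additive statistic
  noise; it cannot express cue-specific human idiosyncrasies (e.g. some
  listeners' genuine ability to hear Huggins Pitch over loudspeakers when
  optimally positioned, which real cohorts show as a secondary peak at
  6/6 in the loudspeaker condition). Crosstalk- or delayed-mix
  loudspeaker presets can create such subpopulations explicitly.
* ROC curves built from four thresholds are coarse; the trapezoidal AUC
  is exact for the polygon but insensitive to behavior between
  thresholds.
* The mixture estimator assumes the reference cohort's equipment and
  population match the unknown cohort's; violations bias `propH` in
  either direction.
* WAV output is fixed at 16-bit PCM stereo, the lowest common denominator
  for browser delivery.
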