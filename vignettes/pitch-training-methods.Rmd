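---
title: "Methods: pitch estimation, exercise scoring and session statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pitch estimation, exercise scoring and session statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitchcoach)
```

pitchcoach is the offline analysis core of a voice-pitch-training workflow
used in gender-affirming voice training (GAVT): it estimates vocal pitch
(f0) from audio, scores target-matching exercises the way the live training
display does, and runs the session-level statistics used to evaluate
performance and usability. This vignette explains the models and the
choices behind them.

## Pitch estimation

`estimate_pitch()` is a frame-wise normalized autocorrelation tracker. Each
40 ms frame (10 ms hop, frame-centre timestamps) is scored by the
normalized cross-correlation function

$$ r(\tau) \;=\; \frac{\sum_t s_t\, s_{t+\tau}}
   {\sqrt{\sum_t s_t^2 \;\sum_t s_{t+\tau}^2}}, \qquad
   \tau \in \left[\tfrac{sr}{f_{\max}},\ \tfrac{sr}{f_{\min}}\right], $$

with the analysis range defaulting to 50–600 Hz, the adjustable range of
the training display. Three details matter in practice:

* **Candidate refinement before comparison.** Every local maximum of
  $r(\tau)$ is interpolated with a Hann-windowed sinc kernel on a fine lag
  grid *before* candidates are compared. Harmonically rich voiced sounds
  have narrow correlation peaks; when the true period falls between integer
  lags, the raw bin value underestimates the peak while an exact-integer
  multiple of the period (one octave down) does not. Comparing refined
  heights removes that systematic octave error.
* **Shortest near-best lag.** A periodic signal repeats at every multiple
  of its period, so all those lags score near 1. Among candidates within
  0.05 of the best refined height, the shortest lag wins.
* **Voicing and smoothing.** Frames whose refined peak falls below the
  voicing threshold (default 0.45) or whose energy sits at the −80 dBFS
  silence floor are unvoiced. A width-5 running median over contiguous
  voiced runs removes isolated octave slips; a median never introduces
  values absent from the neighbourhood it filters.

On synthesized constant-f0 signals from 60 to 580 Hz the tracker's mean
absolute error is well under 1 Hz for sine, sawtooth and pulse-train
sources; the packaged pure-tone validation (`validate_estimator()`, tones
at 110/155/200/300 Hz) reproduces the development-time protocol with a
5 Hz acceptance bound. Background-noise rejection is ordinary
energy-plus-periodicity gating; no noise-robust reweighting is attempted,
and noisy recordings will show more unvoiced frames rather than wrong f0.

`mean_pitch()` is the arithmetic mean of voiced f0 values in Hz (not the
log domain). That convention is committed once and used everywhere a "mean
pitch" appears (assessment, chanting feedback, validation).

## Exercise targets and tolerance

Each exercise presents a target curve over `[0, duration)`:

* **constant** — flat line, 200 Hz by default;
* **stair** — five equal-duration segments at low/mid/high/mid/low, with
  defaults 110 and 200 Hz and the middle level always set midway (155 Hz by
  default). The equal split of the total duration is this package's choice;
  only the total (6 s in the evaluated protocol) is fixed by the exercise;
* **contour** — linear interpolation of a vocal-model pitch contour on a
  10 ms grid.

"Close enough" is a band around the target. The default half-width is one
semitone (100 cents): a ratio unit makes leniency independent of pitch
height, so a band at 110 Hz is as forgiving as one at 200 Hz. An absolute
Hz band remains available for strictness studies. Whether the deployed
display used a ratio or absolute band is not recorded; the choice is
configurable precisely because it is a convention.

Vocal-model contours are extracted from audio by `extract_contour()`:
voiced frames only, unvoiced gaps up to 250 ms bridged linearly, longer
gaps truncating the contour at its voiced extent. The packaged model
contours are **synthetic** (`synthetic_model_contour()`): smooth
declarative intonation shapes around a 210 Hz base. No human recordings
ship with the package.

## Repetition windows and the exercise error

The per-repetition performance metric is the *exercise error*: the mean
absolute difference in Hz between the target and the user's voiced pitch
over the repetition window, with the target clock starting at the window
start. Unvoiced frames carry no pitch and are excluded from the mean; a
`voiced_fraction` field is kept so sparse repetitions can be flagged
(0.3 is a reasonable screening threshold). The windows mirror the
evaluated protocol:

| exercise | window |
|---|---|
| constant /i/ | 5 s from the first voiced frame |
| constant reading | first to last voiced frame |
| stair (both) | recording start to automatic end (6 s, auto-started) |
| human curve | recording start to the contour's end |
| chanting | the final, feedback-free speech phase |

The chanting machine advances from humming to chanting at the first moment
the pitch has stayed inside the tolerance band *continuously* for 1 s;
interrupted accumulation resets, and an unvoiced frame counts as outside
the band. The chant phase has no operational completion signal in the live
exercise ("the graph turns blank"), so a fixed 3 s chant duration stands in
for it. Both the free-phase mean pitch (what the live display reports) and
the free-phase error against the 200 Hz target are returned.

No time-warping is applied to human-curve scoring. The metric is
deliberately timing-sensitive — speaking the right melody at the wrong
cadence scores poorly — because that is the behaviour of the system being
modelled; it is a documented limitation of the metric, not of the
implementation.

## The simulated user

`simulated_user()` produces pitch tracks as *target + bias + AR(1) noise*:

* `bias` — a constant personal offset (Hz); populations draw it from a
  normal distribution with SD 3 Hz;
* AR(1) noise with lag-1 coefficient 0.9 on the 10 ms grid — pitch wander
  is smooth, with a correlation time of roughly 0.1 s, not white noise;
* a per-repetition noise SD following a geometric schedule from
  `noise_sd_start` (default 8 Hz) at repetition 1 to `noise_sd_end`
  (default 4 Hz) at repetition 10. The halving mirrors the observed
  pattern of errors dropping between the first and second five
  repetitions; the within-session shape (geometric) is free and chosen for
  scale-invariance;
* 5% per-frame voicing dropout;
* a hum-phase SD multiplier of 0.3: holding a hummed pitch is a lock-in
  task, and the hum is continuously voiced. Without this the 1 s
  continuous dwell would almost never be met by a noise process that never
  settles — real users settle.

With bias 0 and white noise of SD $\sigma$, the expected exercise error is
the folded-normal mean $\sigma\sqrt{2/\pi}$; this closed form anchors the
Monte-Carlo tests. Defaults of 8 → 4 Hz put errors in the range of the
easier evaluated exercises (≈6 Hz falling to ≈4.5 Hz).

What the generator does *not* emulate: per-exercise difficulty differences
(all exercises share one noise process, where real errors ranged from
≈5 Hz on constant /i/ to ≈50 Hz on human-curve imitation), cadence
mismatch on human-curve exercises, vocal fatigue, and strategy changes.
Tests passing on this generator therefore demonstrate correctness of the
measurement and statistics pipeline, not realism of human learning curves.

`generate_session()` reproduces the evaluated structure — participants ×
the 7-exercise battery × 10 repetitions — scoring every repetition with
`run_repetition()`. A repetition that cannot be scored (a hum phase that
never advances) is redone with fresh noise, mirroring the study's redo
rule, and recorded as excluded after 25 failures. Simulated SUS and IMI
item responses are drawn from discretized normals whose means follow the
qualitative pattern of usable-but-effortful software (high
interest/effort, lower competence for harder exercises, low pressure);
they exercise the scoring code and are not calibrated to any human cohort.

## Session statistics

* **SUS** — standard scoring: odd items contribute `x − 1`, even items
  `5 − x`, the sum scaled by 2.5 to 0–100; the benchmark test is a
  two-tailed one-sample t against 70.
* **IMI** — the 8-item short form maps two consecutive items to each of
  interest/enjoyment, effort/importance, perceived competence and
  pressure/tension (sums, 2–14). The exact item order and reversal status
  of the instrument are configuration (`imi_default_mapping()`), because
  published short forms vary; reversed items score as `8 − x`.
* **Half comparison** — per participant, the mean error over repetitions
  1–5 is paired with the mean over 6–10. A Shapiro–Wilk check on the
  paired differences at α = .05 gates a two-tailed paired t test against a
  Wilcoxon signed-rank fallback. The normality test and its level are this
  package's choice; only the fallback rule itself is inherited. All-zero
  differences return statistic 0 and p = 1 by convention; nonzero
  zero-variance differences fall to the signed-rank branch, where the
  statistic is defined.
* **Multiplicity** — Benjamini–Hochberg step-up at a base α of .05 across
  the seven half-comparisons (via `stats::p.adjust`), and step-down
  Holm–Šidák for post hoc contrasts after repeated-measures ANOVA. When
  reprocessing printed p values, "<.001" entries are represented by the
  bound 0.001; the rejection count is insensitive to any value at or below
  it.
* **RM-ANOVA** — one-way within-subjects F with the subject effect removed,
  df (k−1, (n−1)(k−1)), computed from the sums-of-squares partition and
  cross-checked against `aov` with an `Error(subject)` stratum. No
  sphericity correction is applied; with four conditions this is a known
  limitation.

## Numerical choices and degenerate inputs

Half-open intervals everywhere: volume classes are `[low, high)`, target
curves are defined on `[0, duration)`, and windows are `[t0, t1)`. Stair
segment lookup adds a 10⁻⁹ relative epsilon so frame times that round a
hair below a boundary stay in the intended segment. WAV audio is written
as 16-bit PCM with symmetric ±32767 scaling so a write/read round trip is
identity to within half a quantization step. Cents offsets live in
`[−50, 50)` so every frequency has a unique note reading.

## Monte-Carlo scales

The test suite verifies, among others: type-I error control of the full
generate → compare → BH pipeline over 2000 simulated null studies
(6 participants each — error control does not depend on cohort size, and
this keeps 2000 studies tractable on one CPU), and ≥80% detection of the
SD-halving improvement over 200 studies at the evaluated size of 21
participants. The folded-normal calibration uses 500 seeds. All generators
are pure functions of their seeds, so every reported number is exactly
reproducible.

## A worked session

```{r, eval = FALSE}
ds <- generate_session(n_participants = 21, seed = 1)
s <- summarize_session(ds)
print(s)
tidy(s)      # per-exercise table
glance(s)    # one-row overview
autoplot(s)  # first vs second half errors
```
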