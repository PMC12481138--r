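# pitchcoach

An offline R toolkit for the computational core of voice-pitch-training
software used in gender-affirming voice training (GAVT). Training software
of this kind shows a user their vocal pitch contour in real time next to a
target and scores how closely they match it; evaluating such software needs
the same machinery offline. pitchcoach provides:

* **f0 estimation** — frame-wise normalized autocorrelation
  (`estimate_pitch()`), with windowed-sinc peak refinement, a
  shortest-near-best-lag octave guard, voicing decisions and median
  smoothing; validated against synthesized pure tones
  (`validate_estimator()`).
* **Exercise models** — constant, chanting, stair and human-curve target
  curves with a tolerance band (default ±1 semitone), the chanting
  phase-advance rule (1 s of continuous in-band pitch), and per-repetition
  windows.
* **The exercise error** — the per-repetition performance metric: mean
  absolute difference in Hz between target and produced pitch over the
  repetition window,

  $$\mathrm{error} = \frac{1}{|V|}\sum_{t \in V} \lvert f_0(t) - g(t - t_0)\rvert,$$

  over voiced frames $V$ in the window and target curve $g$.
* **Session statistics** — SUS (0–100) and 8-item IMI scoring,
  first-half/second-half paired comparisons with a Shapiro–Wilk-gated
  signed-rank fallback, Benjamini–Hochberg FDR control, one-sample
  benchmark tests, repeated-measures ANOVA and Holm–Šidák post hoc
  adjustment (`summarize_session()` produces the whole report).
* **Synthetic fixtures** — deterministic tone/voiced-signal synthesis and
  simulated users (target + bias + AR(1) noise with an improvement
  schedule), so everything is testable without human recordings
  (`generate_session()` builds whole participants × exercises ×
  repetitions datasets).

Everything is tibble-in/tibble-out and pipe-friendly, with `tidy()`,
`glance()` and `autoplot()` methods for the session summary, plus a small
CLI (`inst/cli/pitchcoach.R`: `validate | score | simulate | assess`).

## Worked example

```r
library(pitchcoach)

# pure-tone validation of the pitch estimator
validate_estimator(c(110, 155, 200, 300))
#>  frequency mean_f0 deviation
#>        110     110 5.309e-03
#>        155     155 2.493e-03
#>        200     200 6.502e-06
#>        300     300 4.006e-05

# a full simulated evaluation: 21 participants x 7 exercises x 10 repetitions
ds <- generate_session(n_participants = 21, seed = 1)
s  <- summarize_session(ds)
print(s)
#> Exercise errors, first vs second 5 repetitions (Hz)
#>          exercise   first 5  second 5   method       p sig
#>        constant_i 5.9 (0.5) 4.3 (0.6) paired-t 2.3e-16   *
#>  constant_reading 6.0 (0.5) 4.4 (0.6) paired-t 5.1e-17   *
#>          chanting 5.9 (0.4) 4.4 (0.7) paired-t 7.8e-12   *
#>           stair_i 6.0 (0.4) 4.3 (0.6) paired-t 2.3e-13   *
#>      stair_phrase 5.9 (0.4) 4.4 (0.5) paired-t 4.1e-15   *
#>     human_curve_1 6.0 (0.7) 4.5 (0.7) paired-t 1.2e-11   *
#>  human_curve_pref 5.9 (0.7) 4.2 (0.5) paired-t 7.9e-12   *
#>
#> SUS: mean 75.2 (SD 14.1), n = 21; vs benchmark: t = 1.70, p = 0.104
```

Reading this: each simulated participant's mean exercise error over
repetitions 1–5 is paired against their mean over 6–10; the default
simulated population's noise SD halves across the session, so every
exercise shows a significant error reduction after Benjamini–Hochberg
correction (`sig` column). The per-exercise table is available as a tibble
via `tidy(s)`, the one-row overview via `glance(s)`, and
`autoplot(s)` draws the half-by-half comparison.

The methods vignette (`vignettes/pitch-training-methods.Rmd`) documents the
estimator, the tolerance and window conventions, the simulated-user model
and the statistical choices.

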