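# Deterministic synthetic audio and simulated users.
#
# Every generator is a pure function of its arguments and a seed, so every
# other module is testable without human recordings. Simulated users operate
# directly in the pitch domain (a target curve plus bias and AR(1) noise);
# the audio-domain path (synth_voiced of a perturbed contour) is available
# for end-to-end integration tests and shares the same deviation model.

#' Synthesize a pure tone
#'
#' A sine at exactly `f` Hz, amplitude 0.8 — the validation input for the
#' pitch estimator.
#'
#' @param f Frequency in Hz, `0 < f < sample_rate / 2`.
#' @param duration Seconds (> 0).
#' @param sample_rate Hz (default 44100).
#' @param amplitude Peak amplitude (default 0.8).
#' @return An [audio_signal()].
#' @export
synth_tone <- function(f, duration, sample_rate = 44100, amplitude = 0.8) {
  if (duration <= 0) {
    abort("duration must be positive", class = "pitchcoach_bad_spec")
  }
  if (f <= 0 || f >= sample_rate / 2) {
    abort("tone frequency must lie in (0, sample_rate/2)",
          class = "pitchcoach_nyquist_error")
  }
  n <- round(duration * sample_rate)
  audio_signal(amplitude * sin(2 * pi * f * (seq_len(n) - 1) / sample_rate),
               sample_rate)
}

#' Synthesize a voiced signal following an f0 contour
#'
#' Phase-accumulation synthesis: the instantaneous frequency equals the
#' programmed contour at every sample, so the contour is an exact oracle for
#' the pitch estimator. Harmonically rich waveforms (`"pulse_train"`,
#' `"sawtooth"`) imitate voiced speech; `"sine"` gives a pure tone contour.
#'
#' @param f0 The contour: a single Hz value, a numeric vector (uniform grid
#'   over the duration), or a function of time in seconds. All values must
#'   lie in `[50, 600]`.
#' @param duration Seconds.
#' @param sample_rate Hz.
#' @param waveform `"pulse_train"` (default), `"sawtooth"` or `"sine"`.
#' @param amplitude Peak amplitude (default 0.8).
#' @param jitter Relative cycle-to-cycle f0 perturbation SD (default 0).
#' @param snr_db Additive white-noise level as signal-to-noise ratio in dB,
#'   or `NULL` for none.
#' @param seed Seed for jitter/noise (default 1).
#' @return An [audio_signal()].
#' @export
synth_voiced <- function(f0, duration, sample_rate = 44100,
                         waveform = c("pulse_train", "sawtooth", "sine"),
                         amplitude = 0.8, jitter = 0, snr_db = NULL,
                         seed = 1L) {
  waveform <- match.arg(waveform)
  if (duration <= 0) {
    abort("duration must be positive", class = "pitchcoach_bad_spec")
  }
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  f_inst <- if (is.function(f0)) {
    f0(t)
  } else if (length(f0) == 1) {
    rep(f0, n)
  } else {
    approx(seq(0, duration, length.out = length(f0)), f0, xout = t,
           rule = 2)$y
  }
  check_pitch_range(f_inst, "f0 contour")
  withr::with_seed(seed, {
    if (jitter > 0) {
      # slow multiplicative perturbation, smoothed over ~one cycle
      raw <- rnorm(n, 0, jitter)
      w <- round(sample_rate / mean(f_inst))
      raw <- stats::filter(raw, rep(1 / sqrt(w), w), sides = 1)
      raw[is.na(raw)] <- 0
      f_inst <- f_inst * (1 + as.numeric(raw))
    }
    phase <- 2 * pi * cumsum(f_inst) / sample_rate
    n_harm <- switch(waveform, sine = 1L,
                     min(30L, floor(sample_rate / 2 / max(f_inst)) - 1L))
    x <- numeric(n)
    for (k in seq_len(max(n_harm, 1L))) {
      gain <- switch(waveform, sine = 1, sawtooth = 1 / k,
                     pulse_train = 0.9^(k - 1))
      x <- x + gain * sin(k * phase)
    }
    x <- amplitude * x / max(abs(x))
    if (!is.null(snr_db)) {
      noise_sd <- sqrt(mean(x^2)) / 10^(snr_db / 20)
      x <- x + rnorm(n, 0, noise_sd)
      x <- x / max(1, max(abs(x)))
    }
  })
  audio_signal(x, sample_rate)
}

#' A synthetic vocal-model contour
#'
#' A smooth, declarative intonation-like contour (rise to a mid-phrase peak,
#' fall to a low ending) with seeded speaker-specific variation. It is a
#' synthetic stand-in for a recorded vocal model: no human recordings are
#' packaged.
#'
#' @param speaker_id Label.
#' @param duration Phrase duration in seconds (default 2).
#' @param base Speaker median pitch in Hz (default 210, a typical adult
#'   female speaking pitch).
#' @param seed Seed.
#' @param grid_step Grid step in seconds.
#' @return A [model_contour()].
#' @export
synthetic_model_contour <- function(speaker_id = "model1", duration = 2,
                                    base = 210, seed = 1L, grid_step = 0.01) {
  n <- round(duration / grid_step)
  tt <- seq(0, 1, length.out = n)
  withr::with_seed(seed, {
    peak <- runif(1, 0.25, 0.5)
    rise <- runif(1, 0.15, 0.35) * base
    fall <- runif(1, 0.2, 0.35) * base
    shape <- ifelse(tt < peak,
                    rise * sin(pi / 2 * tt / peak),
                    rise - (rise + fall) * (tt - peak) / (1 - peak))
    wob <- 0.04 * base * sin(2 * pi * runif(1, 2, 4) * tt + runif(1, 0, 2 * pi))
  })
  f0 <- pmin(pmax(base + shape + wob, PITCH_RANGE_HZ[1] + 5),
             PITCH_RANGE_HZ[2] - 5)
  model_contour(f0, grid_step = grid_step, phrase_text = "synthetic phrase",
                speaker_id = speaker_id)
}

# simulated users --------------------------------------------------------

#' A simulated training user
#'
#' A user whose produced pitch is the target plus a constant bias and AR(1)
#' noise whose stationary SD follows a geometric improvement schedule across
#' the 10 repetitions (repetition 1 at `noise_sd_start`, repetition 10 at
#' `noise_sd_end`). Frames drop to unvoiced with probability
#' `voicing_dropout`.
#'
#' @param bias Constant pitch offset in Hz (default 0).
#' @param noise_sd_start,noise_sd_end Stationary noise SD (Hz) at
#'   repetitions 1 and 10. Defaults 8 and 4: an error magnitude comparable
#'   to the easier evaluated exercises, halving over the session.
#' @param ar_coefficient Lag-1 autocorrelation of the pitch deviation
#'   process, in `[0, 1)` (default 0.9 at the 10 ms frame grid — pitch
#'   wander is smooth, not white).
#' @param voicing_dropout Per-frame probability of an unvoiced frame
#'   (default 0.05).
#' @param hum_sd_factor Noise-SD multiplier during a chanting hum phase
#'   (default 0.3): holding a hummed pitch is a lock-in task and users track
#'   it far more tightly than connected speech.
#' @param seed Seed; together with the repetition index it fully determines
#'   a track.
#' @return A `simulated_user` object with the 10-element `schedule` of
#'   per-repetition SDs.
#' @export
simulated_user <- function(bias = 0, noise_sd_start = 8, noise_sd_end = 4,
                           ar_coefficient = 0.9, voicing_dropout = 0.05,
                           hum_sd_factor = 0.3, seed = 1L) {
  stopifnot(noise_sd_start >= 0, noise_sd_end >= 0,
            ar_coefficient >= 0, ar_coefficient < 1,
            voicing_dropout >= 0, voicing_dropout < 1,
            hum_sd_factor >= 0)
  schedule <- if (noise_sd_start > 0 && noise_sd_end > 0) {
    noise_sd_start * (noise_sd_end / noise_sd_start)^((0:9) / 9)
  } else {
    seq(noise_sd_start, noise_sd_end, length.out = 10)
  }
  structure(
    list(bias = bias, noise_sd_start = noise_sd_start,
         noise_sd_end = noise_sd_end, ar_coefficient = ar_coefficient,
         voicing_dropout = voicing_dropout, hum_sd_factor = hum_sd_factor,
         schedule = schedule, seed = as.integer(seed)),
    class = "simulated_user"
  )
}

# derived per-repetition seed, kept inside 32-bit integer range
rep_seed <- function(seed, repetition, attempt = 0L) {
  as.integer((as.numeric(seed) * 7919 + repetition * 131 + attempt * 17 + 1) %%
               2147483647)
}

#' Simulate a user's pitch track for one repetition
#'
#' @param target A `target_curve`.
#' @param user A [simulated_user()].
#' @param repetition Repetition index 1-10 (selects the noise SD from the
#'   improvement schedule).
#' @param duration Track duration in seconds; defaults to the target's
#'   duration.
#' @param hop Frame grid in seconds (default 0.01).
#' @param attempt Redo counter folded into the seed (default 0).
#' @param sd_factor Multiplier on the scheduled noise SD (default 1; the
#'   chanting hum phase uses the user's `hum_sd_factor`).
#' @return A [pitch_track()] on the uniform grid starting at 0 s.
#' @export
simulate_user_track <- function(target, user, repetition = 1L,
                                duration = NULL, hop = 0.01, attempt = 0L,
                                sd_factor = 1) {
  if (!inherits(user, "simulated_user") || repetition < 1 || repetition > 10) {
    abort("need a simulated_user and a repetition index in 1..10",
          class = "pitchcoach_bad_spec")
  }
  if (is.null(duration)) duration <- target$duration
  n <- round(duration / hop)
  times <- hop * (seq_len(n) - 1)
  tgt <- if (target$kind == "constant") {
    target$value
  } else {
    target_value(target, pmin(times, target$duration - 1e-9))
  }
  sdr <- user$schedule[repetition] * sd_factor
  rho <- user$ar_coefficient
  withr::with_seed(rep_seed(user$seed, repetition, attempt), {
    e <- if (sdr > 0) {
      innov <- rnorm(n, 0, sdr * sqrt(1 - rho^2))
      as.numeric(stats::filter(innov, rho, method = "recursive",
                               init = rnorm(1, 0, sdr)))
    } else {
      numeric(n)
    }
    voiced <- runif(n) >= user$voicing_dropout
  })
  f0 <- pmin(pmax(tgt + user$bias + e, PITCH_RANGE_HZ[1]), PITCH_RANGE_HZ[2])
  f0[!voiced] <- NA_real_
  new_pitch_track(times, f0, voiced, as.numeric(voiced))
}

#' Simulate a full chanting repetition track
#'
#' Concatenates a hum segment (noise SD scaled by the user's
#' `hum_sd_factor`, long enough to satisfy the dwell rule) with a
#' connected-speech segment at the user's scheduled noise level covering the
#' chant and free-speech phases.
#'
#' @param spec A chanting [exercise_spec()].
#' @inheritParams simulate_user_track
#' @export
simulate_chanting_track <- function(spec, user, repetition = 1L,
                                    hop = 0.01, attempt = 0L) {
  stopifnot(spec$kind == "chanting")
  hum_dur <- spec$dwell_advance + 1
  rest_dur <- spec$chant_duration + 3
  u_hum <- user
  u_hum$voicing_dropout <- 0      # a hum is continuously voiced
  hum <- simulate_user_track(spec$target, u_hum, repetition,
                             duration = hum_dur, hop = hop,
                             attempt = attempt,
                             sd_factor = user$hum_sd_factor)
  rest <- simulate_user_track(spec$target, user, repetition,
                              duration = rest_dur, hop = hop,
                              attempt = attempt + 500L)
  new_pitch_track(c(hum$time, rest$time + hum_dur), c(hum$f0, rest$f0),
                  c(hum$voiced, rest$voiced),
                  c(hum$confidence, rest$confidence))
}

#' A population of simulated users
#'
#' Returns a sampling function mapping a participant seed to a
#' [simulated_user()]; participant biases are drawn from a normal
#' distribution, the noise schedule is shared.
#'
#' @param noise_sd_start,noise_sd_end,ar_coefficient,voicing_dropout See
#'   [simulated_user()].
#' @param bias_sd SD (Hz) of the between-participant bias distribution
#'   (default 3).
#' @return A function `(seed) -> simulated_user`.
#' @export
user_population <- function(noise_sd_start = 8, noise_sd_end = 4,
                            bias_sd = 3, ar_coefficient = 0.9,
                            voicing_dropout = 0.05) {
  function(seed) {
    bias <- withr::with_seed(seed, rnorm(1, 0, bias_sd))
    simulated_user(bias = bias, noise_sd_start = noise_sd_start,
                   noise_sd_end = noise_sd_end,
                   ar_coefficient = ar_coefficient,
                   voicing_dropout = voicing_dropout, seed = seed)
  }
}

# questionnaire simulation -----------------------------------------------

clamp_likert <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

simulate_sus_items <- function(n_participants) {
  purrr::map_dfr(seq_len(n_participants), function(p) {
    u <- rnorm(1, 0, 0.5)                       # participant usability trait
    odd <- clamp_likert(rnorm(5, 4.2 + u, 0.7), 1, 5)
    even <- clamp_likert(rnorm(5, 1.8 - u, 0.7), 1, 5)
    resp <- numeric(10)
    resp[c(1, 3, 5, 7, 9)] <- odd
    resp[c(2, 4, 6, 8, 10)] <- even
    tibble(participant = p, item = 1:10, response = resp)
  })
}

simulate_imi_items <- function(n_participants,
                               exercise_types = c("constant", "chanting",
                                                  "stair", "human_curve")) {
  # item means per scale: interest/effort high, competence middling and
  # lower for harder exercises, pressure low
  base <- c(6, 6, 6.2, 6.2, 5.3, 5.3, 2.7, 2.7)
  hardness <- seq(0, 0.9, length.out = length(exercise_types))
  purrr::map_dfr(seq_len(n_participants), function(p) {
    trait <- rnorm(1, 0, 0.4)
    purrr::map_dfr(seq_along(exercise_types), function(e) {
      mu <- base + trait
      mu[5:6] <- mu[5:6] - hardness[e]          # competence drops
      mu[3:4] <- mu[3:4] + 0.3 * hardness[e]    # effort rises
      tibble(participant = p, exercise_type = exercise_types[e],
             item = 1:8, response = clamp_likert(rnorm(8, mu, 0.8), 1, 7))
    })
  })
}

# session generation -----------------------------------------------------

#' Assemble a session dataset
#'
#' @param errors Tibble with columns `participant`, `exercise`,
#'   `repetition`, `exercise_error`, and optionally `mean_pitch`,
#'   `voiced_fraction`, `excluded`.
#' @param sus Optional tibble `participant`, `item` (1-10), `response`
#'   (1-5).
#' @param imi Optional tibble `participant`, `exercise_type`, `item` (1-8),
#'   `response` (1-7).
#' @return A `session_dataset` object.
#' @export
session_dataset <- function(errors, sus = NULL, imi = NULL) {
  errors <- as_tibble(errors)
  stopifnot(all(c("participant", "exercise", "repetition",
                  "exercise_error") %in% names(errors)))
  if (anyDuplicated(errors[c("participant", "exercise", "repetition")])) {
    abort("duplicated (participant, exercise, repetition) rows",
          class = "pitchcoach_bad_dataset")
  }
  if (any(errors$repetition < 1 | errors$repetition > 10)) {
    abort("repetition indices must lie in 1..10",
          class = "pitchcoach_bad_dataset")
  }
  if (!"excluded" %in% names(errors)) errors$excluded <- FALSE
  if (!is.null(sus) && any(sus$response < 1 | sus$response > 5)) {
    abort("SUS responses must lie in 1..5", class = "pitchcoach_bad_dataset")
  }
  if (!is.null(imi) && any(imi$response < 1 | imi$response > 7)) {
    abort("IMI responses must lie in 1..7", class = "pitchcoach_bad_dataset")
  }
  structure(list(errors = errors, sus = sus, imi = imi),
            class = "session_dataset")
}

#' @export
print.session_dataset <- function(x, ...) {
  cat(sprintf("<session_dataset: %d participants, %d exercises, %d records%s>\n",
              dplyr::n_distinct(x$errors$participant),
              dplyr::n_distinct(x$errors$exercise),
              nrow(x$errors),
              if (is.null(x$sus)) "" else ", with questionnaires"))
  invisible(x)
}

#' Generate a full simulated evaluation session
#'
#' Emulates the structure of the in-person evaluation: `n_participants`
#' simulated users each perform 10 repetitions of each exercise in the
#' battery; every repetition is scored with [run_repetition()]. A
#' repetition that cannot be scored (e.g. a chanting hum phase that never
#' advances) is redone with fresh noise, mirroring the study's redo rule;
#' after `max_redo` failures it is recorded as excluded. Optional SUS and
#' IMI questionnaire items are simulated alongside.
#'
#' @param n_participants Number of simulated participants (default 21, the
#'   evaluated sample size).
#' @param exercises Named list of [exercise_spec()]s (default
#'   [exercise_battery()]).
#' @param population A function `(seed) -> simulated_user`, e.g.
#'   [user_population()].
#' @param seed Master seed; the dataset is a pure function of it.
#' @param questionnaires Simulate SUS/IMI items too? Default `TRUE`.
#' @param max_redo Redo cap per repetition (default 25).
#' @return A [session_dataset()].
#' @export
generate_session <- function(n_participants = 21,
                             exercises = exercise_battery(),
                             population = user_population(),
                             seed = 1L, questionnaires = TRUE,
                             max_redo = 25L) {
  if (length(exercises) == 0) {
    abort("need at least one exercise", class = "pitchcoach_bad_spec")
  }
  if (is.null(names(exercises)) || any(names(exercises) == "")) {
    names(exercises) <- vapply(exercises, `[[`, character(1), "kind")
  }
  p_seeds <- withr::with_seed(seed,
                              sample.int(2147483646, n_participants))
  n_rec <- n_participants * length(exercises) * 10L
  col_p <- integer(n_rec); col_ex <- integer(n_rec); col_r <- integer(n_rec)
  col_err <- col_mp <- col_vf <- rep(NA_real_, n_rec)
  col_excl <- logical(n_rec)
  k <- 0L
  for (p in seq_len(n_participants)) {
    user <- population(p_seeds[p])
    for (ex in seq_along(exercises)) {
      spec <- exercises[[ex]]
      # per-exercise user clone with a distinct seed stream
      u <- user
      u$seed <- rep_seed(user$seed, ex * 101L)
      dur <- sim_track_duration(spec)
      for (r in 1:10) {
        rec <- NULL
        for (attempt in 0:max_redo) {
          trk <- if (spec$kind == "chanting") {
            simulate_chanting_track(spec, u, r, attempt = attempt)
          } else {
            simulate_user_track(spec$target, u, r, duration = dur,
                                attempt = attempt)
          }
          rec <- tryCatch(score_repetition(trk, spec),
                          error = function(e) NULL)
          if (!is.null(rec)) break
        }
        k <- k + 1L
        col_p[k] <- p; col_ex[k] <- ex; col_r[k] <- r
        if (is.null(rec)) {
          col_excl[k] <- TRUE
        } else {
          col_err[k] <- rec$exercise_error
          col_mp[k] <- rec$mean_pitch
          col_vf[k] <- rec$voiced_fraction
        }
      }
    }
  }
  errors <- new_tibble(
    list(participant = col_p, exercise = names(exercises)[col_ex],
         repetition = col_r, exercise_error = col_err, mean_pitch = col_mp,
         voiced_fraction = col_vf, excluded = col_excl),
    nrow = n_rec)
  sus <- imi <- NULL
  if (questionnaires) {
    withr::with_seed(rep_seed(seed, 999L), {
      sus <- simulate_sus_items(n_participants)
      imi <- simulate_imi_items(n_participants)
    })
  }
  session_dataset(errors, sus, imi)
}

# simulated track duration per exercise kind: constant_i holds slightly past
# the 5 s scoring window; chanting spans hum + chant + free speech
sim_track_duration <- function(spec) {
  switch(spec$kind,
    constant_i = spec$repetition_duration + 0.5,
    constant_reading = 4,
    chanting = spec$dwell_advance + spec$chant_duration + 4,
    spec$repetition_duration
  )
}
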