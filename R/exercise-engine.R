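# Exercise session logic: repetition windows, the chanting phase machine,
# the per-repetition exercise-error metric, and the assessment routine.
#
# The exercise error is the session's performance currency: the mean
# absolute difference (Hz) between the target pitch and the user's voiced
# pitch over a defined repetition window. Unvoiced frames carry no pitch and
# are excluded from the mean; a voiced_fraction field is kept so sparse
# repetitions can be flagged.

EXERCISE_KINDS <- c("constant_i", "constant_reading", "chanting",
                    "stair_i", "stair_phrase", "human_curve")

#' Exercise specification
#'
#' Binds a target curve to the session rules of one of the six evaluated
#' exercise kinds (the human-curve kind is instantiated once per vocal
#' model, giving the seven evaluated exercises).
#'
#' @param kind One of `"constant_i"`, `"constant_reading"`, `"chanting"`,
#'   `"stair_i"`, `"stair_phrase"`, `"human_curve"`.
#' @param target A `target_curve`; defaults to the exercise's standard
#'   target (200 Hz constant; 110/155/200 stair; contour required for
#'   human_curve).
#' @param dwell_advance Chanting hum-phase dwell in seconds (default 1):
#'   the hum phase advances once the pitch has stayed within tolerance for
#'   this long, continuously.
#' @param chant_duration Fixed duration (s) of the chanting middle phase
#'   (default 3).
#' @param repetition_duration Repetition length in seconds where fixed
#'   (constant_i 5 s, stair 6 s, human_curve = contour duration); `NA` for
#'   kinds whose window is data-driven.
#' @param auto_start Whether the live system would auto-start on voice
#'   onset.
#' @param threshold_dbfs Auto-start volume threshold.
#' @param phrase_text Optional phrase.
#' @return An `exercise_spec` object.
#' @export
exercise_spec <- function(kind, target = NULL, dwell_advance = 1,
                          chant_duration = 3, repetition_duration = NULL,
                          auto_start = kind %in% c("stair_i", "stair_phrase"),
                          threshold_dbfs = -40, phrase_text = NULL) {
  kind <- match.arg(kind, EXERCISE_KINDS)
  if (is.null(target)) {
    target <- switch(kind,
      constant_i = constant_target(200, duration = 5),
      constant_reading = constant_target(200, duration = 30),
      chanting = constant_target(200, duration = 30),
      stair_i = stair_target(110, 200, duration = 6),
      stair_phrase = stair_target(110, 200, duration = 6),
      human_curve = abort("human_curve requires an explicit contour target",
                          class = "pitchcoach_bad_spec")
    )
  }
  if (is.null(repetition_duration)) {
    repetition_duration <- switch(kind,
      constant_i = 5, stair_i = 6, stair_phrase = 6,
      human_curve = target$duration,
      NA_real_)
  }
  stopifnot(dwell_advance > 0, chant_duration > 0)
  structure(
    list(kind = kind, target = target, dwell_advance = dwell_advance,
         chant_duration = chant_duration,
         repetition_duration = repetition_duration, auto_start = auto_start,
         threshold_dbfs = threshold_dbfs, phrase_text = phrase_text),
    class = "exercise_spec"
  )
}

#' The seven evaluated exercises
#'
#' The battery used in the in-person performance evaluation: constant /i/,
#' constant reading, chanting, stair /i/, stair phrase, and two human-curve
#' exercises with different vocal models. Synthetic model contours stand in
#' for the human vocal-model recordings.
#'
#' @param seed Seed for the synthetic model contours.
#' @return A named list of [exercise_spec()] objects.
#' @export
exercise_battery <- function(seed = 2024) {
  list(
    constant_i = exercise_spec("constant_i"),
    constant_reading = exercise_spec(
      "constant_reading",
      phrase_text = paste("The rainbow is a division of white light",
                          "into many beautiful colors.")),
    chanting = exercise_spec("chanting", phrase_text = "Mary made me mad"),
    stair_i = exercise_spec("stair_i"),
    stair_phrase = exercise_spec("stair_phrase",
                                 phrase_text = "bigger and better"),
    human_curve_1 = exercise_spec(
      "human_curve",
      target = contour_target(synthetic_model_contour("model1", seed = seed)),
      phrase_text = "bathrobe and slippers"),
    human_curve_pref = exercise_spec(
      "human_curve",
      target = contour_target(synthetic_model_contour("model2",
                                                      seed = seed + 1)),
      phrase_text = "bathrobe and slippers")
  )
}

# track helpers ----------------------------------------------------------

track_hop <- function(track) {
  if (nrow(track) > 1) median(diff(track$time)) else 0.01
}

#' Repetition window for an exercise
#'
#' Determines the `[t0, t1)` scoring window for one repetition: 5 s from
#' the first voiced frame for constant /i/; first to last voiced frame for
#' constant reading; the fixed recording span for stair and human-curve
#' (auto-started, so the window begins at the track origin); the
#' no-feedback free-speech phase for chanting.
#'
#' @param track A [pitch_track()].
#' @param spec An [exercise_spec()].
#' @return Numeric `c(t0, t1)`.
#' @export
repetition_window <- function(track, spec) {
  if (!any(track$voiced)) {
    abort("track contains no voiced frames", class = "pitchcoach_no_voicing")
  }
  hop <- track_hop(track)
  t_end <- track$time[nrow(track)] + hop
  switch(spec$kind,
    constant_i = {
      t0 <- track$time[which(track$voiced)[1]]
      t1 <- t0 + spec$repetition_duration
      if (t_end + 1e-9 < t1) {
        abort("track shorter than the required repetition window",
              class = "pitchcoach_track_too_short")
      }
      c(t0, t1)
    },
    constant_reading = {
      v <- which(track$voiced)
      c(track$time[v[1]], track$time[v[length(v)]] + hop / 2)
    },
    chanting = {
      trace <- run_chanting(track, spec)
      if (!trace$advanced) {
        abort("chanting hum phase never advanced; no free-speech window",
              class = "pitchcoach_no_advance")
      }
      c(trace$free_speech_start, t_end)
    },
    # stair and human_curve: recording start to automatic end
    {
      t1 <- track$time[1] + spec$repetition_duration
      c(track$time[1], min(t1, t_end))
    }
  )
}

#' Exercise error over a window
#'
#' Mean absolute difference in Hz between the user's voiced pitch and the
#' target, with the target clock starting at the window start. Unvoiced
#' frames are excluded.
#'
#' @param track A [pitch_track()].
#' @param target A `target_curve`.
#' @param window Numeric `c(t0, t1)` in seconds.
#' @return Error in Hz (non-negative).
#' @export
exercise_error <- function(track, target, window) {
  rel <- track$time - window[1]
  keep <- track$voiced & track$time >= window[1] & track$time < window[2] &
    rel >= 0 & rel < target$duration
  if (!any(keep)) {
    abort("no voiced frames with a defined target in the window",
          class = "pitchcoach_no_voicing")
  }
  mean(abs(track$f0[keep] - target_value(target, rel[keep])))
}

#' Run the chanting phase machine
#'
#' Phase 1 (hum): the user holds the target; once the pitch stays within
#' tolerance continuously for `dwell_advance` seconds the exercise advances.
#' Phase 2 (chant) lasts `chant_duration` seconds. Phase 3 (free speech,
#' feedback removed) runs to the end of the track and supplies both the
#' displayed mean pitch and the chanting exercise error.
#'
#' @param track A [pitch_track()].
#' @param spec A chanting [exercise_spec()].
#' @return A `chanting_trace` list: `advanced`, `tolerance_entry`,
#'   `advance_time` (= entry + dwell), `free_speech_start`,
#'   `final_phase_mean_pitch`, `exercise_error` (the last two `NA` when the
#'   hum phase never advanced or the free phase is silent).
#' @export
run_chanting <- function(track, spec) {
  stopifnot(spec$kind == "chanting")
  in_tol <- if (spec$target$kind == "constant") {
    # constant target: tolerance band reduces to fixed Hz bounds
    b <- if (spec$target$tolerance_unit == "cents") {
      spec$target$value * 2^(c(-1, 1) * spec$target$tolerance / 1200)
    } else {
      spec$target$value + c(-1, 1) * spec$target$tolerance
    }
    track$voiced & !is.na(track$f0) & track$f0 >= b[1] & track$f0 <= b[2]
  } else {
    tol_t <- pmin(track$time, spec$target$duration - 1e-9)
    track$voiced &
      within_tolerance(ifelse(track$voiced, track$f0, 1), spec$target, tol_t)
  }
  hop <- track_hop(track)
  trace <- list(advanced = FALSE, tolerance_entry = NA_real_,
                advance_time = NA_real_, free_speech_start = NA_real_,
                final_phase_mean_pitch = NA_real_, exercise_error = NA_real_)
  class(trace) <- "chanting_trace"
  r <- rle(in_tol)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    entry <- track$time[starts[j]]
    # continuous dwell spanned by this run, counting the frame's own hop
    span <- track$time[ends[j]] - entry + hop
    if (span >= spec$dwell_advance) {
      trace$advanced <- TRUE
      trace$tolerance_entry <- entry
      trace$advance_time <- entry + spec$dwell_advance
      trace$free_speech_start <- trace$advance_time + spec$chant_duration
      break
    }
  }
  if (trace$advanced) {
    free <- c(trace$free_speech_start, track$time[nrow(track)] + hop)
    keep <- track$voiced & track$time >= free[1] & track$time < free[2]
    if (any(keep)) {
      trace$final_phase_mean_pitch <- mean(track$f0[keep])
      trace$exercise_error <-
        mean(abs(track$f0[keep] - spec$target$value))
    }
  }
  trace
}

#' @export
print.chanting_trace <- function(x, ...) {
  if (x$advanced) {
    cat(sprintf(paste0("<chanting_trace: advanced at %.2f s, free speech from",
                       " %.2f s, mean pitch %.1f Hz, error %.1f Hz>\n"),
                x$advance_time, x$free_speech_start,
                x$final_phase_mean_pitch, x$exercise_error))
  } else {
    cat("<chanting_trace: hum phase never advanced>\n")
  }
  invisible(x)
}

# internal fast path shared by run_repetition and generate_session:
# returns a plain list(t0, t1, exercise_error, mean_pitch, voiced_fraction)
score_repetition <- function(track, spec) {
  if (spec$kind == "chanting") {
    trace <- run_chanting(track, spec)
    if (!trace$advanced || is.na(trace$exercise_error)) {
      abort("chanting repetition has no scoreable free-speech phase",
            class = "pitchcoach_no_advance")
    }
    win <- c(trace$free_speech_start,
             track$time[nrow(track)] + track_hop(track))
    err <- trace$exercise_error
    mp <- trace$final_phase_mean_pitch
  } else {
    win <- repetition_window(track, spec)
    err <- exercise_error(track, spec$target, win)
    mp <- mean_pitch(track, win)
  }
  in_win <- track$time >= win[1] & track$time < win[2]
  list(t0 = win[1], t1 = win[2], exercise_error = err, mean_pitch = mp,
       voiced_fraction = mean(track$voiced[in_win]))
}

#' Score one exercise repetition
#'
#' Composes [repetition_window()], [exercise_error()] and [mean_pitch()]
#' into a one-row repetition record.
#'
#' @param track A [pitch_track()].
#' @param spec An [exercise_spec()].
#' @param index Repetition index (1-10 in the evaluated protocol).
#' @return A one-row tibble: `repetition`, `t0`, `t1`, `exercise_error`
#'   (Hz), `mean_pitch` (Hz), `voiced_fraction`.
#' @export
run_repetition <- function(track, spec, index = 1L) {
  rec <- score_repetition(track, spec)
  new_tibble(c(list(repetition = as.integer(index)), rec), nrow = 1L)
}

#' Baseline voice assessment
#'
#' The assessment routine: a sustained /i/ vowel and a read passage, each
#' summarized by its mean pitch (with the musical-note reading alongside).
#'
#' @param sustained,reading [audio_signal()]s of the two vocalizations.
#' @param params A [pitch_params()].
#' @return A tibble with one row per vocalization: `vocalization`,
#'   `mean_f0`, `note`, `cents`.
#' @export
assess <- function(sustained, reading, params = pitch_params()) {
  mp <- vapply(list(sustained, reading), function(sig) {
    mean_pitch(estimate_pitch(sig, params))
  }, numeric(1))
  notes <- hz_to_note(mp)
  tibble(
    vocalization = c("sustained_i", "reading"),
    mean_f0 = mp,
    note = notes$note,
    cents = notes$cents
  )
}
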