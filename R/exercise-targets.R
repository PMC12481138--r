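# Target curves for the pitch exercises.
#
# Every exercise presents a target f0 as a function of time over [0,
# duration), together with a tolerance band. "Close enough" is judged in the
# band's own unit: cents (the default, so leniency is independent of pitch
# height — one semitone = 100 cents) or plain Hz.

#' Target curve constructor (internal representation)
#'
#' @param kind One of `"constant"`, `"stair"`, `"contour"`.
#' @param duration Seconds.
#' @param tolerance Band half-width.
#' @param tolerance_unit `"cents"` or `"hz"`.
#' @keywords internal
new_target_curve <- function(kind, duration, tolerance, tolerance_unit,
                             value = NULL, levels = NULL, boundaries = numeric(),
                             grid_time = NULL, grid_f0 = NULL) {
  stopifnot(duration > 0, tolerance >= 0)
  tolerance_unit <- match.arg(tolerance_unit, c("cents", "hz"))
  structure(
    list(kind = kind, duration = duration, tolerance = tolerance,
         tolerance_unit = tolerance_unit, value = value, levels = levels,
         segment_boundaries = boundaries,
         grid_time = grid_time, grid_f0 = grid_f0),
    class = "target_curve"
  )
}

#' @export
print.target_curve <- function(x, ...) {
  cat(sprintf("<target_curve: %s, %.2f s, tolerance %g %s>\n",
              x$kind, x$duration, x$tolerance, x$tolerance_unit))
  invisible(x)
}

check_pitch_range <- function(f, what = "target frequency") {
  if (any(f < PITCH_RANGE_HZ[1] | f > PITCH_RANGE_HZ[2])) {
    abort(sprintf("%s outside the admissible range [%g, %g] Hz",
                  what, PITCH_RANGE_HZ[1], PITCH_RANGE_HZ[2]),
          class = "pitchcoach_range_error")
  }
  invisible(f)
}

#' Constant-pitch target
#'
#' A flat target line, 200 Hz by default — the default target of the
#' constant-pitch exercise.
#'
#' @param f Target frequency in Hz, within `[50, 600]`.
#' @param duration Seconds (default 5).
#' @param tolerance Band half-width (default 100, i.e. one semitone).
#' @param tolerance_unit `"cents"` (default) or `"hz"`.
#' @return A `target_curve`.
#' @export
constant_target <- function(f = 200, duration = 5, tolerance = 100,
                            tolerance_unit = "cents") {
  check_pitch_range(f)
  new_target_curve("constant", duration, tolerance, tolerance_unit, value = f)
}

#' Stair target: low-medium-high-medium-low
#'
#' Five equal-duration segments at `[low, mid, high, mid, low]` with the
#' middle level set midway between low and high. Defaults 110 and 200 Hz
#' give the classic 110/155/200 staircase.
#'
#' @param low,high Outer pitch levels in Hz, `50 <= low <= high <= 600`.
#' @param duration Total duration in seconds (default 6).
#' @inheritParams constant_target
#' @return A `target_curve` with `segment_boundaries` at the four internal
#'   fifths.
#' @export
stair_target <- function(low = 110, high = 200, duration = 6, tolerance = 100,
                         tolerance_unit = "cents") {
  check_pitch_range(c(low, high))
  if (low > high) {
    abort("`low` must not exceed `high`", class = "pitchcoach_range_error")
  }
  mid <- (low + high) / 2
  new_target_curve("stair", duration, tolerance, tolerance_unit,
                   levels = c(low, mid, high, mid, low),
                   boundaries = duration * (1:4) / 5)
}

#' Contour target from a vocal-model contour
#'
#' Linear interpolation of a uniformly gridded model pitch contour — the
#' target of the human-curve (imitation) exercise.
#'
#' @param model A [model_contour()].
#' @inheritParams constant_target
#' @return A `target_curve` of kind `"contour"` spanning the contour's
#'   duration.
#' @export
contour_target <- function(model, tolerance = 100, tolerance_unit = "cents") {
  stopifnot(inherits(model, "model_contour"))
  n <- length(model$f0)
  new_target_curve("contour", n * model$grid_step, tolerance, tolerance_unit,
                   grid_time = (seq_len(n) - 1) * model$grid_step,
                   grid_f0 = model$f0)
}

#' Evaluate a target curve
#'
#' @param curve A `target_curve`.
#' @param t Time(s) in seconds, each in `[0, duration)`.
#' @return Target frequency in Hz at each `t`.
#' @export
target_value <- function(curve, t) {
  if (any(t < 0 | t >= curve$duration)) {
    abort("t outside the curve domain [0, duration)",
          class = "pitchcoach_domain_error")
  }
  switch(curve$kind,
    constant = rep(curve$value, length(t)),
    # small epsilon keeps half-open boundaries stable under float jitter
    stair = curve$levels[pmin(floor(t / curve$duration * 5 + 1e-9) + 1, 5)],
    contour = if (length(curve$grid_f0) == 1) {
      rep(curve$grid_f0, length(t))
    } else {
      approx(curve$grid_time, curve$grid_f0, xout = t, rule = 2)$y
    }
  )
}

#' Is a pitch within the target's tolerance band?
#'
#' Deviation is measured in the curve's tolerance unit: cents
#' (`1200 * log2(f_user / target)`) or Hz (`f_user - target`). This is the
#' offline twin of the display's colour-change success cue.
#'
#' @param f_user User pitch in Hz (vectorized).
#' @param curve A `target_curve`.
#' @param t Time(s) in `[0, duration)`, same length as `f_user` or scalar.
#' @return Logical vector.
#' @export
within_tolerance <- function(f_user, curve, t) {
  target <- target_value(curve, t)
  dev <- if (curve$tolerance_unit == "cents") {
    1200 * log2(f_user / target)
  } else {
    f_user - target
  }
  abs(dev) <= curve$tolerance
}

# model contours ---------------------------------------------------------

#' Vocal-model contour
#'
#' A uniformly gridded pitch contour of a recorded (or synthesized) vocal
#' model speaking a phrase; grid point `k` sits at `(k-1) * grid_step`
#' seconds and the contour spans `length(f0) * grid_step` seconds.
#'
#' @param f0 Grid f0 values (Hz, all within `[50, 600]`).
#' @param grid_step Grid step in seconds (default 0.01).
#' @param phrase_text The spoken phrase.
#' @param speaker_id Label for the vocal model.
#' @param stressed_syllable Optional stressed-syllable index (heteronym use).
#' @param source_audio Optional path of the audio the contour came from.
#' @return A `model_contour` object.
#' @export
model_contour <- function(f0, grid_step = 0.01, phrase_text = "",
                          speaker_id = "model", stressed_syllable = NULL,
                          source_audio = NULL) {
  if (length(f0) == 0) {
    abort("contour must contain at least one f0 value",
          class = "pitchcoach_empty_contour")
  }
  stopifnot(grid_step > 0)
  check_pitch_range(f0, "contour f0")
  structure(
    list(f0 = as.numeric(f0), grid_step = grid_step,
         duration = length(f0) * grid_step, phrase_text = phrase_text,
         speaker_id = speaker_id, stressed_syllable = stressed_syllable,
         source_audio = source_audio),
    class = "model_contour"
  )
}

#' @export
print.model_contour <- function(x, ...) {
  cat(sprintf("<model_contour: \"%s\" (%s), %.2f s, %g-%g Hz>\n",
              x$phrase_text, x$speaker_id, x$duration,
              min(x$f0), max(x$f0)))
  invisible(x)
}

#' Extract a vocal-model contour from audio
#'
#' Runs the pitch estimator, keeps the voiced extent, linearly bridges
#' unvoiced gaps shorter than `bridge_limit`, truncates at the first longer
#' gap, and resamples onto a uniform grid.
#'
#' @param signal An [audio_signal()].
#' @param phrase_text,speaker_id Metadata for the contour.
#' @param params A [pitch_params()].
#' @param grid_step Output grid step in seconds (default 0.01).
#' @param bridge_limit Longest unvoiced gap (s) to interpolate across
#'   (default 0.25).
#' @return A [model_contour()].
#' @export
extract_contour <- function(signal, phrase_text = "", speaker_id = "model",
                            params = pitch_params(), grid_step = 0.01,
                            bridge_limit = 0.25) {
  trk <- estimate_pitch(signal, params)
  tv <- trk$time[trk$voiced]
  fv <- trk$f0[trk$voiced]
  if (length(tv) == 0) {
    abort("no voiced frames found in the model recording",
          class = "pitchcoach_no_voicing")
  }
  gaps <- diff(tv)
  cut <- which(gaps > bridge_limit)
  if (length(cut) > 0) {
    keep <- seq_len(cut[1])
    tv <- tv[keep]
    fv <- fv[keep]
  }
  grid <- seq(tv[1], tv[length(tv)], by = grid_step)
  f0 <- if (length(tv) == 1) rep(fv, length(grid)) else {
    approx(tv, fv, xout = grid, rule = 2)$y
  }
  model_contour(pmin(pmax(f0, PITCH_RANGE_HZ[1]), PITCH_RANGE_HZ[2]),
                grid_step = grid_step, phrase_text = phrase_text,
                speaker_id = speaker_id)
}

# JSON serialization -----------------------------------------------------

#' Write / read a model contour as versioned JSON
#'
#' The JSON schema (`pitchcoach-contour/1`) is the content format for
#' human-curve and heteronym exercise files.
#'
#' @param model A [model_contour()].
#' @param path File path.
#' @return `read_contour` returns a [model_contour()]; `write_contour`
#'   returns `path` invisibly.
#' @export
write_contour <- function(model, path) {
  stopifnot(inherits(model, "model_contour"))
  jsonlite::write_json(
    list(schema = "pitchcoach-contour/1",
         phrase_text = model$phrase_text,
         speaker_id = model$speaker_id,
         grid_step = model$grid_step,
         stressed_syllable = model$stressed_syllable,
         f0 = model$f0),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_contour
#' @export
read_contour <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "pitchcoach-contour/1")) {
    abort("not a pitchcoach contour file (unknown schema)",
          class = "pitchcoach_bad_schema")
  }
  model_contour(x$f0, grid_step = x$grid_step, phrase_text = x$phrase_text,
                speaker_id = x$speaker_id,
                stressed_syllable = x$stressed_syllable)
}
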