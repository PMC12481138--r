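# Plain-text serialization: pitch tracks and session tables as CSV.

#' Write / read a pitch track
#'
#' CSV by default (columns `time_s`, `f0_hz` — empty when unvoiced —
#' `voiced`, `confidence`); a `.json` path switches both functions to JSON
#' with the same fields.
#'
#' @param track A [pitch_track()].
#' @param path File path (`.csv` or `.json`).
#' @return `read_pitch_track` returns a [pitch_track()]; the writer returns
#'   `path` invisibly.
#' @export
write_pitch_track <- function(track, path) {
  tab <- tibble(time_s = track$time, f0_hz = track$f0,
                voiced = track$voiced, confidence = track$confidence)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(tab), path, digits = NA, null = "null")
  } else {
    readr::write_csv(tab, path)
  }
  invisible(path)
}

#' @rdname write_pitch_track
#' @export
read_pitch_track <- function(path) {
  if (grepl("\\.json$", path)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(pitch_track(x$time_s, x$f0_hz, x$voiced, x$confidence))
  }
  x <- readr::read_csv(path, show_col_types = FALSE)
  pitch_track(x$time_s, x$f0_hz, x$voiced, x$confidence)
}

#' Write / read an exercise spec as JSON
#'
#' Serializes the exercise kind, its session rules and its target curve
#' (constant and stair fully; contour targets embed their grid).
#'
#' @param spec An [exercise_spec()].
#' @param path File path.
#' @return `read_exercise_spec` returns an [exercise_spec()]; the writer
#'   returns `path` invisibly.
#' @export
write_exercise_spec <- function(spec, path) {
  stopifnot(inherits(spec, "exercise_spec"))
  tg <- spec$target
  target <- list(kind = tg$kind, duration = tg$duration,
                 tolerance = tg$tolerance,
                 tolerance_unit = tg$tolerance_unit)
  if (tg$kind == "constant") target$value <- tg$value
  if (tg$kind == "stair") target$levels <- tg$levels
  if (tg$kind == "contour") {
    target$grid_time <- tg$grid_time
    target$grid_f0 <- tg$grid_f0
  }
  jsonlite::write_json(
    list(schema = "pitchcoach-exercise/1", kind = spec$kind,
         dwell_advance = spec$dwell_advance,
         chant_duration = spec$chant_duration,
         repetition_duration = spec$repetition_duration,
         auto_start = spec$auto_start, threshold_dbfs = spec$threshold_dbfs,
         phrase_text = spec$phrase_text, target = target),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_exercise_spec
#' @export
read_exercise_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "pitchcoach-exercise/1")) {
    abort("not a pitchcoach exercise file (unknown schema)",
          class = "pitchcoach_bad_schema")
  }
  tg <- x$target
  target <- switch(tg$kind,
    constant = constant_target(tg$value, tg$duration, tg$tolerance,
                               tg$tolerance_unit),
    stair = stair_target(tg$levels[1], tg$levels[3], tg$duration,
                         tg$tolerance, tg$tolerance_unit),
    contour = contour_target(
      model_contour(tg$grid_f0,
                    grid_step = if (length(tg$grid_time) > 1) {
                      tg$grid_time[2] - tg$grid_time[1]
                    } else {
                      tg$duration
                    }),
      tg$tolerance, tg$tolerance_unit)
  )
  exercise_spec(x$kind, target = target, dwell_advance = x$dwell_advance,
                chant_duration = x$chant_duration,
                repetition_duration = x$repetition_duration,
                auto_start = x$auto_start, threshold_dbfs = x$threshold_dbfs,
                phrase_text = x$phrase_text)
}

#' Write a session dataset to CSV files
#'
#' Writes `errors.csv` and, when present, `sus.csv` and `imi.csv` into
#' `dir`.
#'
#' @param data A [session_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_session <- function(data, dir) {
  stopifnot(inherits(data, "session_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(data$errors, file.path(dir, "errors.csv"))
  if (!is.null(data$sus)) readr::write_csv(data$sus, file.path(dir, "sus.csv"))
  if (!is.null(data$imi)) readr::write_csv(data$imi, file.path(dir, "imi.csv"))
  invisible(dir)
}

#' Read a session dataset from CSV files
#'
#' Expects the layout written by [write_session()]: `errors.csv` required,
#' `sus.csv` / `imi.csv` optional.
#'
#' @param dir Directory containing the CSV files.
#' @return A [session_dataset()].
#' @export
read_session <- function(dir) {
  ef <- file.path(dir, "errors.csv")
  if (!file.exists(ef)) {
    abort(paste0("no errors.csv under ", dir),
          class = "pitchcoach_missing_file")
  }
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) readr::read_csv(p, show_col_types = FALSE) else NULL
  }
  session_dataset(readr::read_csv(ef, show_col_types = FALSE),
                  sus = rd("sus.csv"), imi = rd("imi.csv"))
}
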