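# Declarative run configuration shared by the CLI and scripted analyses.

#' Default run configuration
#'
#' All defaults follow the deployed system where it states a value (200 Hz
#' constant target, 110/155/200 Hz stair, 50-600 Hz analysis range, 1 s
#' chanting dwell, alpha = .05) and this package's documented choices
#' otherwise.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    pitch = list(f_min = 50, f_max = 600, window_length = 0.04, hop = 0.01,
                 voicing_threshold = 0.45, median_filter_width = 5),
    targets = list(constant_hz = 200, stair_low_hz = 110,
                   stair_high_hz = 200, tolerance = 100,
                   tolerance_unit = "cents"),
    exercise = list(dwell_advance_s = 1, chant_duration_s = 3,
                    constant_i_duration_s = 5, stair_duration_s = 6),
    volume = list(quiet_medium_dbfs = -40, medium_loud_dbfs = -20,
                  onset_threshold_dbfs = -40),
    validation = list(tones_hz = c(110, 155, 200, 300), duration_s = 3,
                      sample_rate_hz = 44100, max_deviation_hz = 5),
    stats = list(alpha = 0.05, sus_benchmark = 70),
    seed = 1
  )
}

merge_config <- function(base, extra) {
  for (k in names(extra)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(extra[[k]])) {
      merge_config(base[[k]], extra[[k]])
    } else {
      extra[[k]]
    }
  }
  base
}

#' Load a run configuration
#'
#' Reads a YAML config file and merges it over [default_config()]; keys not
#' present in the file keep their defaults. `overrides` (a nested list) are
#' applied last.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Nested list of final overrides.
#' @return The merged configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(paste0("config file not found: ", path),
            class = "pitchcoach_missing_file")
    }
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  merge_config(cfg, overrides)
}

#' Pitch parameters from a configuration
#'
#' @param cfg A configuration list as from [load_config()].
#' @return A [pitch_params()].
#' @export
config_pitch_params <- function(cfg = default_config()) {
  p <- cfg$pitch
  pitch_params(p$f_min, p$f_max, p$window_length, p$hop,
               p$voicing_threshold, p$median_filter_width)
}
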