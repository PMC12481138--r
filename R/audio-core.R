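# Audio I/O, framing, loudness and onset detection.
#
# Audio here is always mono, amplitudes in [-1, 1]. Loudness is RMS in dBFS
# (decibels relative to digital full scale); a full-scale sine sits at
# 20*log10(1/sqrt(2)) = -3.01 dBFS.

#' Construct an audio signal
#'
#' A lightweight container for a sampled mono waveform. Most users will get
#' one from [read_wav()] or from the synthesis helpers ([synth_tone()],
#' [synth_voiced()]) rather than calling this directly.
#'
#' @param samples Numeric vector of amplitudes in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (positive integer).
#' @return An object of class `audio_signal` with fields `samples`,
#'   `sample_rate` and derived `duration` (seconds).
#' @examples
#' sig <- audio_signal(sin(2 * pi * 220 * seq(0, 1, by = 1 / 8000)), 8000)
#' sig$duration
#' @export
audio_signal <- function(samples, sample_rate) {
  if (length(samples) == 0) {
    abort("audio signal must contain at least one sample",
          class = "pitchcoach_empty_signal")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    abort("`sample_rate` must be a single positive number",
          class = "pitchcoach_bad_rate")
  }
  if (!all(is.finite(samples))) {
    abort("audio samples must all be finite", class = "pitchcoach_bad_samples")
  }
  structure(
    list(
      samples = as.numeric(samples),
      sample_rate = as.numeric(sample_rate),
      duration = length(samples) / sample_rate
    ),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %.3f s @ %g Hz, peak %.3f>\n",
              x$duration, x$sample_rate, max(abs(x$samples))))
  invisible(x)
}

#' Frame plan for short-time analysis
#'
#' Defines how a signal is cut into overlapping analysis frames. Frame
#' timestamps follow the frame-centre convention: frame `i` (1-based) covers
#' `[(i-1)*hop, (i-1)*hop + window_length)` seconds and is stamped at the
#' centre of that interval.
#'
#' @param window_length Window length in seconds. Default 0.04 s, at least
#'   two periods of the 50 Hz lower pitch bound.
#' @param hop Hop between frame starts in seconds. Default 0.01 s.
#' @return A `frame_plan` object.
#' @export
frame_plan <- function(window_length = 0.04, hop = 0.01) {
  if (!(hop > 0 && hop <= window_length)) {
    abort("need 0 < hop <= window_length", class = "pitchcoach_bad_frame_plan")
  }
  structure(list(window_length = window_length, hop = hop),
            class = "frame_plan")
}

# frame start sample indices (1-based) for a signal under a plan;
# integer(0) when the signal is shorter than one window
frame_starts <- function(signal, plan) {
  n <- length(signal$samples)
  win <- round(plan$window_length * signal$sample_rate)
  hop <- plan$hop * signal$sample_rate
  if (n < win) return(integer(0))
  n_frames <- floor((n - win) / hop) + 1
  round((seq_len(n_frames) - 1) * hop) + 1L
}

frame_times <- function(signal, plan) {
  starts <- frame_starts(signal, plan)
  (starts - 1) / signal$sample_rate + plan$window_length / 2
}

# RIFF/WAVE reading ------------------------------------------------------

#' Read a WAV file
#'
#' Reads PCM 16-bit and IEEE float32 WAV files. Multichannel audio is
#' averaged to a single mono channel; samples are scaled to `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("WAV file not found: ", path), class = "pitchcoach_missing_file")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    abort("not a RIFF/WAVE file (missing RIFF header)",
          class = "pitchcoach_wav_format")
  }
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    abort("not a RIFF/WAVE file (missing WAVE tag)",
          class = "pitchcoach_wav_format")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size + size %% 2)
      if (length(body) < 16) {
        abort("truncated fmt chunk", class = "pitchcoach_wav_format")
      }
      u16 <- function(i) sum(as.integer(body[i:(i + 1)]) * c(1, 256))
      u32 <- function(i) sum(as.numeric(body[i:(i + 3)]) * 256^(0:3))
      fmt <- list(
        format = u16(1), channels = u16(3), sample_rate = u32(5),
        bits = u16(15)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      seek(con, size + size %% 2, origin = "current")
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort("WAV file missing fmt or data chunk (corrupt header?)",
          class = "pitchcoach_wav_format")
  }
  nch <- fmt$channels
  if (fmt$format == 1 && fmt$bits == 16) {
    # /32767 mirrors the writer so write -> read is identity to within
    # half a quantization step
    vals <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                    signed = TRUE, endian = "little") / 32767
  } else if (fmt$format == 3 && fmt$bits == 32) {
    vals <- readBin(data_raw, "double", length(data_raw) / 4, size = 4,
                    endian = "little")
  } else {
    abort(sprintf("unsupported WAV encoding (format %d, %d bits)",
                  fmt$format, fmt$bits),
          class = "pitchcoach_wav_format")
  }
  if (nch > 1) {
    vals <- vals[seq_len(length(vals) %/% nch * nch)]
    vals <- rowMeans(matrix(vals, ncol = nch, byrow = TRUE))
  }
  audio_signal(pmax(-1, pmin(1, vals)), fmt$sample_rate)
}

#' Write a WAV file
#'
#' Writes an [audio_signal()] as 16-bit PCM WAV, readable back by
#' [read_wav()] within one quantization step.
#'
#' @param signal An [audio_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- pmax(-1, pmin(1, signal$samples))
  pcm <- as.integer(round(x * 32767))
  sr <- as.integer(round(signal$sample_rate))
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")       # PCM, mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")         # byte rate
  writeBin(c(2L, 16L), con, size = 2, endian = "little")      # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# loudness ---------------------------------------------------------------

#' Frame-wise RMS level in dBFS
#'
#' @param signal An [audio_signal()].
#' @param plan A [frame_plan()].
#' @return A tibble with columns `time` (s, frame centre) and `rms_dbfs`.
#'   Silent frames are clamped at the -80 dBFS floor.
#' @export
rms_level <- function(signal, plan = frame_plan()) {
  starts <- frame_starts(signal, plan)
  if (length(starts) == 0) {
    abort("signal shorter than one analysis window",
          class = "pitchcoach_signal_too_short")
  }
  win <- round(plan$window_length * signal$sample_rate)
  sq <- c(0, cumsum(signal$samples^2))
  ms <- (sq[starts + win] - sq[starts]) / win
  db <- ifelse(ms > 0, 10 * log10(ms), -Inf)
  tibble(
    time = frame_times(signal, plan),
    rms_dbfs = pmax(db, SILENCE_FLOOR_DBFS)
  )
}

#' Classify loudness as quiet, medium or loud
#'
#' Labels follow half-open intervals: quiet below `low`, medium in
#' `[low, high)`, loud at or above `high`.
#'
#' @param rms_dbfs RMS level(s) in dBFS.
#' @param low,high Thresholds in dBFS (defaults -40 and -20).
#' @return An ordered factor with levels quiet < medium < loud.
#' @export
classify_volume <- function(rms_dbfs, low = -40, high = -20) {
  stopifnot(is.finite(rms_dbfs), low < high)
  lab <- ifelse(rms_dbfs < low, "quiet",
                ifelse(rms_dbfs < high, "medium", "loud"))
  factor(lab, levels = c("quiet", "medium", "loud"), ordered = TRUE)
}

#' Detect speech onset by energy thresholding
#'
#' Finds the first analysis frame whose RMS level reaches the start
#' threshold — the rule behind "auto-start" in live exercises.
#'
#' @param signal An [audio_signal()].
#' @param threshold_dbfs Start threshold in dBFS (default -40).
#' @param plan A [frame_plan()].
#' @return Onset time in seconds (frame centre of the first qualifying
#'   frame), or `NA_real_` when no frame reaches the threshold.
#' @export
detect_onset <- function(signal, threshold_dbfs = -40, plan = frame_plan()) {
  lev <- rms_level(signal, plan)
  hit <- which(lev$rms_dbfs >= threshold_dbfs)
  if (length(hit) == 0) return(NA_real_)
  lev$time[hit[1]]
}
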