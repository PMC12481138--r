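# Frame-wise fundamental-frequency (f0) estimation.
#
# The estimator is a normalized autocorrelation method: for each frame the
# normalized cross-correlation function (NCCF)
#
#   r(tau) = sum_t s_t s_{t+tau} / sqrt(sum_t s_t^2 * sum_t s_{t+tau}^2)
#
# is evaluated over candidate lags tau in [sr/f_max, sr/f_min]. Among local
# maxima within a small margin of the global peak, the SHORTEST lag wins
# (periodic signals repeat at every multiple of the true period, so this is
# the standard octave-error guard); parabolic interpolation around the
# chosen peak gives sub-sample lag resolution. Frames whose peak falls below
# the voicing threshold, or whose energy sits at the silence floor, are
# unvoiced. A running median over voiced runs removes isolated octave slips.

#' Pitch analysis parameters
#'
#' @param f_min,f_max Analysis range in Hz (defaults 50 and 600, the
#'   adjustable range of the training display).
#' @param window_length Analysis window in seconds; must cover at least two
#'   periods of `f_min` (default 0.04 s).
#' @param hop Frame hop in seconds (default 0.01 s).
#' @param voicing_threshold Minimum normalized autocorrelation peak for a
#'   frame to count as voiced, in (0, 1). Default 0.45.
#' @param median_filter_width Width (frames, odd) of the median filter run
#'   over voiced stretches. Default 5.
#' @return A `pitch_params` object.
#' @export
pitch_params <- function(f_min = 50, f_max = 600, window_length = 0.04,
                         hop = 0.01, voicing_threshold = 0.45,
                         median_filter_width = 5) {
  if (!(f_min > 0 && f_min < f_max)) {
    abort("need 0 < f_min < f_max", class = "pitchcoach_bad_params")
  }
  if (window_length < 2 / f_min) {
    abort("window_length must be at least 2/f_min seconds",
          class = "pitchcoach_bad_params")
  }
  if (!(voicing_threshold > 0 && voicing_threshold < 1)) {
    abort("voicing_threshold must lie in (0, 1)",
          class = "pitchcoach_bad_params")
  }
  structure(
    list(f_min = f_min, f_max = f_max, window_length = window_length,
         hop = hop, voicing_threshold = voicing_threshold,
         median_filter_width = as.integer(median_filter_width)),
    class = "pitch_params"
  )
}

# pitch_track container --------------------------------------------------

#' Build a pitch track tibble
#'
#' A pitch track is a tibble with one row per analysis frame and columns
#' `time` (s), `f0` (Hz, `NA` when unvoiced), `voiced` (logical) and
#' `confidence` (normalized autocorrelation peak in `[0, 1]`). The analysis
#' parameters travel along as an attribute.
#'
#' @param time,f0,voiced,confidence Equal-length per-frame vectors.
#' @param params The [pitch_params()] used (or `NULL` for simulated tracks).
#' @return A tibble of class `pitch_track`.
#' @export
pitch_track <- function(time, f0, voiced = !is.na(f0),
                        confidence = as.numeric(voiced), params = NULL) {
  n <- length(time)
  stopifnot(length(f0) == n, length(voiced) == n, length(confidence) == n)
  if (n > 1 && any(diff(time) <= 0)) {
    abort("frame times must be strictly increasing",
          class = "pitchcoach_bad_track")
  }
  f0 <- as.numeric(f0)
  voiced <- as.logical(voiced)
  f0[!voiced] <- NA_real_
  new_pitch_track(as.numeric(time), f0, voiced,
                  pmin(pmax(as.numeric(confidence), 0), 1), params)
}

# unvalidated constructor for internal hot paths (inputs known well-formed)
new_pitch_track <- function(time, f0, voiced, confidence, params = NULL) {
  out <- new_tibble(
    list(time = time, f0 = f0, voiced = voiced, confidence = confidence),
    nrow = length(time),
    class = "pitch_track"
  )
  attr(out, "params") <- params
  out
}

#' Estimate the pitch contour of a signal
#'
#' @param signal An [audio_signal()].
#' @param params A [pitch_params()].
#' @return A [pitch_track()] tibble; voiced `f0` values always lie in
#'   `[f_min, f_max]`.
#' @examples
#' sig <- synth_tone(200, duration = 0.5, sample_rate = 16000)
#' trk <- estimate_pitch(sig)
#' mean(trk$f0[trk$voiced])
#' @export
estimate_pitch <- function(signal, params = pitch_params()) {
  stopifnot(inherits(signal, "audio_signal"))
  sr <- signal$sample_rate
  win <- round(params$window_length * sr)
  if (length(signal$samples) < win) {
    abort("signal shorter than one analysis window",
          class = "pitchcoach_signal_too_short")
  }
  pad <- 8L                       # sinc-interpolation support margin (bins)
  max_lag <- min(floor(sr / params$f_min), win - 2L - pad)
  min_lag <- max(2L, ceiling(sr / params$f_max))
  n_sum <- win - max_lag - pad - 1L   # fixed summation length of the NCCF
                                      # (room for interpolation support)
  starts <- frame_starts(signal, frame_plan(params$window_length, params$hop))
  times <- (starts - 1) / sr + params$window_length / 2
  nfr <- length(starts)
  nfft <- 2^ceiling(log2(win + n_sum))

  f0 <- rep(NA_real_, nfr)
  conf <- numeric(nfr)
  lag_idx <- max(2L, min_lag - pad):(max_lag + pad)  # padded support range
  in_range <- lag_idx >= min_lag & lag_idx <= max_lag

  for (i in seq_len(nfr)) {
    s <- signal$samples[starts[i]:(starts[i] + win - 1L)]
    ms <- mean(s^2)
    if (ms <= 10^(SILENCE_FLOOR_DBFS / 10)) next
    a <- s[seq_len(n_sum)]
    cc <- Re(fft(fft(c(s, numeric(nfft - win))) *
                   Conj(fft(c(a, numeric(nfft - n_sum)))), inverse = TRUE)) / nfft
    sq <- c(0, cumsum(s^2))
    e_lag <- sq[lag_idx + n_sum + 1L] - sq[lag_idx + 1L]
    denom <- sqrt(pmax(cc[1] * e_lag, .Machine$double.eps))
    r <- cc[lag_idx + 1L] / denom
    # local maxima in the admissible lag range, compared against their true
    # (finite) neighbours so range-boundary bins are not auto-promoted
    peaks <- which(in_range &
                     r > c(-Inf, head(r, -1)) & r >= c(tail(r, -1), -Inf))
    peaks <- peaks[peaks > 1 & peaks < length(r)]
    if (length(peaks) == 0) next
    # refine every candidate by windowed-sinc interpolation BEFORE
    # comparing: narrow peaks lose height when the true lag falls between
    # bins, which would otherwise favour an exact-integer multiple of the
    # period (an octave-down error)
    ref <- vapply(peaks, function(p) refine_peak(r, p), numeric(2))
    height <- ref[2, ]
    best <- max(height)
    conf[i] <- min(max(best, 0), 1)
    if (best < params$voicing_threshold) next
    p <- which(height >= best - 0.05)[1]      # shortest near-best lag
    lag <- lag_idx[peaks[p]] + ref[1, p]
    f0[i] <- min(max(sr / lag, params$f_min), params$f_max)
  }

  voiced <- !is.na(f0)
  f0 <- smooth_voiced_runs(f0, voiced, params$median_filter_width)
  pitch_track(times, f0, voiced, conf, params)
}

# Interpolate the correlation function around bin p with a Hann-windowed
# sinc kernel on a fine lag grid and refine the located maximum with one
# parabolic step. Returns c(lag offset in bins, interpolated peak height).
refine_peak <- function(r, p, half_width = 8L, step = 0.05) {
  j <- max(1L, p - half_width):min(length(r), p + half_width)
  delta <- seq(-1, 1, by = step)
  x <- outer(delta, j - p, `-`)              # fine offset minus tap offset
  k <- ifelse(x == 0, 1, sin(pi * x) / (pi * x)) *
    0.5 * (1 + cos(pi * pmin(abs(x) / half_width, 1)))
  k <- k / rowSums(k)                        # stabilize clipped edge support
  vals <- pmin(as.numeric(k %*% r[j]), 1)    # |NCCF| cannot exceed 1
  m <- which.max(vals)
  off <- delta[m]
  h <- vals[m]
  if (m > 1 && m < length(vals)) {
    d2 <- vals[m - 1] - 2 * vals[m] + vals[m + 1]
    if (is.finite(d2) && d2 < 0) {
      s <- 0.5 * (vals[m - 1] - vals[m + 1]) / d2
      off <- off + s * step
      h <- vals[m] - 0.25 * (vals[m - 1] - vals[m + 1]) * s
    }
  }
  c(off, h)
}

# median-filter f0 within each contiguous voiced run; runs shorter than the
# filter width pass through unchanged
smooth_voiced_runs <- function(f0, voiced, width) {
  if (width < 3) return(f0)
  if (width %% 2 == 0) width <- width + 1L
  r <- rle(voiced)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values & r$lengths >= width)) {
    idx <- starts[j]:ends[j]
    f0[idx] <- runmed(f0[idx], width, endrule = "median")
  }
  f0
}

#' Mean pitch over a time window
#'
#' Arithmetic mean (in Hz) of the voiced f0 values whose frame time falls in
#' `[t0, t1)`.
#'
#' @param track A [pitch_track()].
#' @param window Numeric `c(t0, t1)` in seconds, or `NULL` for the whole
#'   track.
#' @return Mean pitch in Hz.
#' @export
mean_pitch <- function(track, window = NULL) {
  keep <- track$voiced
  if (!is.null(window)) {
    keep <- keep & track$time >= window[1] & track$time < window[2]
  }
  if (!any(keep)) {
    abort("no voiced frames in the requested window",
          class = "pitchcoach_no_voicing")
  }
  mean(track$f0[keep])
}

# musical notes ----------------------------------------------------------

NOTE_NAMES <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")

#' Convert frequency to the nearest musical note
#'
#' Twelve-tone equal temperament with A4 = 440 Hz. The cents offset lies in
#' `[-50, 50)` so every frequency maps to exactly one note.
#'
#' @param f Frequency (Hz), vectorized; must be positive.
#' @return A tibble with columns `note` (e.g. `"G3"`), `cents` and the input
#'   `frequency`.
#' @examples
#' hz_to_note(c(440, 200))
#' @export
hz_to_note <- function(f) {
  if (any(!is.finite(f) | f <= 0)) {
    abort("frequencies must be positive and finite",
          class = "pitchcoach_bad_frequency")
  }
  midi <- 69 + 12 * log2(f / 440)
  nearest <- floor(midi + 0.5)
  tibble(
    note = paste0(NOTE_NAMES[nearest %% 12 + 1], nearest %/% 12 - 1),
    cents = 100 * (midi - nearest),
    frequency = f
  )
}

#' Convert a musical note back to frequency
#'
#' @param note Note name(s) such as `"A4"` or `"G#3"`.
#' @param cents Cents offset(s), default 0.
#' @return Frequency in Hz.
#' @examples
#' note_to_hz("G3", 35)
#' @export
note_to_hz <- function(note, cents = 0) {
  m <- regmatches(note, regexec("^([A-G]#?)(-?[0-9]+)$", note))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    abort(paste0("unparseable note name: ", note[bad][1]),
          class = "pitchcoach_bad_note")
  }
  pc <- match(vapply(m, `[`, character(1), 2), NOTE_NAMES) - 1
  oct <- as.numeric(vapply(m, `[`, character(1), 3))
  midi <- pc + 12 * (oct + 1) + cents / 100
  440 * 2^((midi - 69) / 12)
}

#' Validate the estimator on pure tones
#'
#' Synthesizes a pure sine at each requested frequency, runs the estimator,
#' and reports the absolute deviation between the known tone frequency and
#' the mean estimated pitch — the development-time validation protocol for
#' the training software's pitch engine.
#'
#' @param frequencies Tone frequencies in Hz; each must lie strictly inside
#'   `(f_min, f_max)`.
#' @param duration Tone duration in seconds (default 3).
#' @param sample_rate Hz (default 44100).
#' @param params A [pitch_params()].
#' @return A tibble with columns `frequency`, `mean_f0`, `deviation` (Hz)
#'   and attribute-free; `max(deviation)` is the headline figure.
#' @export
validate_estimator <- function(frequencies, duration = 3, sample_rate = 44100,
                               params = pitch_params()) {
  if (length(frequencies) == 0) {
    return(tibble(frequency = numeric(), mean_f0 = numeric(),
                  deviation = numeric()))
  }
  if (any(frequencies <= params$f_min | frequencies >= params$f_max)) {
    abort("tone frequencies must lie strictly inside (f_min, f_max)",
          class = "pitchcoach_bad_frequency")
  }
  mean_f0 <- vapply(frequencies, function(f) {
    trk <- estimate_pitch(synth_tone(f, duration, sample_rate), params)
    mean_pitch(trk)
  }, numeric(1))
  tibble(frequency = frequencies, mean_f0 = mean_f0,
         deviation = abs(frequencies - mean_f0))
}
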