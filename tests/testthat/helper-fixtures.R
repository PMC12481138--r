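# shared test fixtures, built in code

# analysis at 22.05 kHz keeps unit tests fast without changing behaviour
SR_TEST <- 22050

# a frame grid that samples segment interiors (offset by half a hop) so
# closed-form expectations over piecewise targets are exact
midpoint_times <- function(duration, hop = 0.01) {
  (seq_len(round(duration / hop)) - 0.5) * hop
}

flat_track <- function(f, duration = 6, hop = 0.01) {
  tm <- midpoint_times(duration, hop)
  pitch_track(tm, rep(f, length(tm)))
}

noiseless_user <- function(bias = 0, seed = 1L) {
  simulated_user(bias = bias, noise_sd_start = 0, noise_sd_end = 0,
                 voicing_dropout = 0, seed = seed)
}
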