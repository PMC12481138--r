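test_that("repetition windows follow each exercise's rule", {
  # constant /i/: 5 s from the first voiced frame
  tm <- midpoint_times(6)
  f0 <- ifelse(tm >= 0.8, 200, NA_real_)
  trk <- pitch_track(tm, f0)
  win <- repetition_window(trk, exercise_spec("constant_i"))
  expect_equal(win[1], tm[tm >= 0.8][1])
  expect_equal(win[2] - win[1], 5)
  # stair: recording start to automatic end
  st <- simulate_user_track(stair_target(), noiseless_user())
  win <- repetition_window(st, exercise_spec("stair_i"))
  expect_equal(win[1], 0)
  expect_equal(win[2], 6, tolerance = 0.011)
  # reading: first to last voiced frame
  f0r <- ifelse(tm >= 0.5 & tm <= 4.2, 190, NA_real_)
  win <- repetition_window(pitch_track(tm, f0r),
                           exercise_spec("constant_reading"))
  expect_lt(abs(win[1] - 0.5), 0.011)
  expect_lt(abs(win[2] - 4.2), 0.011)
  # errors
  silent <- pitch_track(tm, rep(NA_real_, length(tm)),
                        voiced = rep(FALSE, length(tm)))
  expect_error(repetition_window(silent, exercise_spec("constant_i")),
               class = "pitchcoach_no_voicing")
  short <- pitch_track(midpoint_times(2), rep(200, 200))
  expect_error(repetition_window(short, exercise_spec("constant_i")),
               class = "pitchcoach_track_too_short")
})

test_that("exercise error matches closed forms", {
  st <- stair_target()
  # identical to target -> 0
  perfect <- simulate_user_track(st, noiseless_user())
  expect_equal(exercise_error(perfect, st, c(0, 6)), 0)
  # constant offset c -> |c|, for several c
  ct <- constant_target(200, duration = 5)
  for (c_off in c(-25, -10, 0.5, 10, 40)) {
    trk <- flat_track(200 + c_off, duration = 5)
    expect_equal(exercise_error(trk, ct, c(0, 5)), abs(c_off))
  }
  # flat 155 Hz against the default stair: mean(45, 0, 45, 0, 45) = 27
  expect_equal(exercise_error(flat_track(155), st, c(0, 6)), 27)
  # unvoiced frames are excluded, not scored
  tm <- midpoint_times(5)
  f0 <- rep(210, length(tm))
  voiced <- rep(c(TRUE, FALSE), length.out = length(tm))
  trk <- pitch_track(tm, ifelse(voiced, f0, NA), voiced)
  expect_equal(exercise_error(trk, ct, c(0, 5)), 10)
  expect_error(
    exercise_error(pitch_track(tm, rep(NA_real_, 500),
                               voiced = rep(FALSE, 500)), ct, c(0, 5)),
    class = "pitchcoach_no_voicing")
})

test_that("exercise error is invariant to joint time translation", {
  st <- stair_target()
  trk <- simulate_user_track(st, simulated_user(seed = 21))
  e1 <- exercise_error(trk, st, c(0, 6))
  shifted <- pitch_track(trk$time + 2.5, trk$f0, trk$voiced, trk$confidence)
  e2 <- exercise_error(shifted, st, c(2.5, 8.5))
  expect_equal(e1, e2, tolerance = 0.5)
})

test_that("chanting advances after exactly one continuous in-band second", {
  spec <- exercise_spec("chanting")
  tm <- midpoint_times(9)
  # enters tolerance at t = 2.0 and stays
  trk <- pitch_track(tm, ifelse(tm < 2, 150, 200))
  tr <- run_chanting(trk, spec)
  expect_true(tr$advanced)
  expect_equal(tr$advance_time, tr$tolerance_entry + 1)
  expect_lt(abs(tr$advance_time - 3.0), 0.011)
  expect_lt(abs(tr$free_speech_start - 6.0), 0.011)
  expect_equal(tr$final_phase_mean_pitch, 200)
  expect_equal(tr$exercise_error, 0)
  # 0.9 s inside then out: no advance
  f0 <- ifelse(tm >= 1 & tm < 1.9, 200, 150)
  expect_false(run_chanting(pitch_track(tm, f0), spec)$advanced)
  # two 0.6 s bursts separated by an excursion: continuity resets
  f0 <- ifelse((tm >= 1 & tm < 1.6) | (tm >= 2 & tm < 2.6), 200, 150)
  expect_false(run_chanting(pitch_track(tm, f0), spec)$advanced)
})

test_that("chanting advance always honours the dwell lower bound", {
  spec <- exercise_spec("chanting")
  for (s in 1:20) {
    trk <- simulate_chanting_track(spec, simulated_user(seed = s))
    tr <- run_chanting(trk, spec)
    if (tr$advanced) {
      expect_gte(tr$advance_time - tr$tolerance_entry, spec$dwell_advance)
    }
  }
})

test_that("repetition records compose window, error and mean pitch", {
  rec <- run_repetition(simulate_user_track(stair_target(), noiseless_user()),
                        exercise_spec("stair_i"), index = 3)
  expect_equal(rec$repetition, 3L)
  expect_equal(rec$exercise_error, 0)
  # time-weighted stair mean: (110 + 155 + 200 + 155 + 110) / 5
  expect_equal(rec$mean_pitch, 146, tolerance = 1e-6)
  expect_equal(rec$voiced_fraction, 1)
  biased <- simulate_user_track(constant_target(200, duration = 5.5),
                                noiseless_user(bias = 10), duration = 5.5)
  rec2 <- run_repetition(biased, exercise_spec("constant_i"))
  expect_equal(rec2$exercise_error, 10)
  silent <- pitch_track(midpoint_times(6), rep(NA_real_, 600),
                        voiced = rep(FALSE, 600))
  expect_error(run_repetition(silent, exercise_spec("stair_i")),
               class = "pitchcoach_no_voicing")
})

test_that("halved noise SD lowers expected error (Monte-Carlo)", {
  ct <- constant_target(200, duration = 5)
  errs <- vapply(1:200, function(s) {
    u_hi <- simulated_user(noise_sd_start = 10, noise_sd_end = 10, seed = s)
    u_lo <- simulated_user(noise_sd_start = 5, noise_sd_end = 5, seed = s)
    c(exercise_error(simulate_user_track(ct, u_hi), ct, c(0, 5)),
      exercise_error(simulate_user_track(ct, u_lo), ct, c(0, 5)))
  }, numeric(2))
  expect_gt(mean(errs[1, ]) - mean(errs[2, ]), 0)
  expect_equal(mean(errs[1, ]) / mean(errs[2, ]), 2, tolerance = 0.15)
})

test_that("assessment returns mean pitches of both vocalizations", {
  sustained <- synth_voiced(200, 1.5, SR_TEST)
  reading <- synth_voiced(function(t) 180 + 15 * sin(2 * pi * t), 2, SR_TEST)
  res <- assess(sustained, reading)
  expect_equal(res$mean_f0[1], 200, tolerance = 2)
  expect_equal(res$mean_f0[2], 180, tolerance = 2)
  expect_equal(res$note[1], "G3")
  silence <- audio_signal(rep(0, SR_TEST), SR_TEST)
  expect_error(assess(sustained, silence), class = "pitchcoach_no_voicing")
})
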