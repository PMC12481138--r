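test_that("synthesized tones put their spectral peak at the programmed f", {
  for (f in c(110, 200, 340)) {
    sig <- synth_tone(f, 1, SR_TEST)
    spec <- Mod(fft(sig$samples))[1:(SR_TEST / 2)]
    peak_hz <- (which.max(spec) - 1) / 1        # 1 s signal: 1 Hz bins
    expect_lte(abs(peak_hz - f), 1)
  }
  expect_error(synth_tone(200, 0), class = "pitchcoach_bad_spec")
  expect_error(synth_tone(12000, 1, SR_TEST),
               class = "pitchcoach_nyquist_error")
  expect_identical(synth_tone(200, 0.5)$samples,
                   synth_tone(200, 0.5)$samples)
})

test_that("voiced synthesis is deterministic and round-trips estimation", {
  a <- synth_voiced(200, 0.5, SR_TEST, jitter = 0.01, snr_db = 20, seed = 5)
  b <- synth_voiced(200, 0.5, SR_TEST, jitter = 0.01, snr_db = 20, seed = 5)
  expect_identical(a$samples, b$samples)
  c <- synth_voiced(200, 0.5, SR_TEST, jitter = 0.01, snr_db = 20, seed = 6)
  expect_false(identical(a$samples, c$samples))
  # flat pulse train recovered within 2 Hz
  trk <- estimate_pitch(synth_voiced(200, 1, SR_TEST))
  expect_equal(mean_pitch(trk), 200, tolerance = 2)
  # stair-shaped contour reproduces all five plateaus
  st <- stair_target()
  sig <- synth_voiced(function(t) target_value(st, pmin(t, 5.999)), 6, SR_TEST)
  trk <- estimate_pitch(sig)
  for (seg in 0:4) {
    mid <- trk$voiced & trk$time >= seg * 1.2 + 0.3 &
      trk$time < (seg + 1) * 1.2 - 0.3
    expect_equal(mean(trk$f0[mid]), c(110, 155, 200, 155, 110)[seg + 1],
                 tolerance = 2)
  }
  expect_error(synth_voiced(30, 1, SR_TEST), class = "pitchcoach_range_error")
})

test_that("simulated tracks follow target + bias + scheduled AR noise", {
  ct <- constant_target(200, duration = 5)
  expect_equal(exercise_error(simulate_user_track(ct, noiseless_user()),
                              ct, c(0, 5)), 0)
  expect_equal(exercise_error(simulate_user_track(ct, noiseless_user(bias = 10)),
                              ct, c(0, 5)), 10)
  # determinism per (user, repetition); repetitions differ
  u <- simulated_user(seed = 33)
  t1 <- simulate_user_track(ct, u, 2)
  t2 <- simulate_user_track(ct, u, 2)
  expect_identical(t1$f0, t2$f0)
  t3 <- simulate_user_track(ct, u, 3)
  expect_false(identical(t1$f0, t3$f0))
  # improvement schedule is geometric from start to end SD
  expect_equal(u$schedule[1], 8)
  expect_equal(u$schedule[10], 4)
  expect_equal(u$schedule[5] / u$schedule[4], (4 / 8)^(1 / 9),
               tolerance = 1e-12)
})

test_that("AR(1) noise reaches its stationary variance", {
  u <- simulated_user(noise_sd_start = 10, noise_sd_end = 10,
                      ar_coefficient = 0.9, voicing_dropout = 0, seed = 14)
  long <- constant_target(200, duration = 30)
  e <- unlist(lapply(1:2, function(r) {
    simulate_user_track(long, u, r, duration = 60)$f0 - 200
  }))
  n_eff <- length(e) * (1 - 0.9) / (1 + 0.9)   # autocorrelation-adjusted
  se <- 100 * sqrt(2 / n_eff)                  # SE of a variance estimate
  expect_lt(abs(var(e) - 100), 3 * se)
})

test_that("generated sessions have the study's structure and determinism", {
  ds <- generate_session(n_participants = 4, seed = 101)
  expect_s3_class(ds, "session_dataset")
  expect_equal(nrow(ds$errors), 4 * 7 * 10)
  expect_setequal(unique(ds$errors$repetition), 1:10)
  expect_equal(nrow(ds$sus), 40)
  expect_equal(nrow(ds$imi), 4 * 4 * 8)
  expect_true(all(ds$sus$response %in% 1:5))
  expect_true(all(ds$imi$response %in% 1:7))
  ds2 <- generate_session(n_participants = 4, seed = 101)
  expect_identical(ds$errors, ds2$errors)
  ds3 <- generate_session(n_participants = 4, seed = 102)
  expect_false(identical(ds$errors$exercise_error, ds3$errors$exercise_error))
  expect_error(generate_session(2, exercises = list()),
               class = "pitchcoach_bad_spec")
})

test_that("audio-domain and pitch-domain user paths agree on bias recovery", {
  # a biased noiseless user rendered to audio, re-estimated, and scored
  ct <- constant_target(200, duration = 2)
  u <- noiseless_user(bias = 12)
  trk_pitch <- simulate_user_track(ct, u, duration = 2)
  sig <- synth_voiced(trk_pitch$f0, 2, SR_TEST)
  trk_audio <- estimate_pitch(sig)
  e_pitch <- exercise_error(trk_pitch, ct, c(0, 2))
  e_audio <- exercise_error(trk_audio, ct, c(0, 2))
  expect_equal(e_pitch, 12)
  expect_equal(e_audio, 12, tolerance = 1)
})

test_that("duplicate or out-of-range session rows are rejected", {
  errs <- tibble::tibble(participant = c(1, 1), exercise = "constant_i",
                         repetition = c(2, 2), exercise_error = c(1, 2))
  expect_error(session_dataset(errs), class = "pitchcoach_bad_dataset")
  errs$repetition <- c(2, 11)
  expect_error(session_dataset(errs), class = "pitchcoach_bad_dataset")
  sus <- tibble::tibble(participant = 1, item = 1, response = 9)
  ok <- tibble::tibble(participant = 1, exercise = "constant_i",
                       repetition = 1, exercise_error = 1)
  expect_error(session_dataset(ok, sus = sus),
               class = "pitchcoach_bad_dataset")
})
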