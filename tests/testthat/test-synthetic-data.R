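test_that("zero-jitter patterns generate exact nominal grids", {
  dk <- generate_impact_train(double_knock_pattern(inter_knock_interval_s = 0.1))
  expect_equal(nrow(dk), 2L)
  expect_equal(diff(dk$time_s), 0.1)
  expect_equal(dk$amplitude, c(1, 0.8))
  dr <- generate_impact_train(drum_roll_pattern(n_knocks = 10, period_s = 0.06))
  expect_equal(nrow(dr), 10L)
  expect_equal(diff(dr$time_s), rep(0.06, 9))
  expect_equal(dr$amplitude, 0.95^(0:9))
})

test_that("jittered drum-roll intervals average to the period within the sampling bound", {
  pat <- drum_roll_pattern(n_knocks = 1000, period_s = 0.06,
                           timing_jitter_sd_s = 0.005, seed = 42)
  tr <- generate_impact_train(pat)
  bound <- 3 * (0.005 * sqrt(2)) / sqrt(999)
  expect_lt(abs(mean(diff(tr$time_s)) - 0.06), bound)
})

test_that("generators are deterministic under a fixed seed", {
  a <- generate_impact_train(drum_roll_pattern(n_knocks = 20, timing_jitter_sd_s = 0.004, seed = 7))
  b <- generate_impact_train(drum_roll_pattern(n_knocks = 20, timing_jitter_sd_s = 0.004, seed = 7))
  c <- generate_impact_train(drum_roll_pattern(n_knocks = 20, timing_jitter_sd_s = 0.004, seed = 8))
  expect_identical(a, b)
  expect_false(identical(a, c))
  s1 <- generate_flap_sequence(7, 0.7, 60, 30, jitter_frames_sd = 1, seed = 11)
  s2 <- generate_flap_sequence(7, 0.7, 60, 30, jitter_frames_sd = 1, seed = 11)
  expect_identical(s1, s2)
})

test_that("rendered audio peaks at the knock and envelope maxima track knock spacing", {
  spec <- audio_render_spec(noise_rms = 0)
  one <- generate_impact_train(double_knock_pattern())[1, , drop = FALSE]
  class(one) <- c("knock_train", "data.frame")
  au <- render_audio(one, spec)
  t_peak <- (which.max(abs(au$samples)) - 1) / au$sample_rate_hz
  # first ring maximum: within a quarter ring period (plus one sample) of onset
  expect_lt(abs(t_peak - one$time_s[1]),
            1 / (4 * spec$knock_ring_freq_hz) + 1 / au$sample_rate_hz)

  two <- generate_impact_train(double_knock_pattern(inter_knock_interval_s = 0.1))
  au2 <- render_audio(two, spec)
  # direct envelope computation: moving RMS, local maxima above half range
  nw <- round(0.005 * au2$sample_rate_hz)
  env <- as.numeric(stats::filter(au2$samples^2, rep(1 / nw, nw), sides = 1))
  env[is.na(env)] <- 0
  pk <- which(diff(sign(diff(env))) < 0) + 1L
  pk <- pk[env[pk] > 0.25 * max(env)]
  # collapse ripple maxima closer than 20 ms, keep the largest per cluster
  keep <- integer()
  for (i in pk) {
    if (length(keep) && (i - keep[length(keep)]) < 0.02 * au2$sample_rate_hz) {
      if (env[i] > env[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  expect_length(keep, 2L)
  expect_lt(abs(diff(keep) / au2$sample_rate_hz - 0.1), 0.002)
})

test_that("audio rendering validates its inputs", {
  empty <- structure(data.frame(time_s = numeric(), amplitude = numeric()),
                     class = c("knock_train", "data.frame"))
  expect_error(render_audio(empty), "non-empty")
  tr <- generate_impact_train(double_knock_pattern())
  expect_error(render_audio(tr, audio_render_spec(duration_s = 0.05)), "beyond")
  expect_error(audio_render_spec(sample_rate_hz = 4000), "8000")
})

test_that("onset detection closes the generate-render-detect loop", {
  expect_length(detect_onsets(rep(0, 22050), sample_rate_hz = 22050), 0L)

  dk <- generate_impact_train(double_knock_pattern(inter_knock_interval_s = 0.1))
  au <- render_audio(dk, audio_render_spec(noise_rms = 0.02, seed = 3))
  on <- detect_onsets(au)
  expect_length(on, 2L)
  expect_lt(abs(diff(on) - 0.1), 0.005)

  dr <- generate_impact_train(drum_roll_pattern(n_knocks = 8, period_s = 0.06))
  on8 <- detect_onsets(render_audio(dr, audio_render_spec(noise_rms = 0.02, seed = 4)))
  expect_length(on8, 8L)
  expect_lt(max(abs(diff(on8) - 0.06)), 0.005)
})

test_that("round-trip recovery holds across noise levels and spacings", {
  for (noise in c(0, 0.05)) {
    for (gap in c(0.05, 0.12)) {
      tr <- generate_impact_train(double_knock_pattern(inter_knock_interval_s = gap))
      on <- detect_onsets(render_audio(tr, audio_render_spec(noise_rms = noise, seed = 1)))
      expect_length(on, 2L)
      expect_lt(abs(diff(on) - gap), 0.005)
    }
  }
})

test_that("WAV files round-trip samples and stay byte-identical under a fixed seed", {
  tr <- generate_impact_train(double_knock_pattern())
  au <- render_audio(tr, audio_render_spec(noise_rms = 0.01, seed = 5))
  f1 <- tempfile(fileext = ".wav"); f2 <- tempfile(fileext = ".wav")
  write_wav(au, f1)
  back <- read_wav(f1)
  expect_equal(back$sample_rate_hz, au$sample_rate_hz)
  expect_lt(max(abs(back$samples - au$samples)), 1 / 32767)
  au2 <- render_audio(tr, audio_render_spec(noise_rms = 0.01, seed = 5))
  write_wav(au2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("flap sequences lay out cycles at the nominal cadence", {
  s <- generate_flap_sequence(5, duty = 1, fps = 60, n_flaps = 10)
  expect_equal(diff(s$start_frame), rep(12, 9))
  expect_equal(s$end_frame - s$start_frame, rep(12, 10))
  expect_error(generate_flap_sequence(5, 1.2, 60, 10), "duty")
  expect_error(generate_flap_sequence(40, 0.7, 60, 10), "resolve")
})

test_that("the cruising-flight configuration recovers the published raw rate", {
  s <- generate_flap_sequence(9.25, duty = 0.714, fps = 60, n_flaps = 15)
  est <- estimate_flap_rates(s)
  expect_lt(abs(est$span_frames - 2.27 * 60), 1)
  expect_equal(est$raw_hz, 6.61, tolerance = 0.05 / 6.61)
  expect_equal(est$intrinsic_hz, est$raw_hz / 0.714)
})

test_that("intrinsic rate is recovered within 2% from a long jittered sequence", {
  s <- generate_flap_sequence(7.3, duty = 0.714, fps = 60, n_flaps = 200,
                              jitter_frames_sd = 1, seed = 99)
  est <- estimate_flap_rates(s)
  expect_lt(abs(est$intrinsic_hz - 7.3) / 7.3, 0.02)
})

test_that("synthetic CSV writers emit the documented headers", {
  tr <- generate_impact_train(double_knock_pattern())
  s <- generate_flap_sequence(5, 0.7, 60, 5)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_knock_train_csv(tr, f1)
  write_flap_sequence_csv(s, f2)
  expect_identical(readLines(f1, n = 1L), "time_s,amplitude")
  expect_identical(readLines(f2, n = 1L), "flap_idx,start_frame,end_frame")
})
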