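test_that("high-pass removes DC and preserves the passband", {
  fs <- 1000
  # constant offset -> zero
  out <- emg_highpass(rep(0.5, 2000), 1, fs)
  expect_lt(max(abs(out[500:1500])), 1e-6)
  # 50 Hz unit sinusoid: interior amplitude within 1%
  t <- seq_len(4000) / fs
  y <- emg_highpass(sin(2 * pi * 50 * t), 1, fs)
  interior <- y[1000:3000]
  expect_lt(abs(max(interior) - 1), 0.01)
  # applying twice ~ applying once on DC-free content
  twice <- emg_highpass(y, 1, fs)
  expect_lt(max(abs(twice[1000:3000] - interior)) / max(abs(interior)), 0.01)
  expect_error(emg_highpass(rnorm(100), 600, fs), "Nyquist")
})

test_that("high-pass passband response matches a DFT oracle of the filter", {
  # oracle: measure the realized transfer magnitude by direct DFT of an
  # impulse response, independent of the filtering path under test
  fs <- 1000
  n <- 4096
  imp <- c(1, rep(0, n - 1))
  h <- emg_highpass(imp, 1, fs, zero_phase = FALSE)
  H <- Mod(fft(h))
  freq <- (seq_len(n) - 1) * fs / n
  band <- freq >= 10 & freq <= 450
  expect_true(all(abs(H[band] - 1) < 0.01))
})

test_that("frame energy matches its closed form and a loop oracle", {
  p <- segmentation_params()
  fs <- 1000
  # all ones: every frame sums 250 samples
  fe <- frame_energy(rep(1, 1000), p, fs)
  expect_equal(length(fe), floor((1000 - 250) / 100) + 1)
  expect_true(all(fe == 250))
  expect_true(all(frame_energy(rep(0, 600), p, fs) == 0))
  # brute-force windowed-sum oracle on random data
  set.seed(1)
  x <- rnorm(1234)
  fe <- frame_energy(x, p, fs)
  oracle <- sapply(seq_along(fe), function(k) {
    idx <- ((k - 1) * 100 + 1):((k - 1) * 100 + 250)
    sum(x[idx]^2)
  })
  expect_equal(fe, oracle, tolerance = 1e-12)
  expect_warning(short <- frame_energy(rnorm(10), p, fs), "shorter")
  expect_length(short, 0)
})

test_that("a silent recording yields no segments", {
  rec <- recording(matrix(2048L, 5000, 8), default_meta())
  segs <- detect_segments(rec, segmentation_params(xi = 1e-4, delta = 2e-4))
  expect_length(segs, 0)
  # and with auto thresholds on pure noise floor
  cfg <- generator_config(reps_per_session = 1, amp_scale = 1e-9)
  noise_only <- generate_session(cfg, default_meta(), seed = 2)
  expect_length(detect_segments(noise_only), 0)
})

test_that("detected boundaries agree with an envelope-threshold oracle", {
  cfg <- generator_config(reps_per_session = 1)
  meta <- default_meta(exercise = "pullover", load = "rm67")
  rec <- generate_session(cfg, meta, seed = 11)
  segs <- detect_segments(rec)
  expect_length(segs, 1)
  thr <- attr(segs, "thresholds")

  # oracle: expected frame energy of the channel-averaged signal from the
  # generator's envelope model, thresholded by the same rule
  fs <- 1000
  n <- nrow(rec$channels)
  profile <- default_activation_profiles()$pullover
  amb <- 1 + cfg$ambiguity_overlap * (-0.25)
  amp <- cfg$amp_scale * cfg$load_gain[["rm67"]] * amb
  ann <- attr(rec, "annotations")
  env <- numeric(n)
  n_rep <- round(cfg$rep_duration_s * fs)
  idx <- round(ann$t_start_s[1] * fs) + seq_len(n_rep)
  env[idx] <- sin(pi * (seq_len(n_rep) - 0.5) / n_rep)^2
  # channel-averaged variance of 8 independent channels + noise floor
  v <- (amp * env)^2 * sum(profile^2) / 64 / 4096^2 +
    cfg$noise_floor^2 * 8 / 64 / 4096^2
  n_frames <- floor((n - 250) / 100) + 1
  frame_var <- sapply(seq_len(n_frames), function(k) {
    sum(v[((k - 1) * 100 + 1):((k - 1) * 100 + 250)])
  })
  above <- which(frame_var > thr[["xi"]])
  t_s_oracle <- (min(above) - 1) * 0.1
  t_e_oracle <- max(above) * 0.1
  expect_lt(abs(segs[[1]]$t_start_s - t_s_oracle), 0.25)
  expect_lt(abs(segs[[1]]$t_end_s - t_e_oracle), 0.25)
})

test_that("short bursts are removed by the duration filter", {
  # hand-built recordings: a Hann-windowed 50 Hz burst of given duration on
  # the ADC mid-scale, silence elsewhere
  burst_recording <- function(dur_s, total_s = 5, fs = 1000) {
    n <- total_s * fs
    x <- rep(2048, n)
    nb <- dur_s * fs
    idx <- 2 * fs + seq_len(nb)
    x[idx] <- 2048 + round(500 * sin(pi * (seq_len(nb) - 0.5) / nb)^2 *
                             sin(2 * pi * 50 * seq_len(nb) / fs))
    recording(matrix(rep(x, 8), n, 8), default_meta())
  }
  p <- segmentation_params(xi = 1e-4, delta = 2e-4)
  expect_length(detect_segments(burst_recording(1.0), p), 0)  # duration filter
  expect_length(detect_segments(burst_recording(2.5), p), 1)
})

test_that("returned segments honour the duration and max-energy filters", {
  rec <- generate_session(generator_config(), default_meta(), seed = 21)
  segs <- detect_segments(rec)
  thr <- attr(segs, "thresholds")
  p <- segmentation_params()
  sig <- emg_highpass(rowMeans(normalize_recording(rec)), 1, 1000)
  fe <- frame_energy(sig, p, 1000)
  for (s in segs) {
    expect_gte(s$t_end_s - s$t_start_s, p$min_duration_s)
    run <- fe[(s$f_start + 1):min(s$f_end, length(fe))]
    expect_gte(max(run), thr[["delta"]])
    # frame-to-time mapping is t = f * step exactly
    expect_equal(s$t_start_s, s$f_start * p$frame_step_s)
    expect_equal(s$t_end_s, s$f_end * p$frame_step_s)
    # extension clipped to the recording
    expect_gte(s$t_start_s - p$extend_s, -1e-9)
    expect_lte(s$t_end_s + p$extend_s, recording_duration(rec) + p$frame_step_s + 1e-9)
  }
})

test_that("auto thresholds recover all bursts and resist a louder noise floor", {
  count_for <- function(noise_floor, seed) {
    cfg <- generator_config(noise_floor = noise_floor)
    length(detect_segments(generate_session(cfg, default_meta(), seed)))
  }
  for (s in 1:3) {
    expect_equal(count_for(4, s), 12)
    expect_equal(count_for(8, s), 12)  # doubled noise floor, same recovery
  }
})
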