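test_that("time-domain features match their closed forms", {
  expect_equal(emg_rms(rep(3, 10)), 3)
  expect_equal(emg_rms(c(3, 4)), sqrt(12.5))
  t <- seq_len(1000) / 1000
  expect_equal(emg_rms(sin(2 * pi * 10 * t)), 1 / sqrt(2), tolerance = 1e-3)

  expect_equal(waveform_length(c(0, 1, 0, 1)), 3)
  expect_equal(waveform_length(rep(2, 5)), 0)

  expect_equal(mav(c(-1, 1, -1, 1)), 1)
  expect_equal(mav(numeric(5)), 0)

  expect_equal(var_emg(c(1, -1, 1, -1)), 4 / 3)
  expect_equal(var_emg(numeric(4)), 0)

  expect_equal(zero_crossings(c(1, -1, 1, -1), 0), 3)
  expect_equal(zero_crossings(c(0.1, -0.1, 0.1), 0.5), 0)

  expect_error(emg_rms(numeric(0)), "empty")
  expect_error(waveform_length(1), "2 samples")
  expect_error(var_emg(1), "2 samples")
  expect_error(zero_crossings(1, 0), "2 samples")
})

test_that("time-domain features equal independent loop oracles on random windows", {
  # brute-force element-by-element oracles, coded independently of the
  # vectorised implementations
  oracle_rms <- function(x) { s <- 0; for (v in x) s <- s + v * v; sqrt(s / length(x)) }
  oracle_wl <- function(x) { s <- 0; for (i in 2:length(x)) s <- s + abs(x[i] - x[i - 1]); s }
  oracle_mav <- function(x) { s <- 0; for (v in x) s <- s + abs(v); s / length(x) }
  oracle_var <- function(x) { s <- 0; for (v in x) s <- s + v * v; s / (length(x) - 1) }
  oracle_zc <- function(x, th) {
    cnt <- 0
    for (i in 2:length(x)) {
      if (sign(x[i - 1]) != sign(x[i]) && abs(x[i - 1] - x[i]) >= th) cnt <- cnt + 1
    }
    cnt
  }
  set.seed(99)
  for (i in 1:100) {
    x <- rnorm(sample(50:400, 1))
    th <- runif(1, 0, 0.5)
    expect_equal(emg_rms(x), oracle_rms(x), tolerance = 1e-9)
    expect_equal(waveform_length(x), oracle_wl(x), tolerance = 1e-9)
    expect_equal(mav(x), oracle_mav(x), tolerance = 1e-9)
    expect_equal(var_emg(x), oracle_var(x), tolerance = 1e-9)
    expect_equal(zero_crossings(x, th), oracle_zc(x, th))
  }
})

test_that("feature inequalities and identities hold on random input", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(200)
    expect_lte(mav(x), emg_rms(x))                      # Cauchy-Schwarz
    n <- length(x)
    expect_equal(var_emg(x), n / (n - 1) * emg_rms(x)^2, tolerance = 1e-12)
  }
})

test_that("spectral features locate tones correctly", {
  fs <- 1000
  n <- 1000
  t <- seq_len(n) / fs
  tone50 <- sin(2 * pi * 50 * t)
  expect_lt(abs(mmdf(tone50, fs) - 50), fs / n + 1e-9)    # within one bin
  expect_lt(abs(mmnf(tone50, fs) - 50), 1)

  two <- sin(2 * pi * 30 * t) + sin(2 * pi * 90 * t)
  # equal amplitude masses: median hits the first (30 Hz) line, mean is 60 Hz
  expect_lt(abs(mmdf(two, fs) - 30), fs / n + 1e-9)
  expect_lt(abs(mmnf(two, fs) - 60), 1)

  # scale invariance
  expect_equal(mmdf(two, fs), mmdf(2 * two, fs))
  expect_equal(mmnf(two, fs), mmnf(2 * two, fs), tolerance = 1e-9)

  expect_warning(z1 <- mmdf(numeric(16), fs), "all-zero")
  expect_equal(z1, 0)
  expect_warning(z2 <- mmnf(numeric(16), fs), "all-zero")
  expect_equal(z2, 0)
})

test_that("mmdf matches a cumulative-spectrum oracle on random signals", {
  set.seed(31)
  fs <- 1000
  for (i in 1:20) {
    x <- rnorm(512)
    # oracle: explicit cumulative scan over an independently computed
    # one-sided amplitude spectrum
    amp <- Mod(fft(x))[1:257]
    freq <- (0:256) * fs / 512
    half <- sum(amp) / 2
    run <- 0
    m <- NA
    for (j in seq_along(amp)) {
      run <- run + amp[j]
      if (run >= half) { m <- freq[j]; break }
    }
    expect_equal(mmdf(x, fs), m)
    expect_equal(mmnf(x, fs), sum(freq * amp) / sum(amp), tolerance = 1e-9)
  }
})

test_that("featurize returns an ordered, labelled 56-vector", {
  rec <- quick_session(seed = 2, reps = 1, load = "rm85", attention = "with")
  seg <- detect_segments(rec)[[1]]
  fv <- featurize(seg)
  expect_length(fv, 56)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv)[1:7],
                   paste0("ch1_", c("rms", "wl", "mav", "var", "zc", "mmdf", "mmnf")))
  lab <- attr(fv, "labels")
  expect_identical(lab$load, "rm85")
  expect_identical(lab$attention, "with")
  # non-negativity and Nyquist bounds
  idx <- function(f) which(grepl(f, names(fv)))
  expect_true(all(fv[idx("rms|wl|mav|var|zc")] >= 0))
  expect_true(all(fv[idx("mmdf|mmnf")] >= 0 & fv[idx("mmdf|mmnf")] <= 500))
  # band-passed burst: spectral centroids inside the generator band
  expect_true(all(fv[idx("mmnf")] > 20 & fv[idx("mmnf")] < 180))

  # determinism
  expect_identical(featurize(seg), featurize(seg))

  # permuting channels permutes feature blocks
  seg_perm <- seg
  perm <- c(3, 1, 2, 4:8)
  seg_perm$window <- seg$window[, perm]
  fv_perm <- featurize(seg_perm)
  for (ch in 1:8) {
    expect_equal(unname(fv_perm[(ch - 1) * 7 + 1:7]),
                 unname(fv[(perm[ch] - 1) * 7 + 1:7]))
  }
})

test_that("an all-zero window yields zero time-domain features", {
  seg <- structure(list(window = matrix(0, 300, 8), sampling_rate_hz = 1000,
                        t_start_s = 0, t_end_s = 0.3, f_start = 0L, f_end = 3L,
                        meta = default_meta()),
                   class = "segment")
  fv <- suppressWarnings(featurize(seg))
  expect_true(all(fv[grepl("rms|wl|mav|var|zc", names(fv))] == 0))
})
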