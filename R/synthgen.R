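#' Default per-exercise channel activation profiles
#'
#' Eight-channel gain vectors (values in `[0, 1]`) describing which electrode
#' sites are recruited by each exercise. Channel layout mirrors the sensing
#' garment: ch1-2 chest (pectoralis major), ch3-4 shoulders (deltoids),
#' ch5-6 triceps, ch7-8 biceps. The bench press is the compound movement
#' (chest + shoulders + triceps); the other four are isolation movements
#' dominated by one muscle pair. Channels with gain >= 0.8 are the
#' exercise's "target" channels, the ones attentional focus up-modulates.
#'
#' @return Named list of five numeric 8-vectors.
#' @export
default_activation_profiles <- function() {
  list(
    bench_press = c(1.00, 1.00, 0.60, 0.60, 0.50, 0.50, 0.20, 0.20),
    pullover    = c(1.00, 0.90, 0.35, 0.30, 0.25, 0.20, 0.15, 0.15),
    front_raise = c(0.20, 0.20, 1.00, 0.95, 0.30, 0.25, 0.15, 0.15),
    kickback    = c(0.15, 0.15, 0.25, 0.20, 1.00, 0.95, 0.20, 0.20),
    biceps_curl = c(0.15, 0.15, 0.20, 0.20, 0.20, 0.25, 1.00, 0.95)
  )
}

#' Synthetic-study generator configuration
#'
#' Parameters of the synthetic EMG study emulating the acquisition protocol:
#' 12 subjects, 5 exercises x 3 loads x 2 attention conditions (30 sessions
#' per subject), 12 repetitions per session. Each repetition is a burst of
#' band-limited (20-150 Hz) Gaussian noise under a Hann amplitude envelope —
#' the amplitude-modulated Gaussian process that RMS-based contraction
#' measurement assumes — riding on the ADC mid-scale (2048) plus a small
#' noise floor, digitised to integer codes in `[0, 4096]`.
#'
#' Amplitude structure (in ADC codes, per channel):
#' `amp_scale * profile[ch] * load_gain[load] * ambiguity[exercise] *
#'  attention_gain^(with & target ch) * subject_gain[ch] * rep_jitter`.
#'
#' `ambiguity_overlap` interpolates per-exercise amplitude multipliers
#' `1 + overlap * direction[exercise]` (directions +0.6, -0.25, +0.6, -0.25, 0)
#' so that, as overlap grows, the channel-averaged energy of one exercise at
#' 67% 1RM approaches another exercise at 85% 1RM — the cross-exercise
#' load-energy ambiguity that motivates the network's fusion layer.
#'
#' @param n_subjects Number of subjects (default 12).
#' @param reps_per_session Bursts per session (default 12).
#' @param rep_duration_s Burst duration, seconds (default 2.5; must be >= 1.5
#'   or the downstream duration filter would discard every repetition).
#' @param inter_rep_gap_s Rest gap between bursts and before the first burst,
#'   seconds (default 1.0; guarantees the >= 0.5 s leading rest that
#'   threshold auto-calibration requires).
#' @param sampling_rate_hz Sampling rate (default 1000).
#' @param activation_profiles Per-exercise 8-vectors of channel gains.
#' @param load_gain Named gains for `rm0`, `rm67`, `rm85`; `rm0 < rm67 < rm85`.
#' @param attention_gain Multiplier (>= 1) on target channels when the
#'   session is performed with attentional focus (default 1.3).
#' @param ambiguity_overlap Fraction in `[0, 1)` (default 0.3).
#' @param attention_band_shift Fractional upward shift of the burst noise
#'   band under attentional focus (default 0.1). Attentional focus is
#'   modelled as an amplitude gain plus this mild spectral shift (focused
#'   contractions recruit at higher firing rates); without a spectral
#'   component, an amplitude-only attention effect would be almost
#'   collinear with the load effect and no classifier could reach the
#'   recognition rates the emulated study design presumes. Set 0 for an
#'   amplitude-only attention model.
#' @param amp_scale Burst amplitude scale in ADC codes (default 700).
#' @param noise_floor Baseline code jitter, standard deviation in ADC codes
#'   (default 4).
#' @param rep_jitter_sd Lognormal sd of per-repetition amplitude jitter,
#'   shared across channels (default 0.08).
#' @param subject_gain_sd Lognormal sd of fixed per-subject channel gains
#'   (default 0.1).
#' @param band_hz Burst noise band, Hz (default c(20, 150)).
#' @param seed Base seed for [generate_study()].
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_subjects = 12L,
                             reps_per_session = 12L,
                             rep_duration_s = 2.5,
                             inter_rep_gap_s = 1.0,
                             sampling_rate_hz = 1000,
                             activation_profiles = default_activation_profiles(),
                             load_gain = c(rm0 = 0.5, rm67 = 0.7, rm85 = 1.0),
                             attention_gain = 1.3,
                             ambiguity_overlap = 0.3,
                             attention_band_shift = 0.1,
                             amp_scale = 700,
                             noise_floor = 4,
                             rep_jitter_sd = 0.08,
                             subject_gain_sd = 0.1,
                             band_hz = c(20, 150),
                             seed = 1L) {
  if (rep_duration_s < 1.5) {
    stop("rep_duration_s must be >= 1.5 s: shorter bursts are discarded by the ",
         "segmentation duration filter", call. = FALSE)
  }
  stopifnot(n_subjects >= 1, reps_per_session >= 1, inter_rep_gap_s > 0,
            sampling_rate_hz > 0, attention_gain >= 1,
            ambiguity_overlap >= 0, ambiguity_overlap < 1,
            amp_scale > 0, noise_floor >= 0,
            length(band_hz) == 2, band_hz[1] > 0,
            band_hz[2] < sampling_rate_hz / 2)
  if (!all(exercise_levels() %in% names(activation_profiles))) {
    stop("activation_profiles must name all five exercises", call. = FALSE)
  }
  if (!all(names(load_gain)[order(load_gain)] == c("rm0", "rm67", "rm85")) ||
      load_gain[["rm0"]] >= load_gain[["rm67"]] || load_gain[["rm85"]] <= 0) {
    stop("load_gain must satisfy rm0 < rm67 and rm85 > 0", call. = FALSE)
  }
  structure(as.list(environment()), class = "generator_config")
}

# Per-exercise amplitude multipliers implementing the load-energy ambiguity.
ambiguity_multipliers <- function(cfg) {
  direction <- c(bench_press = 0.6, pullover = -0.25, front_raise = 0.6,
                 kickback = -0.25, biceps_curl = 0)
  1 + cfg$ambiguity_overlap * direction
}

target_channels <- function(profile) profile >= 0.8

# Band-limited unit-variance Gaussian noise of length n: white Gaussian
# noise shaped in the frequency domain by a 4th-order Butterworth band-pass
# magnitude response (linear spectral shaping preserves Gaussianity and is
# much faster than time-domain filtering for long records).
bandlimited_noise <- function(n, band_hz, fs) {
  # pad to a 2-3-5-smooth length so the FFT stays fast, then truncate
  m <- stats::nextn(n, c(2, 3, 5))
  H <- butterworth_mask(m, band_hz, fs)
  x <- Re(stats::fft(stats::fft(rnorm(m)) * H, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

# 4th-order Butterworth band-pass magnitude response on FFT bin frequencies.
butterworth_mask <- function(m, band_hz, fs) {
  k <- 0:(m - 1)
  f <- pmin(k, m - k) * fs / m
  H <- 1 / sqrt(1 + (band_hz[1] / pmax(f, 1e-12))^8) /
    sqrt(1 + (f / band_hz[2])^8)
  H[f == 0] <- 0
  H
}

#' Generate one synthetic EMG session
#'
#' Produces a [recording()] with `reps_per_session` bursts, each
#' `rep_duration_s` long, separated (and preceded) by `inter_rep_gap_s` of
#' noise-floor signal. Deterministic given `seed`. Ground-truth burst
#' intervals are attached as `attr(rec, "annotations")` (data frame with
#' columns `rep`, `t_start_s`, `t_end_s`).
#'
#' @param cfg A [generator_config()].
#' @param meta A [session_meta()] for the session.
#' @param seed Integer seed.
#' @param subject_gains Optional fixed per-subject channel gain 8-vector
#'   (drawn by [generate_study()]; defaults to 1s).
#' @return A [recording()] with burst annotations.
#' @export
generate_session <- function(cfg, meta, seed, subject_gains = rep(1, 8)) {
  stopifnot(inherits(cfg, "generator_config"), inherits(meta, "session_meta"))
  set.seed(as.integer(seed))
  fs <- cfg$sampling_rate_hz
  dur <- cfg$rep_duration_s
  gap <- cfg$inter_rep_gap_s
  reps <- cfg$reps_per_session
  n <- round((gap + reps * (dur + gap)) * fs)

  profile <- cfg$activation_profiles[[meta$exercise]]
  targets <- target_channels(profile)
  amb <- ambiguity_multipliers(cfg)[[meta$exercise]]
  base_amp <- cfg$amp_scale * cfg$load_gain[[meta$load]] * amb
  att <- meta$attention == "with"
  ch_gain <- profile * subject_gains *
    ifelse(att & targets, cfg$attention_gain, 1)

  starts <- gap + (seq_len(reps) - 1) * (dur + gap)
  rep_jitter <- exp(rnorm(reps, 0, cfg$rep_jitter_sd))

  # Hann amplitude envelope, shared across channels.
  envelope <- numeric(n)
  n_rep <- round(dur * fs)
  hann <- sin(pi * (seq_len(n_rep) - 0.5) / n_rep)^2
  for (r in seq_len(reps)) {
    i0 <- round(starts[r] * fs)
    envelope[i0 + seq_len(n_rep)] <- hann * rep_jitter[r]
  }

  band <- cfg$band_hz
  if (att && cfg$attention_band_shift > 0) {
    band <- pmin(band * (1 + cfg$attention_band_shift), fs / 2 - 1)
  }

  # Burst noise is generated per burst (the envelope is zero elsewhere);
  # the spectral mask is shared across bursts and channels.
  m_fft <- stats::nextn(n_rep, c(2, 3, 5))
  H <- butterworth_mask(m_fft, band, fs)
  x <- matrix(2048 + cfg$noise_floor * rnorm(n * 8), n, 8)
  for (r in seq_len(reps)) {
    idx <- round(starts[r] * fs) + seq_len(n_rep)
    env_r <- envelope[idx]
    for (c_i in 1:8) {
      z <- Re(stats::fft(stats::fft(rnorm(m_fft)) * H,
                         inverse = TRUE))[seq_len(n_rep)] / m_fft
      z <- z / stats::sd(z)
      x[idx, c_i] <- x[idx, c_i] + base_amp * ch_gain[c_i] * env_r * z
    }
  }
  channels <- matrix(as.integer(pmin(pmax(round(x), 0), ADC_MAX)), n, 8)

  rec <- recording(channels, meta)
  attr(rec, "annotations") <- data.frame(
    rep = seq_len(reps), t_start_s = starts, t_end_s = starts + dur)
  rec
}

#' Generate a full synthetic study
#'
#' For each subject: 5 exercises x 3 loads x 2 attention conditions, one
#' session each (30 sessions), `reps_per_session` repetitions per session —
#' at defaults, 72 repetitions per exercise and 360 per subject, matching
#' the acquisition protocol the generator emulates. Subject heterogeneity is
#' a fixed lognormal channel-gain 8-vector per subject. Session seeds are
#' derived deterministically from `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @param dir Optional directory: if given, each session is written as a
#'   CSV + JSON pair under `dir/<subject>/<exercise>/` and paths are
#'   returned instead of recordings.
#' @param subjects Optional subset of subject indices to generate.
#' @return A list of [recording()]s (or written file paths if `dir` given).
#' @export
generate_study <- function(cfg, dir = NULL, subjects = seq_len(cfg$n_subjects)) {
  stopifnot(inherits(cfg, "generator_config"))
  conditions <- expand.grid(attention = attention_levels(),
                            load = load_levels(),
                            exercise = exercise_levels(),
                            stringsAsFactors = FALSE)
  out <- list()
  for (s in subjects) {
    set.seed(as.integer(cfg$seed) + 7919L * as.integer(s))
    subject_gains <- exp(rnorm(8, 0, cfg$subject_gain_sd))
    subject_id <- sprintf("S%02d", s)
    for (k in seq_len(nrow(conditions))) {
      cond <- conditions[k, ]
      meta <- session_meta(subject_id, cond$exercise, cond$load, cond$attention,
                           session_index = k,
                           planned_reps = cfg$reps_per_session,
                           sampling_rate_hz = cfg$sampling_rate_hz)
      sess_seed <- (as.integer(cfg$seed) + 1009L * as.integer(s) + k) %% .Machine$integer.max
      rec <- generate_session(cfg, meta, sess_seed, subject_gains)
      key <- sprintf("%s_%s_%s_%s", subject_id, cond$exercise, cond$load, cond$attention)
      if (is.null(dir)) {
        out[[key]] <- rec
      } else {
        path <- file.path(dir, subject_id, cond$exercise, paste0(key, ".csv"))
        write_recording(rec, path)
        out[[key]] <- path
      }
    }
  }
  out
}
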