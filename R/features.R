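#' Feature-extraction parameters
#'
#' @param zc_threshold Amplitude-difference threshold for zero-crossing
#'   counting, in normalized signal units (default 0.01; suppresses
#'   noise-floor crossings). Set 0 for unthresholded counting.
#' @param window_fn Taper for the spectral features: `"none"` (default) or
#'   `"hann"`.
#' @param exact_var If TRUE, the variance feature subtracts the sample mean;
#'   default FALSE uses the zero-mean simplification appropriate for
#'   high-passed EMG.
#' @return A `feature_params` object.
#' @export
feature_params <- function(zc_threshold = 0.01, window_fn = c("none", "hann"),
                           exact_var = FALSE) {
  stopifnot(zc_threshold >= 0)
  window_fn <- match.arg(window_fn)
  structure(list(zc_threshold = zc_threshold, window_fn = window_fn,
                 exact_var = exact_var), class = "feature_params")
}

#' Root mean square
#'
#' `sqrt(mean(x^2))` — the muscle-activation proxy for an
#' amplitude-modulated zero-mean process.
#'
#' @param x Numeric vector, length >= 1.
#' @return Non-negative scalar.
#' @export
emg_rms <- function(x) {
  if (!length(x)) stop("rms of an empty window is undefined", call. = FALSE)
  sqrt(mean(x^2))
}

#' Waveform length
#'
#' Cumulative absolute first difference, `sum(|x[i+1] - x[i]|)`; grows with
#' amplitude, frequency and duration together.
#'
#' @param x Numeric vector, length >= 2.
#' @return Non-negative scalar.
#' @export
waveform_length <- function(x) {
  if (length(x) < 2) stop("waveform length needs at least 2 samples", call. = FALSE)
  sum(abs(diff(x)))
}

#' Mean absolute value
#' @param x Numeric vector, length >= 1.
#' @return Non-negative scalar.
#' @export
mav <- function(x) {
  if (!length(x)) stop("mav of an empty window is undefined", call. = FALSE)
  mean(abs(x))
}

#' EMG variance (zero-mean form)
#'
#' `sum(x^2) / (N - 1)`: the signal's power with the conventional
#' EMG simplification that the mean is zero (the signal is high-passed
#' upstream). `exact = TRUE` subtracts the sample mean instead.
#'
#' @param x Numeric vector, length >= 2.
#' @param exact Subtract the sample mean (default FALSE).
#' @return Non-negative scalar.
#' @export
var_emg <- function(x, exact = FALSE) {
  if (length(x) < 2) stop("variance needs at least 2 samples", call. = FALSE)
  if (exact) stats::var(x) else sum(x^2) / (length(x) - 1)
}

#' Thresholded zero-crossing count
#'
#' Counts sample pairs whose signs differ and whose amplitude jump is at
#' least `threshold` (the threshold abstains from counting noise-floor
#' chatter). A crude frequency-content proxy.
#'
#' @param x Numeric vector, length >= 2.
#' @param threshold Non-negative amplitude-difference threshold (default 0).
#' @return Integer count.
#' @export
zero_crossings <- function(x, threshold = 0) {
  if (length(x) < 2) stop("zero crossings need at least 2 samples", call. = FALSE)
  a <- x[-length(x)]
  b <- x[-1]
  sum(sign(a) != sign(b) & abs(a - b) >= threshold)
}

# One-sided magnitude spectrum with bin frequencies.
magnitude_spectrum <- function(x, fs, window_fn = "none") {
  n <- length(x)
  if (window_fn == "hann") {
    x <- x * sin(pi * (seq_len(n) - 0.5) / n)^2
  }
  n_half <- floor(n / 2) + 1
  amp <- Mod(stats::fft(x))[seq_len(n_half)]
  list(freq = (seq_len(n_half) - 1) * fs / n, amp = amp)
}

#' Modified median frequency
#'
#' The smallest frequency bin at which the cumulative one-sided *amplitude*
#' spectrum reaches half its total ("modified": amplitude, not power,
#' spectrum). Zero (flagged with a warning) for an all-zero window.
#'
#' @param x Numeric vector, length >= 4.
#' @param fs Sampling rate, Hz.
#' @param window_fn `"none"` or `"hann"`.
#' @return Frequency in `[0, fs/2]`.
#' @export
mmdf <- function(x, fs, window_fn = "none") {
  if (length(x) < 4) stop("mmdf needs at least 4 samples", call. = FALSE)
  sp <- magnitude_spectrum(x, fs, window_fn)
  total <- sum(sp$amp)
  if (total == 0) {
    warning("all-zero window: mmdf defined as 0")
    return(0)
  }
  # relative tolerance so an exact half-split (two equal tones) resolves to
  # the lower bin instead of falling to floating-point rounding
  sp$freq[which(cumsum(sp$amp) >= total / 2 * (1 - 1e-9))[1]]
}

#' Modified mean frequency
#'
#' Amplitude-spectrum centroid: `sum(f * A) / sum(A)` over the one-sided
#' magnitude spectrum. Zero (flagged) for an all-zero window.
#'
#' @inheritParams mmdf
#' @return Frequency in `[0, fs/2]`.
#' @export
mmnf <- function(x, fs, window_fn = "none") {
  if (length(x) < 4) stop("mmnf needs at least 4 samples", call. = FALSE)
  sp <- magnitude_spectrum(x, fs, window_fn)
  total <- sum(sp$amp)
  if (total == 0) {
    warning("all-zero window: mmnf defined as 0")
    return(0)
  }
  sum(sp$freq * sp$amp) / total
}

#' Extract the 56-dimensional feature vector from one segment
#'
#' Computes the seven features per channel, in the fixed order RMS, WL, MAV,
#' VAR, ZC, MMDF, MMNF, channel-major (channel 1's seven features first).
#' Features are computed on the segment's conditioned (normalized,
#' high-passed) window. Labels from the session metadata are attached.
#'
#' @param seg A `segment` (from [detect_segments()]).
#' @param params A [feature_params()].
#' @return A `feature_vector`: numeric length-56 vector named per
#'   [feature_column_names()], with a `labels` attribute.
#' @export
featurize <- function(seg, params = feature_params()) {
  stopifnot(inherits(seg, "segment"))
  w <- seg$window
  if (ncol(w) != 8) stop("segment window must have 8 channels", call. = FALSE)
  fs <- seg$sampling_rate_hz
  vals <- numeric(56)
  for (ch in 1:8) {
    x <- w[, ch]
    v <- c(emg_rms(x), waveform_length(x), mav(x),
           var_emg(x, exact = params$exact_var),
           zero_crossings(x, params$zc_threshold),
           mmdf(x, fs, params$window_fn), mmnf(x, fs, params$window_fn))
    if (any(!is.finite(v))) {
      stop(sprintf("non-finite feature for channel %d (feature %s)", ch,
                   c("rms", "wl", "mav", "var", "zc", "mmdf", "mmnf")[which(!is.finite(v))[1]]),
           call. = FALSE)
    }
    vals[(ch - 1) * 7 + 1:7] <- v
  }
  names(vals) <- feature_column_names()
  structure(vals,
            labels = list(exercise = seg$meta$exercise,
                          attention = seg$meta$attention,
                          load = seg$meta$load,
                          subject = seg$meta$subject_id),
            class = c("feature_vector", "numeric"))
}

#' Feature table for a recording
#'
#' Runs [detect_segments()] then [featurize()] on every segment, returning
#' one row per repetition with the 56 feature columns plus `subject`,
#' `exercise`, `load`, `attention`, `session_index` and `rep`.
#'
#' @param rec A [recording()].
#' @param seg_params A [segmentation_params()].
#' @param feat_params A [feature_params()].
#' @param segments Optional pre-computed segment list (skips detection).
#' @return Data frame (zero rows if no segments were found).
#' @export
featurize_recording <- function(rec, seg_params = segmentation_params(),
                                feat_params = feature_params(),
                                segments = NULL) {
  if (is.null(segments)) segments <- detect_segments(rec, seg_params)
  if (!length(segments)) {
    return(cbind(as.data.frame(matrix(numeric(0), 0, 56,
                                      dimnames = list(NULL, feature_column_names()))),
                 data.frame(subject = character(0), exercise = character(0),
                            load = character(0), attention = character(0),
                            session_index = integer(0), rep = integer(0))))
  }
  rows <- t(vapply(segments, featurize, numeric(56), params = feat_params))
  df <- as.data.frame(rows)
  df$subject <- rec$meta$subject_id
  df$exercise <- rec$meta$exercise
  df$load <- rec$meta$load
  df$attention <- rec$meta$attention
  df$session_index <- rec$meta$session_index
  df$rep <- seq_along(segments)
  df
}

#' Feature table for a collection of recordings
#'
#' @param recs List of [recording()]s (e.g. from [generate_study()]).
#' @param seg_params A [segmentation_params()].
#' @param feat_params A [feature_params()].
#' @return Row-bound data frame of per-repetition features and labels.
#' @export
featurize_study <- function(recs, seg_params = segmentation_params(),
                            feat_params = feature_params()) {
  do.call(rbind, lapply(recs, featurize_recording,
                        seg_params = seg_params, feat_params = feat_params))
}
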