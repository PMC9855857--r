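#' @importFrom stats median rnorm runif sd var wilcox.test fft setNames
#' @importFrom utils read.csv write.csv head tail modifyList
NULL

# ADC full-scale of the acquisition front-end; fixed, not data-dependent.
ADC_MAX <- 4096
N_CHANNELS <- 8L

#' Label vocabularies
#'
#' Closed vocabularies for the three classification tasks: exercise type
#' (task A), attentional focus (task B) and lifted load as a fraction of the
#' one-repetition maximum (task C). Level order is fixed so that class
#' indices, confusion matrices and trained models are reproducible.
#'
#' @return Character vector of levels.
#' @export
exercise_levels <- function() {
  c("bench_press", "pullover", "front_raise", "kickback", "biceps_curl")
}

#' @rdname exercise_levels
#' @export
load_levels <- function() c("rm0", "rm67", "rm85")

#' @rdname exercise_levels
#' @export
attention_levels <- function() c("with", "without")

#' Session metadata
#'
#' Describes one recording session: the subject, which of the five dumbbell
#' exercises was performed, the load (0%, 67% or 85% of the subject's 1RM),
#' whether the subject adopted attentional focus on the target muscle, the
#' session index within the study, and how many repetitions were planned.
#'
#' @param subject_id Character token identifying the subject.
#' @param exercise One of [exercise_levels()].
#' @param load One of [load_levels()].
#' @param attention One of [attention_levels()].
#' @param session_index Integer >= 1.
#' @param planned_reps Planned repetition count (default 12).
#' @param sampling_rate_hz Sampling rate in Hz (default 1000).
#' @return A `session_meta` object (named list).
#' @export
session_meta <- function(subject_id, exercise, load, attention,
                         session_index = 1L, planned_reps = 12L,
                         sampling_rate_hz = 1000) {
  exercise <- match.arg(exercise, exercise_levels())
  load <- match.arg(load, load_levels())
  attention <- match.arg(attention, attention_levels())
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            session_index >= 1, planned_reps >= 1, sampling_rate_hz > 0)
  structure(list(subject_id = subject_id, exercise = exercise, load = load,
                 attention = attention, session_index = as.integer(session_index),
                 planned_reps = as.integer(planned_reps),
                 sampling_rate_hz = sampling_rate_hz),
            class = "session_meta")
}

#' @export
print.session_meta <- function(x, ...) {
  cat(sprintf("<session_meta> subject %s | %s | %s | attention %s | session %d | %d reps planned\n",
              x$subject_id, x$exercise, x$load, x$attention,
              x$session_index, x$planned_reps))
  invisible(x)
}

#' Construct a validated EMG recording
#'
#' A recording is an `n x 8` matrix of raw ADC codes in `[0, 4096]` (the
#' acquisition hardware's range) plus session metadata.
#'
#' @param channels Integer matrix, `n_samples x 8`, values in `[0, 4096]`.
#' @param meta A [session_meta()] object.
#' @return A `recording` object.
#' @export
recording <- function(channels, meta) {
  channels <- as.matrix(channels)
  if (ncol(channels) != N_CHANNELS) {
    stop("recording must have exactly ", N_CHANNELS, " channels, got ",
         ncol(channels), call. = FALSE)
  }
  if (nrow(channels) < 1L) stop("recording must contain at least one sample", call. = FALSE)
  if (!is.numeric(channels) || anyNA(channels)) {
    stop("channel values must be numeric and non-missing", call. = FALSE)
  }
  rng <- range(channels)
  if (rng[1] < 0 || rng[2] > ADC_MAX) {
    stop(sprintf("ADC codes out of range [0, %d]: observed [%g, %g]",
                 ADC_MAX, rng[1], rng[2]), call. = FALSE)
  }
  if (!inherits(meta, "session_meta")) stop("meta must be a session_meta", call. = FALSE)
  storage.mode(channels) <- "integer"
  colnames(channels) <- paste0("ch", seq_len(N_CHANNELS))
  structure(list(channels = channels,
                 sampling_rate_hz = meta$sampling_rate_hz,
                 meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$channels), ncol(x$channels), x$sampling_rate_hz,
              nrow(x$channels) / x$sampling_rate_hz))
  print(x$meta)
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A [recording()].
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) nrow(rec$channels) / rec$sampling_rate_hz

#' Normalize ADC codes to the unit interval
#'
#' Divides every channel by the fixed full-scale value 4096, mapping the
#' hardware range `[0, 4096]` onto `[0, 1]`. The divisor is a property of the
#' ADC, not of the recording: normalization is deliberately not per-recording
#' min-max, so the scale is comparable across sessions and subjects.
#'
#' @param rec A [recording()] or a numeric matrix of ADC codes.
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
normalize_recording <- function(rec) {
  ch <- if (inherits(rec, "recording")) rec$channels else as.matrix(rec)
  ch / ADC_MAX
}

#' Read a recording from disk
#'
#' Expects a comma-delimited table with header `ch1..ch8` (one row per
#' sample, integer ADC codes) and a JSON metadata sidecar at
#' `<path minus .csv>.json` carrying the session metadata fields.
#'
#' @param path Path to the channel CSV.
#' @return A validated [recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path, call. = FALSE)
  sidecar <- sidecar_path(path)
  if (!file.exists(sidecar)) {
    stop("metadata sidecar not found: ", sidecar, call. = FALSE)
  }
  tab <- read.csv(path, check.names = FALSE)
  if (ncol(tab) != N_CHANNELS) {
    stop("expected ", N_CHANNELS, " channel columns, found ", ncol(tab),
         " in ", path, call. = FALSE)
  }
  m <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  required <- c("subject_id", "exercise", "load", "attention",
                "session_index", "planned_reps")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    stop("sidecar ", sidecar, " lacks fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta <- session_meta(m$subject_id, m$exercise, m$load, m$attention,
                       m$session_index, m$planned_reps,
                       if (is.null(m$sampling_rate_hz)) 1000 else m$sampling_rate_hz)
  recording(as.matrix(tab), meta)
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Write a recording to disk
#'
#' Emits the channel CSV and JSON sidecar consumed by [read_recording()];
#' the integer ADC codes and all metadata fields round-trip exactly.
#'
#' @param rec A [recording()].
#' @param path Destination CSV path (sidecar written alongside).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(rec$channels), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(rec$meta), sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Write a feature table to CSV
#'
#' Columns `ch{1..8}_{rms,wl,mav,var,zc,mmdf,mmnf}` plus the label and
#' bookkeeping columns.
#'
#' @param features Data frame from [featurize_study()] or [featurize_recording()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#' @param path CSV path.
#' @return Data frame with feature and label columns.
#' @export
read_features <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  feat <- feature_column_names()
  missing <- setdiff(feat, names(df))
  if (length(missing)) {
    stop("feature table lacks columns: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Canonical 56 feature column names (channel-major)
#' @return Character vector of length 56.
#' @export
feature_column_names <- function() {
  as.vector(t(outer(paste0("ch", 1:8), c("rms", "wl", "mav", "var", "zc", "mmdf", "mmnf"),
                    paste, sep = "_")))
}

#' Write an evaluation report as JSON
#' @param report List produced by [evaluate_model()] or [metrics()].
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
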