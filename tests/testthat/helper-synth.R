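# Shared fixtures, built in code at test time.

default_meta <- function(exercise = "pullover", load = "rm67",
                         attention = "without", subject = "S01", ...) {
  session_meta(subject, exercise, load, attention, ...)
}

# A small session: fewer reps, otherwise default burst structure.
quick_session <- function(seed = 1, reps = 3, exercise = "pullover",
                          load = "rm67", attention = "without", ...) {
  cfg <- generator_config(reps_per_session = reps, ...)
  generate_session(cfg, default_meta(exercise, load, attention), seed)
}

# One subject's full default study as a feature table (cached per options so
# the expensive end-to-end path runs once per combination).
.feature_cache <- new.env()
subject_features <- function(seed = 1, ...) {
  key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.feature_cache[[key]])) {
    cfg <- generator_config(n_subjects = 1, seed = seed, ...)
    recs <- generate_study(cfg, subjects = 1)
    .feature_cache[[key]] <- featurize_study(recs)
  }
  .feature_cache[[key]]
}

# Probability matrix with all mass on the given class per row.
one_hot_probs <- function(k, classes) {
  m <- matrix(0, length(classes), k)
  m[cbind(seq_along(classes), classes)] <- 1
  m
}

# Trivially separable three-task toy features: each (exercise, attention,
# load) combination gets its own well-separated Gaussian blob, with each
# task's signature carried by a disjoint block of feature columns.
toy_features <- function(n_per_combo = 4, seed = 42, sd = 0.02) {
  set.seed(seed)
  combos <- expand.grid(exercise = exercise_levels(), load = load_levels(),
                        attention = attention_levels(),
                        session_index = 1L, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    centre <- numeric(56)
    centre[match(combos$exercise[i], exercise_levels())] <- 3
    centre[10 + match(combos$attention[i], attention_levels())] <- 3
    centre[20 + match(combos$load[i], load_levels())] <- 3
    m <- matrix(rnorm(n_per_combo * 56, 0, sd), n_per_combo, 56, byrow = TRUE)
    m <- sweep(m, 2, centre, "+")
    df <- as.data.frame(m)
    names(df) <- feature_column_names()
    df$subject <- "T01"
    df$exercise <- combos$exercise[i]
    df$load <- combos$load[i]
    df$attention <- combos$attention[i]
    df$session_index <- combos$session_index[i]
    df$rep <- seq_len(n_per_combo)
    df
  })
  do.call(rbind, rows)
}
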