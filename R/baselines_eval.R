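#' Baseline configuration
#'
#' One-vs-one RBF SVM and independently trained single-task networks, the
#' two comparison models. The single-task networks reuse the multitask
#' architecture (trunk + one branch), trained with that task's loss only;
#' the single-task load network has no fusion inputs.
#'
#' @param C SVM soft-margin cost (default 1).
#' @param gamma RBF width; default `NULL` means `1 / (56 * mean feature
#'   variance)` computed on the training data.
#' @return A `baseline_config` object.
#' @export
baseline_config <- function(C = 1, gamma = NULL) {
  structure(list(C = C, gamma = gamma), class = "baseline_config")
}

#' Train a one-vs-one RBF SVM baseline for one task
#'
#' Fits `e1071::svm` (which implements one-vs-one multiclass voting,
#' C(k, 2) pairwise classifiers) on the training rows with an RBF kernel.
#'
#' @param features Feature data frame.
#' @param task `"exercise"`, `"attention"` or `"rm"`.
#' @param cfg A [baseline_config()].
#' @param train_idx Training row indices (default all rows).
#' @return Object of class `svm_baseline` with the fitted model and scaler.
#' @export
train_svm_baseline <- function(features, task = c("exercise", "attention", "rm"),
                               cfg = baseline_config(),
                               train_idx = seq_len(nrow(features))) {
  task <- match.arg(task)
  X <- feature_matrix(features)[train_idx, , drop = FALSE]
  col <- c(exercise = "exercise", attention = "attention", rm = "load")[[task]]
  y <- factor(features[[col]][train_idx], levels = task_levels(task))
  if (length(unique(y)) < 2) {
    stop("training data contain a single class for task ", task, call. = FALSE)
  }
  mu <- colMeans(X); sdv <- apply(X, 2, sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  gamma <- if (is.null(cfg$gamma)) 1 / (ncol(Xs) * mean(apply(Xs, 2, var))) else cfg$gamma
  fit <- e1071::svm(Xs, droplevels(y), kernel = "radial", cost = cfg$C,
                    gamma = gamma, scale = FALSE)
  structure(list(fit = fit, task = task, scaler = list(mu = mu, sd = sdv),
                 levels = task_levels(task)),
            class = "svm_baseline")
}

#' @export
predict.svm_baseline <- function(object, features, ...) {
  X <- if (is.data.frame(features)) feature_matrix(features) else as.matrix(features)
  Xs <- sweep(sweep(X, 2, object$scaler$mu), 2, object$scaler$sd, "/")
  as.character(predict(object$fit, Xs))
}

#' Small grid search for SVM hyperparameters
#'
#' Evaluates a `C` x `gamma` grid on a validation split and returns the pair
#' with the best validation accuracy.
#'
#' @param features Feature data frame.
#' @param task Task name.
#' @param train_idx,val_idx Row-index vectors.
#' @param C_grid,gamma_grid Candidate values (`NA` in `gamma_grid` means the
#'   variance-scaled default).
#' @return List with `C`, `gamma`, `accuracy` and the full grid results.
#' @export
svm_grid_search <- function(features, task, train_idx, val_idx,
                            C_grid = c(0.1, 1, 10),
                            gamma_grid = c(NA, 0.001, 0.01, 0.1)) {
  col <- c(exercise = "exercise", attention = "attention", rm = "load")[[task]]
  truth <- features[[col]][val_idx]
  grid <- expand.grid(C = C_grid, gamma = gamma_grid)
  grid$accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- baseline_config(C = grid$C[i],
                           gamma = if (is.na(grid$gamma[i])) NULL else grid$gamma[i])
    fit <- train_svm_baseline(features, task, cfg, train_idx)
    grid$accuracy[i] <- mean(predict(fit, features[val_idx, ]) == truth)
  }
  best <- grid[which.max(grid$accuracy), ]
  list(C = best$C, gamma = best$gamma, accuracy = best$accuracy, grid = grid)
}

#' Train a single-task network baseline
#'
#' The multitask architecture with the other two loss weights zeroed and no
#' fusion wiring: the trunk and the task's branch are trained with that
#' task's categorical cross-entropy alone.
#'
#' @param features One subject's feature data frame.
#' @param task Task name.
#' @param cfg A [network_config()] (fusion and loss weights are overridden).
#' @param split_mode,split_seed Passed to [train_subject()].
#' @return A trained `multitask_model` whose loss saw only `task`.
#' @export
train_single_task_dnn <- function(features, task = c("exercise", "attention", "rm"),
                                  cfg = network_config(),
                                  split_mode = "per_session_8_2_2",
                                  split_seed = cfg$seed) {
  task <- match.arg(task)
  w <- c(exercise = 0, attention = 0, rm = 0)
  w[task] <- 1
  cfg$fusion <- FALSE
  cfg$loss_weights <- w
  train_subject(features, cfg, split_mode, split_seed)
}

#' Confusion matrix
#'
#' `matrix[true, pred]` counts over a closed label vocabulary.
#'
#' @param pred,truth Equal-length label vectors (character or factor).
#' @param levels Class levels fixing row/column order.
#' @return Integer matrix with `levels` as dimnames.
#' @export
confusion <- function(pred, truth, levels) {
  stopifnot(length(pred) == length(truth))
  pred <- as.character(pred); truth <- as.character(truth)
  bad <- setdiff(unique(c(pred, truth)), levels)
  if (length(bad)) stop("labels outside vocabulary: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cm <- table(factor(truth, levels), factor(pred, levels))
  m <- matrix(as.integer(cm), nrow(cm), dimnames = dimnames(cm))
  names(dimnames(m)) <- c("truth", "pred")
  m
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, overall accuracy `trace/total`, and macro averages.
#' A zero denominator yields `NA` (undefined, not 0) with a warning.
#'
#' @param cm Confusion matrix from [confusion()].
#' @return List with `per_class` (data frame), `macro` (named numerics) and
#'   `accuracy`.
#' @export
metrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), sum(cm) > 0)
  k <- nrow(cm)
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(num, den, what) {
    out <- num / den
    if (any(den == 0)) {
      warning(what, " undefined (zero denominator) for class(es): ",
              paste(rownames(cm)[den == 0], collapse = ", "))
      out[den == 0] <- NA_real_
    }
    out
  }
  per_class <- data.frame(
    class = rownames(cm),
    precision = safe_div(tp, tp + fp, "precision"),
    recall = safe_div(tp, tp + fn, "recall"),
    specificity = safe_div(tn, tn + fp, "specificity"),
    row.names = NULL)
  list(per_class = per_class,
       macro = c(precision = mean(per_class$precision, na.rm = TRUE),
                 recall = mean(per_class$recall, na.rm = TRUE),
                 specificity = mean(per_class$specificity, na.rm = TRUE)),
       accuracy = sum(tp) / total)
}

#' Majority vote within groups
#'
#' Modal label per group; ties break toward the lower class index (and are
#' flagged with a warning).
#'
#' @param labels Label vector.
#' @param groups Grouping vector (same length).
#' @param levels Class levels fixing the tie-break order.
#' @return Named character vector, one label per group.
#' @export
majority_vote <- function(labels, groups, levels = sort(unique(as.character(labels)))) {
  stopifnot(length(labels) == length(groups), length(labels) >= 1)
  labels <- factor(as.character(labels), levels)
  out <- tapply(labels, groups, function(l) {
    counts <- table(l)
    top <- which(counts == max(counts))
    if (length(top) > 1) warning("majority-vote tie broken toward lower class index")
    names(counts)[top[1]]
  })
  setNames(as.character(out), names(out))
}

#' Evaluate a model on a test split
#'
#' Builds per-task confusion matrices and metrics at repetition level and,
#' optionally, after majority voting within an aggregation unit (per
#' subject, the study's headline aggregation, or per session).
#'
#' @param model A trained `multitask_model` or `svm_baseline`.
#' @param features Feature data frame.
#' @param test_idx Row indices to evaluate (default all rows).
#' @param vote_by `"none"`, `"subject"` or `"session"`: majority-voting
#'   unit. For `"subject"` votes are taken within each
#'   (subject, true-condition) block so the voted prediction has a
#'   well-defined true label.
#' @return An `eval_report` list: per task, `confusion`, `metrics`, and (if
#'   voting) `voted_confusion`/`voted_metrics`; plus `aggregation`.
#' @export
evaluate_model <- function(model, features, test_idx = seq_len(nrow(features)),
                           vote_by = c("none", "subject", "session")) {
  vote_by <- c(none = "per_repetition", subject = "per_subject_majority",
               session = "per_session_majority")[[match.arg(vote_by)]]
  df <- features[test_idx, , drop = FALSE]
  if (inherits(model, "multitask_model")) {
    pred <- predict(model, df)$label
    tasks <- TASKS
  } else {
    tasks <- model$task
    pred <- setNames(list(predict(model, df)), model$task)
  }
  truth_col <- c(exercise = "exercise", attention = "attention", rm = "load")
  report <- list(aggregation = vote_by)
  for (t in tasks) {
    lv <- task_levels(t)
    truth <- df[[truth_col[[t]]]]
    cm <- confusion(pred[[t]], truth, lv)
    entry <- list(confusion = cm, metrics = metrics(cm))
    if (vote_by != "per_repetition") {
      unit <- if (vote_by == "per_subject_majority") {
        interaction(df$subject, truth, drop = TRUE)
      } else {
        interaction(df$subject, df$exercise, df$load, df$attention,
                    df$session_index, drop = TRUE)
      }
      voted <- majority_vote(pred[[t]], unit, lv)
      unit_truth <- tapply(as.character(truth), unit, `[`, 1)
      vcm <- confusion(voted[names(unit_truth)], unit_truth, lv)
      entry$voted_confusion <- vcm
      entry$voted_metrics <- metrics(vcm)
    }
    report[[t]] <- entry
  }
  class(report) <- "eval_report"
  report
}
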