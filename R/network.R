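TASKS <- c("exercise", "attention", "rm")

task_levels <- function(task) {
  switch(task,
         exercise = exercise_levels(),
         attention = attention_levels(),
         rm = load_levels())
}

#' Multitask network configuration
#'
#' Architecture: a shared trunk of two fully connected sigmoid layers
#' (56 -> 64, dropout, 64 -> 32) feeding three task branches (one hidden
#' sigmoid layer of 32 each) with softmax classification layers: exercise
#' (5 classes), attentional focus (2), load/%1RM (3). With `fusion = TRUE`
#' the load head's classification layer receives, concatenated to its branch
#' features, the output probability vectors of the exercise and attention
#' heads (32 + 5 + 2 = 39 inputs): because different exercises at different
#' loads can produce EMG of similar energy, the load decision needs to be
#' conditioned on which exercise was performed and whether it was focused.
#' Training minimises the weighted sum of the three categorical
#' cross-entropies with Adam.
#'
#' @param shared_layers Trunk layer widths (default `c(64, 32)`).
#' @param branch_layers Per-task branch hidden widths (default 32).
#' @param dropout_rate Dropout after the first trunk layer (default 0.5).
#' @param fusion Wire exercise/attention outputs into the load head
#'   (default TRUE).
#' @param detach_fusion If TRUE (default) the load loss does not
#'   backpropagate through the fused probability inputs, so it cannot
#'   corrupt the other two heads; FALSE enables joint backprop.
#' @param loss_weights Named task weights `omega` (default all 1 — the three
#'   tasks are equally important).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Maximum training epochs (default 600; training
#'   normally ends earlier via the validation-loss early stop).
#' @param batch_size Minibatch size (default 16).
#' @param patience Early-stop patience on validation loss (default 60).
#' @param seed Seed controlling initialisation, shuffling and dropout.
#' @return A `network_config` object.
#' @export
network_config <- function(shared_layers = c(64, 32), branch_layers = 32,
                           dropout_rate = 0.5, fusion = TRUE,
                           detach_fusion = TRUE,
                           loss_weights = c(exercise = 1, attention = 1, rm = 1),
                           learning_rate = 0.001, epochs = 600,
                           batch_size = 16, patience = 60, seed = 1L) {
  stopifnot(length(shared_layers) == 2, all(shared_layers > 0),
            length(branch_layers) == 1, branch_layers > 0,
            dropout_rate >= 0, dropout_rate < 1,
            all(loss_weights >= 0), learning_rate > 0,
            epochs >= 1, batch_size >= 1)
  if (is.null(names(loss_weights))) names(loss_weights) <- TASKS
  stopifnot(all(TASKS %in% names(loss_weights)))
  structure(list(input_dim = 56L, shared_layers = as.integer(shared_layers),
                 branch_layers = as.integer(branch_layers),
                 dropout_rate = dropout_rate, fusion = fusion,
                 detach_fusion = detach_fusion,
                 n_classes = c(exercise = 5L, attention = 2L, rm = 3L),
                 loss_weights = loss_weights[TASKS],
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "network_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Build (initialise) a multitask network
#'
#' Seeded Glorot-uniform initialisation of every layer in the architecture
#' described by [network_config()].
#'
#' @param cfg A [network_config()].
#' @return A `multitask_model` (untrained; no feature scaler attached yet).
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  set.seed(cfg$seed)
  h1 <- cfg$shared_layers[1]; h2 <- cfg$shared_layers[2]
  bh <- cfg$branch_layers
  w <- list(W1 = glorot(cfg$input_dim, h1), b1 = numeric(h1),
            W2 = glorot(h1, h2), b2 = numeric(h2))
  for (t in TASKS) {
    w[[paste0("Wh_", t)]] <- glorot(h2, bh)
    w[[paste0("bh_", t)]] <- numeric(bh)
    in_dim <- if (t == "rm" && cfg$fusion) bh + 5L + 2L else bh
    w[[paste0("Wo_", t)]] <- glorot(in_dim, cfg$n_classes[[t]])
    w[[paste0("bo_", t)]] <- numeric(cfg$n_classes[[t]])
  }
  structure(list(weights = w, config = cfg, scaler = NULL,
                 levels = lapply(setNames(TASKS, TASKS), task_levels)),
            class = "multitask_model")
}

#' Number of trainable parameters
#' @param model A `multitask_model`.
#' @return Integer parameter count.
#' @export
network_param_count <- function(model) {
  sum(vapply(model$weights, length, integer(1)))
}

# Forward pass. X already scaled. Returns activations needed for backprop.
mtl_forward <- function(w, cfg, X, dropout_mask = NULL) {
  A1 <- sigmoid(sweep(X %*% w$W1, 2, w$b1, "+"))
  A1d <- if (is.null(dropout_mask)) A1 else A1 * dropout_mask
  A2 <- sigmoid(sweep(A1d %*% w$W2, 2, w$b2, "+"))
  H <- P <- list()
  for (t in c("exercise", "attention")) {
    H[[t]] <- sigmoid(sweep(A2 %*% w[[paste0("Wh_", t)]], 2, w[[paste0("bh_", t)]], "+"))
    P[[t]] <- softmax_rows(sweep(H[[t]] %*% w[[paste0("Wo_", t)]], 2, w[[paste0("bo_", t)]], "+"))
  }
  H$rm <- sigmoid(sweep(A2 %*% w$Wh_rm, 2, w$bh_rm, "+"))
  rm_in <- if (cfg$fusion) cbind(H$rm, P$exercise, P$attention) else H$rm
  P$rm <- softmax_rows(sweep(rm_in %*% w$Wo_rm, 2, w$bo_rm, "+"))
  list(A1 = A1, A1d = A1d, A2 = A2, H = H, P = P, rm_in = rm_in)
}

#' Combined multitask loss
#'
#' Weighted sum over tasks of the categorical cross-entropy (mean over the
#' batch): `sum_t omega_t * CE_t`. Probabilities for the true class are
#' clamped at 1e-12 (with a warning) so a confident wrong prediction yields
#' a large finite loss.
#'
#' @param Y Named list of one-hot label matrices (or integer class vectors)
#'   per task.
#' @param P Named list of predicted probability matrices per task.
#' @param weights Named task weights (default all 1).
#' @return Scalar loss.
#' @export
combined_loss <- function(Y, P, weights = c(exercise = 1, attention = 1, rm = 1)) {
  total <- 0
  for (t in names(P)) {
    p <- P[[t]]
    y <- Y[[t]]
    if (is.null(dim(y))) y <- one_hot(y, ncol(p))
    p_true <- rowSums(p * y)
    if (any(p_true < 1e-12)) {
      warning("true-class probability clamped at 1e-12 for task ", t)
      p_true <- pmax(p_true, 1e-12)
    }
    total <- total + weights[[t]] * mean(-log(p_true))
  }
  total
}

one_hot <- function(idx, n_classes) {
  m <- matrix(0, length(idx), n_classes)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

# One gradient evaluation on a batch; returns list(grads, loss).
mtl_backward <- function(w, cfg, X, Y, dropout_mask) {
  n <- nrow(X)
  fw <- mtl_forward(w, cfg, X, dropout_mask)
  om <- cfg$loss_weights
  bh <- cfg$branch_layers

  g <- lapply(w, function(p) array(0, dim = if (is.matrix(p)) dim(p) else length(p)))

  # Softmax+CE logit gradients per head.
  G <- list()
  for (t in TASKS) G[[t]] <- (fw$P[[t]] - Y[[t]]) * (om[[t]] / n)

  # Load head (possibly fused input).
  g$Wo_rm <- t(fw$rm_in) %*% G$rm
  g$bo_rm <- colSums(G$rm)
  dH_rm <- G$rm %*% t(w$Wo_rm[seq_len(bh), , drop = FALSE])

  if (cfg$fusion && !cfg$detach_fusion) {
    dP_ex <- G$rm %*% t(w$Wo_rm[bh + 1:5, , drop = FALSE])
    dP_at <- G$rm %*% t(w$Wo_rm[bh + 5 + 1:2, , drop = FALSE])
    # back through the softmax of the donor heads
    G$exercise <- G$exercise +
      fw$P$exercise * (dP_ex - rowSums(dP_ex * fw$P$exercise))
    G$attention <- G$attention +
      fw$P$attention * (dP_at - rowSums(dP_at * fw$P$attention))
  }

  dA2 <- matrix(0, n, cfg$shared_layers[2])
  for (t in TASKS) {
    dH <- if (t == "rm") dH_rm else G[[t]] %*% t(w[[paste0("Wo_", t)]])
    if (t != "rm") {
      g[[paste0("Wo_", t)]] <- t(fw$H[[t]]) %*% G[[t]]
      g[[paste0("bo_", t)]] <- colSums(G[[t]])
    }
    dZh <- dH * fw$H[[t]] * (1 - fw$H[[t]])
    g[[paste0("Wh_", t)]] <- t(fw$A2) %*% dZh
    g[[paste0("bh_", t)]] <- colSums(dZh)
    dA2 <- dA2 + dZh %*% t(w[[paste0("Wh_", t)]])
  }

  dZ2 <- dA2 * fw$A2 * (1 - fw$A2)
  g$W2 <- t(fw$A1d) %*% dZ2
  g$b2 <- colSums(dZ2)
  dA1 <- (dZ2 %*% t(w$W2))
  if (!is.null(dropout_mask)) dA1 <- dA1 * dropout_mask
  dZ1 <- dA1 * fw$A1 * (1 - fw$A1)
  g$W1 <- t(X) %*% dZ1
  g$b1 <- colSums(dZ1)

  loss <- combined_loss(Y, fw$P, om)
  list(grads = g, loss = loss)
}

#' Repetition-level train/validation/test splits
#'
#' `per_session_8_2_2` (default): within every session — one (subject,
#' exercise, load, attention, session index) block of at least 12
#' repetitions — a seeded shuffle assigns 8 repetitions to training, 2 to
#' validation, 2 to test (extras beyond 12 go to training). Every session
#' therefore appears in every split, so stratification over all three label
#' vocabularies is inherent. `fraction_70_15_15` draws a plain 70/15/15
#' split over all repetitions instead.
#'
#' @param features Feature data frame ([featurize_study()] layout).
#' @param mode `"per_session_8_2_2"` or `"fraction_70_15_15"`.
#' @param seed Shuffle seed.
#' @return Named list of disjoint, exhaustive row-index vectors
#'   `train`, `val`, `test`.
#' @export
make_splits <- function(features, mode = c("per_session_8_2_2", "fraction_70_15_15"),
                        seed = 1L) {
  mode <- match.arg(mode)
  n <- nrow(features)
  set.seed(as.integer(seed))
  if (mode == "fraction_70_15_15") {
    idx <- sample.int(n)
    n_tr <- round(0.70 * n); n_va <- round(0.15 * n)
    return(list(train = sort(idx[seq_len(n_tr)]),
                val = sort(idx[n_tr + seq_len(n_va)]),
                test = sort(idx[(n_tr + n_va + 1):n])))
  }
  key <- interaction(features$subject, features$exercise, features$load,
                     features$attention, features$session_index, drop = TRUE)
  tr <- va <- te <- integer(0)
  for (k in levels(key)) {
    rows <- which(key == k)
    if (length(rows) < 12) {
      stop("session ", k, " has only ", length(rows),
           " repetitions; per_session_8_2_2 needs >= 12", call. = FALSE)
    }
    rows <- rows[sample.int(length(rows))]
    tr <- c(tr, rows[1:8], if (length(rows) > 12) rows[13:length(rows)])
    va <- c(va, rows[9:10])
    te <- c(te, rows[11:12])
  }
  list(train = sort(tr), val = sort(va), test = sort(te))
}

feature_matrix <- function(features) {
  as.matrix(features[, feature_column_names(), drop = FALSE])
}

label_matrices <- function(features) {
  lapply(setNames(TASKS, TASKS), function(t) {
    col <- c(exercise = "exercise", attention = "attention", rm = "load")[[t]]
    idx <- match(features[[col]], task_levels(t))
    if (anyNA(idx)) stop("unknown ", col, " label in feature table", call. = FALSE)
    one_hot(idx, length(task_levels(t)))
  })
}

#' Train a per-subject multitask model
#'
#' Minimises the combined loss on the training split with Adam (learning
#' rate 0.001), selecting the epoch with the best validation combined loss.
#' Features are z-scored with training-split statistics (sigmoid trunks
#' saturate on raw feature magnitudes); the scaler is stored on the model.
#' Deterministic given `cfg$seed`.
#'
#' @param features One subject's feature data frame.
#' @param cfg A [network_config()].
#' @param split_mode Passed to [make_splits()].
#' @param split_seed Seed for the splits (default `cfg$seed`).
#' @return A trained `multitask_model` with elements `log` (per-epoch train
#'   and validation losses), `splits`, and `best_epoch`.
#' @export
train_subject <- function(features, cfg = network_config(),
                          split_mode = "per_session_8_2_2",
                          split_seed = cfg$seed) {
  splits <- make_splits(features, split_mode, seed = split_seed)
  X <- feature_matrix(features)
  Y <- label_matrices(features)

  mu <- colMeans(X[splits$train, , drop = FALSE])
  sdv <- apply(X[splits$train, , drop = FALSE], 2, sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  Xtr <- Xs[splits$train, , drop = FALSE]
  Ytr <- lapply(Y, function(m) m[splits$train, , drop = FALSE])
  Xva <- Xs[splits$val, , drop = FALSE]
  Yva <- lapply(Y, function(m) m[splits$val, , drop = FALSE])

  model <- build_network(cfg)
  w <- model$weights
  adam_m <- lapply(w, function(p) p * 0)
  adam_v <- lapply(w, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  keep <- 1 - cfg$dropout_rate

  n_tr <- nrow(Xtr)
  log_df <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
  best_val <- Inf; best_w <- w; best_epoch <- 0L; stall <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n_tr)
    epoch_loss <- 0; n_batches <- 0L
    for (b0 in seq(1, n_tr, by = cfg$batch_size)) {
      rows <- ord[b0:min(b0 + cfg$batch_size - 1, n_tr)]
      Xb <- Xtr[rows, , drop = FALSE]
      Yb <- lapply(Ytr, function(m) m[rows, , drop = FALSE])
      mask <- if (cfg$dropout_rate > 0) {
        matrix(rbinom(length(rows) * cfg$shared_layers[1], 1, keep),
               length(rows)) / keep
      } else NULL
      bw <- mtl_backward(w, cfg, Xb, Yb, mask)
      step <- step + 1L
      corr <- cfg$learning_rate *
        sqrt(1 - beta2^step) / (1 - beta1^step)
      for (p in names(w)) {
        adam_m[[p]] <- beta1 * adam_m[[p]] + (1 - beta1) * bw$grads[[p]]
        adam_v[[p]] <- beta2 * adam_v[[p]] + (1 - beta2) * bw$grads[[p]]^2
        w[[p]] <- w[[p]] - corr * adam_m[[p]] / (sqrt(adam_v[[p]]) + eps)
      }
      epoch_loss <- epoch_loss + bw$loss; n_batches <- n_batches + 1L
    }
    val_fw <- mtl_forward(w, cfg, Xva)
    val_loss <- combined_loss(Yva, val_fw$P, cfg$loss_weights)
    log_df <- rbind(log_df, data.frame(epoch = epoch,
                                       train_loss = epoch_loss / n_batches,
                                       val_loss = val_loss))
    if (val_loss < best_val - 1e-8) {
      best_val <- val_loss; best_w <- w; best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) {
        message("early stop at epoch ", epoch,
                " (no validation improvement for ", cfg$patience, " epochs)")
        break
      }
    }
  }

  model$weights <- best_w
  model$scaler <- list(mu = mu, sd = sdv)
  model$log <- log_df
  model$splits <- splits
  model$best_epoch <- best_epoch
  model
}

#' Predict with a multitask model
#'
#' Applies the stored feature scaler and returns per-task probabilities and
#' argmax labels (ties break toward the lower class index).
#'
#' @param object A trained `multitask_model`.
#' @param features Feature data frame or 56-column numeric matrix.
#' @param ... Unused.
#' @return List with `prob` (named list of matrices) and `label` (named list
#'   of character vectors).
#' @export
predict.multitask_model <- function(object, features, ...) {
  X <- if (is.data.frame(features)) feature_matrix(features) else as.matrix(features)
  if (ncol(X) != object$config$input_dim) {
    stop("expected ", object$config$input_dim, " feature columns, got ",
         ncol(X), call. = FALSE)
  }
  if (!is.null(object$scaler)) {
    X <- sweep(sweep(X, 2, object$scaler$mu), 2, object$scaler$sd, "/")
  }
  fw <- mtl_forward(object$weights, object$config, X)
  label <- lapply(setNames(TASKS, TASKS), function(t) {
    task_levels(t)[apply(fw$P[[t]], 1, which.max)]
  })
  list(prob = fw$P, label = label)
}

#' @export
print.multitask_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<multitask_model> trunk %d-%d-%d, branches %d, fusion=%s, %d parameters%s\n",
              cfg$input_dim, cfg$shared_layers[1], cfg$shared_layers[2],
              cfg$branch_layers, cfg$fusion, network_param_count(x),
              if (is.null(x$scaler)) " (untrained)" else ""))
  invisible(x)
}
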