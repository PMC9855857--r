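test_that("parameter count matches the analytic layer-shape formula", {
  cfg <- network_config()
  model <- build_network(cfg)
  # independent closed form: sum over layers of (in + 1) * out
  dense <- function(i, o) (i + 1) * o
  expected <- dense(56, 64) + dense(64, 32) +
    3 * dense(32, 32) +
    dense(32, 5) + dense(32, 2) + dense(32 + 5 + 2, 3)
  expect_equal(network_param_count(model), expected)
  # no fusion: load classification layer narrows to the branch width
  m2 <- build_network(network_config(fusion = FALSE))
  expect_equal(network_param_count(m2), expected - dense(39, 3) + dense(32, 3))
  expect_equal(dim(m2$weights$Wo_rm), c(32L, 3L))
  expect_equal(dim(model$weights$Wo_rm), c(39L, 3L))
})

test_that("combined loss obeys its closed forms and is linear in the weights", {
  P_perfect <- list(exercise = one_hot_probs(5, c(1, 3)),
                    attention = one_hot_probs(2, c(2, 1)),
                    rm = one_hot_probs(3, c(3, 2)))
  Y <- list(exercise = c(1, 3), attention = c(2, 1), rm = c(3, 2))
  expect_equal(combined_loss(Y, P_perfect), 0, tolerance = 1e-9)

  P_unif <- list(exercise = matrix(1 / 5, 2, 5), attention = matrix(1 / 2, 2, 2),
                 rm = matrix(1 / 3, 2, 3))
  expect_equal(combined_loss(Y, P_unif), log(5) + log(2) + log(3),
               tolerance = 1e-9)

  # weight masking and linearity
  set.seed(5)
  P_rand <- lapply(list(exercise = 5, attention = 2, rm = 3), function(k) {
    z <- matrix(abs(rnorm(4 * k)) + 0.01, 4, k); z / rowSums(z)
  })
  Y4 <- list(exercise = c(1, 2, 3, 4), attention = c(1, 2, 1, 2), rm = c(1, 2, 3, 1))
  ce <- vapply(names(P_rand), function(t) {
    w <- c(exercise = 0, attention = 0, rm = 0); w[t] <- 1
    combined_loss(Y4, P_rand, w)
  }, numeric(1))
  a <- 0.3; b <- 1.7; d <- 2.5
  expect_equal(combined_loss(Y4, P_rand, c(exercise = a, attention = b, rm = d)),
               a * ce[["exercise"]] + b * ce[["attention"]] + d * ce[["rm"]],
               tolerance = 1e-9)
  expect_equal(combined_loss(Y4, P_rand, c(exercise = 1, attention = 0, rm = 0)),
               ce[["exercise"]], tolerance = 1e-12)
})

test_that("true-class probability of zero is clamped, not infinite", {
  P <- list(attention = matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  Y <- list(attention = c(2, 2))  # first row has zero mass on the truth
  expect_warning(l <- combined_loss(Y, P, c(attention = 1)), "clamped")
  expect_true(is.finite(l))
})

test_that("per-session splits are 8/2/2, disjoint and exhaustive", {
  df <- toy_features(n_per_combo = 12)
  sp <- make_splits(df, seed = 3)
  n_sessions <- nrow(df) / 12
  expect_length(sp$train, 8 * n_sessions)
  expect_length(sp$val, 2 * n_sessions)
  expect_length(sp$test, 2 * n_sessions)
  all_idx <- c(sp$train, sp$val, sp$test)
  expect_length(all_idx, nrow(df))
  expect_length(unique(all_idx), nrow(df))
  # partition property for any seed
  for (s in c(11, 99)) {
    sp2 <- make_splits(df, seed = s)
    expect_setequal(c(sp2$train, sp2$val, sp2$test), seq_len(nrow(df)))
  }
  # a 360-repetition subject maps to (240, 60, 60)
  expect_equal(8 * n_sessions / nrow(df), 240 / 360)

  # undersized session is an error naming the offender
  expect_error(make_splits(toy_features(n_per_combo = 11)), "11 repetitions")

  # fractional mode
  sp3 <- make_splits(df, mode = "fraction_70_15_15", seed = 1)
  expect_equal(length(sp3$train), round(0.7 * nrow(df)))
  expect_setequal(c(sp3$train, sp3$val, sp3$test), seq_len(nrow(df)))
})

test_that("training is deterministic and learns separable toy data perfectly", {
  df <- toy_features(n_per_combo = 12)
  cfg <- network_config(epochs = 150, patience = 150, seed = 13)
  m1 <- train_subject(df, cfg)
  m2 <- train_subject(df, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_equal(m1$log, m2$log)

  # optimization sanity
  expect_lt(tail(m1$log$train_loss, 1), m1$log$train_loss[1])

  # well-separated blobs: perfect test accuracy on all tasks
  pred <- predict(m1, df[m1$splits$test, ])
  expect_equal(mean(pred$label$exercise == df$exercise[m1$splits$test]), 1)
  expect_equal(mean(pred$label$attention == df$attention[m1$splits$test]), 1)
  expect_equal(mean(pred$label$rm == df$load[m1$splits$test]), 1)
})

test_that("prediction contracts hold", {
  df <- toy_features(n_per_combo = 12)
  cfg <- network_config(epochs = 5, patience = 10, seed = 1)
  model <- train_subject(df, cfg)
  pred <- predict(model, df)
  for (t in c("exercise", "attention", "rm")) {
    expect_equal(rowSums(pred$prob[[t]]), rep(1, nrow(df)), tolerance = 1e-6)
  }
  expect_error(predict(model, matrix(0, 2, 40)), "56")

  # fusion wiring leaves the exercise and attention heads untouched:
  # identical trunk + head weights give identical predictions
  nofuse <- model
  nofuse$config$fusion <- FALSE
  nofuse$weights$Wo_rm <- model$weights$Wo_rm[1:32, , drop = FALSE]
  p2 <- predict(nofuse, df)
  expect_equal(p2$prob$exercise, pred$prob$exercise)
  expect_equal(p2$prob$attention, pred$prob$attention)
})

test_that("joint-backprop fusion gradients match finite differences", {
  # numerical check of the analytic gradient, including the softmax
  # Jacobian path through the donor heads
  df <- toy_features(n_per_combo = 2, sd = 0.5)
  cfg <- network_config(dropout_rate = 0, detach_fusion = FALSE, seed = 3)
  model <- build_network(cfg)
  X <- matrix(rnorm(10 * 56), 10, 56)
  Y <- list(exercise = emgfocus:::one_hot(sample(1:5, 10, TRUE), 5),
            attention = emgfocus:::one_hot(sample(1:2, 10, TRUE), 2),
            rm = emgfocus:::one_hot(sample(1:3, 10, TRUE), 3))
  bw <- emgfocus:::mtl_backward(model$weights, cfg, X, Y, NULL)
  loss_at <- function(w) {
    fw <- emgfocus:::mtl_forward(w, cfg, X)
    combined_loss(Y, fw$P, cfg$loss_weights)
  }
  eps <- 1e-6
  for (p in c("W1", "Wh_rm", "Wo_rm", "Wo_exercise", "bo_attention")) {
    w_pert <- model$weights
    i <- sample(length(w_pert[[p]]), 1)
    w_pert[[p]][i] <- w_pert[[p]][i] + eps
    num <- (loss_at(w_pert) - loss_at(model$weights)) / eps
    # gradients are scaled by 1/n inside backward; loss_at is the mean too
    expect_equal(as.numeric(bw$grads[[p]][i]), num, tolerance = 1e-3)
  }
})
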