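test_that("stratified split preserves class balance and is reproducible", {
  labels <- factor(rep(c("fast_thaw", "slow_thaw"), each = 90))
  sp <- stratified_split(labels, 0.8, seed = 5)
  expect_length(sp$train, 144L)
  expect_length(sp$test, 36L)
  expect_equal(as.integer(table(labels[sp$train])), c(72L, 72L))
  expect_equal(as.integer(table(labels[sp$test])), c(18L, 18L))
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  sp2 <- stratified_split(labels, 0.8, seed = 5)
  expect_identical(sp, sp2)
  expect_error(stratified_split(labels, 1), "between 0 and 1")
  expect_error(stratified_split(factor(c("a", "b", "b")), 0.8), "at least 2")
})

test_that("group-aware split keeps a physical sample on one side", {
  labels <- factor(rep(c("fast_thaw", "slow_thaw"), each = 45))
  groups <- rep(sprintf("s%02d", 1:10), each = 9)
  sp <- stratified_split(labels, 0.8, seed = 3, groups = groups)
  overlap <- intersect(unique(groups[sp$train]), unique(groups[sp$test]))
  expect_length(overlap, 0L)
})

test_that("an all-zero network is exactly uninformative", {
  cfg <- lstm_config(hidden_units = 4L, seed = 1)
  set.seed(1)
  m <- lstm_init(cfg, seq_len = 6L)
  m <- lstm_set_param_vector(m, 0 * lstm_param_vector(m))
  m$params$gamma <- rep(1, 4L)  # unit scale: normalization stays defined
  x <- matrix(stats::rnorm(12L), 2L, 6L)
  p <- lstm_forward(m, x)$probs
  expect_equal(unname(p), matrix(0.5, 2L, 2L), tolerance = 1e-12)
  # uniform probabilities give the closed-form binary cross-entropy
  ev <- evaluate_classifier(m, x, c(1L, 2L))
  expect_equal(ev$loss, log(2), tolerance = 1e-12)
})

test_that("softmax rows sum to one and eval mode is deterministic", {
  cfg <- lstm_config(hidden_units = 5L, dropout_rate = 0.5, seed = 2)
  set.seed(2)
  m <- lstm_init(cfg, seq_len = 8L)
  x <- matrix(stats::rnorm(40L), 5L, 8L)
  p1 <- lstm_forward(m, x)$probs
  expect_equal(rowSums(p1), rep(1, 5L), tolerance = 1e-12)
  p2 <- lstm_forward(m, x)$probs
  expect_identical(p1, p2)
})

test_that("analytic gradients match central finite differences", {
  cfg <- lstm_config(hidden_units = 4L, dropout_rate = 0, l2_penalty = 1e-4,
                     seed = 3)
  set.seed(3)
  m <- lstm_init(cfg, seq_len = 5L)
  x <- matrix(stats::rnorm(15L), 3L, 5L)
  y <- c(1L, 2L, 1L)
  analytic <- unlist(lstm_gradients(m, x, y, training = TRUE)$grads)
  numeric_g <- lstm_numeric_gradient(m, x, y)
  rel <- abs(analytic - numeric_g) /
    pmax(pmax(abs(analytic), abs(numeric_g)), 1e-4)
  expect_lt(max(rel), 1e-5)
})

test_that("the ridge term contributes exactly 2 * lambda * w", {
  set.seed(4)
  cfg0 <- lstm_config(hidden_units = 3L, dropout_rate = 0, l2_penalty = 0)
  m0 <- lstm_init(cfg0, seq_len = 4L)
  m1 <- m0
  m1$config$l2_penalty <- 0.01
  x <- matrix(stats::rnorm(8L), 2L, 4L)
  y <- c(1L, 2L)
  g0 <- lstm_gradients(m0, x, y, training = TRUE)$grads
  g1 <- lstm_gradients(m1, x, y, training = TRUE)$grads
  for (nm in c("W1", "U1", "W2", "U2", "Wd")) {
    expect_equal(g1[[nm]] - g0[[nm]], 2 * 0.01 * m0$params[[nm]],
                 tolerance = 1e-12)
  }
  expect_equal(g1$b1, g0$b1, tolerance = 1e-12)  # biases unpenalized
})

test_that("training separates a trivially separable sequence task", {
  set.seed(6)
  n <- 60L; Tn <- 10L
  x <- rbind(matrix(stats::rnorm(n / 2 * Tn, 1, 0.2), n / 2, Tn),
             matrix(stats::rnorm(n / 2 * Tn, -1, 0.2), n / 2, Tn))
  y <- factor(rep(c("up", "down"), each = n / 2))
  res <- train_classifier(x, y, lstm_config(hidden_units = 8L,
                                            max_epochs = 50L,
                                            patience = 50L, seed = 2))
  expect_equal(res$report$heldout_accuracy, 1.0)
  h <- res$report$history
  expect_lt(h$train_loss[min(10L, nrow(h))], h$train_loss[1L])
})

test_that("label permutation drives accuracy to chance", {
  co <- small_cohort(seed = 19, n_fast = 4L, n_slow = 4L)
  f <- cohort_features(co, "X")
  set.seed(77)
  y_perm <- factor(sample(as.character(f$labels)))
  res <- train_classifier(f$x, y_perm,
                          lstm_config(hidden_units = 8L, max_epochs = 25L,
                                      patience = 25L, seed = 7))
  expect_gte(res$report$heldout_accuracy, 0.2)
  expect_lte(res$report$heldout_accuracy, 0.8)
})

test_that("training is deterministic from the config seed", {
  co <- small_cohort(seed = 23, n_fast = 3L, n_slow = 3L)
  f <- cohort_features(co, "R")
  cfg <- lstm_config(hidden_units = 6L, max_epochs = 8L, patience = 8L,
                     seed = 13)
  r1 <- train_classifier(f$x, f$labels, cfg)
  r2 <- train_classifier(f$x, f$labels, cfg)
  expect_identical(r1$report$history, r2$report$history)
  expect_identical(lstm_param_vector(r1$model), lstm_param_vector(r2$model))
})

test_that("a serialized model predicts identically after reload", {
  co <- small_cohort(seed = 29, n_fast = 3L, n_slow = 3L)
  f <- cohort_features(co, "X")
  res <- train_classifier(f$x, f$labels,
                          lstm_config(hidden_units = 6L, max_epochs = 5L,
                                      patience = 5L, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier_json(res$model, path)
  back <- read_classifier_json(path)
  ev1 <- evaluate_classifier(res$model, f$x, f$labels)
  ev2 <- evaluate_classifier(back, f$x, f$labels)
  expect_identical(ev1$accuracy, ev2$accuracy)
  expect_equal(predict_classifier(back, f$x),
               predict_classifier(res$model, f$x), tolerance = 1e-12)
})

test_that("non-finite inputs are rejected before the forward pass", {
  cfg <- lstm_config(hidden_units = 3L)
  set.seed(1)
  m <- lstm_init(cfg, seq_len = 4L)
  x <- matrix(c(1, NA, 0, 1, 2, 3, 4, 5), 2L, 4L)
  expect_error(lstm_forward(m, x), "non-finite")
})
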