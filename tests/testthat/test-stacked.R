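test_that("softmax is symmetric, shift-invariant and matches the formula", {
  expect_equal(softmax(c(0, 0, 0, 0)), rep(0.25, 4))
  set.seed(31)
  for (i in 1:20) {
    z <- rnorm(sample(2:6, 1), sd = 5)
    p <- softmax(z)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, exp(z) / sum(exp(z)), tolerance = 1e-12)
    expect_equal(softmax(z + rnorm(1) * 100), p, tolerance = 1e-12)
  }
  # extreme logits stay finite
  expect_equal(sum(softmax(c(1000, 0, -1000))), 1, tolerance = 1e-12)
})

test_that("pretraining chains layer inputs to previous hidden outputs", {
  set.seed(32)
  X <- matrix(runif(30 * 8), 30, 8)
  cfg <- train_config(hidden_size = 5L, max_epochs = 20L, seed = 33L)
  layers <- sae_pretrain(X, c(10L, 15L), cfg)
  expect_length(layers, 2L)
  expect_equal(dim(layers[[1L]]$W), c(10L, 8L))
  expect_equal(dim(layers[[2L]]$W), c(15L, 10L))
  # a single layer equals train_ae on the raw features (same derived seed)
  single <- sae_pretrain(X, 6L, cfg)
  cfg1 <- cfg
  cfg1$hidden_size <- 6L
  cfg1$seed <- ridergait:::derive_seed(cfg$seed, 101L)
  expect_identical(single[[1L]], train_ae(X, cfg1)$params)
})

test_that("an untuned model with zero head outputs uniform probabilities", {
  set.seed(34)
  X <- matrix(runif(10 * 8), 10, 8)
  layers <- sae_pretrain(X, 4L, train_config(max_epochs = 5L, seed = 35L))
  model <- sae_model(layers, c("a", "b", "c"))
  P <- sae_predict_proba(model, X)
  expect_equal(unname(P), matrix(1 / 3, 10, 3), tolerance = 1e-12)
})

test_that("stacked-objective gradients match central differences", {
  set.seed(36)
  X <- matrix(runif(6 * 5, 0.1, 0.9), 6, 5)
  labels <- rep(c("a", "b"), 3)
  cfg <- train_config(hidden_size = 4L, max_epochs = 3L, seed = 37L,
                      l2_weight = 1e-3)
  layers <- sae_pretrain(X, c(4L, 3L), cfg)
  model <- sae_model(layers, c("a", "b"), cfg)
  model$head$weights[] <- rnorm(length(model$head$weights), sd = 0.3)
  model$head$biases[] <- rnorm(2, sd = 0.1)
  Y <- ridergait:::.one_hot(labels, c("a", "b"))
  g <- ridergait:::sae_gradients(model, X, Y, cfg$l2_weight)
  loss_fn <- function(m) ridergait:::sae_loss(m, X, Y, cfg$l2_weight)
  # head blocks
  for (blk in c("weights", "biases")) {
    num <- g[[paste0("head_", blk)]]
    num[] <- NA_real_
    for (i in seq_along(num)) {
      m1 <- model; m2 <- model
      m1$head[[blk]][i] <- m1$head[[blk]][i] + 1e-6
      m2$head[[blk]][i] <- m2$head[[blk]][i] - 1e-6
      num[i] <- (loss_fn(m1) - loss_fn(m2)) / 2e-6
    }
    expect_lt(max_rel_err(g[[paste0("head_", blk)]], num), 1e-6)
  }
  # encoder blocks of both layers
  for (k in 1:2) {
    for (blk in c("W", "b")) {
      num <- g[[blk]][[k]]
      num[] <- NA_real_
      for (i in seq_along(num)) {
        m1 <- model; m2 <- model
        m1$layers[[k]][[blk]][i] <- m1$layers[[k]][[blk]][i] + 1e-6
        m2$layers[[k]][[blk]][i] <- m2$layers[[k]][[blk]][i] - 1e-6
        num[i] <- (loss_fn(m1) - loss_fn(m2)) / 2e-6
      }
      expect_lt(max_rel_err(g[[blk]][[k]], num), 1e-6)
    }
  }
})

test_that("fine-tuning separates two linearly separable classes", {
  blob <- make_blob_features(n_per_class = 50L, d = 40L, gap = 0.4, seed = 38L)
  cfg <- train_config(hidden_size = 10L, max_epochs = 3000L, seed = 39L)
  model <- train_sae(blob$X, blob$labels, hidden_sizes = 10L, config = cfg)
  expect_true(model$fine_tuned)
  acc <- mean(classify(model, blob$X) == blob$labels)
  expect_equal(acc, 1.0)
  # loss strictly below the uniform-probability starting point
  expect_lt(tail(model$trace$loss, 1), log(2))
})

test_that("zero learning rate leaves the model unchanged", {
  set.seed(40)
  X <- matrix(runif(20 * 5), 20, 5)
  labels <- rep(c("a", "b"), 10)
  cfg <- train_config(hidden_size = 3L, max_epochs = 10L, seed = 41L)
  layers <- sae_pretrain(X, 3L, cfg)
  model <- sae_model(layers, c("a", "b"), cfg)
  cfg0 <- cfg
  cfg0$learning_rate <- 0
  tuned <- sae_fine_tune(model, X, labels, cfg0)
  expect_identical(tuned$layers, model$layers)
  expect_identical(tuned$head$weights, model$head$weights)
})

test_that("fine-tuning requires at least two classes", {
  set.seed(42)
  X <- matrix(runif(10 * 4), 10, 4)
  layers <- sae_pretrain(X, 3L, train_config(max_epochs = 2L, seed = 43L))
  model <- sae_model(layers, c("a", "b"))
  expect_error(sae_fine_tune(model, X, rep("a", 10), model$config),
               "at least two classes")
})

test_that("prediction equals stage-wise recomputation and survives a round trip", {
  set.seed(44)
  X <- matrix(runif(15 * 6), 15, 6)
  labels <- rep(c("a", "b", "c"), 5)
  cfg <- train_config(hidden_size = 4L, max_epochs = 50L, seed = 45L)
  model <- train_sae(X, labels, hidden_sizes = c(5L, 4L), config = cfg)
  P <- sae_predict_proba(model, X)
  expect_equal(unname(rowSums(P)), rep(1, 15), tolerance = 1e-12)
  # manual layer-by-layer evaluation
  H <- X
  for (lay in model$layers) {
    H <- 1 / (1 + exp(-(H %*% t(lay$W) + rep(lay$b, each = nrow(H)))))
  }
  logits <- H %*% t(model$head$weights) + rep(model$head$biases, each = nrow(H))
  expect_equal(unname(P), unname(t(apply(logits, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))),
               tolerance = 1e-12)
  # serialization round trip is bit-exact
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back, model)
  expect_identical(sae_predict_proba(back, X), P)
  expect_error(sae_predict_proba(model, X[, 1:3]), "width mismatch")
})

test_that("pretrained encoders beat frozen random encoders on training loss", {
  for (seed in c(51L, 52L, 53L)) {
    blob <- make_blob_features(n_per_class = 30L, d = 20L, gap = 0.3,
                               seed = seed)
    cfg <- train_config(hidden_size = 8L, max_epochs = 400L, seed = seed)
    Y <- ridergait:::.one_hot(blob$labels, c("a", "b"))
    # pretrain + fine-tune everything
    tuned <- train_sae(blob$X, blob$labels, hidden_sizes = 8L, config = cfg,
                       class_names = c("a", "b"))
    loss_tuned <- ridergait:::sae_loss(tuned, blob$X, Y, cfg$l2_weight)
    # frozen random encoder, head-only training
    frozen <- sae_model(list(ae_init(20L, 8L, seed = seed)), c("a", "b"), cfg)
    for (epoch in seq_len(cfg$max_epochs)) {
      g <- ridergait:::sae_gradients(frozen, blob$X, Y, cfg$l2_weight)
      frozen$head$weights <- frozen$head$weights - cfg$learning_rate * g$head_weights
      frozen$head$biases <- frozen$head$biases - cfg$learning_rate * g$head_biases
    }
    loss_frozen <- ridergait:::sae_loss(frozen, blob$X, Y, cfg$l2_weight)
    expect_lte(loss_tuned, loss_frozen + 1e-9)
  }
})
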