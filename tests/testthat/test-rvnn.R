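test_that("composition applies tanh(W [left; right]) exactly", {
  W0 <- matrix(0, 2, 4)
  expect_equal(compose(c(0.3, -0.7), c(0.1, 0.9), W0), c(0, 0))

  W <- rbind(c(1, 0, 0, 0), c(0, 0, 0, 1))
  out <- compose(c(0.5, -0.2), c(0.1, 0.3), W)
  expect_equal(out, c(tanh(0.5), tanh(0.3)), tolerance = 1e-12)
  expect_equal(out, c(0.46211716, 0.29131261), tolerance = 1e-7)

  # strict tanh bounds and oddness in the concatenated input
  set.seed(6)
  for (i in 1:20) {
    W <- matrix(rnorm(2 * 3 * 3), 3, 6)
    l <- rnorm(3); r <- rnorm(3)
    o <- compose(l, r, W)
    expect_true(all(abs(o) < 1))
    expect_equal(compose(-l, -r, W), -o, tolerance = 1e-12)
  }
  expect_error(compose(c(1, 2), c(1, 2, 3), matrix(0, 2, 4)),
               class = "momofuse_parameter_error")
})

test_that("forward pass yields normalized probabilities; zero parameters give uniform", {
  spans <- list(ambient = 1:3, motion = 4:8, vision = 9:12)
  params <- rvnn_init(c(3, 5, 4), n = 6, n_classes = 4, seed = 2)
  set.seed(8)
  X <- matrix(rnorm(100 * 12), 100, 12)
  P <- rvnn_forward(params, X, spans)
  expect_equal(rowSums(P), rep(1, 100), tolerance = 1e-9)
  expect_true(all(P > 0))

  zero <- params
  zero$W[] <- 0; zero$V[] <- 0; zero$c[] <- 0
  for (m in names(zero$leaf)) { zero$leaf[[m]]$U[] <- 0; zero$leaf[[m]]$b[] <- 0 }
  expect_equal(rvnn_forward(zero, X[1, ], spans), rep(0.25, 4), tolerance = 1e-12)

  # balanced tree also normalizes
  Pb <- rvnn_forward(params, X, spans, tree_shape = "balanced")
  expect_equal(rowSums(Pb), rep(1, 100), tolerance = 1e-9)
})

test_that("analytic gradients agree with central differences in every block", {
  spans <- list(ambient = 1:2, motion = 3:5, vision = 6:7)
  set.seed(10)
  X <- matrix(rnorm(8 * 7), 8, 7)
  Y <- diag(3)[sample(1:3, 8, replace = TRUE), ]
  for (shape in c("left-deep", "balanced")) {
    params <- rvnn_init(c(2, 3, 2), n = 3, n_classes = 3, seed = 4)
    lg <- momofuse:::rvnn_loss_grad(params, X, Y, spans, shape, l2 = 1e-3)
    eps <- 1e-6
    fd <- function(setter) {
      p1 <- setter(params, +eps); p2 <- setter(params, -eps)
      (momofuse:::rvnn_loss_grad(p1, X, Y, spans, shape, l2 = 1e-3)$loss -
       momofuse:::rvnn_loss_grad(p2, X, Y, spans, shape, l2 = 1e-3)$loss) / (2 * eps)
    }
    checks <- list(
      list(g = lg$grads$W[2, 5],
           s = function(p, e) { p$W[2, 5] <- p$W[2, 5] + e; p }),
      list(g = lg$grads$V[1, 2],
           s = function(p, e) { p$V[1, 2] <- p$V[1, 2] + e; p }),
      list(g = lg$grads$c[3],
           s = function(p, e) { p$c[3] <- p$c[3] + e; p }),
      list(g = lg$grads$leaf$ambient$U[1, 2],
           s = function(p, e) { p$leaf$ambient$U[1, 2] <- p$leaf$ambient$U[1, 2] + e; p }),
      list(g = lg$grads$leaf$motion$U[3, 1],
           s = function(p, e) { p$leaf$motion$U[3, 1] <- p$leaf$motion$U[3, 1] + e; p }),
      list(g = lg$grads$leaf$vision$b[2],
           s = function(p, e) { p$leaf$vision$b[2] <- p$leaf$vision$b[2] + e; p }))
    for (ch in checks) {
      num <- fd(ch$s)
      expect_equal(ch$g, num, tolerance = 1e-4)
    }
  }
})

test_that("training separates linearly separable classes and is seed-deterministic", {
  set.seed(15)
  n_per <- 200
  spans <- list(ambient = 1:2, motion = 3:4, vision = 5:6)
  mu <- rbind(c(2, 0, 0, 0, 0, 0), c(0, 0, 2, 0, 0, 0), c(0, 0, 0, 0, 2, 0))
  X <- do.call(rbind, lapply(1:3, function(k)
    matrix(rnorm(n_per * 6, mean = rep(mu[k, ], each = n_per), sd = 0.4),
           n_per, 6)))
  y <- rep(1:3, each = n_per)
  cfg <- train_config(n = 8, epochs = 60, learning_rate = 0.05, seed = 3)
  model <- rvnn_train(X, y, cfg, spans = spans)
  expect_gte(model$train_accuracy, 0.95)

  model2 <- rvnn_train(X, y, cfg, spans = spans)
  expect_identical(model$loss_history, model2$loss_history)

  # label permutation control: shuffled labels give near-chance accuracy
  set.seed(99)
  ysh <- sample(y)
  msh <- rvnn_train(X, ysh, cfg, spans = spans)
  expect_lt(msh$train_accuracy, model$train_accuracy - 0.3)

  expect_error(rvnn_train(X, rep(1, length(y)), cfg, spans = spans),
               class = "momofuse_training_error")
})

test_that("stratified k-fold evaluation partitions windows correctly", {
  set.seed(30)
  labels <- rep(1:5, each = 100)
  folds <- momofuse:::stratified_folds(labels, 10, seed = 7)
  expect_setequal(unique(folds), 1:10)
  sizes <- table(folds)
  expect_true(all(abs(sizes - 50) <= 1))
  # per-fold class proportions within one window of balance
  for (f in 1:10) for (cl in 1:5)
    expect_lte(abs(sum(labels[folds == f] == cl) - 10), 1)

  # folds cover all windows exactly once
  expect_length(folds, length(labels))

  # a perfectly separable problem scores 1.0 in every fold
  spans <- list(ambient = integer(0), motion = 1:2, vision = integer(0))
  X <- cbind(rep(c(0, 10), each = 50) + rnorm(100, 0, 0.1), rnorm(100))
  y <- rep(1:2, each = 50)
  res <- kfold_evaluate(X, y, k = 5,
                        cfg = train_config(n = 4, epochs = 40,
                                           learning_rate = 0.1, seed = 1),
                        seed = 2, spans = spans)
  expect_true(all(res$fold_accuracy == 1))
  expect_equal(res$mean_class_accuracy, 1)
  expect_equal(unname(diag(res$confusion$matrix)), c(1, 1))

  expect_error(kfold_evaluate(X, y, k = 1), class = "momofuse_parameter_error")
  few <- c(1:4, 51:54)
  w <- capture_warnings(kfold_evaluate(X[few, ], y[few], k = 10,
                                       cfg = train_config(n = 2, epochs = 5, seed = 1),
                                       spans = spans))
  expect_true(any(grepl("reducing k", w)))
})
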