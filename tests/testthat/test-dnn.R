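test_that("activations follow their formulas and softmax is overflow-safe", {
  expect_equal(relu(c(-2, 3)), c(0, 3))
  expect_equal(linear(c(-2, 3)), c(-2, 3))
  expect_equal(as.numeric(softmax_rows(matrix(c(0, 0), 1))), c(0.5, 0.5))

  big <- softmax_rows(matrix(c(1000, 0), 1))
  # extended-precision reference: 1/(1+exp(-1000)) is 1 to double precision
  expect_equal(as.numeric(big), c(1, 0))
  expect_false(any(is.nan(big)))

  set.seed(1)
  m <- matrix(rnorm(50 * 6, sd = 5), 50, 6)
  s <- softmax_rows(m)
  expect_true(all(abs(rowSums(s) - 1) < 1e-9))
  expect_true(all(s > 0))
  # invariance to adding a constant to every input of a row
  expect_equal(softmax_rows(m + 7), s)
})

test_that("the network specification matches the published architecture", {
  spec <- build_network(12, "age_class")
  expect_equal(spec$n_main_layers, 9L)
  expect_equal(spec$input_dim, 12L)
  expect_equal(spec$trunk, c(1024L, 512L, 256L, 128L, 64L, 32L, 16L, 8L))
  expect_equal(spec$head_dim, 4L)
  expect_equal(spec$trunk_activations, c(rep("relu", 7), "softmax"))
  expect_equal(spec$head_activation, "linear")

  # dropping features changes only the input width
  spec9 <- build_network(9, "age_class")
  expect_equal(spec9$trunk, spec$trunk)
  expect_equal(spec9$input_dim, 9L)

  expect_equal(build_network(12, "sex")$head_dim, 2L)
  expect_equal(build_network(12, "age_regression")$head_dim, 1L)
  expect_error(build_network(0, "sex"), "positive")

  expect_equal(train_config()$epochs, 100L)

  params <- gadnn:::dnn_init(spec)
  expect_equal(dim(params[[1]]$W), c(12, 1024))
  expect_equal(dim(params[[9]]$W), c(8, 4))
})

test_that("training is seeded and bit-reproducible; inference deterministic", {
  set.seed(3)
  x <- matrix(runif(60 * 12), 60, 12)
  lab <- sample(c("F", "M"), 60, TRUE)
  y <- one_hot(lab, c("F", "M"))
  spec <- build_network(12, "sex")
  cfg <- train_config(epochs = 4, seed = 99)
  f1 <- dnn_train(spec, x, y, cfg)
  f2 <- dnn_train(spec, x, y, cfg)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$params, f2$params)
  expect_true(all(is.finite(f1$loss_trace)))
  p1 <- predict(f1, x)
  expect_identical(p1, predict(f1, x))
  expect_equal(ncol(p1), 2)
  expect_error(dnn_train(spec, x[, 1:5], y, cfg), "input_dim")
  expect_error(predict(f1, x[, 1:5]), "input_dim")
})

test_that("an untrained network performs at chance on balanced labels", {
  set.seed(8)
  x <- matrix(runif(500 * 12), 500, 12)
  lab <- rep(c("F", "M"), 250)
  spec <- build_network(12, "sex")
  f0 <- dnn_train(spec, x, one_hot(lab, c("F", "M")),
                  train_config(epochs = 0, seed = 1))
  expect_length(f0$loss_trace, 0)
  acc <- mean(as.character(predict(f0, x, type = "label")) == lab)
  # two-sided binomial test against 0.5
  expect_gt(stats::binom.test(round(acc * 500), 500, 0.5)$p.value, 1e-4)
})

test_that("well-separated classes are fit perfectly", {
  set.seed(5)
  n <- 200
  x <- matrix(rnorm(n * 12), n, 12)
  lab <- rep(c("A", "B"), each = n / 2)
  x[lab == "B", ] <- x[lab == "B", ] + 10 / sqrt(12) # centroid distance 10 SD
  x <- minmax_normalize(x)$train
  fit <- dnn_train(build_network(12, "sex"), x, one_hot(lab, c("A", "B")),
                   train_config(epochs = 60, dropout = 0, seed = 1))
  expect_equal(mean(as.character(predict(fit, x, type = "label")) == lab), 1.0)
  expect_true(all(is.finite(fit$loss_trace)))
})

test_that("the network can memorize a small random-label problem", {
  set.seed(6)
  x <- matrix(runif(50 * 12), 50, 12)
  lab <- sample(c("A", "B"), 50, TRUE)
  fit <- dnn_train(build_network(12, "sex"), x, one_hot(lab, c("A", "B")),
                   train_config(epochs = 300, lr = 0.05, dropout = 0, seed = 1))
  acc <- mean(as.character(predict(fit, x, type = "label")) == lab)
  expect_gte(acc, 0.99)
})
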