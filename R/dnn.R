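#' Activation functions
#'
#' The three activations used by the network: rectified linear
#' `relu(x) = max(x, 0)`, the softmax map
#' `softmax(x)_i = exp(x_i) / sum_j exp(x_j)` (computed with max-subtraction
#' so large inputs cannot overflow), and the identity `linear(x) = x`.
#'
#' @param x numeric vector or matrix (for `softmax_rows`, a matrix whose rows
#'   are transformed independently).
#' @return Transformed values; `softmax_rows` rows are positive and sum to 1.
#' @export
#' @examples
#' relu(c(-2, 3))
#' softmax_rows(matrix(c(0, 0), 1))
relu <- function(x) pmax(x, 0)

#' @rdname relu
#' @export
softmax_rows <- function(x) {
  x <- as.matrix(x)
  shifted <- x - apply(x, 1, max)
  e <- exp(shifted)
  e / rowSums(e)
}

#' @rdname relu
#' @export
linear <- function(x) x

#' Build the fixed nine-layer network specification
#'
#' The trunk is always the eight dense layers of widths 1024, 512, 256, 128,
#' 64, 32, 16, 8, with batch normalization after every trunk layer, ReLU on
#' trunk layers 1--7 and softmax on trunk layer 8; the ninth (output) layer is
#' a linear head whose width follows the task: 4 units for the four age
#' groups, 2 for sex, 1 for continuous age. Only the input width changes when
#' features are dropped by the genetic algorithm.
#'
#' @param input_dim number of input features (>= 1).
#' @param task one of `"sex"`, `"age_class"`, `"age_regression"`.
#' @return A list of class `network_spec`.
#' @export
#' @examples
#' build_network(12, "age_class")
build_network <- function(input_dim,
                          task = c("sex", "age_class", "age_regression")) {
  task <- match.arg(task)
  input_dim <- as.integer(input_dim)
  if (is.na(input_dim) || input_dim < 1) {
    stop("build_network: input_dim must be a positive integer")
  }
  trunk <- c(1024L, 512L, 256L, 128L, 64L, 32L, 16L, 8L)
  head_dim <- switch(task, sex = 2L, age_class = 4L, age_regression = 1L)
  structure(list(
    input_dim = input_dim,
    trunk = trunk,
    head_dim = head_dim,
    task = task,
    trunk_activations = c(rep("relu", 7), "softmax"),
    head_activation = "linear",
    batchnorm = TRUE,
    n_main_layers = length(trunk) + 1L
  ), class = "network_spec")
}

#' Training configuration for the dense network
#'
#' The loss is the mean squared error between the network output and the
#' (one-hot or raw) target, optimized by plain stochastic gradient descent.
#' Epochs default to 100. The remaining knobs (learning rate, batch size,
#' dropout rate, batch-norm momentum, initialization scale) are artifact
#' defaults, all overridable.
#'
#' @param epochs number of passes over the training data (>= 0).
#' @param lr SGD learning rate (> 0).
#' @param batch_size minibatch size (>= 1).
#' @param dropout dropout rate on trunk activations, in `[0, 1)`.
#' @param bn_momentum running-statistics momentum of batch normalization.
#' @param head `"linear"` implements the literal architecture (softmax on
#'   trunk layer 8, linear output); `"softmax"` applies a conventional
#'   softmax on the head instead (classification only).
#' @param loss `"mse"` (default) or `"cross_entropy"` (non-default option,
#'   classification with softmax head only).
#' @param seed integer seed governing initialization, batching and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100, lr = 0.01, batch_size = 16,
                         dropout = 0.2, bn_momentum = 0.9,
                         head = c("linear", "softmax"),
                         loss = c("mse", "cross_entropy"),
                         seed = 1) {
  head <- match.arg(head)
  loss <- match.arg(loss)
  stopifnot(epochs >= 0, lr > 0, batch_size >= 1,
            dropout >= 0, dropout < 1,
            bn_momentum >= 0, bn_momentum < 1)
  if (loss == "cross_entropy" && head != "softmax") {
    stop("train_config: cross-entropy requires the softmax head")
  }
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), dropout = dropout,
                 bn_momentum = bn_momentum, head = head, loss = loss,
                 seed = as.integer(seed)),
            class = "train_config")
}

# fan-in scaled uniform initialization of all weights and batch-norm
# parameters; consumes RNG in a fixed order so training is bit-reproducible.
dnn_init <- function(spec) {
  widths <- c(spec$input_dim, spec$trunk, spec$head_dim)
  n_layers <- length(widths) - 1
  params <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    d_in <- widths[l]; d_out <- widths[l + 1]
    s <- 1 / sqrt(d_in)
    p <- list(W = matrix(stats::runif(d_in * d_out, -s, s), d_in, d_out))
    if (l <= length(spec$trunk)) {
      # batch-norm absorbs any bias on trunk layers
      p$gamma <- rep(1, d_out)
      p$beta <- rep(0, d_out)
      p$r_mean <- rep(0, d_out)
      p$r_var <- rep(1, d_out)
    } else {
      p$b <- rep(0, d_out)
    }
    params[[l]] <- p
  }
  params
}

bn_eps <- 1e-5

# Forward pass. In training mode batch statistics are used (and running
# statistics updated in-place via the returned params); in inference mode the
# running statistics are used and dropout is disabled.
dnn_forward <- function(params, spec, cfg, x, training = FALSE) {
  n_trunk <- length(spec$trunk)
  cache <- list(a = vector("list", n_trunk + 1), bn = vector("list", n_trunk),
                act = vector("list", n_trunk), drop = vector("list", n_trunk))
  a <- x
  for (l in seq_len(n_trunk)) {
    cache$a[[l]] <- a
    z <- a %*% params[[l]]$W
    if (training) {
      mu <- colMeans(z)
      v <- colMeans(z^2) - mu^2
      params[[l]]$r_mean <- cfg$bn_momentum * params[[l]]$r_mean +
        (1 - cfg$bn_momentum) * mu
      params[[l]]$r_var <- cfg$bn_momentum * params[[l]]$r_var +
        (1 - cfg$bn_momentum) * v
    } else {
      mu <- params[[l]]$r_mean
      v <- params[[l]]$r_var
    }
    inv_sd <- 1 / sqrt(v + bn_eps)
    zhat <- sweep(sweep(z, 2, mu, "-"), 2, inv_sd, "*")
    h <- sweep(sweep(zhat, 2, params[[l]]$gamma, "*"), 2, params[[l]]$beta, "+")
    cache$bn[[l]] <- list(zhat = zhat, inv_sd = inv_sd)
    act <- spec$trunk_activations[l]
    s <- if (act == "relu") relu(h) else softmax_rows(h)
    cache$act[[l]] <- s
    if (training && cfg$dropout > 0) {
      keep <- matrix(stats::runif(length(s)) >= cfg$dropout,
                     nrow(s), ncol(s)) / (1 - cfg$dropout)
      cache$drop[[l]] <- keep
      a <- s * keep
    } else {
      a <- s
    }
  }
  cache$a[[n_trunk + 1]] <- a
  out <- a %*% params[[n_trunk + 1]]$W
  out <- sweep(out, 2, params[[n_trunk + 1]]$b, "+")
  if (cfg$head == "softmax") out <- softmax_rows(out)
  list(out = out, cache = cache, params = params)
}

# Backward pass + SGD update for one minibatch. Returns updated params and
# the batch loss.
dnn_step <- function(params, spec, cfg, x, y) {
  fw <- dnn_forward(params, spec, cfg, x, training = TRUE)
  params <- fw$params
  out <- fw$out
  n <- nrow(x)
  k <- ncol(out)
  if (cfg$loss == "mse") {
    loss <- mean((out - y)^2)
    d <- 2 * (out - y) / (n * k)
  } else {
    p <- pmax(out, 1e-12)
    loss <- -mean(rowSums(y * log(p)))
    d <- -(y / p) / n
  }
  if (!is.finite(loss)) {
    stop("dnn_train: non-finite training loss; reduce the learning rate")
  }
  if (cfg$head == "softmax") {
    s <- out
    d <- s * (d - rowSums(d * s))
  }
  n_trunk <- length(spec$trunk)
  hl <- n_trunk + 1
  a_head <- fw$cache$a[[hl]]
  gW_head <- crossprod(a_head, d)
  gb_head <- colSums(d)
  d <- tcrossprod(d, params[[hl]]$W)
  params[[hl]]$W <- params[[hl]]$W - cfg$lr * gW_head
  params[[hl]]$b <- params[[hl]]$b - cfg$lr * gb_head
  for (l in rev(seq_len(n_trunk))) {
    if (!is.null(fw$cache$drop[[l]])) d <- d * fw$cache$drop[[l]]
    s <- fw$cache$act[[l]]
    if (spec$trunk_activations[l] == "relu") {
      d <- d * (s > 0)
    } else {
      d <- s * (d - rowSums(d * s))
    }
    # batch-norm backward
    zhat <- fw$cache$bn[[l]]$zhat
    inv_sd <- fw$cache$bn[[l]]$inv_sd
    g_gamma <- colSums(d * zhat)
    g_beta <- colSums(d)
    dzh <- sweep(d, 2, params[[l]]$gamma, "*")
    m <- nrow(d)
    dz <- sweep(
      dzh - matrix(colMeans(dzh), m, ncol(d), byrow = TRUE) -
        zhat * matrix(colMeans(dzh * zhat), m, ncol(d), byrow = TRUE),
      2, inv_sd, "*")
    a_in <- fw$cache$a[[l]]
    gW <- crossprod(a_in, dz)
    if (l > 1) d <- tcrossprod(dz, params[[l]]$W)
    params[[l]]$W <- params[[l]]$W - cfg$lr * gW
    params[[l]]$gamma <- params[[l]]$gamma - cfg$lr * g_gamma
    params[[l]]$beta <- params[[l]]$beta - cfg$lr * g_beta
  }
  list(params = params, loss = loss)
}

#' Train the dense network
#'
#' Seeded minibatch SGD on mean-squared error (default). Classification
#' targets must be one-hot matrices; regression targets are standardized
#' internally (train mean/SD) and predictions are mapped back, which keeps
#' the default learning rate well-conditioned regardless of the target's
#' units. With `epochs = 0` the initialized network is returned untrained.
#'
#' @param spec a [build_network()] specification.
#' @param x numeric feature matrix (`ncol(x) == spec$input_dim`).
#' @param y one-hot target matrix (classification) or numeric vector
#'   (regression).
#' @param cfg a [train_config()].
#' @return An object of class `dnn_fit`: the spec, fitted weights and
#'   batch-norm statistics, the per-epoch training-loss trace, and the
#'   configuration. Same seed, data and config give identical traces.
#' @export
dnn_train <- function(spec, x, y, cfg = train_config()) {
  x <- as.matrix(x)
  if (ncol(x) != spec$input_dim) {
    stop(sprintf("dnn_train: feature count %d != input_dim %d",
                 ncol(x), spec$input_dim))
  }
  target_scale <- NULL
  if (spec$task == "age_regression") {
    y <- as.numeric(y)
    mu <- mean(y); sdv <- stats::sd(y)
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    target_scale <- list(mean = mu, sd = sdv)
    y <- matrix((y - mu) / sdv, ncol = 1)
  } else {
    y <- as.matrix(y)
    if (ncol(y) != spec$head_dim) {
      stop("dnn_train: classification targets must be one-hot with one column per class")
    }
  }
  if (nrow(y) != nrow(x)) stop("dnn_train: x and y row counts differ")
  classes <- colnames(y)
  with_seed(cfg$seed, {
    params <- dnn_init(spec)
    trace <- numeric(cfg$epochs)
    n <- nrow(x)
    if (cfg$epochs > 0) {
      for (epoch in seq_len(cfg$epochs)) {
        ord <- sample.int(n)
        losses <- c()
        starts <- seq(1, n, by = cfg$batch_size)
        for (s0 in starts) {
          idx <- ord[s0:min(s0 + cfg$batch_size - 1, n)]
          if (length(idx) < 2 && isTRUE(spec$batchnorm)) next
          step <- dnn_step(params, spec, cfg,
                           x[idx, , drop = FALSE], y[idx, , drop = FALSE])
          params <- step$params
          losses <- c(losses, step$loss)
        }
        trace[epoch] <- mean(losses)
      }
    }
    structure(list(spec = spec, params = params, cfg = cfg,
                   loss_trace = trace, classes = classes,
                   target_scale = target_scale),
              class = "dnn_fit")
  })
}

#' Predict from a trained network
#'
#' Inference is deterministic: dropout is disabled and batch normalization
#' uses the fitted running statistics.
#'
#' @param object a `dnn_fit`.
#' @param x feature matrix with `spec$input_dim` columns.
#' @param type `"score"` for raw head outputs (regression: the age in years);
#'   `"label"` for decoded class labels (argmax, ties toward the lowest class
#'   index).
#' @param ... unused.
#' @return Matrix of scores, numeric vector (regression), or factor of labels.
#' @export
predict.dnn_fit <- function(object, x, type = c("score", "label"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) != object$spec$input_dim) {
    stop(sprintf("predict.dnn_fit: feature count %d != input_dim %d",
                 ncol(x), object$spec$input_dim))
  }
  out <- dnn_forward(object$params, object$spec, object$cfg, x,
                     training = FALSE)$out
  if (object$spec$task == "age_regression") {
    v <- as.numeric(out)
    if (!is.null(object$target_scale)) {
      v <- v * object$target_scale$sd + object$target_scale$mean
    }
    return(v)
  }
  colnames(out) <- object$classes
  if (type == "score") return(out)
  decode_one_hot(out, object$classes %||% as.character(seq_len(ncol(out))))
}

#' @export
print.network_spec <- function(x, ...) {
  cat("Dense network spec:", x$task, "\n")
  cat("  input:", x$input_dim, "features\n")
  cat("  trunk:", paste(x$trunk, collapse = "-"),
      "(batch-norm; ReLU x7, softmax on layer 8)\n")
  cat("  head :", x$head_dim, "unit(s), linear\n")
  invisible(x)
}

#' @export
print.dnn_fit <- function(x, ...) {
  print(x$spec)
  cat("Trained for", length(x$loss_trace), "epochs; final loss",
      if (length(x$loss_trace)) signif(utils::tail(x$loss_trace, 1), 4) else NA,
      "\n")
  invisible(x)
}
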