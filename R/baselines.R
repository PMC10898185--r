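#' Baseline model specification
#'
#' The comparison models run through the same preprocessing and evaluation
#' path as the GADNN fit: logistic regression (multinomial for the age
#' groups; ordinary least squares in the regression scenario, where the
#' conventional "logistic regression for a continuous outcome" naming is
#' nonstandard), random forest, and a 150-100-50 ReLU multilayer perceptron.
#' Baselines always receive the full 12-feature set (no genetic mask).
#'
#' @param kind `"logistic_regression"`, `"random_forest"`, `"mlp"` or
#'   `"dnn"` (the plain nine-layer network without feature selection).
#' @param hyper named list of hyperparameters. MLP: `widths` (default
#'   `c(150, 100, 50)`), plus [train_config()] fields; RF: `ntree` (default
#'   500, the library default); DNN: [train_config()] fields.
#' @param seed integer seed.
#' @return A list of class `baseline_spec`.
#' @export
baseline_spec <- function(kind = c("logistic_regression", "random_forest",
                                   "mlp", "dnn"),
                          hyper = list(), seed = 1) {
  kind <- match.arg(kind)
  if (kind == "mlp") hyper$widths <- hyper$widths %||% c(150L, 100L, 50L)
  if (kind == "random_forest") hyper$ntree <- hyper$ntree %||% 500L
  structure(list(kind = kind, hyper = hyper, seed = as.integer(seed)),
            class = "baseline_spec")
}

# An MLP is a dense network with plain (non-batch-norm, no softmax trunk)
# hidden layers; reuses the package's training engine with a custom spec.
mlp_spec <- function(input_dim, widths, task) {
  base <- build_network(input_dim, task)
  base$trunk <- as.integer(widths)
  base$trunk_activations <- rep("relu", length(widths))
  base$n_main_layers <- length(widths) + 1L
  base
}

#' Run a baseline model on a prepared split
#'
#' @param spec a [baseline_spec()].
#' @param split a `split_dataset` whose `train`/`test` carry the feature
#'   columns; labels are taken from `split$train_labels`/`split$test_labels`
#'   for classification, or from the `age` column for regression.
#' @param task `"sex"`, `"age_class"` or `"age_regression"`.
#' @param scale logical; min--max scale features (train-fitted) before
#'   fitting, matching the network path.
#' @return An `eval_report` or `regression_report` computed strictly on the
#'   test partition, with the spec attached as attribute `"spec"`.
#' @export
run_baseline <- function(spec, split,
                         task = c("sex", "age_class", "age_regression"),
                         scale = TRUE) {
  task <- match.arg(task)
  stopifnot(inherits(spec, "baseline_spec"), inherits(split, "split_dataset"))
  feats <- sinus_features()
  if (scale) {
    sc <- minmax_normalize(split$train[, feats], split$test[, feats])
    x_train <- sc$train; x_test <- sc$test
  } else {
    x_train <- as.matrix(split$train[, feats])
    x_test <- as.matrix(split$test[, feats])
  }
  regression <- task == "age_regression"
  if (regression) {
    y_train <- split$train$age
    y_test <- split$test$age
  } else {
    y_train <- droplevels(split$train_labels)
    y_test <- droplevels(split$test_labels)
  }

  pred <- switch(
    spec$kind,
    logistic_regression = {
      df_train <- data.frame(y = y_train, x_train)
      df_test <- data.frame(x_test)
      if (regression) {
        # OLS linear regression for the continuous-age scenario
        fit <- stats::lm(y ~ ., data = df_train)
        as.numeric(stats::predict(fit, df_test))
      } else if (nlevels(y_train) == 2) {
        fit <- with_seed(spec$seed,
          stats::glm(y ~ ., data = df_train, family = stats::binomial()))
        p <- stats::predict(fit, df_test, type = "response")
        factor(levels(y_train)[1 + (p > 0.5)], levels = levels(y_train))
      } else {
        fit <- with_seed(spec$seed,
          nnet::multinom(y ~ ., data = df_train, trace = FALSE))
        factor(as.character(stats::predict(fit, df_test)),
               levels = levels(y_train))
      }
    },
    random_forest = with_seed(spec$seed, {
      fit <- randomForest::randomForest(x_train, y_train,
                                        ntree = spec$hyper$ntree)
      stats::predict(fit, x_test)
    }),
    mlp = {
      cfg <- do.call(train_config, c(
        spec$hyper[intersect(names(spec$hyper),
                             names(formals(train_config)))],
        list(seed = spec$seed)))
      mspec <- mlp_spec(ncol(x_train), spec$hyper$widths, task)
      y <- if (regression) y_train else one_hot(y_train, levels(y_train))
      fit <- dnn_train(mspec, x_train, y, cfg)
      if (regression) predict(fit, x_test)
      else predict(fit, x_test, type = "label")
    },
    dnn = {
      cfg <- do.call(train_config, c(
        spec$hyper[intersect(names(spec$hyper),
                             names(formals(train_config)))],
        list(seed = spec$seed)))
      dspec <- build_network(ncol(x_train), task)
      y <- if (regression) y_train else one_hot(y_train, levels(y_train))
      fit <- dnn_train(dspec, x_train, y, cfg)
      if (regression) predict(fit, x_test)
      else predict(fit, x_test, type = "label")
    },
    stop("run_baseline: unknown model kind: ", spec$kind)
  )

  report <- if (regression) regression_report(y_test, pred)
            else classification_report(as.character(y_test),
                                       as.character(pred),
                                       levels(y_test))
  attr(report, "spec") <- spec
  report
}

#' Compare baseline models (and optionally GADNN) on one split
#'
#' Every model sees the identical train/test partition. Classification models
#' are ranked by accuracy (ties by macro F1); regression models by RMSE (ties
#' by R^2).
#'
#' @param specs list of [baseline_spec()] objects.
#' @param split a `split_dataset` (see [run_baseline()]).
#' @param task task string.
#' @param gadnn_fit optional fitted [gadnn()] object evaluated on the same
#'   split, appended as a `"gadnn"` row using its stored test report.
#' @param scale passed to [run_baseline()].
#' @return Data frame, one row per model, ranked best-first; per-model
#'   reports attached as attribute `"reports"`.
#' @export
compare_models <- function(specs, split, task, gadnn_fit = NULL,
                           scale = TRUE) {
  n_models <- length(specs) + as.integer(!is.null(gadnn_fit))
  if (n_models < 2) stop("compare_models: need at least two models")
  reports <- lapply(specs, run_baseline, split = split, task = task,
                    scale = scale)
  names(reports) <- vapply(specs, function(s) s$kind, "")
  if (!is.null(gadnn_fit)) reports$gadnn <- gadnn_fit$report
  if (task == "age_regression") {
    tab <- data.frame(
      model = names(reports),
      rmse = vapply(reports, function(r) r$rmse, 0),
      r2 = vapply(reports, function(r) r$r2, 0)
    )
    tab <- tab[order(tab$rmse, -tab$r2), ]
  } else {
    tab <- data.frame(
      model = names(reports),
      accuracy = vapply(reports, function(r) r$accuracy, 0),
      macro_f1 = vapply(reports, function(r) mean(r$per_class$f1), 0)
    )
    tab <- tab[order(-tab$accuracy, -tab$macro_f1), ]
  }
  rownames(tab) <- NULL
  attr(tab, "reports") <- reports
  tab
}
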