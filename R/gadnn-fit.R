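#' Fit a GADNN model
#'
#' The full hybrid pipeline: (optionally) SMOTE class balancing, min--max
#' normalization, one-hot encoding of class labels, a stratified 80/20
#' train/test split, a binary-chromosome genetic search over feature subsets
#' whose fitness is the held-out accuracy of the fixed nine-layer network
#' (see [build_network()]), and a final network retrained at full epochs on
#' the selected features. Test-set metrics are computed once, on rows the
#' genetic search never saw.
#'
#' Two SMOTE orderings are available. `"paper"` (default) oversamples the
#' whole dataset before splitting — the original protocol, which leaks
#' synthetic neighbours of test points into training. `"safe"` splits first
#' and oversamples the training partition only; it is the recommended setting
#' for honest generalization estimates. Regression runs never apply SMOTE.
#'
#' @param data a sinus dataset (see [read_sinus_csv()], [simulate_cohort()]).
#' @param task `"sex"`, `"age_class"` or `"age_regression"`.
#' @param ga a [ga_config()]; `NULL` skips feature selection (plain DNN on
#'   all features).
#' @param net a [train_config()] for the final network.
#' @param smote logical; apply SMOTE balancing (classification tasks only).
#' @param smote_order `"paper"` or `"safe"` (see Details).
#' @param smote_k SMOTE neighbour count.
#' @param test_fraction held-out test share.
#' @param scheme [age_group_scheme()] used when `task = "age_class"`.
#' @param seed master seed; all stage seeds derive from it.
#' @return An object of class `gadnn` with components `task`, `mask`
#'   (named 0/1 vector over [sinus_features()]), `selected`, `dropped`,
#'   `ga` (the `ga_result`, or `NULL`), `net` (the final `dnn_fit`),
#'   `scaler`, `report` (an `eval_report` or `regression_report` on the test
#'   partition), `split` sizes, and `manifest` (see [run_manifest()]).
#' @seealso [predict.gadnn()], [plot.gadnn()], [gadnn_select()]
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(n = 120, seed = 3))
#' fit <- gadnn(cohort, "sex", ga = NULL,
#'              net = train_config(epochs = 5), seed = 3)
#' fit$report$accuracy
#' }
gadnn <- function(data,
                  task = c("sex", "age_class", "age_regression"),
                  ga = ga_config(),
                  net = train_config(),
                  smote = TRUE,
                  smote_order = c("paper", "safe"),
                  smote_k = 5,
                  test_fraction = 0.2,
                  scheme = age_group_scheme(),
                  seed = 1) {
  task <- match.arg(task)
  smote_order <- match.arg(smote_order)
  t_start <- proc.time()[3]
  data <- as_sinus_dataset(data)
  feats <- sinus_features()
  data_digest <- checksum(data[, c("sex", "age", feats)])

  labels_of <- function(d) {
    switch(task,
           sex = droplevels(factor(d$sex, levels = c("F", "M"))),
           age_class = bin_age(d$age, scheme),
           age_regression = NULL)
  }
  use_smote <- isTRUE(smote) && task != "age_regression"
  classes <- switch(task, sex = c("F", "M"), age_class = scheme$label, NULL)

  labels <- labels_of(data)
  smote_counts <- NULL
  if (use_smote && smote_order == "paper") {
    bal <- smote_balance(data, labels, k = smote_k,
                         seed = child_seed(seed, 11))
    data <- bal$data
    labels <- bal$labels
    smote_counts <- table(labels)
  }
  strat <- if (task == "age_regression") NULL else labels
  split <- split_dataset(data, strat, fraction = test_fraction,
                         seed = child_seed(seed, 12))
  train <- split$train
  test <- split$test
  train_labels <- if (!is.null(strat)) split$train_labels
  test_labels <- if (!is.null(strat)) split$test_labels
  if (use_smote && smote_order == "safe") {
    bal <- smote_balance(train, train_labels, k = smote_k,
                         seed = child_seed(seed, 11))
    train <- bal$data
    train_labels <- bal$labels
    smote_counts <- table(train_labels)
  }

  sc <- minmax_normalize(train[, feats], test[, feats])
  x_train <- sc$train
  x_test <- sc$test
  if (task == "age_regression") {
    y_train <- train$age
    y_test <- test$age
  } else {
    y_train <- one_hot(train_labels, classes)
    y_test <- test_labels
  }

  mask <- structure(rep(1L, length(feats)), names = feats)
  ga_result <- NULL
  if (!is.null(ga)) {
    stopifnot(inherits(ga, "ga_config"))
    ga_run <- ga
    ga_run$seed <- as.integer(child_seed(seed, 13))
    fitness_fn <- dnn_fitness(x_train, y_train, task, ga_run, net)
    ga_result <- evolve(ga_run, length(feats), fitness_fn)
    mask <- structure(ga_result$best_mask, names = feats)
  }
  cols <- which(mask == 1)

  final_cfg <- net
  final_cfg$seed <- as.integer(child_seed(seed, 14))
  spec <- build_network(length(cols), task)
  fit <- dnn_train(spec, x_train[, cols, drop = FALSE], y_train, final_cfg)

  if (task == "age_regression") {
    pred <- predict(fit, x_test[, cols, drop = FALSE])
    report <- regression_report(y_test, pred)
  } else {
    pred <- predict(fit, x_test[, cols, drop = FALSE], type = "label")
    report <- classification_report(as.character(y_test), as.character(pred),
                                    classes)
  }

  manifest <- run_manifest(
    task = task, seed = seed, data_digest = data_digest,
    ga = ga, net = net,
    smote = use_smote, smote_order = smote_order, smote_k = smote_k,
    test_fraction = test_fraction, mask = mask,
    wall_time = proc.time()[3] - t_start
  )
  structure(list(
    task = task,
    classes = classes,
    mask = mask,
    selected = feats[cols],
    dropped = feats[mask == 0],
    ga = ga_result,
    net = fit,
    scaler = sc$scaler,
    report = report,
    smote_counts = smote_counts,
    split = list(n_train = nrow(train), n_test = nrow(test),
                 n_synthetic_train = sum(train$synthetic),
                 n_synthetic_test = sum(test$synthetic)),
    manifest = manifest
  ), class = "gadnn")
}

#' Genetic feature selection with the network fitness
#'
#' Convenience wrapper around [gadnn()] that returns the selection outcome:
#' which of the twelve features were retained, which were dropped, and the
#' final test report of the network retrained on the selected subset. (On the
#' original clinical cohort this procedure dropped FSW, FSV and LMSW; the
#' outcome is data-dependent.)
#'
#' @inheritParams gadnn
#' @param ga a [ga_config()].
#' @return List with `selected`, `dropped`, `mask`, `report`, `history` and
#'   the full `fit`.
#' @export
gadnn_select <- function(data, task = c("sex", "age_class", "age_regression"),
                         ga = ga_config(), net = train_config(), seed = 1,
                         ...) {
  fit <- gadnn(data, task, ga = ga, net = net, seed = seed, ...)
  list(selected = fit$selected, dropped = fit$dropped, mask = fit$mask,
       report = fit$report, history = fit$ga$history, fit = fit)
}

#' @export
print.gadnn <- function(x, ...) {
  cat("GADNN fit —", x$task, "\n")
  cat("  features:", length(x$selected), "selected of",
      length(x$mask), "\n")
  if (length(x$dropped)) {
    cat("  dropped :", paste(x$dropped, collapse = ", "), "\n")
  }
  if (!is.null(x$ga)) {
    cat("  GA best fitness:", signif(x$ga$best_fitness, 4),
        "over", max(x$ga$history$generation), "generations\n")
  }
  cat("  train/test:", x$split$n_train, "/", x$split$n_test, "rows\n")
  if (inherits(x$report, "regression_report")) {
    cat("  test RMSE:", signif(x$report$rmse, 4),
        " R^2:", signif(x$report$r2, 4), "\n")
  } else {
    cat("  test accuracy:", signif(x$report$accuracy, 4), "\n")
  }
  invisible(x)
}

#' @export
summary.gadnn <- function(object, ...) {
  print(object)
  cat("\nTest-set report:\n")
  print(object$report)
  invisible(object)
}

#' @export
coef.gadnn <- function(object, ...) object$mask

#' Predict from a fitted GADNN model
#'
#' New data is scaled with the training-fitted min--max bounds, masked to the
#' selected features, and pushed through the final network.
#'
#' @param object a [gadnn()] fit.
#' @param newdata a sinus dataset or a data frame containing the twelve
#'   feature columns.
#' @param type `"label"` (classification default), `"score"`, or `"response"`
#'   (regression: predicted age in years).
#' @param ... unused.
#' @return Factor of labels, score matrix, or numeric vector.
#' @export
predict.gadnn <- function(object, newdata,
                          type = c("label", "score", "response"), ...) {
  type <- match.arg(type)
  feats <- sinus_features()
  stopifnot(all(feats %in% names(newdata)))
  x <- apply_scaler(object$scaler, as.matrix(newdata[, feats]))
  cols <- which(object$mask == 1)
  x <- x[, cols, drop = FALSE]
  if (object$task == "age_regression") {
    return(predict(object$net, x))
  }
  predict(object$net, x, type = if (type == "score") "score" else "label")
}

#' Plot the genetic-search fitness history
#'
#' Best-so-far and population-mean fitness per generation; the best line is
#' non-decreasing by elitism.
#'
#' @param x a [gadnn()] fit (with a GA run).
#' @param ... passed to [graphics::plot()].
#' @export
plot.gadnn <- function(x, ...) {
  if (is.null(x$ga)) stop("plot.gadnn: no genetic search in this fit")
  h <- x$ga$history
  graphics::plot(h$generation, h$best, type = "s", lwd = 2,
                 xlab = "generation", ylab = "fitness",
                 ylim = range(c(h$best, h$mean)),
                 main = "GADNN feature search", ...)
  graphics::lines(h$generation, h$mean, lty = 2)
  graphics::legend("bottomright", legend = c("best", "population mean"),
                   lty = c(1, 2), lwd = c(2, 1), bty = "n")
  invisible(x)
}
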