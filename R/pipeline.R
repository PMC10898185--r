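#' Run manifest
#'
#' A complete, serializable record of one pipeline run: the task, every
#' module configuration, the master seed and the input-data checksum. A
#' manifest plus the original dataset is sufficient to reproduce the run
#' bit-for-bit with [replay_run()].
#'
#' @param task task string.
#' @param seed master seed of the run.
#' @param data_digest checksum of the input data (see internals).
#' @param ga,net,smote,smote_order,smote_k,test_fraction,mask,wall_time run
#'   settings and outcomes.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(task, seed, data_digest, ga, net, smote,
                         smote_order, smote_k, test_fraction, mask,
                         wall_time = NA_real_) {
  structure(list(
    task = task, seed = as.integer(seed), data_digest = data_digest,
    ga = ga, net = net, smote = smote, smote_order = smote_order,
    smote_k = smote_k, test_fraction = test_fraction,
    mask = mask, wall_time = unname(wall_time),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Run manifest:", x$task, "| seed", x$seed,
      "| data", x$data_digest, "\n")
  cat("  smote:", if (x$smote) paste0("on (", x$smote_order, ", k=",
                                      x$smote_k, ")") else "off",
      "| test fraction:", x$test_fraction, "\n")
  cat("  selected mask:", paste(names(x$mask)[x$mask == 1], collapse = ", "),
      "\n")
  invisible(x)
}

# shared driver behind the three pipeline entry points
run_pipeline <- function(data, task, ga, net, smote, smote_order, seed, ...) {
  fit <- gadnn(data, task = task, ga = ga, net = net, smote = smote,
               smote_order = smote_order, seed = seed, ...)
  list(report = fit$report, manifest = fit$manifest, fit = fit)
}

#' End-to-end pipelines for the three tasks
#'
#' Thin orchestration over [gadnn()], mirroring the method's flow: age
#' grouping (age task) -> SMOTE -> min--max scaling -> one-hot -> stratified
#' 80/20 split -> optional genetic feature selection -> final network ->
#' test-set report. `run_sex_pipeline` balances the sex classes;
#' `run_age_classification` balances the four age groups and reports
#' per-group metrics; `run_age_regression` keeps age continuous, never
#' applies SMOTE (oversampling has no meaning for a continuous target), and
#' reports RMSE and R^2. When the genetic search is enabled for regression
#' its fitness is `1 / (1 + RMSE)`, since classification accuracy is
#' undefined there.
#'
#' @param data a sinus dataset.
#' @param ga a [ga_config()] or `NULL` to skip feature selection.
#' @param net a [train_config()].
#' @param smote logical (classification pipelines).
#' @param smote_order `"paper"` or `"safe"` (see [gadnn()]).
#' @param seed master seed.
#' @param ... further arguments to [gadnn()].
#' @return List with `report`, `manifest` and the full `fit`.
#' @export
run_sex_pipeline <- function(data, ga = ga_config(), net = train_config(),
                             smote = TRUE, smote_order = "paper", seed = 1,
                             ...) {
  run_pipeline(data, "sex", ga, net, smote, smote_order, seed, ...)
}

#' @rdname run_sex_pipeline
#' @export
run_age_classification <- function(data, ga = ga_config(),
                                   net = train_config(), smote = TRUE,
                                   smote_order = "paper", seed = 1, ...) {
  run_pipeline(data, "age_class", ga, net, smote, smote_order, seed, ...)
}

#' @rdname run_sex_pipeline
#' @export
run_age_regression <- function(data, ga = ga_config(),
                               net = train_config(), seed = 1, ...) {
  run_pipeline(data, "age_regression", ga, net, smote = FALSE,
               smote_order = "paper", seed, ...)
}

#' Replay a run from its manifest
#'
#' Re-executes the pipeline recorded in a manifest against the original
#' dataset and returns the reproduced result. The dataset is checked against
#' the manifest's checksum first; every seed is taken from the manifest, so
#' the reproduced report is identical to the original.
#'
#' @param manifest a `run_manifest`.
#' @param data the dataset the original run consumed.
#' @return List with `report`, `manifest` and `fit`, as from the pipeline
#'   entry points.
#' @export
replay_run <- function(manifest, data) {
  stopifnot(inherits(manifest, "run_manifest"))
  data <- as_sinus_dataset(data)
  digest <- checksum(data[, c("sex", "age", sinus_features())])
  if (!identical(digest, manifest$data_digest)) {
    stop("replay_run: dataset checksum ", digest,
         " does not match manifest ", manifest$data_digest)
  }
  run_pipeline(data, manifest$task, ga = manifest$ga, net = manifest$net,
               smote = manifest$smote, smote_order = manifest$smote_order,
               seed = manifest$seed, smote_k = manifest$smote_k,
               test_fraction = manifest$test_fraction)
}
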