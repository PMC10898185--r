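#' Classification evaluation report
#'
#' Per-class one-vs-rest confusion counts and the derived metrics:
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * P * R / (P + R)`, plus overall
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`, which for the multi-class
#' confusion matrix equals trace / total. Ratios with a zero denominator are
#' reported as 0 and flagged, so reports always serialize cleanly. Per-class
#' rows are reported without macro/micro averaging by default; macro averages
#' are available behind `macro = TRUE`.
#'
#' @param truth,predicted vectors of labels of equal length.
#' @param classes ordered character vector of classes (defaults to the union
#'   of levels).
#' @param macro also attach macro-averaged precision/recall/F1.
#' @return An object of class `eval_report`: list with `per_class` (data
#'   frame: class, precision, recall, f1, support), `accuracy`, `confusion`
#'   (k-by-k table, truth in rows), `undefined` (flag: any zero-denominator
#'   metric), and optionally `macro`.
#' @export
#' @examples
#' classification_report(c("a", "a", "b"), c("a", "b", "b"))
classification_report <- function(truth, predicted, classes = NULL,
                                  macro = FALSE) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("classification_report: truth and predicted lengths differ")
  }
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  stopifnot(all(truth %in% classes), all(predicted %in% classes))
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  confusion <- table(truth = tf, predicted = pf)
  n <- length(truth)
  undefined <- FALSE
  ratio <- function(num, den) {
    if (den == 0) { undefined <<- TRUE; return(0) }
    num / den
  }
  rows <- lapply(classes, function(cls) {
    tp <- confusion[cls, cls]
    fp <- sum(confusion[, cls]) - tp
    fn <- sum(confusion[cls, ]) - tp
    p <- ratio(tp, tp + fp)
    r <- ratio(tp, tp + fn)
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else { undefined <<- TRUE; 0 }
    data.frame(class = cls, precision = p, recall = r, f1 = f1,
               support = sum(confusion[cls, ]), stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  out <- list(per_class = per_class,
              accuracy = sum(diag(confusion)) / n,
              confusion = confusion,
              undefined = undefined)
  if (macro) {
    out$macro <- c(precision = mean(per_class$precision),
                   recall = mean(per_class$recall),
                   f1 = mean(per_class$f1))
  }
  class(out) <- "eval_report"
  out
}

#' Regression evaluation report
#'
#' `RMSE = sqrt(mean((truth - predicted)^2))` and the coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot`, with `SS_tot` taken about the
#' mean of the truth. A constant truth vector leaves `R^2` undefined; it is
#' reported as 0 with a flag.
#'
#' @param truth,predicted numeric vectors of equal, non-zero length.
#' @return An object of class `regression_report`: list with `rmse`, `r2`,
#'   `n` and `undefined`.
#' @export
#' @examples
#' regression_report(1:5, c(1.1, 2, 2.9, 4, 5))
regression_report <- function(truth, predicted) {
  truth <- as.numeric(truth)
  predicted <- as.numeric(predicted)
  if (length(truth) == 0) stop("regression_report: empty input")
  if (length(truth) != length(predicted)) {
    stop("regression_report: truth and predicted lengths differ")
  }
  ss_res <- sum((truth - predicted)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  undefined <- ss_tot == 0
  structure(list(
    rmse = sqrt(mean((truth - predicted)^2)),
    r2 = if (undefined) 0 else 1 - ss_res / ss_tot,
    n = length(truth),
    undefined = undefined
  ), class = "regression_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat("Classification report (accuracy:", round(x$accuracy, digits), ")\n")
  df <- x$per_class
  df[, 2:4] <- round(df[, 2:4], digits)
  print(df, row.names = FALSE)
  if (!is.null(x$macro)) {
    cat("macro:", paste(names(x$macro), round(x$macro, digits),
                        sep = "=", collapse = "  "), "\n")
  }
  if (x$undefined) cat("note: zero-denominator metric(s) reported as 0\n")
  invisible(x)
}

#' @export
print.regression_report <- function(x, digits = 4, ...) {
  cat("Regression report: RMSE =", round(x$rmse, digits),
      " R^2 =", round(x$r2, digits), " (n =", x$n, ")\n")
  if (x$undefined) cat("note: constant truth; R^2 reported as 0\n")
  invisible(x)
}

#' Serialize an evaluation report as a data frame
#'
#' One row per class plus an overall row, mirroring the usual layout of
#' published per-class tables.
#'
#' @param report an `eval_report` or `regression_report`.
#' @return A data frame.
#' @export
report_as_table <- function(report) {
  if (inherits(report, "regression_report")) {
    return(data.frame(metric = c("rmse", "r2"),
                      value = c(report$rmse, report$r2)))
  }
  overall <- data.frame(class = "overall", precision = NA_real_,
                        recall = NA_real_, f1 = NA_real_,
                        support = sum(report$per_class$support))
  out <- rbind(report$per_class, overall)
  out$accuracy <- c(rep(NA_real_, nrow(report$per_class)), report$accuracy)
  out
}
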