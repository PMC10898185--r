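test_that("binary confusion counts reproduce the printed formulas", {
  # TP=3, TN=5, FP=1, FN=1 for the positive class "p"
  truth <- c(rep("p", 4), rep("n", 6))
  pred <- c("p", "p", "p", "n", "p", rep("n", 5))
  rep_ <- classification_report(truth, pred, classes = c("p", "n"))
  p_row <- rep_$per_class[rep_$per_class$class == "p", ]
  expect_equal(rep_$accuracy, 0.8)
  expect_equal(p_row$precision, 0.75)
  expect_equal(p_row$recall, 0.75)
  expect_equal(p_row$f1, 0.75)
  expect_equal(p_row$support, 4)
})

test_that("perfect and degenerate predictions hit the metric boundaries", {
  truth <- rep(c("a", "b", "c"), 5)
  rep_ <- classification_report(truth, truth)
  expect_equal(rep_$accuracy, 1)
  expect_true(all(rep_$per_class[, c("precision", "recall", "f1")] == 1))
  expect_false(rep_$undefined)

  # a class never predicted: zero-denominator precision reported as 0, flagged
  rep0 <- classification_report(c("a", "a", "b"), c("a", "a", "a"),
                                classes = c("a", "b"))
  expect_equal(rep0$per_class$precision[2], 0)
  expect_true(rep0$undefined)
})

test_that("classification report equals a brute-force oracle on random labels", {
  set.seed(14)
  classes <- c("A", "B", "C", "D")
  truth <- sample(classes, 500, TRUE)
  pred <- sample(classes, 500, TRUE)
  rep_ <- classification_report(truth, pred, classes, macro = TRUE)

  # independently coded count-and-divide oracle
  expect_equal(rep_$accuracy, sum(truth == pred) / 500)
  for (cls in classes) {
    tp <- sum(truth == cls & pred == cls)
    fp <- sum(truth != cls & pred == cls)
    fn <- sum(truth == cls & pred != cls)
    row <- rep_$per_class[rep_$per_class$class == cls, ]
    expect_identical(row$precision, tp / (tp + fp))
    expect_identical(row$recall, tp / (tp + fn))
    expect_identical(row$f1, 2 * row$precision * row$recall /
                               (row$precision + row$recall))
  }
  # F1 is the harmonic mean of its own precision/recall where both nonzero
  pc <- rep_$per_class
  nz <- pc$precision > 0 & pc$recall > 0
  expect_equal(pc$f1[nz],
               2 / (1 / pc$precision[nz] + 1 / pc$recall[nz]))
})

test_that("accuracy is invariant under consistent class relabeling", {
  set.seed(2)
  truth <- sample(c("A", "B", "C"), 200, TRUE)
  pred <- sample(c("A", "B", "C"), 200, TRUE)
  map <- c(A = "z", B = "x", C = "y")
  r1 <- classification_report(truth, pred, c("A", "B", "C"))
  r2 <- classification_report(map[truth], map[pred], c("x", "y", "z"))
  expect_equal(r1$accuracy, r2$accuracy)
  expect_error(classification_report(truth, pred[-1]), "lengths differ")
})

test_that("regression metrics match their closed forms", {
  expect_equal(regression_report(1:5, 1:5)$rmse, 0)
  expect_equal(regression_report(1:5, 1:5)$r2, 1)
  truth <- c(2, 4, 9, 1)
  rep_mean <- regression_report(truth, rep(mean(truth), 4))
  expect_equal(rep_mean$r2, 0)

  set.seed(21)
  t2 <- rnorm(200, 30, 8)
  p2 <- t2 + rnorm(200, 0, 3)
  rep_ <- regression_report(t2, p2)
  expect_equal(rep_$rmse, sqrt(mean((t2 - p2)^2)), tolerance = 1e-12)
  expect_equal(rep_$r2, 1 - sum((t2 - p2)^2) / sum((t2 - mean(t2))^2),
               tolerance = 1e-12)

  const <- regression_report(rep(5, 4), c(5, 5, 5, 6))
  expect_true(const$undefined)
  expect_equal(const$r2, 0)
  expect_error(regression_report(numeric(0), numeric(0)), "empty")
  expect_error(regression_report(1:3, 1:2), "lengths differ")
})

test_that("report serialization mirrors the per-class table layout", {
  rep_ <- classification_report(c("F", "M", "F"), c("F", "M", "M"),
                                c("F", "M"))
  tab <- report_as_table(rep_)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$class, c("F", "M", "overall"))
  expect_equal(tab$accuracy[3], rep_$accuracy)

  rtab <- report_as_table(regression_report(1:4, c(1, 2, 3, 5)))
  expect_equal(rtab$metric, c("rmse", "r2"))
})
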