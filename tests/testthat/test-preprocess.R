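test_that("SMOTE balances every class to the majority count", {
  sizes <- c(A = 39, B = 70, C = 90, D = 40)
  cohort <- cohort_with_group_sizes(sizes)
  cohort$synthetic <- FALSE
  labels <- bin_age(cohort$age)
  bal <- smote_balance(cohort, labels, k = 5, seed = 9)
  expect_equal(as.integer(table(bal$labels)), rep(90L, 4))
  expect_equal(nrow(bal$data), 360)
  # original rows first and unchanged
  expect_identical(bal$data[1:239, names(cohort)], cohort)
  expect_false(any(bal$data$synthetic[1:239]))
  expect_true(all(bal$data$synthetic[240:360]))
})

test_that("every SMOTE point is a convex combination of a real point and one of its k nearest same-class neighbours", {
  cohort <- simulate_cohort(sim_config(n = 40, seed = 11))
  cohort$synthetic <- FALSE
  labels <- factor(rep(c("x", "y"), c(28, 12)))
  k <- 3
  bal <- smote_balance(cohort, labels, k = k, seed = 5)
  syn <- bal$data[bal$data$synthetic, ]
  expect_equal(nrow(syn), 16)
  real_y <- as.matrix(cohort[labels == "y", sinus_features()])
  for (i in seq_len(nrow(syn))) {
    expect_true(smote_witness_exists(
      as.numeric(syn[i, sinus_features()]), real_y, k))
  }
})

test_that("SMOTE edge cases: balanced input unchanged, tiny classes handled", {
  cohort <- simulate_cohort(sim_config(n = 20, seed = 2))
  labels <- factor(rep(c("F", "M"), 10))
  bal <- smote_balance(cohort, labels, seed = 1)
  expect_identical(bal$data, cohort)
  expect_equal(sum(bal$data$synthetic != cohort$synthetic), 0)

  # class smaller than k + 1: k reduced with a warning
  labels3 <- factor(rep(c("a", "b"), c(17, 3)))
  expect_warning(bal3 <- smote_balance(cohort, labels3, k = 5, seed = 1),
                 "k reduced")
  expect_equal(as.integer(table(bal3$labels)), c(17L, 17L))

  # singleton class: no neighbour exists
  labels1 <- factor(rep(c("a", "b"), c(19, 1)))
  expect_error(smote_balance(cohort, labels1, seed = 1), "single member")
})

test_that("min-max scaling maps train to [0,1], leaves test unclipped, inverts", {
  out <- minmax_normalize(matrix(c(2, 4, 6), ncol = 1))
  expect_equal(as.numeric(out$train), c(0, 0.5, 1))

  const <- minmax_normalize(matrix(c(5, 5, 5), ncol = 1))
  expect_equal(as.numeric(const$train), c(0, 0, 0))

  both <- minmax_normalize(matrix(c(2, 6), ncol = 1), matrix(8, ncol = 1))
  expect_equal(as.numeric(both$test), 1.5)

  set.seed(4)
  x <- matrix(runif(60, 5, 50), 20, 3)
  fit <- minmax_normalize(x)
  back <- invert_scaler(fit$scaler, fit$train)
  expect_lt(max(abs(back - x) / abs(x)), 1e-9)
})

test_that("one-hot encoding and argmax decoding follow the declared rules", {
  m <- one_hot(c("B", "D"), c("A", "B", "C", "D"))
  expect_equal(m[1, ], c(A = 0, B = 1, C = 0, D = 0))
  expect_true(all(rowSums(m) == 1))
  expect_error(one_hot("E", c("A", "B")), "E")

  scores <- rbind(c(0.1, 0.7, 0.1, 0.1), c(0.5, 0.5, 0, 0))
  dec <- decode_one_hot(scores, c("A", "B", "C", "D"))
  expect_equal(as.character(dec), c("B", "A")) # tie broken toward lowest index
})

test_that("stratified split is seeded, arithmetic and guarded", {
  sizes <- c(A = 39, B = 70, C = 90, D = 40)
  cohort <- cohort_with_group_sizes(sizes)
  labels <- bin_age(cohort$age)
  bal <- smote_balance(cohort, labels, seed = 1)

  sp <- split_dataset(bal$data, bal$labels, fraction = 0.2, seed = 7)
  expect_equal(nrow(sp$train), 288)
  expect_equal(nrow(sp$test), 72)
  expect_equal(as.integer(table(sp$test_labels)), rep(18L, 4))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)

  sp2 <- split_dataset(bal$data, bal$labels, fraction = 0.2, seed = 7)
  expect_identical(sp$test_idx, sp2$test_idx)

  expect_error(split_dataset(bal$data, bal$labels, fraction = 0), "fraction")
  tiny <- cohort[1:3, ]
  expect_error(split_dataset(tiny, factor(c("a", "a", "b"))), "fewer than 2")
})
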