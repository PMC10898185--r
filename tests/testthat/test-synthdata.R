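test_that("the default cohort matches the target composition", {
  cohort <- simulate_cohort(sim_config())
  expect_equal(nrow(cohort), 240)
  expect_equal(sum(cohort$sex == "F"), 129)
  expect_equal(sum(cohort$sex == "M"), 111)
  expect_true(all(cohort$age >= 18 & cohort$age <= 52))
  expect_true(all(as.matrix(cohort[, sinus_features()]) > 0))
  expect_true(all(cohort$synthetic))
})

test_that("generation is deterministic down to the emitted CSV bytes", {
  cfg <- sim_config(n = 60, seed = 123)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_sinus_csv(simulate_cohort(cfg), f1)
  write_sinus_csv(simulate_cohort(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("marginal means and SDs track the configuration at large n", {
  cfg <- sim_config(n = 5000, sex_effect = 0, age_effect = 0, seed = 77)
  cohort <- simulate_cohort(cfg)
  for (f in names(cfg$dim_means)) {
    m <- mean(cohort[[f]]); s <- sd(cohort[[f]])
    se_mean <- cfg$dim_sds[f] / sqrt(5000)
    se_sd <- cfg$dim_sds[f] / sqrt(2 * 5000)
    expect_lt(abs(m - cfg$dim_means[f]), 3 * se_mean)
    expect_lt(abs(s - cfg$dim_sds[f]), 4 * se_sd)
  }
})

test_that("bilateral correlation and volume coupling hold empirically", {
  cfg <- sim_config(n = 5000, sex_effect = 0, age_effect = 0,
                    bilateral_rho = 0.6, seed = 31)
  cohort <- simulate_cohort(cfg)
  for (pair in list(c("RMSL", "LMSL"), c("RMSW", "LMSW"), c("RMSH", "LMSH"))) {
    expect_lt(abs(cor(cohort[[pair[1]]], cohort[[pair[2]]]) - 0.6), 0.05)
  }
  # log(V / (c L W H)) ~ N(0, volume_sigma)
  ratio <- log(cohort$FSV / (cfg$volume_c * cohort$FSL * cohort$FSW * cohort$FSH))
  expect_lt(abs(mean(ratio)), 3 * cfg$volume_sigma / sqrt(5000))
  expect_lt(abs(sd(ratio) - cfg$volume_sigma), 0.01)
})

test_that("a null cohort carries no sex signal", {
  cfg <- sim_config(n = 1000, sex_effect = 0, age_effect = 0, seed = 55)
  cohort <- simulate_cohort(cfg)
  sp <- split_dataset(cohort, cohort$sex, 0.2, seed = 1)
  fit <- suppressWarnings(
    glm(sex ~ ., data = data.frame(sex = sp$train_labels,
                                   sp$train[, sinus_features()]),
        family = binomial()))
  p <- predict(fit, sp$test[, sinus_features()], type = "response")
  acc <- mean(levels(sp$train_labels)[1 + (p > 0.5)] ==
                as.character(sp$test_labels))
  n_test <- nrow(sp$test)
  half_width <- 1.96 * sqrt(0.25 / n_test)
  expect_gt(acc, 0.5 - half_width)
  expect_lt(acc, 0.5 + half_width)
})

test_that("planted-relevance cohorts separate on informative features only", {
  cohort <- planted_relevance_cohort(n = 500, effect = 2, seed = 8)
  mask <- attr(cohort, "informative_mask")
  expect_equal(sum(mask), 6)
  expect_named(mask, sinus_features())

  sp <- split_dataset(cohort, cohort$sex, 0.2, seed = 2)
  inf_feats <- names(mask)[mask]
  fit <- suppressWarnings(
    glm(sex ~ ., data = data.frame(sex = sp$train_labels,
                                   sp$train[, inf_feats]),
        family = binomial()))
  p <- predict(fit, sp$test[, inf_feats], type = "response")
  acc <- mean(levels(sp$train_labels)[1 + (p > 0.5)] ==
                as.character(sp$test_labels))
  expect_gte(acc, 0.9)

  # permuting the labels destroys separability
  set.seed(3)
  perm <- sample(sp$train_labels)
  fitp <- suppressWarnings(
    glm(sex ~ ., data = data.frame(sex = perm, sp$train[, inf_feats]),
        family = binomial()))
  pp <- predict(fitp, sp$test[, inf_feats], type = "response")
  accp <- mean(levels(perm)[1 + (pp > 0.5)] == as.character(sp$test_labels))
  expect_lt(accp, 0.5 + 1.96 * sqrt(0.25 / nrow(sp$test)) + 0.05)

  expect_error(planted_relevance_cohort(informative = sinus_features()),
               "proper subset")
  expect_error(planted_relevance_cohort(informative = character(0)),
               "proper subset")
})
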