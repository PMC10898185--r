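test_that("population initialization is seeded and never all-zero", {
  cfg <- ga_config(pop_size = 30, seed = 4)
  pop <- init_population(cfg, 12)
  expect_equal(dim(pop), c(30, 12))
  expect_true(all(pop %in% 0:1))
  expect_true(all(rowSums(pop) >= 1))
  expect_identical(pop, init_population(cfg, 12))
})

test_that("crossover and mutation follow the declared operator rules", {
  cr <- crossover_masks(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1), point = 3)
  expect_equal(cr$child1, c(1, 1, 1, 1, 1, 1))
  expect_equal(sum(cr$child2), 1) # all-zero child repaired to one bit

  off <- crossover_masks(c(1, 0), c(0, 1), point = 1, apply = FALSE)
  expect_equal(off$child1, c(1, 0))
  expect_error(crossover_masks(c(1, 0), c(0, 1), point = 2), "point")

  set.seed(1)
  expect_equal(mutate_mask(c(1L, 0L, 1L, 1L), rate = 0), c(1L, 0L, 1L, 1L))
  expect_equal(mutate_mask(c(1L, 0L, 1L, 1L), rate = 1), c(0L, 1L, 0L, 0L))
  set.seed(2)
  expect_equal(sum(mutate_mask(c(1L, 1L, 0L), rate = 1)), 1) # complement repaired
})

test_that("evolution maximizes an analytic fitness with monotone history", {
  hits <- 0
  for (s in 1:10) {
    r <- evolve(ga_config(seed = s), 12, function(m) sum(m) / 12)
    expect_false(is.unsorted(r$history$best))
    expect_lte(r$evaluations, 20 * 16)
    if (all(r$best_mask == 1)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("at L = 4 the search equals exhaustive enumeration", {
  all_masks <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))[-1, ]
  for (s in 1:15) {
    set.seed(300 + s)
    tab <- runif(16)
    fitf <- function(m) tab[sum(m * c(1, 2, 4, 8)) + 1]
    best_true <- max(apply(all_masks, 1, fitf))
    r <- evolve(ga_config(pop_size = 10, generations = 10, seed = s), 4, fitf)
    expect_equal(r$best_fitness, best_true)
  }
})

test_that("constant fitness and degenerate operators behave as documented", {
  r <- evolve(ga_config(pop_size = 8, generations = 4, seed = 2), 6,
              function(m) 0.5)
  expect_equal(unique(r$history$best), 0.5)
  expect_gte(sum(r$best_mask), 1)

  # no mutation, no crossover, elitism: best never changes
  rd <- evolve(ga_config(p_crossover = 0, p_mutation = 0, generations = 5,
                         seed = 3), 8, function(m) sum(m) / 8)
  expect_length(unique(rd$history$best), 1)
})

test_that("fitness evaluations are cached by mask", {
  calls <- 0
  r <- evolve(ga_config(pop_size = 10, generations = 8, seed = 1), 5,
              function(m) { calls <<- calls + 1; sum(m) / 5 })
  expect_equal(r$evaluations, calls)
  expect_lte(calls, 2^5 - 1) # never more distinct evaluations than masks
  expect_lt(calls, 10 * 9)   # caching saved repeat evaluations
})

test_that("the DNN fitness trains on a train-only fold and caches", {
  cohort <- planted_relevance_cohort(n = 120, seed = 9)
  prep <- prep_xy(cohort)
  cfg <- ga_config(fitness_epochs = 2, val_fraction = 0.25, seed = 5)
  ff <- dnn_fitness(prep$x, prep$y, "sex", cfg,
                    train_config(batch_size = 32))
  m <- rep(1L, 12)
  v1 <- ff(m)
  expect_true(v1 >= 0 && v1 <= 1)
  expect_identical(ff(m), v1) # fixed mask-independent seed: same value
  expect_error(ff(rep(0L, 12)), "all-zero")
})
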