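#' Genetic-algorithm configuration
#'
#' Standard small-GA settings: tournament selection (size 2), single-point
#' crossover, independent per-bit mutation at rate `1/L`, and one elite
#' chromosome carried over unchanged (so best-so-far fitness never
#' decreases). `fitness_epochs` is the reduced training budget used when the
#' fitness function trains the network; the final model is retrained at full
#' epochs after selection.
#'
#' @param pop_size population size (>= 2).
#' @param generations number of generations (>= 1).
#' @param tournament tournament size.
#' @param p_crossover crossover probability.
#' @param p_mutation per-bit mutation probability; `NULL` means `1/L`.
#' @param elitism number of elite chromosomes (>= 1 keeps history monotone).
#' @param fitness_epochs epoch budget for fitness evaluations.
#' @param val_fraction fraction of the training partition held out as the
#'   fitness validation fold.
#' @param seed integer seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 20, generations = 15, tournament = 2,
                      p_crossover = 0.8, p_mutation = NULL, elitism = 1,
                      fitness_epochs = 30, val_fraction = 0.2, seed = 1) {
  stopifnot(pop_size >= 2, generations >= 1, tournament >= 1,
            p_crossover >= 0, p_crossover <= 1,
            is.null(p_mutation) || (p_mutation >= 0 && p_mutation <= 1),
            elitism >= 0, fitness_epochs >= 0,
            val_fraction > 0, val_fraction < 1)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 tournament = as.integer(tournament),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elitism = as.integer(elitism),
                 fitness_epochs = as.integer(fitness_epochs),
                 val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "ga_config")
}

# All-zero chromosomes are repaired by setting one uniformly chosen bit;
# a zero mask is never evaluated.
repair_mask <- function(mask) {
  if (sum(mask) == 0) mask[sample.int(length(mask), 1)] <- 1L
  mask
}

#' Initialize a GA population of feature masks
#'
#' Each bit is an independent fair coin; all-zero chromosomes are repaired by
#' setting one uniformly chosen bit.
#'
#' @param cfg a [ga_config()].
#' @param n_features chromosome length.
#' @return Integer 0/1 matrix, `pop_size` rows by `n_features` columns.
#' @export
init_population <- function(cfg, n_features) {
  stopifnot(n_features >= 1)
  with_seed(cfg$seed, {
    pop <- matrix(as.integer(stats::runif(cfg$pop_size * n_features) < 0.5),
                  cfg$pop_size, n_features)
    t(apply(pop, 1, repair_mask))
  })
}

#' Single-point crossover of two feature masks
#'
#' Exchanges the suffixes after `point` when `apply` is `TRUE`; children that
#' come out all-zero are repaired.
#'
#' @param parent1,parent2 equal-length 0/1 vectors.
#' @param point crossover point in `[1, L - 1]`.
#' @param apply whether the exchange happens (otherwise parents are copied).
#' @return List with `child1` and `child2`.
#' @export
crossover_masks <- function(parent1, parent2, point, apply = TRUE) {
  l <- length(parent1)
  stopifnot(length(parent2) == l)
  if (point < 1 || point > l - 1) stop("crossover_masks: point out of range")
  if (!apply) return(list(child1 = parent1, child2 = parent2))
  c1 <- c(parent1[1:point], parent2[(point + 1):l])
  c2 <- c(parent2[1:point], parent1[(point + 1):l])
  list(child1 = repair_mask(c1), child2 = repair_mask(c2))
}

#' Per-bit mutation of a feature mask
#'
#' Flips each bit independently with probability `rate`; repairs all-zero
#' results. Uses the current RNG stream.
#'
#' @param mask 0/1 vector.
#' @param rate per-bit flip probability.
#' @return Mutated 0/1 vector.
#' @export
mutate_mask <- function(mask, rate) {
  flip <- stats::runif(length(mask)) < rate
  repair_mask(as.integer(xor(mask == 1, flip)))
}

mask_key <- function(mask) paste(mask, collapse = "")

# Fitness comparison with a parsimony tie-break: exactly equal fitness is
# resolved toward the mask with fewer selected features (wrapper-selection
# convention; keeps the search from accumulating free-riding features).
mask_better <- function(f1, m1, f2, m2) {
  if (f1 != f2) return(f1 > f2)
  sum(m1) < sum(m2)
}

#' Evolve feature masks by genetic search
#'
#' Runs tournament selection, single-point crossover, bit-flip mutation and
#' elitism for `cfg$generations` generations, maximizing `fitness_fn(mask)`.
#' Fitness values are cached by mask, so re-evaluating a chromosome is free
#' and total fitness calls are bounded by `pop_size * (generations + 1)`.
#' Exact fitness ties are broken toward smaller masks.
#'
#' @param cfg a [ga_config()].
#' @param n_features chromosome length.
#' @param fitness_fn function taking a 0/1 mask and returning a scalar
#'   fitness (larger is better).
#' @return A list of class `ga_result`: `best_mask`, `best_fitness`,
#'   `history` (data frame: generation, best, mean), `population`,
#'   `evaluations` (number of distinct masks actually evaluated).
#' @export
evolve <- function(cfg, n_features, fitness_fn) {
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fit_of <- function(mask) {
    key <- mask_key(mask)
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- fitness_fn(mask)
    n_eval <<- n_eval + 1L
    cache[[key]] <- v
    v
  }
  pop <- init_population(cfg, n_features)
  with_seed(child_seed(cfg$seed, 1), {
    fits <- apply(pop, 1, fit_of)
    best_i <- which.max(fits)
    best_mask <- pop[best_i, ]
    best_fit <- fits[best_i]
    history <- data.frame(generation = 0, best = best_fit, mean = mean(fits))
    rate <- cfg$p_mutation %||% (1 / n_features)
    for (gen in seq_len(cfg$generations)) {
      new_pop <- matrix(0L, cfg$pop_size, n_features)
      filled <- 0L
      if (cfg$elitism > 0) {
        elite_order <- order(-fits, rowSums(pop))
        n_el <- min(cfg$elitism, cfg$pop_size)
        new_pop[seq_len(n_el), ] <- pop[elite_order[seq_len(n_el)], ]
        filled <- n_el
      }
      pick <- function() {
        cand <- sample.int(cfg$pop_size, cfg$tournament, replace = TRUE)
        best <- cand[1]
        for (c2 in cand[-1]) {
          if (mask_better(fits[c2], pop[c2, ], fits[best], pop[best, ])) best <- c2
        }
        pop[best, ]
      }
      while (filled < cfg$pop_size) {
        p1 <- pick(); p2 <- pick()
        if (stats::runif(1) < cfg$p_crossover && n_features > 1) {
          point <- sample.int(n_features - 1, 1)
          ch <- crossover_masks(p1, p2, point, apply = TRUE)
        } else {
          ch <- list(child1 = p1, child2 = p2)
        }
        for (child in list(ch$child1, ch$child2)) {
          if (filled >= cfg$pop_size) break
          filled <- filled + 1L
          new_pop[filled, ] <- mutate_mask(child, rate)
        }
      }
      pop <- new_pop
      fits <- apply(pop, 1, fit_of)
      gen_best <- which.max(fits)
      if (mask_better(fits[gen_best], pop[gen_best, ], best_fit, best_mask)) {
        best_fit <- fits[gen_best]
        best_mask <- pop[gen_best, ]
      }
      history <- rbind(history,
                       data.frame(generation = gen, best = best_fit,
                                  mean = mean(fits)))
    }
    structure(list(best_mask = as.integer(best_mask), best_fitness = best_fit,
                   history = history, population = pop,
                   evaluations = n_eval),
              class = "ga_result")
  })
}

#' DNN-accuracy fitness for feature masks
#'
#' Builds the fitness function the genetic search maximizes: for a candidate
#' mask it trains the fixed network (input width = number of selected
#' features) on the masked training features for `cfg$fitness_epochs` epochs
#' with a fixed, mask-independent seed, and scores it on an internal
#' validation fold carved once from the training partition — never on the
#' test partition, so reported test metrics stay honest. Classification
#' fitness is validation accuracy; regression fitness is `1 / (1 + RMSE)`.
#'
#' @param x_train scaled training feature matrix (all candidate features).
#' @param y_train training targets (one-hot matrix or numeric vector).
#' @param task task string as in [build_network()].
#' @param cfg a [ga_config()].
#' @param net_cfg a [train_config()] supplying lr/batch/dropout for fitness
#'   training (its `epochs` is overridden by `cfg$fitness_epochs`).
#' @return Function `(mask) -> fitness in [0, 1]`.
#' @export
dnn_fitness <- function(x_train, y_train, task, cfg, net_cfg = train_config()) {
  x_train <- as.matrix(x_train)
  n <- nrow(x_train)
  strat <- if (task == "age_regression") factor(rep("all", n))
           else decode_one_hot(y_train)
  idx_split <- split_dataset(data.frame(i = seq_len(n)), strat,
                             fraction = cfg$val_fraction,
                             seed = child_seed(cfg$seed, 2))
  fit_idx <- idx_split$train_idx
  val_idx <- idx_split$test_idx
  fit_cfg <- net_cfg
  fit_cfg$epochs <- cfg$fitness_epochs
  fit_cfg$seed <- as.integer(child_seed(cfg$seed, 3))
  y_is_matrix <- is.matrix(y_train)
  function(mask) {
    if (sum(mask) == 0) stop("dnn_fitness: all-zero mask must be repaired first")
    cols <- which(mask == 1)
    spec <- build_network(length(cols), task)
    y_fit <- if (y_is_matrix) y_train[fit_idx, , drop = FALSE] else y_train[fit_idx]
    net <- dnn_train(spec, x_train[fit_idx, cols, drop = FALSE], y_fit, fit_cfg)
    if (task == "age_regression") {
      pred <- predict(net, x_train[val_idx, cols, drop = FALSE])
      rep <- regression_report(y_train[val_idx], pred)
      1 / (1 + rep$rmse)
    } else {
      pred <- predict(net, x_train[val_idx, cols, drop = FALSE], type = "label")
      truth <- decode_one_hot(y_train[val_idx, , drop = FALSE])
      mean(as.character(pred) == as.character(truth))
    }
  }
}
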