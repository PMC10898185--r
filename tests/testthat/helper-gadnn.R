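# Shared fixture builders. Everything is generated in code, seeded.

# A cohort whose age-group sizes are exactly `sizes` (named A-D), with
# plausible feature values from the simulator.
cohort_with_group_sizes <- function(sizes, seed = 42) {
  n <- sum(sizes)
  base <- simulate_cohort(sim_config(n = n, seed = seed))
  lows <- c(A = 18, B = 26, C = 34, D = 42)
  highs <- c(A = 25, B = 33, C = 41, D = 50)
  ages <- numeric(0)
  set.seed(seed)
  for (g in names(sizes)) {
    ages <- c(ages, runif(sizes[[g]], lows[[g]], highs[[g]]))
  }
  base$age <- ages
  attr(base, "sim_config") <- NULL
  base
}

# Brute-force SMOTE witness check: a synthetic row must lie exactly on the
# segment between some real same-class point a and one of a's k nearest
# same-class neighbours (all-pairs distances, exhaustive scan).
smote_witness_exists <- function(syn_row, real_x, k, tol = 1e-8) {
  n <- nrow(real_x)
  d <- as.matrix(dist(real_x))
  for (a in seq_len(n)) {
    nn <- order(d[a, ])[2:(min(k, n - 1) + 1)]
    for (b in nn) {
      diff_ab <- real_x[b, ] - real_x[a, ]
      diff_sa <- syn_row - real_x[a, ]
      nz <- which(abs(diff_ab) > 1e-12)
      if (!length(nz)) next
      u <- diff_sa[nz[1]] / diff_ab[nz[1]]
      if (is.na(u) || u < -tol || u > 1 + tol) next
      if (max(abs(diff_sa - u * diff_ab)) < tol * max(1, max(abs(real_x)))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Scaled feature matrix + one-hot labels from a cohort, for direct network
# training in tests.
prep_xy <- function(cohort, label_col = "sex") {
  x <- minmax_normalize(cohort[, sinus_features()])$train
  labels <- droplevels(as.factor(cohort[[label_col]]))
  list(x = x, y = one_hot(labels, levels(labels)), labels = labels)
}
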