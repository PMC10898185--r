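#' SMOTE oversampling to the majority class
#'
#' Balances every class up to the size of the largest class by synthesizing
#' minority-class rows: each synthetic row is `x + u * (x_nn - x)` for a real
#' minority member `x`, one of its `k` nearest same-class neighbours `x_nn`
#' (Euclidean distance in the raw 12-feature space), and `u` uniform on
#' `[0, 1]`. Age is interpolated along with the features (parents share a
#' class, so for age-group labels the interpolant stays inside the group's
#' interval); sex of a synthetic row is taken from its seed parent. Original
#' rows are returned unchanged, first, and synthetic rows carry
#' `synthetic = TRUE`.
#'
#' @param data a sinus dataset.
#' @param labels factor of class labels, one per row (e.g. sex or age group).
#' @param k neighbour count; reduced per class to `class size - 1` with a
#'   warning when a class is smaller than `k + 1`.
#' @param seed integer seed.
#' @return A list with `data` (original rows followed by synthetic rows) and
#'   `labels` (extended in step).
#' @export
smote_balance <- function(data, labels, k = 5, seed = 1) {
  labels <- as.factor(labels)
  stopifnot(nrow(data) == length(labels), k >= 1)
  counts <- table(labels)
  if (any(counts == 0)) {
    stop("smote_balance: empty class: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  }
  target <- max(counts)
  feats <- sinus_features()
  x <- as.matrix(data[, feats])
  new_rows <- list()
  new_labels <- list()
  with_seed(seed, {
    for (cls in names(counts)) {
      need <- target - counts[[cls]]
      if (need == 0) next
      members <- which(labels == cls)
      m <- length(members)
      if (m < 2) {
        stop("smote_balance: class '", cls,
             "' has a single member; no neighbour exists")
      }
      kk <- min(k, m - 1)
      if (kk < k) {
        warning(sprintf("smote_balance: k reduced to %d for class '%s' (size %d)",
                        kk, cls, m))
      }
      d <- as.matrix(stats::dist(x[members, , drop = FALSE]))
      # k nearest same-class neighbours of each member (excluding itself)
      nn <- t(apply(d, 1, function(r) order(r)[2:(kk + 1)]))
      seeds <- members[sample.int(m, need, replace = TRUE)]
      for (i in seq_len(need)) {
        a <- seeds[i]
        a_local <- match(a, members)
        b <- members[nn[a_local, sample.int(kk, 1)]]
        u <- stats::runif(1)
        row <- data[a, , drop = FALSE]
        row[, feats] <- data[a, feats] + u * (data[b, feats] - data[a, feats])
        row$age <- data$age[a] + u * (data$age[b] - data$age[a])
        row$synthetic <- TRUE
        new_rows[[length(new_rows) + 1]] <- row
        new_labels[[length(new_labels) + 1]] <- cls
      }
    }
  })
  if (length(new_rows)) {
    syn <- do.call(rbind, new_rows)
    syn$id <- max(data$id) + seq_len(nrow(syn))
    out <- rbind(data, syn)
    out_labels <- factor(c(as.character(labels), unlist(new_labels)),
                         levels = levels(labels))
  } else {
    out <- data
    out_labels <- labels
  }
  rownames(out) <- NULL
  list(data = out, labels = out_labels)
}

#' Fit and apply min--max normalization
#'
#' Per-feature bounds are fitted on the training rows only; the test rows are
#' mapped with the train-fitted bounds and may legitimately fall outside
#' `[0, 1]` (no clipping). A constant training feature maps to 0 everywhere.
#'
#' @param train,test numeric matrices or data frames of features (test may be
#'   `NULL`).
#' @return A list with `train`, `test` (scaled matrices) and `scaler` (class
#'   `minmax_scaler`, usable with [apply_scaler()] and [invert_scaler()]).
#' @export
minmax_normalize <- function(train, test = NULL) {
  train <- as.matrix(train)
  stopifnot(nrow(train) > 0)
  scaler <- structure(
    list(min = apply(train, 2, min), max = apply(train, 2, max)),
    class = "minmax_scaler"
  )
  list(
    train = apply_scaler(scaler, train),
    test = if (!is.null(test)) apply_scaler(scaler, as.matrix(test)),
    scaler = scaler
  )
}

#' @rdname minmax_normalize
#' @param scaler a fitted `minmax_scaler`.
#' @param x matrix to scale (columns matching the fitted features).
#' @export
apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  rng <- scaler$max - scaler$min
  out <- sweep(x, 2, scaler$min, "-")
  safe <- ifelse(rng > 0, rng, 1)
  out <- sweep(out, 2, safe, "/")
  out[, rng == 0] <- 0
  out
}

#' @rdname minmax_normalize
#' @export
invert_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  rng <- scaler$max - scaler$min
  sweep(sweep(x, 2, ifelse(rng > 0, rng, 0), "*"), 2, scaler$min, "+")
}

#' One-hot encoding and decoding
#'
#' `one_hot` turns a factor into an n-by-k binary matrix over an ordered
#' class set; `decode_one_hot` maps score rows back to labels by argmax,
#' breaking exact ties toward the lowest class index.
#'
#' @param labels vector of labels.
#' @param classes ordered character vector of allowed classes.
#' @return `one_hot`: binary matrix with one 1 per row; `decode_one_hot`:
#'   factor of labels.
#' @export
one_hot <- function(labels, classes = levels(as.factor(labels))) {
  labels <- as.character(labels)
  unseen <- setdiff(unique(labels), classes)
  if (length(unseen)) {
    stop("one_hot: unseen label(s): ", paste(unseen, collapse = ", "))
  }
  m <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  m[cbind(seq_along(labels), match(labels, classes))] <- 1
  m
}

#' @rdname one_hot
#' @param scores numeric matrix of per-class scores (columns ordered as
#'   `classes`).
#' @export
decode_one_hot <- function(scores, classes = colnames(scores)) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == length(classes))
  factor(classes[max.col(scores, ties.method = "first")], levels = classes)
}

#' Stratified train/test split
#'
#' Seeded, reproducible split stratified by the task label, so every class
#' appears in both partitions. The test share of each stratum is
#' `round(fraction * stratum size)`, bounded so each stratum keeps at least
#' one row on each side.
#'
#' @param data a sinus dataset.
#' @param labels factor used for stratification (one per row). For regression
#'   tasks pass a single-level factor or `NULL` for an unstratified split.
#' @param fraction test fraction in `(0, 1)`.
#' @param seed integer seed.
#' @return A list of class `split_dataset` with `train`, `test` (row subsets
#'   of `data`), `train_labels`, `test_labels`, `train_idx`, `test_idx`,
#'   `fraction` and `seed`.
#' @export
split_dataset <- function(data, labels = NULL, fraction = 0.2, seed = 1) {
  n <- nrow(data)
  if (!(fraction > 0 && fraction < 1)) {
    stop("split_dataset: fraction must be strictly inside (0, 1)")
  }
  if (is.null(labels)) labels <- factor(rep("all", n))
  labels <- droplevels(as.factor(labels))
  stopifnot(length(labels) == n)
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("split_dataset: stratum with fewer than 2 rows: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  test_idx <- integer(0)
  with_seed(seed, {
    for (cls in names(counts)) {
      members <- which(labels == cls)
      m <- length(members)
      n_test <- min(max(round(fraction * m), 1L), m - 1L)
      test_idx <- c(test_idx, sample(members, n_test))
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  structure(list(
    train = data[train_idx, , drop = FALSE],
    test = data[test_idx, , drop = FALSE],
    train_labels = labels[train_idx],
    test_labels = labels[test_idx],
    train_idx = train_idx,
    test_idx = test_idx,
    fraction = fraction,
    seed = seed
  ), class = "split_dataset")
}
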