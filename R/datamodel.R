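#' Canonical sinus feature names
#'
#' The twelve CBCT-derived measurements in their canonical order: the frontal
#' sinus block (length, width, height, volume), then the right maxillary
#' block, then the left maxillary block. The order is fixed because the
#' genetic algorithm's binary chromosomes index features positionally.
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' sinus_features()
sinus_features <- function() {
  c("FSL", "FSW", "FSH", "FSV",
    "RMSL", "RMSW", "RMSH", "RMSV",
    "LMSL", "LMSW", "LMSH", "LMSV")
}

# Feature indices of linear dimensions (lengths/widths/heights); volumes are
# at positions 4, 8, 12.
sinus_dimension_idx <- function() c(1:3, 5:7, 9:11)
sinus_volume_idx <- function() c(4L, 8L, 12L)

#' Age-group binning scheme
#'
#' Four contiguous closed bins used to turn continuous age into the ordinal
#' groups A (18--25), B (26--33), C (34--41) and D (42--50). Ages above the
#' top bin can be clamped into D (with a warning) so cohorts containing a few
#' subjects just over 50 remain ingestible.
#'
#' @param clamp_above logical; if `TRUE` (default) ages above 50 map to D.
#' @return An object of class `age_group_scheme`: a data frame with columns
#'   `label`, `lower`, `upper` and attribute `clamp_above`.
#' @export
#' @examples
#' age_group_scheme()
age_group_scheme <- function(clamp_above = TRUE) {
  scheme <- data.frame(
    label = c("A", "B", "C", "D"),
    lower = c(18, 26, 34, 42),
    upper = c(25, 33, 41, 50),
    stringsAsFactors = FALSE
  )
  attr(scheme, "clamp_above") <- isTRUE(clamp_above)
  class(scheme) <- c("age_group_scheme", "data.frame")
  scheme
}

#' Assign ages to age groups
#'
#' A total, monotone step function on `[18, Inf)`: each age maps to the label
#' of the bin containing it. Ages above the top bin return the top label with
#' a warning when the scheme clamps, and error otherwise.
#'
#' @param age numeric vector of ages in years.
#' @param scheme an [age_group_scheme()].
#' @return Factor with the scheme's labels as levels.
#' @export
#' @examples
#' bin_age(c(18, 25, 26, 33, 34, 41, 42, 50))
bin_age <- function(age, scheme = age_group_scheme()) {
  stopifnot(is.numeric(age))
  if (anyNA(age)) stop("bin_age: missing ages are not binnable")
  if (any(age < scheme$lower[1])) {
    stop(sprintf("bin_age: age below cohort minimum %s (got %s)",
                 scheme$lower[1], min(age)))
  }
  top <- scheme$upper[nrow(scheme)]
  if (any(age > top)) {
    if (!isTRUE(attr(scheme, "clamp_above"))) {
      stop(sprintf("bin_age: age above top bin (%s) and clamping disabled", top))
    }
    warning(sprintf("bin_age: %d age(s) above %s clamped into group %s",
                    sum(age > top), top, scheme$label[nrow(scheme)]))
  }
  breaks <- c(scheme$lower, Inf)
  idx <- findInterval(age, breaks)
  factor(scheme$label[pmin(idx, nrow(scheme))], levels = scheme$label)
}

#' Count subjects per age group
#'
#' @param data a sinus dataset (see [read_sinus_csv()]).
#' @param scheme an [age_group_scheme()].
#' @return Named integer vector of per-group counts; sums to `nrow(data)`.
#' @export
group_counts <- function(data, scheme = age_group_scheme()) {
  groups <- bin_age(data$age, scheme)
  counts <- table(groups)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

# Validates the measurement/label columns of a sinus data frame.
# Returns the data invisibly; stops with a row-indexed message on violation.
validate_sinus_data <- function(data) {
  feats <- sinus_features()
  needed <- c(feats, "sex", "age")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    stop("sinus data: missing column(s): ", paste(missing, collapse = ", "))
  }
  for (f in feats) {
    v <- data[[f]]
    if (!is.numeric(v)) {
      stop(sprintf("sinus data: column %s is not numeric", f))
    }
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad)) {
      stop(sprintf("sinus data: non-positive or missing %s in row(s) %s",
                   f, paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  if (!all(as.character(data$sex) %in% c("F", "M"))) {
    stop("sinus data: sex must be coded 'F'/'M'")
  }
  if (!is.numeric(data$age) || any(!is.finite(data$age) | data$age < 0)) {
    bad <- which(!is.finite(data$age) | data$age < 0)
    stop("sinus data: invalid age in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(data)
}

# Coerce a validated data frame into the canonical column layout.
as_sinus_dataset <- function(data, synthetic = FALSE) {
  validate_sinus_data(data)
  if (is.null(data$id)) data$id <- seq_len(nrow(data))
  if (is.null(data$synthetic)) data$synthetic <- rep(isTRUE(synthetic), nrow(data))
  data$sex <- factor(as.character(data$sex), levels = c("F", "M"))
  rownames(data) <- NULL
  data[, c("id", "sex", "age", sinus_features(), "synthetic")]
}

#' Read a sinus morphometry CSV
#'
#' Expects a header row with columns `id` (optional), `sex` (coded `"F"`/
#' `"M"`), `age` (years) and the twelve measurements named as in
#' [sinus_features()]. A `schema` map can rename non-standard headers.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector mapping canonical column
#'   names to the names used in the file, e.g. `c(FSL = "frontal_length")`.
#' @return A data frame with columns `id`, `sex`, `age`, the twelve features
#'   in canonical order, and `synthetic` (all `FALSE`), one row per subject,
#'   in file order.
#' @export
read_sinus_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("read_sinus_csv: no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(raw)) {
        stop("read_sinus_csv: schema column not in file: ", src)
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  as_sinus_dataset(raw, synthetic = FALSE)
}

#' Write a sinus morphometry CSV
#'
#' Emits the canonical dialect ([read_sinus_csv()]) plus the `synthetic`
#' audit column, at full double precision so a read/write cycle round-trips
#' the numeric content exactly.
#'
#' @param data a sinus dataset.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sinus_csv <- function(data, path) {
  out <- data
  for (f in sinus_features()) out[[f]] <- format(out[[f]], digits = 17, trim = TRUE)
  out$age <- format(data$age, digits = 17, trim = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
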