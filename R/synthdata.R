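#' Configuration for the synthetic sinus-morphometry cohort generator
#'
#' The generator emulates a forensic CBCT cohort: a linear Gaussian model on
#' the nine linear dimensions (lengths, widths, heights) with configurable
#' sex dimorphism and age trends, a shared latent factor giving right/left
#' maxillary homologues a bilateral correlation `rho`, and volumes derived
#' from their own sinus's dimensions through `V = c * L * W * H * exp(eps)`
#' with `eps ~ N(0, volume_sigma)`. Deriving volumes from dimensions builds
#' the redundancy that makes wrapper feature selection meaningful.
#'
#' Default baseline magnitudes are plausible adult values (maxillary length
#' around 38 mm, maxillary volume around 15,000 mm^3) chosen only to keep the
#' CSVs human-readable; they carry no claim about any clinical distribution.
#'
#' @param n cohort size.
#' @param female_fraction expected proportion of female subjects.
#' @param age_range ages are drawn uniformly on this interval (years).
#' @param dim_means,dim_sds named numeric vectors over the nine dimension
#'   features (means/SDs in mm).
#' @param sex_effect standardized mean shift (male minus female, in SD units)
#'   per dimension feature; scalar or named vector.
#' @param age_effect standardized slope per decade of age per dimension
#'   feature; scalar or named vector.
#' @param bilateral_rho correlation between right and left maxillary
#'   homologues, in `[0, 1)`.
#' @param volume_c multiplicative constant of the volume coupling.
#' @param volume_sigma SD of the log-normal volume noise.
#' @param seed integer seed; the same configuration always yields a
#'   byte-identical cohort.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 240,
                       female_fraction = 129 / 240,
                       age_range = c(18, 52),
                       dim_means = NULL,
                       dim_sds = NULL,
                       sex_effect = 0.7,
                       age_effect = -0.1,
                       bilateral_rho = 0.6,
                       volume_c = 0.4,
                       volume_sigma = 0.08,
                       seed = 1) {
  dims <- sinus_features()[sinus_dimension_idx()]
  default_means <- c(FSL = 13, FSW = 48, FSH = 25,
                     RMSL = 38, RMSW = 28, RMSH = 36,
                     LMSL = 38, LMSW = 28, LMSH = 36)
  default_sds <- c(FSL = 2.5, FSW = 6, FSH = 5,
                   RMSL = 3.5, RMSW = 3, RMSH = 3.5,
                   LMSL = 3.5, LMSW = 3, LMSH = 3.5)
  expand <- function(x, default) {
    if (is.null(x)) return(default)
    if (length(x) == 1 && is.null(names(x))) {
      out <- rep(as.numeric(x), length(dims)); names(out) <- dims; return(out)
    }
    stopifnot(all(dims %in% names(x)))
    x[dims]
  }
  cfg <- list(
    n = as.integer(n),
    female_fraction = female_fraction,
    age_range = age_range,
    dim_means = expand(dim_means, default_means),
    dim_sds = expand(dim_sds, default_sds),
    sex_effect = expand(sex_effect, structure(rep(0.7, 9), names = dims)),
    age_effect = expand(age_effect, structure(rep(-0.1, 9), names = dims)),
    bilateral_rho = bilateral_rho,
    volume_c = volume_c,
    volume_sigma = volume_sigma,
    seed = as.integer(seed)
  )
  stopifnot(cfg$n >= 4,
            cfg$female_fraction > 0, cfg$female_fraction < 1,
            cfg$bilateral_rho >= 0, cfg$bilateral_rho < 1,
            all(cfg$dim_sds > 0), cfg$volume_sigma >= 0, cfg$volume_c > 0,
            diff(cfg$age_range) >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic sinus-morphometry cohort
#'
#' @param config a [sim_config()].
#' @return A sinus dataset (see [read_sinus_csv()]) with `synthetic = TRUE`
#'   on every row and the generating configuration attached as attribute
#'   `"sim_config"`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 50, seed = 7))
#' nrow(cohort)
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  dims <- sinus_features()[sinus_dimension_idx()]
  pairs <- list(c("RMSL", "LMSL"), c("RMSW", "LMSW"), c("RMSH", "LMSH"))
  with_seed(config$seed, {
    n <- config$n
    n_f <- round(config$female_fraction * n)
    sex <- factor(c(rep("F", n_f), rep("M", n - n_f)), levels = c("F", "M"))
    sex <- sample(sex)
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    male <- as.numeric(sex == "M")
    age_c <- (age - 35) / 10

    draw_noise <- function() {
      z <- matrix(stats::rnorm(n * length(dims)), n, length(dims),
                  dimnames = list(NULL, dims))
      rho <- config$bilateral_rho
      if (rho > 0) {
        for (p in pairs) {
          shared <- stats::rnorm(n)
          z[, p[1]] <- sqrt(rho) * shared + sqrt(1 - rho) * z[, p[1]]
          z[, p[2]] <- sqrt(rho) * shared + sqrt(1 - rho) * z[, p[2]]
        }
      }
      z
    }

    make_dims <- function(rows) {
      z <- draw_noise()[rows, , drop = FALSE]
      m <- length(rows)
      x <- matrix(0, m, length(dims), dimnames = list(NULL, dims))
      for (j in seq_along(dims)) {
        f <- dims[j]
        x[, j] <- config$dim_means[f] + config$dim_sds[f] *
          (config$sex_effect[f] * male[rows] +
             config$age_effect[f] * age_c[rows] + z[, j])
      }
      x
    }

    x <- make_dims(seq_len(n))
    # resample rows violating strict positivity (vanishingly rare at the
    # default magnitudes, but the invariant is enforced)
    for (iter in 1:100) {
      bad <- which(apply(x, 1, function(r) any(r <= 0)))
      if (!length(bad)) break
      x[bad, ] <- make_dims(bad)
    }
    if (any(x <= 0)) stop("simulate_cohort: could not satisfy positivity")

    vol <- function(l, w, h) {
      config$volume_c * l * w * h *
        exp(stats::rnorm(n, 0, config$volume_sigma))
    }
    out <- data.frame(
      id = seq_len(n), sex = sex, age = age,
      FSL = x[, "FSL"], FSW = x[, "FSW"], FSH = x[, "FSH"],
      FSV = vol(x[, "FSL"], x[, "FSW"], x[, "FSH"]),
      RMSL = x[, "RMSL"], RMSW = x[, "RMSW"], RMSH = x[, "RMSH"],
      RMSV = vol(x[, "RMSL"], x[, "RMSW"], x[, "RMSH"]),
      LMSL = x[, "LMSL"], LMSW = x[, "LMSW"], LMSH = x[, "LMSH"],
      LMSV = vol(x[, "LMSL"], x[, "LMSW"], x[, "LMSH"]),
      synthetic = TRUE
    )
    out <- as_sinus_dataset(out, synthetic = TRUE)
    attr(out, "sim_config") <- config
    out
  })
}

#' Cohort with planted feature relevance
#'
#' Builds a benchmark cohort for wrapper feature selection: the features in
#' `informative` carry a standardized sex effect of size `effect`; all other
#' features are independent pure noise. All twelve features are generated
#' independently (no bilateral correlation, no volume coupling) so that the
#' ground-truth relevance of each feature is unambiguous. Age is uniform and
#' carries no signal.
#'
#' @param n cohort size.
#' @param informative character vector of feature names (or integer indices
#'   into [sinus_features()]); a non-empty proper subset of the 12 features.
#' @param effect standardized mean shift (male minus female) on informative
#'   features, in SD units.
#' @param seed integer seed.
#' @return A sinus dataset with attribute `"informative_mask"`, a named
#'   logical vector over the 12 features marking the planted-relevant ones.
#' @export
planted_relevance_cohort <- function(n = 500,
                                     informative = sinus_features()[c(1, 3, 5, 7, 9, 11)],
                                     effect = 2,
                                     seed = 1) {
  feats <- sinus_features()
  if (is.numeric(informative)) informative <- feats[informative]
  stopifnot(all(informative %in% feats))
  if (length(informative) == 0 || length(informative) == length(feats)) {
    stop("planted_relevance_cohort: informative set must be a non-empty proper subset")
  }
  means <- c(FSL = 13, FSW = 48, FSH = 25, FSV = 6000,
             RMSL = 38, RMSW = 28, RMSH = 36, RMSV = 15000,
             LMSL = 38, LMSW = 28, LMSH = 36, LMSV = 15000)
  sds <- means * 0.12
  with_seed(seed, {
    sex <- factor(ifelse(stats::runif(n) < 0.5, "F", "M"), levels = c("F", "M"))
    male <- as.numeric(sex == "M")
    age <- stats::runif(n, 18, 52)
    x <- matrix(stats::rnorm(n * 12), n, 12, dimnames = list(NULL, feats))
    for (f in feats) {
      shift <- if (f %in% informative) effect * male else 0
      x[, f] <- pmax(means[f] + sds[f] * (x[, f] + shift), 1e-3)
    }
    out <- data.frame(id = seq_len(n), sex = sex, age = age,
                      as.data.frame(x), synthetic = TRUE)
    out <- as_sinus_dataset(out, synthetic = TRUE)
    mask <- structure(feats %in% informative, names = feats)
    attr(out, "informative_mask") <- mask
    out
  })
}
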