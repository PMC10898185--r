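#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so package functions never leak RNG
#' state into the caller's session. All stochastic operations in the package
#' route their randomness through this helper.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic child seed derivation; keeps every derived seed < 2^31.
child_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 10007) %% 2147483629
}

# FNV-1a checksum over a serialized object; used in run manifests to pin the
# input dataset without a heavyweight digest dependency.
checksum <- function(object) {
  bytes <- as.integer(serialize(object, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967291
  }
  sprintf("%x", as.integer(h %% 2147483647))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
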