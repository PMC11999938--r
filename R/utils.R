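#' @useDynLib emgforce, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd median mad approx rnorm runif quantile cor
#'   pnorm pchisq rlnorm
#' @importFrom utils head combn
NULL

#' Min-max normalization of a sequence
#'
#' Rescales a numeric vector to the unit interval,
#' `x' = (x - min(x)) / (max(x) - min(x))`. This is the normalization
#' applied to every per-channel envelope, to the collapsed one-dimensional
#' envelope and to the smoothed force trace, so that force targets and
#' envelope amplitudes live on a common `[0, 1]` scale.
#'
#' Degenerate input (constant vector, `max == min`) cannot be rescaled;
#' it is mapped to all zeros with a warning, matching how a dead channel
#' should be represented downstream.
#'
#' @param x numeric vector, all values finite.
#' @return numeric vector of the same length in `[0, 1]`.
#' @examples
#' minmax_normalize(c(2, 4, 6)) # 0, 0.5, 1
#' @export
minmax_normalize <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  rng <- range(x)
  if (rng[2] <= rng[1]) {
    warning("constant sequence: min-max normalization degenerate, returning zeros")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# Deterministic per-stage seed derivation: a single top-level seed is
# expanded into stage seeds by hashing the stage label into [0, 2^31 - 2].
derive_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "emgforce_error")))
}
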