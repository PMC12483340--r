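# Internal helpers shared across modules.

#' Derive reproducible sub-seeds from a base seed
#'
#' Every source of randomness in the package descends from one user-supplied
#' integer seed; nested components receive sub-seeds drawn deterministically
#' from it so that adding a component never perturbs the draws of another.
#'
#' @param seed Integer base seed.
#' @param n Number of sub-seeds required.
#' @return Integer vector of length `n`, each a valid `set.seed()` value.
#' @keywords internal
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

# Moments of a normal distribution truncated to [lo, hi]; standard closed forms.
trunc_norm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

trunc_norm_var <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  d <- (stats::dnorm(a) - stats::dnorm(b)) / z
  sd^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / z - d^2)
}

# Inverse-CDF sampler for the truncated normal; adequate far from extreme tails.
rtrunc_norm <- function(n, mu, sd, lo, hi) {
  pa <- stats::pnorm(lo, mu, sd)
  pb <- stats::pnorm(hi, mu, sd)
  stats::qnorm(stats::runif(n, pa, pb), mu, sd)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
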