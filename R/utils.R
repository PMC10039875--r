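#' @importFrom rlang .data abort warn
#' @importFrom stats median mad rnorm rpois runif rgamma rbinom dpois dgamma
#'   dnorm dbeta pgamma qnorm quantile sd var optim glm binomial predict
#'   coef plogis qlogis approx setNames rexp lm confint fft nextn
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

log_sum_exp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic components of the package draw their randomness from
#' sub-streams derived deterministically from one master seed, so that an
#' entire simulated experiment is reproducible from a single integer.
#'
#' @param seed master seed (single integer).
#' @param stream label of the sub-stream (string or integer).
#' @return A single integer seed, always below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1, is.finite(seed))
  key <- paste0(format(seed, scientific = FALSE), "/", as.character(stream))
  # small string hash (polynomial rolling, modulo a prime < 2^31)
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% 2147483587
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %s (got %s)",
                  name, min, paste(x, collapse = ",")))
  }
  as.integer(x)
}

assert_positive <- function(x, name, strict = TRUE) {
  bad <- !is.finite(x) | (if (strict) x <= 0 else x < 0)
  if (any(bad)) {
    abort(sprintf("`%s` must be %s (got %s)", name,
                  if (strict) "> 0" else ">= 0", paste(x[bad], collapse = ",")))
  }
  x
}

# Gamma distribution parameterized by mean and sd, as used throughout the
# connectivity models; shape k = (mu/sigma)^2, scale theta = sigma^2/mu.
gamma_mean_sd <- function(mu, sigma) {
  assert_positive(mu, "mu")
  assert_positive(sigma, "sigma")
  list(shape = (mu / sigma)^2, scale = sigma^2 / mu)
}

dgamma_mean_sd <- function(x, mu, sigma, log = FALSE) {
  p <- gamma_mean_sd(mu, sigma)
  dgamma(x, shape = p$shape, scale = p$scale, log = log)
}

rgamma_mean_sd <- function(n, mu, sigma) {
  p <- gamma_mean_sd(mu, sigma)
  rgamma(n, shape = p$shape, scale = p$scale)
}

#' @useDynLib synaptomap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
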