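# Internal numerical helpers.

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

# log Bernoulli(y | sigmoid(l)), stable for large |l|:
# y*l - log(1 + exp(l)) computed via the log1p trick.
log_bernoulli_logit <- function(y, l) {
  y * l - ifelse(l > 35, l, log1p(exp(l)))
}

# log N(x | mean, 1/prec)
log_dnorm_prec <- function(x, mean, prec) {
  0.5 * log(prec) - 0.5 * log(2 * pi) - 0.5 * prec * (x - mean)^2
}

# Inverse-Gaussian sampler (Michael, Schucany & Haas 1976 transform).
# Used for the 1/tau^2 full conditional of the Laplace scale mixture.
rinvgauss <- function(n, mean, shape) {
  stopifnot(all(mean > 0), all(shape > 0))
  nu <- stats::rnorm(n)
  w <- nu^2
  x1 <- mean + mean^2 * w / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * w + mean^2 * w^2)
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x1), x1, mean^2 / x1)
}

# Evaluate a thunk under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
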