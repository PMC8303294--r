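# internal helpers shared across modules

# draw NB counts parameterized by mean and dispersion alpha
# (variance = mu + alpha * mu^2); alpha = 0 degenerates to Poisson
rnbinom_mu <- function(n, mu, alpha) {
  if (alpha == 0) {
    stats::rpois(n, lambda = mu)
  } else {
    stats::rnbinom(n, mu = mu, size = 1 / alpha)
  }
}

# geometric mean; 0 if any element is 0 (convention of median-of-ratios
# normalization, where such rows are excluded)
geomean <- function(x) {
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (strict && x <= lower) stopf("'%s' must be > %g", name, lower)
  if (!strict && x < lower) stopf("'%s' must be >= %g", name, lower)
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    stopf("'%s' must be a single integer", name)
  }
  if (x < lower) stopf("'%s' must be >= %d", name, lower)
  invisible(as.integer(x))
}
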