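#' Derive a reproducible sub-stream seed from a master seed
#'
#' Simulation experiments run many independently reproducible replicates.
#' Each replicate's RNG stream is derived from the master seed and a counter
#' so that any single replicate can be re-run in isolation.
#'
#' @param seed master seed (integer).
#' @param counter non-negative integer identifying the sub-stream.
#' @return an integer seed strictly below 2^31, usable with [set.seed()].
#' @export
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(counter))
  # splitmix-style integer hash, kept in [0, 2^31 - 1]
  x <- (as.double(seed) %% 2147483647) + 1
  y <- (as.double(counter) %% 2147483647) + 1
  h <- (x * 48271 + y * 69621 + (x * y) %% 94906249) %% 2147483647
  as.integer(h)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return named numeric vector with `estimate`, `lower`, `upper`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(estimate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

# internal: stop with a classed condition so callers/tests can match on class
tl_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "transloci_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# internal: column-wise standardization (mean 0, sd 1, denominator n - 1)
standardize_columns <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  s <- sqrt(colSums(xc^2) / (nrow(x) - 1))
  if (any(s == 0)) tl_stop("zero-variance column cannot be standardized", "transloci_degenerate")
  sweep(xc, 2L, s, "/")
}
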