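# shared helpers for the test suite; all synthetic data is generated in
# code under fixed seeds

fast_cfg <- function(...) {
  rosetta_config(max_components_per_cluster = c(1L, 1L), ...)
}

# numeric CDF of a 1-D density by cumulative trapezoid on a fine grid
numeric_cdf <- function(pdf, lo, hi, n = 4001L) {
  x <- seq(lo, hi, length.out = n)
  y <- pdf(x)
  cdf <- c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
  cdf <- cdf / cdf[n]
  function(q) approx(x, cdf, xout = q, rule = 2)$y
}

# one-sample KS statistic against a numeric CDF
ks_stat_numeric <- function(sample, cdf) {
  s <- sort(sample)
  n <- length(s)
  u <- cdf(s)
  max(pmax(abs(seq_len(n) / n - u), abs(u - (seq_len(n) - 1) / n)))
}

sample_skewness <- function(x) mean(((x - mean(x)) / sd(x))^3)

# independent quadrature oracle: second moment of the standardized
# kurtosis-Gaussian family
kurt_m2_oracle <- function(beta) {
  integrate(function(z) z^2 * 2 * dnorm(z) * pnorm(beta * abs(z)),
            -Inf, Inf, rel.tol = 1e-10)$value / (1 + (2 / pi) * atan(beta))
}

# angular distance in degrees, axis-agnostic modulo 360
ang_dist <- function(a, b) {
  d <- abs((a - b) %% 360)
  min(d, 360 - d)
}
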