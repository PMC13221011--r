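#' Location-scale-shape parameters for one distribution component
#'
#' A component of a cluster model is described by a location `mu` (channel
#' arbitrary units, a.u.), a scale `sigma` (a.u., strictly positive) and one
#' shape parameter: `alpha` for the skew-Gaussian family used along the X
#' (projection) axis, or `beta` for the kurtosis-Gaussian family used along
#' the Y (principal) axis. Exactly one of `alpha`/`beta` must be given.
#'
#' @param mu location, a.u.
#' @param sigma scale, a.u.; must be strictly positive.
#' @param alpha skew shape (dimensionless, finite) of the skew-Gaussian
#'   family; mutually exclusive with `beta`.
#' @param beta tail shape (dimensionless, finite) of the kurtosis-Gaussian
#'   family; mutually exclusive with `alpha`.
#' @return An object of class `shape_params`.
#' @examples
#' shape_params(0, 1, alpha = 2)
#' shape_params(100, 400, beta = 0.4)
#' @export
shape_params <- function(mu, sigma, alpha = NULL, beta = NULL) {
  for (v in list(mu, sigma)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_arg("'mu' and 'sigma' must be finite scalars")
  }
  if (sigma <= 0) stop_arg("'sigma' must be strictly positive")
  if (is.null(alpha) == is.null(beta))
    stop_arg("exactly one of 'alpha' or 'beta' must be set")
  shape <- if (is.null(alpha)) beta else alpha
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape))
    stop_arg("the shape parameter must be a finite scalar")
  structure(
    list(mu = mu, sigma = sigma, alpha = alpha, beta = beta,
         family = if (is.null(alpha)) "kurt" else "skew"),
    class = "shape_params")
}

#' @export
print.shape_params <- function(x, ...) {
  shp <- if (x$family == "skew") sprintf("alpha = %g", x$alpha)
         else sprintf("beta = %g", x$beta)
  cat(sprintf("<shape_params: %s family, mu = %g, sigma = %g, %s>\n",
              x$family, x$mu, x$sigma, shp))
  invisible(x)
}

## ------------------------------------------------------------------
## Skew-Gaussian family (X axis):  f(x) = (2/sigma) phi(z) Phi(alpha z)
## Kurtosis-Gaussian family (Y axis):
##   f(y) = (2/sigma) phi(z) Phi(beta |z|) / C(beta),
##   C(beta) = 1 + (2/pi) arctan(beta)  (the raw form integrates to C).
## z = (value - mu)/sigma; Phi(t) = (1 + erf(t/sqrt(2)))/2 = pnorm(t).
## ------------------------------------------------------------------

#' Normalization constant of the kurtosis-Gaussian family
#'
#' The printed functional form `2 phi(z) Phi(beta |z|)` integrates (in `z`)
#' to `C(beta) = 1 + (2/pi) arctan(beta)`; dividing by `C` makes it a proper
#' density. `C(0) = 1` (Gaussian case), `C(1) = 1.5`.
#'
#' @param beta tail shape.
#' @return The constant `C(beta)`, strictly positive for all finite `beta`.
#' @export
kurt_gauss_const <- function(beta) 1 + (2 / pi) * atan(beta)

.check_num <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop_arg("non-finite ", what)
  x
}

#' Skew-Gaussian probability density
#'
#' Density of the skew-Gaussian family used to model the projection (X)
#' dimension: `(2/sigma) * phi(z) * pnorm(alpha * z)` with
#' `z = (x - mu)/sigma`. At `alpha = 0` this is the normal density
#' `N(mu, sigma^2)`; it integrates to one for every finite `alpha`.
#'
#' @param x evaluation points, a.u.
#' @param p a [shape_params()] with the `alpha` shape set (or `mu`, when the
#'   `sigma`/`alpha` arguments are supplied directly).
#' @param sigma,alpha optional direct parameterization, used when `p` is the
#'   numeric location.
#' @param log return the log density?
#' @return Density values (per a.u.), same length as `x`.
#' @examples
#' skew_gauss_pdf(0, shape_params(0, 1, alpha = 3))  # = 1/sqrt(2*pi)
#' @export
skew_gauss_pdf <- function(x, p, sigma = NULL, alpha = NULL, log = FALSE) {
  if (!inherits(p, "shape_params"))
    p <- shape_params(p, sigma, alpha = alpha)
  if (p$family != "skew") stop_arg("'p' must carry the alpha (skew) shape")
  .check_num(x, "x")
  z <- (x - p$mu) / p$sigma
  ld <- log(2 / p$sigma) + dnorm(z, log = TRUE) + pnorm(p$alpha * z, log.p = TRUE)
  if (log) ld else exp(ld)
}

#' Kurtosis-Gaussian probability density
#'
#' Density of the symmetric tail-shape family used to model the principal
#' (Y) dimension: `(2/sigma) * phi(z) * pnorm(beta * |z|) / C(beta)` with
#' `z = (y - mu)/sigma` and `C(beta) = 1 + (2/pi) arctan(beta)`. The
#' absolute value makes the family symmetric about `mu`; `beta = 0` recovers
#' `N(mu, sigma^2)`. Positive `beta` moves mass into both tails jointly,
#' negative `beta` lightens them.
#'
#' @param y evaluation points, a.u.
#' @param p a [shape_params()] with the `beta` shape set (or `mu` when
#'   `sigma`/`beta` are supplied directly).
#' @param sigma,beta optional direct parameterization.
#' @param log return the log density?
#' @return Density values (per a.u.), same length as `y`.
#' @export
kurt_gauss_pdf <- function(y, p, sigma = NULL, beta = NULL, log = FALSE) {
  if (!inherits(p, "shape_params"))
    p <- shape_params(p, sigma, beta = beta)
  if (p$family != "kurt") stop_arg("'p' must carry the beta (kurtosis) shape")
  .check_num(y, "y")
  z <- (y - p$mu) / p$sigma
  ld <- log(2 / p$sigma) + dnorm(z, log = TRUE) +
    pnorm(p$beta * abs(z), log.p = TRUE) - log(kurt_gauss_const(p$beta))
  if (log) ld else exp(ld)
}

#' Sample from the skew-Gaussian family
#'
#' Exact sampler through the additive representation of the skew-normal:
#' with `delta = alpha/sqrt(1 + alpha^2)` and independent standard normals
#' `Z0, Z1`, the draw `mu + sigma * (delta*|Z0| + sqrt(1-delta^2)*Z1)` has
#' the [skew_gauss_pdf()] density.
#'
#' @param n number of draws (>= 1).
#' @param p a [shape_params()] with `alpha` set.
#' @param seed optional integer seed; draws are reproducible given the seed
#'   and the caller's RNG state is untouched.
#' @return Numeric vector of `n` draws (a.u.).
#' @export
sample_skew <- function(n, p, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop_arg("'n' must be >= 1")
  if (!inherits(p, "shape_params") || p$family != "skew")
    stop_arg("'p' must be shape_params with alpha set")
  n <- as.integer(n)
  with_seed(seed, {
    d <- p$alpha / sqrt(1 + p$alpha^2)
    z0 <- abs(rnorm(n)); z1 <- rnorm(n)
    p$mu + p$sigma * (d * z0 + sqrt(1 - d^2) * z1)
  })
}

#' Sample from the kurtosis-Gaussian family
#'
#' Rejection sampler with the dominating envelope `2 phi(z) / C(beta)`:
#' standard-normal proposals `z` are accepted with probability
#' `pnorm(beta * |z|)`, giving an expected acceptance rate of `C(beta)/2`.
#' The realized acceptance rate is attached as attribute
#' `"acceptance_rate"`.
#'
#' @param n number of draws (>= 1).
#' @param p a [shape_params()] with `beta` set.
#' @param seed optional integer seed.
#' @return Numeric vector of `n` draws (a.u.) with attribute
#'   `acceptance_rate`.
#' @export
sample_kurt <- function(n, p, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop_arg("'n' must be >= 1")
  if (!inherits(p, "shape_params") || p$family != "kurt")
    stop_arg("'p' must be shape_params with beta set")
  n <- as.integer(n)
  with_seed(seed, {
    rate <- kurt_gauss_const(p$beta) / 2
    out <- numeric(0); proposed <- 0L; accepted <- 0L
    while (length(out) < n) {
      m <- max(64L, ceiling((n - length(out)) / max(rate, 0.01) * 1.1))
      z <- rnorm(m)
      keep <- runif(m) < pnorm(p$beta * abs(z))
      proposed <- proposed + m; accepted <- accepted + sum(keep)
      out <- c(out, z[keep])
    }
    structure(p$mu + p$sigma * out[seq_len(n)],
              acceptance_rate = accepted / proposed)
  })
}

# delta parameter of the skew-normal
.skew_delta <- function(alpha) alpha / sqrt(1 + alpha^2)

# second moment of the standardized kurtosis family (z units)
.kurt_m2 <- function(beta) {
  if (beta == 0) return(1)
  f <- function(z) z^2 * 2 * dnorm(z) * pnorm(beta * abs(z))
  integrate(f, -Inf, Inf, rel.tol = 1e-10)$value / kurt_gauss_const(beta)
}

.kurt_m4 <- function(beta) {
  if (beta == 0) return(3)
  f <- function(z) z^4 * 2 * dnorm(z) * pnorm(beta * abs(z))
  integrate(f, -Inf, Inf, rel.tol = 1e-10)$value / kurt_gauss_const(beta)
}

#' Standardized moments implied by shape parameters
#'
#' For the skew (`alpha`) family, returns the closed-form skew-normal
#' skewness and excess kurtosis; for the kurtosis (`beta`) family, skewness
#' is zero by symmetry and the excess kurtosis is computed by adaptive
#' quadrature of the normalized density.
#'
#' @param p a [shape_params()].
#' @return Named numeric vector `c(skewness, excess_kurtosis)`.
#' @examples
#' shape_moments(shape_params(0, 1, alpha = 0))   # c(0, 0)
#' shape_moments(shape_params(0, 1, alpha = 5))   # skewness ~ 0.851
#' @export
shape_moments <- function(p) {
  if (!inherits(p, "shape_params")) stop_arg("'p' must be shape_params")
  if (p$family == "skew") {
    d <- .skew_delta(p$alpha)
    g <- d * sqrt(2 / pi)
    v <- 1 - 2 * d^2 / pi
    c(skewness = (4 - pi) / 2 * g^3 / v^1.5,
      excess_kurtosis = 2 * (pi - 3) * g^4 / v^2)
  } else {
    m2 <- .kurt_m2(p$beta); m4 <- .kurt_m4(p$beta)
    c(skewness = 0, excess_kurtosis = m4 / m2^2 - 3)
  }
}

#' Convert between generator skew units and the distribution shape
#'
#' The cluster generator (and the analysis reports) express X-dimension
#' skewness in the cluster-generator argument convention; the fitted
#' distribution shape `alpha` of [skew_gauss_pdf()] relates to it by a
#' constant factor of `2*pi` (the final fitted skew values are divided by pi
#' and by 2 when reported, correcting the 2-D-to-1-D mapping of the
#' support-line generator). These two helpers are the single place the
#' constant lives.
#'
#' @param skew skew in generator/report units.
#' @param alpha distribution shape parameter.
#' @return The converted value.
#' @export
alpha_from_generator_skew <- function(skew) 2 * pi * skew

#' @rdname alpha_from_generator_skew
#' @export
generator_skew_from_alpha <- function(alpha) alpha / (2 * pi)
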