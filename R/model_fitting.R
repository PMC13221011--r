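# ---------------------------------------------------------------------
# Constrained EM fitting of per-dimension skew/kurtosis Gaussian mixtures
# ---------------------------------------------------------------------

# log density of one component family on raw parameters
.ldens <- function(v, mu, sigma, shape, family) {
  z <- (v - mu) / sigma
  if (family == "skew")
    log(2 / sigma) + dnorm(z, log = TRUE) + pnorm(shape * z, log.p = TRUE)
  else
    log(2 / sigma) + dnorm(z, log = TRUE) + pnorm(shape * abs(z), log.p = TRUE) -
      log(kurt_gauss_const(shape))
}


# log probability mass of one component inside a truncation window.
# The outlier-removal step cuts the sample at known per-dimension limits;
# fitting the unrestricted density to such data attenuates scale and
# (especially) shape estimates, so the likelihood is renormalized over
# the retained window when bounds are supplied.
.window_logmass <- function(mu, sigma, shape, family, window) {
  if (is.null(window)) return(0)
  zlo <- (window[1L] - mu) / sigma
  zhi <- (window[2L] - mu) / sigma
  f <- if (family == "skew") function(z) 2 * dnorm(z) * pnorm(shape * z)
       else function(z) 2 * dnorm(z) * pnorm(shape * abs(z)) /
         kurt_gauss_const(shape)
  p <- tryCatch(integrate(f, zlo, zhi, rel.tol = 1e-8)$value,
                error = function(e) NA_real_)
  if (!is.finite(p) || p <= 1e-12) return(Inf)  # degenerate placement
  log(min(p, 1))
}

# invert the closed-form skew-normal skewness for the shape alpha;
# |g1| is clamped below the family's attainable supremum (~0.995).
.alpha_from_skewness <- function(g1) {
  if (!is.finite(g1)) return(0)
  k <- (4 - pi) / 2
  b <- sqrt(2 / pi)
  g1 <- max(min(g1, 0.99), -0.99)
  R <- sign(g1) * (abs(g1) / k)^(1 / 3)
  d <- R / sqrt(b^2 + 2 * R^2 / pi)
  d <- max(min(d, 0.995), -0.995)
  d / sqrt(1 - d^2)
}

# invert the kurtosis-family excess kurtosis for beta on the monotone
# branch [-3, 1.2] (outside it the map folds back and the ends are used).
.beta_from_exkurt <- function(ek) {
  if (!is.finite(ek)) return(0)
  if (ek >= 0 && ek <= 1e-8) return(0)
  lo <- -3; hi <- 1.2
  ex <- function(b) .kurt_m4(b) / .kurt_m2(b)^2 - 3
  if (ek >= ex(lo)) return(lo)   # ex() is decreasing on [lo, hi]
  if (ek <= ex(hi)) return(hi)
  stats::uniroot(function(b) ex(b) - ek, c(lo, hi), tol = 1e-4)$root
}


# central moments of a standardized family truncated to a z-window
.trunc_moments <- function(shape, family, zwin, upto = 3L) {
  f0 <- if (family == "skew") function(z) 2 * dnorm(z) * pnorm(shape * z)
        else function(z) 2 * dnorm(z) * pnorm(shape * abs(z))
  ig <- function(g) integrate(g, zwin[1L], zwin[2L], rel.tol = 1e-9)$value
  nrm <- ig(f0)
  m1 <- ig(function(z) z * f0(z)) / nrm
  m2 <- ig(function(z) (z - m1)^2 * f0(z)) / nrm
  out <- c(m1 = m1, m2 = m2)
  if (upto >= 3L) out["m3"] <- ig(function(z) (z - m1)^3 * f0(z)) / nrm
  if (upto >= 4L) out["m4"] <- ig(function(z) (z - m1)^4 * f0(z)) / nrm
  out
}

# moment-matched initial (mu, sigma, shape) under a known truncation
# window: inverts the *truncated* family's standardized skewness /
# excess kurtosis, so the initialization is unbiased for trimmed data.
.init_trunc <- function(mb, sb, g_obs, family, window) {
  zwin <- (window - mb) / sb
  if (family == "skew") {
    gfun <- function(a) {
      m <- .trunc_moments(a, "skew", zwin, 3L)
      m[["m3"]] / m[["m2"]]^1.5
    }
    lo <- -8; hi <- 8
    g_obs <- max(min(g_obs, gfun(hi) - 1e-6), gfun(lo) + 1e-6)
    shape <- tryCatch(stats::uniroot(function(a) gfun(a) - g_obs,
                                     c(lo, hi), tol = 1e-3)$root,
                      error = function(e) .alpha_from_skewness(g_obs))
    m <- .trunc_moments(shape, "skew", zwin, 2L)
  } else {
    gfun <- function(b) {
      m <- .trunc_moments(b, "kurt", zwin, 4L)
      m[["m4"]] / m[["m2"]]^2 - 3
    }
    lo <- -3; hi <- 1.2
    g_obs <- max(min(g_obs, gfun(lo) - 1e-6), gfun(hi) + 1e-6)  # decreasing
    shape <- tryCatch(stats::uniroot(function(b) gfun(b) - g_obs,
                                     c(lo, hi), tol = 1e-3)$root,
                      error = function(e) .beta_from_exkurt(g_obs))
    m <- .trunc_moments(shape, "kurt", zwin, 2L)
  }
  sigma <- sb / sqrt(m[["m2"]])
  mu <- mb - sigma * m[["m1"]]
  c(mu = mu, sigma = sigma, shape = shape)
}

# weighted maximum likelihood polish for one component of one dimension.
# A finite mu_box constrains the location to start[1] +/- mu_box *inside*
# the optimization (tanh reparameterization), so scale and shape always
# adapt to the constrained location — clipping the location afterwards
# would leave the component parameters mutually inconsistent.
.wmle <- function(v, w, family, start, sigma_floor = 1e-12, mu_box = Inf,
                  maxit = 80L, window = NULL, profile = FALSE) {
  sw <- sum(w)
  mu0 <- start[1L]
  mu_of <- if (is.finite(mu_box)) function(p1) mu0 + mu_box * tanh(p1)
           else function(p1) p1
  p1_0 <- if (is.finite(mu_box)) 0 else mu0
  neg <- function(p) {
    if (abs(p[3L]) > 30 || p[2L] > 700) return(1e12)
    s <- max(exp(p[2L]), sigma_floor)
    mu <- mu_of(p[1L])
    val <- -sum(w * .ldens(v, mu, s, p[3L], family)) +
      sw * .window_logmass(mu, s, p[3L], family, window)
    if (!is.finite(val)) 1e12 else val
  }
  par0 <- c(p1_0, log(max(start[2L], sigma_floor)), start[3L])
  if (profile) {
    # the skew likelihood is multimodal with a symmetric saddle: scan a
    # coarse shape grid (location/scale re-optimized per shape) and keep
    # the best basin before the local polish
    best <- list(value = neg(par0), par = par0)
    for (a in c(-4, -2, -1, -0.6, -0.3, 0, 0.3, 0.6, 1, 2, 4)) {
      o <- optim(par0[1:2], function(p) neg(c(p, a)), method = "Nelder-Mead",
                 control = list(maxit = 80L, reltol = 1e-8))
      if (o$value < best$value) best <- list(value = o$value, par = c(o$par, a))
    }
    par0 <- best$par
    maxit <- 300L
  }
  o <- optim(par0, neg, method = "Nelder-Mead",
             control = list(maxit = maxit, reltol = 1e-8))
  list(mu = mu_of(o$par[1L]), sigma = max(exp(o$par[2L]), sigma_floor),
       shape = max(min(o$par[3L], 30), -30), value = -o$value)
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

.comp_df <- function(weight, mu, sigma, shape)
  data.frame(weight = weight, mu = mu, sigma = sigma, shape = shape)

# loglik of a 1-D mixture at given component table
.mix_loglik <- function(v, comps, family, window = NULL) {
  ld <- vapply(seq_len(nrow(comps)), function(c)
    log(comps$weight[c]) + .ldens(v, comps$mu[c], comps$sigma[c],
                                  comps$shape[c], family) -
      .window_logmass(comps$mu[c], comps$sigma[c], comps$shape[c],
                      family, window),
    numeric(length(v)))
  sum(.logsumexp_rows(matrix(ld, nrow = length(v))))
}

#' Histogram-based initial component parameters
#'
#' Divides the data range into `m` equal-width bins (one per requested
#' component) and derives each component's initial values from its bin:
#' the bin point fraction becomes the weight, and the bin's sample mean,
#' SD, and standardized third (X axis) or fourth (Y axis) moment are
#' converted to moment-matched location, scale and shape starting values
#' (sample skewness inverted through the closed-form skew-normal skewness;
#' sample excess kurtosis inverted through the kurtosis family's
#' quadrature moments). An empty bin reduces the effective component count
#' with a warning rather than aborting the fit.
#'
#' @param values numeric vector (one dimension of one cluster).
#' @param m requested number of components (>= 1).
#' @param family `"skew"` (X axis) or `"kurt"` (Y axis); controls which
#'   moment the shape initialization uses.
#' @param window optional known truncation range of the data (from
#'   [remove_outliers()]); when given, the initial values invert the
#'   truncated family's moments instead of the unrestricted ones.
#' @return A data frame with columns `weight`, `mu`, `sigma`, `shape`
#'   (one row per retained component; weights sum to 1).
#' @export
init_from_histogram <- function(values, m, family = c("skew", "kurt"),
                                window = NULL) {
  family <- match.arg(family)
  if (!is.numeric(values) || length(values) < 2L)
    stop_arg("'values' must be a numeric vector with >= 2 points")
  m <- as.integer(m)
  if (m < 1L) stop_arg("'m' must be >= 1")
  rng <- range(values)
  if (rng[1L] == rng[2L]) stop_arg("degenerate data: zero range")
  breaks <- seq(rng[1L], rng[2L], length.out = m + 1L)
  idx <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L), m)
  rows <- list()
  for (b in seq_len(m)) {
    pts <- values[idx == b]
    if (length(pts) == 0L) {
      warning("empty histogram bin: reducing component count", call. = FALSE)
      next
    }
    mb <- mean(pts)
    sb <- if (length(pts) >= 2L && sd(pts) > 0) sd(pts)
          else (breaks[b + 1L] - breaks[b]) / 6
    z <- (pts - mb) / sb
    g_obs <- if (length(pts) < 8L) 0
             else if (family == "skew") mean(z^3) else mean(z^4) - 3
    if (!is.null(window) && length(pts) >= 8L) {
      ini <- .init_trunc(mb, sb, g_obs, family, window)
      mu <- ini[["mu"]]; sigma <- ini[["sigma"]]; shape <- ini[["shape"]]
    } else if (family == "skew") {
      shape <- .alpha_from_skewness(g_obs)
      d <- .skew_delta(shape)
      sigma <- sb / sqrt(1 - 2 * d^2 / pi)
      mu <- mb - sigma * d * sqrt(2 / pi)
    } else {
      shape <- .beta_from_exkurt(g_obs)
      sigma <- sb / sqrt(.kurt_m2(shape))
      mu <- mb
    }
    rows[[length(rows) + 1L]] <- .comp_df(length(pts) / length(values),
                                          mu, sigma, shape)
  }
  out <- do.call(rbind, rows)
  out$weight <- out$weight / sum(out$weight)
  out
}

# EM for one dimension (independent weights); m = nrow(init)
.em_1d <- function(v, init, family, cfg, mu_cap, window = NULL) {
  comps <- init
  m <- nrow(comps)
  converged <- FALSE; iter <- 0L
  floor_s <- 1e-4 * sd(v)
  prev_ll <- -Inf
  while (iter < cfg$max_iterations) {
    iter <- iter + 1L
    ld <- vapply(seq_len(m), function(c)
      log(comps$weight[c]) + .ldens(v, comps$mu[c], comps$sigma[c],
                                    comps$shape[c], family) -
        .window_logmass(comps$mu[c], comps$sigma[c], comps$shape[c],
                        family, window),
      numeric(length(v)))
    ld <- matrix(ld, nrow = length(v))
    lse <- .logsumexp_rows(ld)
    if (any(!is.finite(lse)))
      stop_arg("non-finite likelihood in EM (iteration ", iter, ")")
    ll <- sum(lse)
    if (iter > 2L && abs(ll - prev_ll) < 1e-5 * length(v)) {
      converged <- TRUE; break   # likelihood stalled: parameters stable
    }
    prev_ll <- ll
    r <- exp(ld - lse)
    new <- comps
    new$weight <- pmax(colMeans(r), 1e-8)
    new$weight <- new$weight / sum(new$weight)
    for (c in seq_len(m)) {
      f <- .wmle(v, r[, c], family,
                 c(comps$mu[c], comps$sigma[c], comps$shape[c]),
                 sigma_floor = floor_s,
                 mu_box = if (iter == 1L) Inf else mu_cap * comps$sigma[c],
                 window = window, profile = (iter == 1L))
      new$mu[c] <- f$mu
      new$sigma[c] <- f$sigma; new$shape[c] <- f$shape
    }
    delta <- max(abs(new$mu - comps$mu) / comps$sigma,
                 abs(new$sigma - comps$sigma) / comps$sigma,
                 abs(new$shape - comps$shape))
    comps <- new
    if (delta < cfg$tolerance) { converged <- TRUE; break }
  }
  list(components = comps, loglik = .mix_loglik(v, comps, family, window),
       converged = converged, iterations = iter)
}

# joint EM: shared weights, responsibilities from the product of the
# per-dimension component densities (m_x == m_y == m)
.em_joint <- function(x, y, init_x, init_y, cfg, mu_cap,
                      window_x = NULL, window_y = NULL) {
  cx <- init_x; cy <- init_y
  m <- nrow(cx)
  w <- (cx$weight + cy$weight) / 2
  w <- w / sum(w)
  converged <- FALSE; iter <- 0L
  fx <- 1e-4 * sd(x); fy <- 1e-4 * sd(y)
  loglik <- NA_real_
  while (iter < cfg$max_iterations) {
    iter <- iter + 1L
    ld <- vapply(seq_len(m), function(c)
      log(w[c]) + .ldens(x, cx$mu[c], cx$sigma[c], cx$shape[c], "skew") -
        .window_logmass(cx$mu[c], cx$sigma[c], cx$shape[c], "skew", window_x) +
        .ldens(y, cy$mu[c], cy$sigma[c], cy$shape[c], "kurt") -
        .window_logmass(cy$mu[c], cy$sigma[c], cy$shape[c], "kurt", window_y),
      numeric(length(x)))
    ld <- matrix(ld, nrow = length(x))
    lse <- .logsumexp_rows(ld)
    if (any(!is.finite(lse)))
      stop_arg("non-finite likelihood in EM (iteration ", iter, ")")
    prev_ll <- loglik
    loglik <- sum(lse)
    if (iter > 2L && is.finite(prev_ll) &&
        abs(loglik - prev_ll) < 1e-5 * length(x)) {
      converged <- TRUE; break   # likelihood stalled: parameters stable
    }
    r <- exp(ld - lse)
    wn <- pmax(colMeans(r), 1e-8); wn <- wn / sum(wn)
    nx <- cx; ny <- cy
    for (c in seq_len(m)) {
      f1 <- .wmle(x, r[, c], "skew", c(cx$mu[c], cx$sigma[c], cx$shape[c]),
                  sigma_floor = fx,
                  mu_box = if (iter == 1L) Inf else mu_cap * cx$sigma[c],
                  window = window_x, profile = (iter == 1L))
      f2 <- .wmle(y, r[, c], "kurt", c(cy$mu[c], cy$sigma[c], cy$shape[c]),
                  sigma_floor = fy,
                  mu_box = if (iter == 1L) Inf else mu_cap * cy$sigma[c],
                  window = window_y, profile = (iter == 1L))
      nx$mu[c] <- f1$mu; ny$mu[c] <- f2$mu
      nx$sigma[c] <- f1$sigma; nx$shape[c] <- f1$shape
      ny$sigma[c] <- f2$sigma; ny$shape[c] <- f2$shape
    }
    delta <- max(abs(nx$mu - cx$mu) / cx$sigma, abs(ny$mu - cy$mu) / cy$sigma,
                 abs(nx$sigma - cx$sigma) / cx$sigma,
                 abs(ny$sigma - cy$sigma) / cy$sigma,
                 abs(nx$shape - cx$shape), abs(ny$shape - cy$shape),
                 abs(wn - w))
    cx <- nx; cy <- ny; w <- wn
    cx$weight <- w; cy$weight <- w
    if (delta < cfg$tolerance) { converged <- TRUE; break }
  }
  list(cx = cx, cy = cy, loglik = loglik,
       converged = converged, iterations = iter)
}

#' Bayesian information criterion
#'
#' `BIC = k * ln(n) - 2 * loglik`; lower is better. The per-dimension
#' parameter count of an `m`-component model is `3m + (m - 1)` (location,
#' scale and shape per component plus the free mixture weights).
#'
#' @param loglik log-likelihood in nats.
#' @param k_params number of free parameters.
#' @param n number of observations (>= 1).
#' @return The BIC value (dimensionless).
#' @export
bic_score <- function(loglik, k_params, n) {
  if (n < 1) stop_arg("'n' must be >= 1")
  k_params * log(n) - 2 * loglik
}

.dim_k <- function(m) 3L * m + (m - 1L)

#' Fit the constrained EM mixture model to one cluster
#'
#' Fits `m_x` skew-Gaussian components to the X (projection) dimension and
#' `m_y` kurtosis-Gaussian components to the Y (principal) dimension of an
#' aligned, outlier-cleaned cluster. When `m_x == m_y` the dimensions are
#' fitted jointly: each component has a single shared weight and the
#' responsibilities use the product of its X and Y densities, so
#' skew-induced cross-axis structure is absorbed coherently. Otherwise the
#' dimensions are fitted as independent 1-D mixtures. Starting values come
#' from the moment-matched histogram initialization
#' ([init_from_histogram()]); each M-step performs a weighted
#' maximum-likelihood update of every component with the location step
#' constrained to `mu_cap` times the component's current scale per
#' iteration — enforced inside the optimization, so scale and shape stay
#' consistent with the constrained location. Iteration stops when every
#' scaled parameter change falls below `cfg$tolerance`, or at
#' `cfg$max_iterations` (flagged non-converged).
#'
#' Note that for weak shapes the skew likelihood is extremely flat (the
#' symmetric model is a stationary point), so the fitted shape is a
#' moment-anchored local maximum-likelihood estimate; this is what makes
#' the recovered skew stable across replicate generations.
#'
#' @param x,y numeric vectors of equal length (aligned cluster
#'   coordinates).
#' @param m_x,m_y component counts per dimension.
#' @param cfg a [rosetta_config()].
#' @param init_x,init_y optional initial component tables (defaults come
#'   from [init_from_histogram()]).
#' @param mu_cap per-iteration location step limit as a fraction of the
#'   component scale (default 0.05, i.e. the 5 percent step-size rule;
#'   `Inf` disables the cap).
#' @param bounds optional per-dimension truncation window (list with `x`
#'   and `y` ranges, as recorded by [remove_outliers()]); when supplied,
#'   every component density is renormalized over its window so the fit
#'   compensates for the outlier trimming instead of absorbing it into
#'   attenuated scale and shape estimates.
#' @return An object of class `cluster_model`: per-dimension models
#'   (components, log-likelihood, BIC), the full-model BIC, and convergence
#'   diagnostics.
#' @export
em_fit <- function(x, y, m_x, m_y, cfg = rosetta_config(),
                   init_x = NULL, init_y = NULL, mu_cap = 0.05,
                   bounds = NULL) {
  if (length(x) != length(y)) stop_arg("'x' and 'y' must have the same length")
  n <- length(x)
  if (n < 10L * (m_x + m_y))
    stop_arg("need at least 10*(m_x + m_y) points to fit (", n, " given)")
  if (is.null(init_x)) init_x <- init_from_histogram(x, m_x, "skew", bounds$x)
  if (is.null(init_y)) init_y <- init_from_histogram(y, m_y, "kurt", bounds$y)
  m_x <- nrow(init_x); m_y <- nrow(init_y)  # may have been reduced
  wx <- bounds$x; wy <- bounds$y
  if (m_x == m_y) {
    fit <- .em_joint(x, y, init_x, init_y, cfg, mu_cap, wx, wy)
    cx <- fit$cx; cy <- fit$cy
    llx <- .mix_loglik(x, cx, "skew", wx); lly <- .mix_loglik(y, cy, "kurt", wy)
    joint_ll <- fit$loglik
    converged <- fit$converged; iters <- fit$iterations
  } else {
    fx <- .em_1d(x, init_x, "skew", cfg, mu_cap, wx)
    fy <- .em_1d(y, init_y, "kurt", cfg, mu_cap, wy)
    cx <- fx$components; cy <- fy$components
    llx <- fx$loglik; lly <- fy$loglik
    joint_ll <- llx + lly
    converged <- fx$converged && fy$converged
    iters <- max(fx$iterations, fy$iterations)
  }
  structure(list(
    n_events = n, m_x = m_x, m_y = m_y,
    x_model = list(axis = "X", components = cx, loglik = llx,
                   bic = bic_score(llx, .dim_k(m_x), n)),
    y_model = list(axis = "Y", components = cy, loglik = lly,
                   bic = bic_score(lly, .dim_k(m_y), n)),
    loglik = joint_ll,
    full_bic = bic_score(joint_ll, .dim_k(m_x) + .dim_k(m_y), n),
    converged = converged, iterations = iters,
    joint = (m_x == m_y)), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model: n = %d, %d x / %d y components, full BIC = %.1f%s>\n",
              x$n_events, x$m_x, x$m_y, x$full_bic,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Sweep component configurations and select by BIC
#'
#' Fits every `(m_x, m_y)` pair in the configured per-dimension ranges and
#' returns the model with the lowest full-model BIC; ties are broken toward
#' fewer total components.
#'
#' @param x,y aligned cluster coordinates.
#' @param cfg a [rosetta_config()] (component ranges, EM controls).
#' @param init_fn initializer, called as `init_fn(values, m, family, window)`.
#' @param bounds optional truncation window, see [em_fit()].
#' @return The selected `cluster_model`, with attribute `candidates` — a
#'   data frame of every configuration's full BIC.
#' @export
select_model <- function(x, y, cfg = rosetta_config(),
                         init_fn = init_from_histogram, bounds = NULL) {
  rx <- seq(cfg$min_components_per_cluster[1L], cfg$max_components_per_cluster[1L])
  ry <- seq(cfg$min_components_per_cluster[2L], cfg$max_components_per_cluster[2L])
  fits <- list(); cand <- list(); errs <- character()
  for (mx in rx) for (my in ry) {
    f <- tryCatch(
      em_fit(x, y, mx, my, cfg,
             init_x = init_fn(x, mx, "skew", bounds$x),
             init_y = init_fn(y, my, "kurt", bounds$y),
             bounds = bounds),
      error = function(e) e)
    if (inherits(f, "error")) {
      errs <- c(errs, sprintf("(%d,%d): %s", mx, my, conditionMessage(f)))
      next
    }
    fits[[length(fits) + 1L]] <- f
    cand[[length(cand) + 1L]] <- data.frame(m_x = f$m_x, m_y = f$m_y,
                                            full_bic = f$full_bic)
  }
  if (length(fits) == 0L)
    stop_arg("all component configurations failed to fit:\n  ",
             paste(errs, collapse = "\n  "))
  cand <- do.call(rbind, cand)
  best_bic <- min(cand$full_bic)
  ok <- which(cand$full_bic <= best_bic + 1e-9)
  ok <- ok[order(cand$m_x[ok] + cand$m_y[ok], cand$m_x[ok])][1L]
  structure(fits[[ok]], candidates = cand, failures = errs,
            class = class(fits[[ok]]))
}
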