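# Joint dependence of (IR, LCR): 2D kernel density, Weibull and skew-Laplace
# marginals, and the Farlie-Gumbel-Morgenstern (FGM) copula.
#
# FGM is a weak-dependence family: C(u,v) = uv[1 + theta(1-u)(1-v)],
# |theta| <= 1, with Spearman correlation rho_S = theta / 3 (so
# |rho_S| <= 1/3). That weakness is exactly what is expected of the IR-LCR
# association: most regions sit near |IR| ~ 0 with small LCR.

#' Two-dimensional kernel density of (IR, LCR)
#'
#' Gaussian product-kernel density on a regular grid, with per-axis
#' normal-reference (Silverman-type) bandwidths by default. The returned
#' grid density integrates to 1 (trapezoid quadrature) up to boundary
#' truncation.
#'
#' @param ir_values,lcr_values paired observations (n >= 10).
#' @param n_grid grid points per axis; default 64.
#' @param bandwidth optional length-2 numeric of per-axis bandwidths.
#' @param expand fractional margin added around the data range; default 0.35.
#' @return list(x, y, z) with z an `n_grid` x `n_grid` density matrix,
#'   plus attribute `integral`.
#' @export
kde2d_density <- function(ir_values, lcr_values, n_grid = 64,
                          bandwidth = NULL, expand = 0.35) {
  if (length(ir_values) != length(lcr_values)) stop("mismatched lengths")
  if (length(ir_values) < 10) stop("need at least 10 paired observations")
  if (is.null(bandwidth)) {
    bandwidth <- c(MASS::bandwidth.nrd(ir_values), MASS::bandwidth.nrd(lcr_values))
    bandwidth[bandwidth <= 0] <- 1e-6
  }
  rx <- range(ir_values); ry <- range(lcr_values)
  pad <- c(diff(rx), diff(ry)) * expand + bandwidth
  lims <- c(rx[1] - pad[1], rx[2] + pad[1], ry[1] - pad[2], ry[2] + pad[2])
  kd <- MASS::kde2d(ir_values, lcr_values, h = bandwidth, n = n_grid, lims = lims)
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  w <- function(k) c(0.5, rep(1, k - 2), 0.5) # trapezoid weights
  integral <- sum(outer(w(n_grid), w(n_grid)) * kd$z) * dx * dy
  structure(kd, integral = integral, bandwidth = bandwidth)
}

#' Skew-Laplace (asymmetric Laplace) distribution
#'
#' Density
#' \deqn{f(x) = \frac{\alpha\beta}{\alpha+\beta} e^{\alpha (x-\mu)}, x < \mu;
#'   \quad \frac{\alpha\beta}{\alpha+\beta} e^{-\beta (x-\mu)}, x \ge \mu}
#' with location mu, left rate alpha > 0 and right rate beta > 0. The
#' symmetric Laplace is alpha = beta.
#'
#' @param x,q,p,n usual distribution-function arguments.
#' @param mu location (mode).
#' @param alpha left exponential rate (> 0).
#' @param beta right exponential rate (> 0).
#' @return density, probability, quantile or random draws respectively.
#' @name skew_laplace
NULL

#' @rdname skew_laplace
#' @export
dskewlap <- function(x, mu = 0, alpha = 1, beta = 1) {
  if (alpha <= 0 || beta <= 0) stop("rates must be positive")
  k <- alpha * beta / (alpha + beta)
  ifelse(x < mu, k * exp(alpha * (x - mu)), k * exp(-beta * (x - mu)))
}

#' @rdname skew_laplace
#' @export
pskewlap <- function(q, mu = 0, alpha = 1, beta = 1) {
  if (alpha <= 0 || beta <= 0) stop("rates must be positive")
  ifelse(q < mu,
         beta / (alpha + beta) * exp(alpha * (q - mu)),
         1 - alpha / (alpha + beta) * exp(-beta * (q - mu)))
}

#' @rdname skew_laplace
#' @export
qskewlap <- function(p, mu = 0, alpha = 1, beta = 1) {
  if (alpha <= 0 || beta <= 0) stop("rates must be positive")
  if (any(p < 0 | p > 1)) stop("p outside [0, 1]")
  p0 <- beta / (alpha + beta) # CDF at the mode
  ifelse(p <= p0,
         mu + log(p / p0) / alpha,
         mu - log((1 - p) * (alpha + beta) / alpha) / beta)
}

#' @rdname skew_laplace
#' @export
rskewlap <- function(n, mu = 0, alpha = 1, beta = 1) {
  qskewlap(runif(n), mu, alpha, beta)
}

#' Fit a Weibull marginal by maximum likelihood
#'
#' @param lcr_values strictly positive observations.
#' @return list(shape, scale) of class `weibull_fit`.
#' @export
fit_weibull <- function(lcr_values) {
  if (any(lcr_values <= 0)) stop("Weibull data must be strictly positive")
  # fitdistr explores invalid corners en route; those NaN warnings are noise
  fd <- suppressWarnings(MASS::fitdistr(lcr_values, "weibull"))
  structure(list(shape = unname(fd$estimate["shape"]),
                 scale = unname(fd$estimate["scale"])),
            class = "weibull_fit")
}

#' Fit a skew-Laplace marginal by maximum likelihood
#'
#' Numerical maximization of the asymmetric-Laplace log-likelihood over
#' (mu, log alpha, log beta), multi-started from the quartiles of the data
#' (the profile likelihood in mu is piecewise smooth with its optimum at a
#' data point).
#'
#' @param ir_values observations.
#' @return list(mu, alpha, beta) of class `skewlap_fit`.
#' @export
fit_skew_laplace <- function(ir_values) {
  x <- ir_values[is.finite(ir_values)]
  if (length(x) < 5) stop("need at least 5 finite observations")
  nll <- function(par) {
    mu <- par[1]; a <- exp(par[2]); b <- exp(par[3])
    s1 <- sum(pmax(mu - x, 0)); s2 <- sum(pmax(x - mu, 0))
    -(length(x) * log(a * b / (a + b)) - a * s1 - b * s2)
  }
  sc <- sd(x); if (sc == 0) stop("degenerate (constant) input")
  starts <- lapply(quantile(x, c(0.25, 0.5, 0.75)),
                   function(m) c(m, log(1 / sc), log(1 / sc)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(optim(s, nll, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("skew-Laplace fit failed")
  structure(list(mu = best$par[1], alpha = exp(best$par[2]),
                 beta = exp(best$par[3])),
            class = "skewlap_fit")
}

#' FGM copula density
#'
#' \deqn{c(u, v) = 1 + \theta (1 - 2u)(1 - 2v)} on the unit square;
#' theta = 0 is independence, and c is non-negative for all |theta| <= 1.
#'
#' @param u,v values in \[0, 1\].
#' @param theta dependence parameter in \[-1, 1\].
#' @return copula density values.
#' @export
fgm_density <- function(u, v, theta) {
  if (abs(theta) > 1) stop("|theta| must be <= 1")
  if (any(u < 0 | u > 1) || any(v < 0 | v > 1)) stop("u, v must lie in [0, 1]")
  1 + theta * (1 - 2 * u) * (1 - 2 * v)
}

#' FGM copula CDF
#' @inheritParams fgm_density
#' @export
fgm_cdf <- function(u, v, theta) {
  if (abs(theta) > 1) stop("|theta| must be <= 1")
  u * v * (1 + theta * (1 - u) * (1 - v))
}

#' Sample from the FGM copula by conditional inversion
#'
#' @param n number of pairs.
#' @param theta dependence parameter in \[-1, 1\].
#' @return n x 2 matrix of (u, v) pairs.
#' @export
rfgm <- function(n, theta) {
  if (abs(theta) > 1) stop("|theta| must be <= 1")
  u <- runif(n)
  w <- runif(n)
  a <- theta * (1 - 2 * u)
  v <- ifelse(abs(a) < 1e-12, w,
              ((1 + a) - sqrt((1 + a)^2 - 4 * a * w)) / (2 * a))
  cbind(u = u, v = pmin(pmax(v, 0), 1))
}

#' Estimate the FGM dependence parameter
#'
#' Default: Spearman inversion via the FGM identity
#' \eqn{\rho_S = \theta / 3}, i.e. \eqn{\hat\theta = 3 \rho_S}, clipped to
#' \[-1, 1\] with a warning (closed-form and robust to marginal misfit).
#' Alternative: maximum likelihood on rank pseudo-observations.
#'
#' @param ir_values,lcr_values paired observations.
#' @param method "spearman" (default) or "mle".
#' @return theta estimate in \[-1, 1\].
#' @export
fit_fgm_theta <- function(ir_values, lcr_values,
                          method = c("spearman", "mle")) {
  method <- match.arg(method)
  if (length(ir_values) != length(lcr_values)) stop("mismatched lengths")
  if (method == "spearman") {
    theta <- 3 * cor(ir_values, lcr_values, method = "spearman")
  } else {
    n <- length(ir_values)
    u <- rank(ir_values) / (n + 1)
    v <- rank(lcr_values) / (n + 1)
    nll <- function(th) -sum(log(pmax(fgm_density(u, v, th), 1e-12)))
    theta <- stats::optimize(nll, c(-1, 1))$minimum
  }
  if (abs(theta) > 1) {
    warning("theta estimate ", signif(theta, 4), " clipped to [-1, 1]")
    theta <- sign(theta)
  }
  theta
}

#' Fit the full (IR, LCR) copula model
#'
#' Fits the Weibull marginal to LCR, the skew-Laplace marginal to IR, and
#' the FGM dependence parameter, yielding the joint model of Sklar's
#' theorem.
#'
#' @inheritParams fit_fgm_theta
#' @param theta_method passed to [fit_fgm_theta()].
#' @return object of class `copula_model`: list(theta, weibull, skew_laplace).
#' @export
fit_copula_model <- function(ir_values, lcr_values,
                             theta_method = "spearman") {
  structure(list(
    theta = fit_fgm_theta(ir_values, lcr_values, theta_method),
    weibull = fit_weibull(lcr_values),
    skew_laplace = fit_skew_laplace(ir_values)
  ), class = "copula_model")
}

#' @export
print.copula_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<copula_model> FGM theta = %.4f\n",
    "  LCR ~ Weibull(shape = %.4g, scale = %.4g)\n",
    "  IR  ~ SkewLaplace(mu = %.4g, alpha = %.4g, beta = %.4g)\n"),
    x$theta, x$weibull$shape, x$weibull$scale,
    x$skew_laplace$mu, x$skew_laplace$alpha, x$skew_laplace$beta))
  invisible(x)
}

#' Joint density of (IR, LCR) under a fitted copula model
#'
#' Sklar construction:
#' \eqn{f(ir, lcr) = c(F_{IR}(ir), F_{LCR}(lcr)) f_{IR}(ir) f_{LCR}(lcr)}.
#'
#' @param ir,lcr evaluation points (recycled to a common length).
#' @param model a [fit_copula_model()] result.
#' @return joint density values.
#' @export
joint_density <- function(ir, lcr, model) {
  stopifnot(inherits(model, "copula_model"))
  sl <- model$skew_laplace; wb <- model$weibull
  u <- pskewlap(ir, sl$mu, sl$alpha, sl$beta)
  v <- pweibull(lcr, wb$shape, wb$scale)
  fgm_density(u, v, model$theta) *
    dskewlap(ir, sl$mu, sl$alpha, sl$beta) *
    dweibull(lcr, wb$shape, wb$scale)
}

#' Write copula model parameters as key-value text
#' @param model a `copula_model`.
#' @param path output path.
#' @export
write_copula_model <- function(model, path) {
  stopifnot(inherits(model, "copula_model"))
  writeLines(c(
    sprintf("theta\t%.12g", model$theta),
    sprintf("weibull_shape\t%.12g", model$weibull$shape),
    sprintf("weibull_scale\t%.12g", model$weibull$scale),
    sprintf("skewlap_mu\t%.12g", model$skew_laplace$mu),
    sprintf("skewlap_alpha\t%.12g", model$skew_laplace$alpha),
    sprintf("skewlap_beta\t%.12g", model$skew_laplace$beta)
  ), path)
  invisible(path)
}

#' Write a gridded density as TSV (long format: x, y, density)
#' @param kd a [kde2d_density()] result (list with x, y, z).
#' @param path output path.
#' @export
write_density_grid <- function(kd, path) {
  df <- expand.grid(x = kd$x, y = kd$y)
  df$density <- as.vector(kd$z)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
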