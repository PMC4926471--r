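# Boltzmann model of SNP fixation uncertainty.
#
# The probability that a SNP is fixed at a site grows with the log2
# normalized supporting-read count LC:
#   p = P(LC <= lc) = 1 - lambda * exp(-beta * lc),   lc > 0
# so q = lambda * exp(-beta * lc) (the Boltzmann factor) is the probability
# of NOT observing the SNP, and p + q = 1. lambda plays the role of the
# partition function, beta an inverse-temperature-like rate per bit.
# For lambda < 1 the law puts mass 1 - lambda at LC = 0 (sites with no SNP
# evidence); the continuous part lives on lc > 0.

#' Boltzmann CDF of SNP fixation
#'
#' \eqn{p = 1 - \lambda e^{-\beta \, lc}}, clipped to \[0, 1\]; the number of
#' clipped evaluations is reported in the `"n_clipped"` attribute.
#'
#' @param lc positive log2 normalized read count(s), bits.
#' @param lambda_ partition-function parameter, > 0.
#' @param beta rate parameter per bit, > 0.
#' @return probabilities in \[0, 1\].
#' @examples
#' boltzmann_cdf(1, lambda_ = 1, beta = log(2)) # 0.5
#' @export
boltzmann_cdf <- function(lc, lambda_, beta) {
  if (lambda_ <= 0 || beta <= 0) stop("lambda_ and beta must be positive")
  if (any(lc <= 0)) stop("lc must be positive (model support is lc > 0)")
  p <- 1 - lambda_ * exp(-beta * lc)
  n_clip <- sum(p < 0 | p > 1)
  p <- pmin(pmax(p, 0), 1)
  attr(p, "n_clipped") <- n_clip
  p
}

#' SNP uncertainty from fixation probability
#'
#' Inverse of [boltzmann_cdf()]:
#' \eqn{lc = -\frac{1}{\beta}\log\frac{1-p}{\lambda}} -- the uncertainty of
#' not observing a SNP at a site whose fixation probability is p.
#'
#' @param p fixation probability/ies; p = 1 maps to `Inf` with a warning.
#' @inheritParams boltzmann_cdf
#' @return lc values (bits).
#' @export
lc_from_p <- function(p, lambda_, beta) {
  if (lambda_ <= 0 || beta <= 0) stop("lambda_ and beta must be positive")
  if (any(p < 0 | p > 1)) stop("p outside [0, 1]")
  ratio <- (1 - p) / lambda_
  if (any(ratio > 1 + 1e-12)) {
    stop("(1 - p)/lambda must lie in (0, 1]: p below the model's floor 1 - lambda")
  }
  if (any(p == 1)) warning("p = 1 maps to infinite uncertainty (overflow)")
  -log(pmin(ratio, 1)) / beta
}

#' Sample from the Boltzmann SNP-uncertainty law
#'
#' Draws include the atom at 0 carried by lambda < 1 (probability
#' 1 - lambda of no SNP evidence); positive draws follow the continuous
#' part of the law.
#'
#' @param n number of draws.
#' @inheritParams boltzmann_cdf
#' @return numeric vector of lc values >= 0.
#' @export
rboltzmann <- function(n, lambda_, beta) {
  if (lambda_ <= 0 || lambda_ > 1 || beta <= 0) {
    stop("need 0 < lambda_ <= 1 and beta > 0 to sample")
  }
  u <- runif(n)
  lc <- numeric(n)
  pos <- u > 1 - lambda_
  lc[pos] <- -log((1 - u[pos]) / lambda_) / beta
  lc
}

#' Fit the Boltzmann fixation model
#'
#' Least-squares fit of the CDF \eqn{1 - \lambda e^{-\beta lc}} to the
#' empirical CDF of the data at its sorted positive points (default), or
#' maximum likelihood on the mixed atom-at-zero/exponential law. Empirical
#' ranks are computed over the full sample including zeros: the zero-atom
#' mass is what identifies lambda. A deterministic multi-start grid makes
#' the fit reproducible. During optimization lambda is constrained so the
#' predicted probability stays in \[0, 1\] on the observed support.
#'
#' @param lc_values lc values >= 0; at least 20 must be positive.
#' @param method "cdf" (default) or "mle".
#' @return object of class `boltzmann_fit`: list(lambda_, beta, rss, n,
#'   method).
#' @export
fit_boltzmann <- function(lc_values, method = c("cdf", "mle")) {
  method <- match.arg(method)
  if (any(lc_values < 0)) stop("lc values must be >= 0")
  pos <- lc_values[lc_values > 0]
  if (length(pos) < 20) stop("need at least 20 positive lc values")
  if (length(unique(pos)) == 1L) stop("degenerate (constant) lc input")
  n_tot <- length(lc_values)
  x <- sort(pos)
  # midrank plotting positions over the FULL sample (zeros push ranks up)
  p_emp <- ((n_tot - length(x)) + seq_along(x) - 0.5) / n_tot
  lc_min <- x[1L]
  obj_cdf <- function(par) {
    lam <- par[1L]; bet <- par[2L]
    if (lam <= 0 || bet <= 0) return(Inf)
    if (lam * exp(-bet * lc_min) > 1) return(Inf) # keep p >= 0 on support
    sum((1 - lam * exp(-bet * x) - p_emp)^2)
  }
  obj_mle <- function(par) {
    lam <- par[1L]; bet <- par[2L]
    if (lam <= 0 || lam > 1 || bet <= 0) return(Inf)
    ll <- (n_tot - length(x)) * log(max(1 - lam, 1e-300)) +
      length(x) * log(lam * bet) - bet * sum(x)
    -ll
  }
  obj <- if (method == "cdf") obj_cdf else obj_mle
  beta0 <- 1 / mean(x)
  starts <- expand.grid(lambda_ = c(0.5, 0.9, 0.99, length(x) / n_tot),
                        beta = beta0 * c(0.5, 1, 2))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(as.numeric(starts[k, ]), obj, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("Boltzmann fit failed to converge")
  lam <- best$par[1L]; bet <- best$par[2L]
  rss <- sum((1 - lam * exp(-bet * x) - p_emp)^2)
  structure(list(lambda_ = lam, beta = bet, rss = rss, n = length(x),
                 method = method),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> lambda = %.6g, beta = %.6g (per bit), rss = %.3g, n = %d [%s]\n",
              x$lambda_, x$beta, x$rss, x$n, x$method))
  invisible(x)
}

#' P-P diagnostic data for a Boltzmann fit
#'
#' Paired (empirical, theoretical) cumulative probabilities at the sorted
#' positive lc values; on-diagonal points indicate a good fit.
#'
#' @param lc_values data used for (or comparable to) the fit.
#' @param fit a [fit_boltzmann()] result.
#' @return data.frame with columns `empirical` and `theoretical`, sorted.
#' @export
pp_plot_data <- function(lc_values, fit) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  if (any(lc_values < 0)) stop("lc values must be >= 0")
  n_tot <- length(lc_values)
  x <- sort(lc_values[lc_values > 0])
  p_emp <- ((n_tot - length(x)) + seq_along(x) - 0.5) / n_tot
  p_the <- pmin(pmax(1 - fit$lambda_ * exp(-fit$beta * x), 0), 1)
  data.frame(empirical = p_emp, theoretical = p_the)
}

#' Write a Boltzmann fit report as key-value text
#' @param fit a [fit_boltzmann()] result.
#' @param path output path.
#' @export
write_boltzmann_fit <- function(fit, path) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  writeLines(c(
    sprintf("lambda\t%.12g", fit$lambda_),
    sprintf("beta\t%.12g", fit$beta),
    sprintf("rss\t%.12g", fit$rss),
    sprintf("n\t%d", fit$n),
    sprintf("method\t%s", fit$method)
  ), path)
  invisible(path)
}
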