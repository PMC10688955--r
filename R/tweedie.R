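#' @useDynLib riskbn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rpois rgamma rnorm runif optimize sd lm.fit qnorm pnorm
NULL

check_tweedie_params <- function(mu, phi, p) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be positive and finite")
  if (length(phi) != 1L || !is.finite(phi) || phi <= 0) stop("phi must be a positive scalar")
  if (length(p) != 1L || !is.finite(p) || p <= 1 || p >= 2) {
    stop("p must lie strictly in (1, 2)")
  }
  invisible(TRUE)
}

#' Compound Poisson-gamma representation of a Tweedie law
#'
#' Maps the Tweedie parameterisation (mu, phi, p), 1 < p < 2, to the
#' equivalent compound Poisson-gamma triplet: the event-rate lambda of the
#' Poisson count and the shape/scale of the i.i.d. gamma summands. A draw is
#' `Y = sum_{i=1}^{N} X_i` with `N ~ Poisson(lambda)` and
#' `X_i ~ Gamma(shape, scale)`.
#'
#' @param mu Mean of the Tweedie law (positive).
#' @param phi Dispersion parameter (positive); the variance is `phi * mu^p`.
#' @param p Power parameter, strictly between 1 and 2.
#' @return A list with elements `lambda`, `shape`, `scale`.
#' @seealso [tw_from_compound_poisson()] for the inverse map.
#' @export
#' @examples
#' tw_compound_poisson(1, 1, 1.5)  # lambda = 2, shape = 1, scale = 0.5
tw_compound_poisson <- function(mu, phi, p) {
  check_tweedie_params(mu, phi, p)
  list(
    lambda = mu^(2 - p) / (phi * (2 - p)),
    shape  = (2 - p) / (p - 1),
    scale  = phi * (p - 1) * mu^(p - 1)
  )
}

#' Inverse of the compound Poisson-gamma map
#'
#' @param lambda Poisson rate (positive).
#' @param shape,scale Gamma shape and scale of the summands (positive).
#' @return A list with elements `mu`, `phi`, `p`.
#' @export
tw_from_compound_poisson <- function(lambda, shape, scale) {
  stopifnot(lambda > 0, shape > 0, scale > 0)
  p <- (shape + 2) / (shape + 1)
  mu <- lambda * shape * scale
  phi <- scale / ((p - 1) * mu^(p - 1))
  list(mu = mu, phi = phi, p = p)
}

#' Probability of an exact zero under a Tweedie law
#'
#' For 1 < p < 2 the Tweedie law has an atom at zero (no skin-conductance
#' response in a trial): `Pr(Y = 0) = exp(-mu^(2-p) / (phi * (2-p)))`.
#'
#' @inheritParams tw_compound_poisson
#' @return Probability in (0, 1); vectorised over `mu`.
#' @export
#' @examples
#' tw_zero_probability(1, 1, 1.5)  # exp(-2)
tw_zero_probability <- function(mu, phi, p) {
  check_tweedie_params(mu, phi, p)
  exp(-mu^(2 - p) / (phi * (2 - p)))
}

#' Tweedie log-density by series evaluation
#'
#' Evaluates the exact compound Poisson-gamma log-density: the atom
#' `log Pr(Y = 0)` at zero, and for `y > 0` the Poisson-gamma mixture series
#' summed outward from its dominant term with adaptive truncation (relative
#' tolerance below 1e-10).
#'
#' @param y Non-negative observations.
#' @param mu Mean, recycled against `y`.
#' @inheritParams tw_compound_poisson
#' @return Vector of log-density values.
#' @export
tw_log_density <- function(y, mu, phi, p) {
  if (any(y < 0)) stop("y must be non-negative")
  check_tweedie_params(mu, phi, p)
  n <- max(length(y), length(mu))
  .tw_logdens_cpp(rep_len(as.numeric(y), n), rep_len(as.numeric(mu), n),
                  as.numeric(phi), as.numeric(p))
}

#' Sample from a Tweedie (compound Poisson-gamma) law
#'
#' Draws via the additive representation: `N ~ Poisson(lambda)` events, each
#' with an independent gamma amplitude; `Y` is their sum (0 when `N = 0`).
#'
#' @param n Number of draws.
#' @param mu Mean, scalar or length-`n`.
#' @inheritParams tw_compound_poisson
#' @return Numeric vector of `n` non-negative draws.
#' @export
rtweedie_cpg <- function(n, mu, phi, p) {
  check_tweedie_params(mu, phi, p)
  cp <- tw_compound_poisson(rep_len(mu, n), phi, p)
  nev <- rpois(n, cp$lambda)
  y <- numeric(n)
  pos <- nev > 0L
  # sum of N iid gammas is Gamma(N * shape, scale)
  y[pos] <- rgamma(sum(pos), shape = nev[pos] * cp$shape, scale = cp$scale[pos])
  y
}

## IRLS for the log-link Tweedie GLM at fixed p. The coefficient MLE does not
## depend on phi (exponential dispersion family), so phi is profiled out
## afterwards by one-dimensional likelihood maximisation.
tw_irls <- function(y, X, p, maxit = 50L, tol = 1e-9, beta_start = NULL) {
  if (is.null(beta_start)) {
    mu <- rep(mean(y) + mean(y[y > 0]) / 10, length(y))
    eta <- log(mu)
  } else {
    eta <- pmin(pmax(drop(X %*% beta_start), -30), 30)
    mu <- exp(eta)
  }
  dev_old <- Inf
  beta <- NULL
  for (it in seq_len(maxit)) {
    w <- mu^(2 - p)
    z <- eta + (y - mu) / mu
    fit <- lm.fit(X * sqrt(w), z * sqrt(w))
    beta <- fit$coefficients
    eta <- drop(X %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    # unit deviance for the Tweedie family, up to y-only terms
    dev <- -2 * sum(y * mu^(1 - p) / (1 - p) - mu^(2 - p) / (2 - p))
    if (is.finite(dev_old) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) break
    dev_old <- dev
  }
  list(beta = beta, mu = mu, iter = it, converged = it < maxit)
}

## Profile log-likelihood over phi at fixed p and fitted mu.
tw_profile_phi <- function(y, mu, p, phi_bracket) {
  f <- function(lphi) .tw_loglik_cpp(y, mu, exp(lphi), p)
  lo <- log(min(phi_bracket)); hi <- log(max(phi_bracket))
  for (i in 1:5) {
    opt <- optimize(f, interval = c(lo, hi), maximum = TRUE, tol = 2e-3)
    at_edge <- opt$maximum - lo < 0.02 || hi - opt$maximum < 0.02
    if (!at_edge) break
    lo <- lo - 2; hi <- hi + 2  # widen if the optimum hit the bracket
  }
  list(phi = exp(opt$maximum), loglik = opt$objective)
}

#' Fit a log-link Tweedie regression by maximum likelihood
#'
#' Fits `log mu = X beta` with a compound Poisson-gamma response
#' (1 < p < 2). For each candidate power `p` the coefficients are obtained by
#' iteratively reweighted least squares (exact MLE at fixed `p`), the
#' dispersion `phi` by one-dimensional maximisation of the exact series
#' log-likelihood, and `p` itself by profile likelihood over `p_grid`
#' followed by golden-section refinement between the best grid point's
#' neighbours.
#'
#' @param y Non-negative responses (not all zero, not degenerate).
#' @param X Model matrix (full column rank), including the intercept column.
#' @param p_grid Grid of candidate power parameters in (1, 2).
#' @param refine Refine `p` between the best grid point's neighbours
#'   (golden-section search); set to `FALSE` to keep the grid optimum.
#' @return An object of class `tweedie_fit`: coefficients, their standard
#'   errors and covariance, `phi`, `p`, the maximised `loglik`, `n`, the
#'   free-parameter count `k = length(beta) + 2`, and a convergence flag.
#' @export
tw_fit_glm <- function(y, X, p_grid = seq(1.1, 1.9, by = 0.1), refine = TRUE) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (any(y < 0)) stop("y must be non-negative")
  if (all(y == 0)) stop("all responses are zero: Tweedie mean is unidentifiable")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (qr(X)$rank < ncol(X)) stop("X must have full column rank")
  if (any(p_grid <= 1 | p_grid >= 2)) stop("p_grid must lie strictly in (1, 2)")
  n <- length(y)

  # warm starts: coefficients and dispersion vary smoothly in p, so each
  # profile point starts from the previous solution
  warm <- new.env(parent = emptyenv())
  profile_p <- function(p) {
    ir <- tw_irls(y, X, p, beta_start = warm$beta)
    warm$beta <- ir$beta
    # dispersion bracket around the Pearson estimate (or the previous optimum)
    phi_pe <- sum((y - ir$mu)^2 / ir$mu^p) / max(n - ncol(X), 1)
    if (!is.finite(phi_pe) || phi_pe < 1e-8) {
      stop("zero dispersion: responses are deterministic given the covariates")
    }
    bracket <- if (is.null(warm$phi)) c(phi_pe / 50, phi_pe * 50) else
      range(warm$phi / 6, warm$phi * 6, phi_pe)
    pr <- tw_profile_phi(y, ir$mu, p, bracket)
    warm$phi <- pr$phi
    list(p = p, irls = ir, phi = pr$phi, loglik = pr$loglik)
  }

  fits <- lapply(p_grid, profile_p)
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  i_best <- which.max(ll)
  best <- fits[[i_best]]
  if (refine && length(p_grid) > 1L) {
    lo <- if (i_best > 1L) p_grid[i_best - 1L] else p_grid[1L]
    hi <- if (i_best < length(p_grid)) p_grid[i_best + 1L] else p_grid[length(p_grid)]
    if (hi > lo) {
      gr <- (sqrt(5) - 1) / 2
      a <- lo; b <- hi
      x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
      f1 <- profile_p(x1); f2 <- profile_p(x2)
      while (b - a > 5e-3) {
        if (f1$loglik >= f2$loglik) {
          b <- x2; x2 <- x1; f2 <- f1
          x1 <- b - gr * (b - a); f1 <- profile_p(x1)
        } else {
          a <- x1; x1 <- x2; f1 <- f2
          x2 <- a + gr * (b - a); f2 <- profile_p(x2)
        }
      }
      cand <- if (f1$loglik >= f2$loglik) f1 else f2
      if (cand$loglik > best$loglik) best <- cand
    }
  }

  mu <- best$irls$mu
  w <- mu^(2 - best$p)
  xtwx <- crossprod(X * sqrt(w))
  vcov <- best$phi * solve(xtwx)
  beta <- best$irls$beta
  names(beta) <- colnames(X)
  structure(list(
    coefficients = beta,
    se = sqrt(diag(vcov)),
    vcov = vcov,
    phi = best$phi,
    p = best$p,
    loglik = best$loglik,
    n = n,
    k = ncol(X) + 2L,
    fitted = mu,
    converged = best$irls$converged,
    profile = data.frame(p = p_grid, loglik = ll)
  ), class = "tweedie_fit")
}

#' @export
print.tweedie_fit <- function(x, ...) {
  cat("Tweedie log-link regression (compound Poisson-gamma)\n")
  cat(sprintf("  n = %d, p = %.3f, phi = %.4f, logLik = %.3f, k = %d\n",
              x$n, x$p, x$phi, x$loglik, x$k))
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' BIC of a fitted Tweedie regression
#' @param object A `tweedie_fit`.
#' @param ... Ignored.
#' @export
BIC.tweedie_fit <- function(object, ...) {
  -2 * object$loglik + object$k * log(object$n)
}
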