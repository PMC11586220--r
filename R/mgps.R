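#' Fit the gamma-Poisson mixture prior of the MGPS model
#'
#' The multi-item gamma-Poisson shrinker (MGPS) models the observed count
#' `a_i` of each drug-event pair as Poisson with mean `lambda_i * E_i`, where
#' `E_i = (a+b)(a+c)/N` is the count expected under independence and the
#' relative reporting rate `lambda_i` has a two-component gamma mixture prior
#'
#' `lambda ~ p * Gamma(alpha1, rate beta1) + (1-p) * Gamma(alpha2, rate beta2)`.
#'
#' Marginally each count is a two-component negative binomial mixture; this
#' function maximizes the marginal likelihood over the five hyperparameters by
#' bounded quasi-Newton (`optim` L-BFGS-B on log/logit-transformed parameters)
#' from the classical start `(0.2, 0.1, 2, 4, 1/3)`.
#'
#' @param a non-negative integer counts, one per drug-event pair.
#' @param E positive expected counts, same length.
#' @param start numeric vector `c(alpha1, beta1, alpha2, beta2, p_mix)`.
#' @return an object of class `mgps_prior`: list with the five
#'   hyperparameters, `logLik`, `n` (number of cells), `converged`, and
#'   `fallback` (TRUE when optimization failed and the start values were
#'   returned).
#' @seealso [compute_ebgm()] for the per-table posterior summaries.
#' @export
fit_mgps_prior <- function(a, E, start = c(0.2, 0.1, 2, 4, 1 / 3)) {
  if (length(a) != length(E)) stopf("'a' and 'E' must have the same length")
  keep <- is.finite(E) & E > 0
  a <- a[keep]; E <- E[keep]
  if (length(a) < 50L) {
    stopf("MGPS prior fit needs at least 50 cells with E > 0 (got %d)", length(a))
  }
  if (any(a < 0) || any(a != floor(a))) stopf("counts must be non-negative integers")
  if (all(a == 0)) {
    warning("all counts are zero; MGPS prior is not identifiable, using start values")
    prior <- list(alpha1 = start[1], beta1 = start[2], alpha2 = start[3],
                  beta2 = start[4], p_mix = start[5],
                  logLik = sum(mix_loglik(a, E, start[1], start[2], start[3],
                                          start[4], start[5])),
                  n = length(a), converged = FALSE, fallback = TRUE)
    class(prior) <- "mgps_prior"
    return(prior)
  }

  nll <- function(theta) {
    p <- exp(theta[1:4])
    w <- stats::plogis(theta[5])
    -sum(mix_loglik(a, E, p[1], p[2], p[3], p[4], w))
  }
  theta0 <- c(log(start[1:4]), stats::qlogis(start[5]))
  fit <- tryCatch(
    stats::optim(theta0, nll, method = "L-BFGS-B",
                 lower = c(rep(log(1e-6), 4), stats::qlogis(1e-6)),
                 upper = c(rep(log(1e6), 4), stats::qlogis(1 - 1e-6)),
                 control = list(maxit = 500)),
    error = function(e) NULL
  )
  fallback <- is.null(fit) || fit$convergence != 0 || !is.finite(fit$value)
  if (fallback) {
    warning("MGPS prior optimization did not converge; using start values")
    theta <- theta0
    ll <- -nll(theta0)
  } else {
    theta <- fit$par
    ll <- -fit$value
  }
  par <- exp(theta[1:4])
  prior <- list(
    alpha1 = par[1], beta1 = par[2], alpha2 = par[3], beta2 = par[4],
    p_mix = stats::plogis(theta[5]),
    logLik = ll, n = length(a),
    converged = !fallback, fallback = fallback
  )
  class(prior) <- "mgps_prior"
  prior
}

# per-cell log marginal likelihood of the two-component NB mixture,
# computed by log-sum-exp for stability
mix_loglik <- function(a, E, alpha1, beta1, alpha2, beta2, p_mix) {
  l1 <- log(p_mix) + stats::dnbinom(a, size = alpha1, prob = beta1 / (beta1 + E), log = TRUE)
  l2 <- log1p(-p_mix) + stats::dnbinom(a, size = alpha2, prob = beta2 / (beta2 + E), log = TRUE)
  m <- pmax(l1, l2)
  m + log(exp(l1 - m) + exp(l2 - m))
}

#' Empirical-Bayes geometric mean and EB05 lower bound
#'
#' Given the fitted prior, the posterior of the relative reporting rate
#' `lambda` for a table with count `a` and expected count `E` is again a
#' two-component gamma mixture with weights proportional to the prior weight
#' times the component's negative-binomial marginal, and components
#' `Gamma(alpha_j + a, rate beta_j + E)`. EBGM is the posterior geometric
#' mean, `exp(E[log lambda])`, computed from the digamma function; EB05 is
#' the 5th percentile of the posterior mixture, solved by bisection on the
#' mixture CDF to 1e-8 relative tolerance.
#'
#' @param a counts (vectorized).
#' @param E expected counts under independence, `(a+b)(a+c)/N`.
#' @param prior an `mgps_prior` object (or list with the five hyperparameters).
#' @return data.frame with columns `ebgm, eb05`. Rows with `E <= 0` are NA.
#' @export
compute_ebgm <- function(a, E, prior) {
  stopifnot(length(a) == length(E))
  a1 <- prior$alpha1; b1 <- prior$beta1
  a2 <- prior$alpha2; b2 <- prior$beta2
  p <- prior$p_mix
  ok <- is.finite(E) & E > 0
  Q <- ebgm <- eb05 <- rep(NA_real_, length(a))
  if (any(ok)) {
    ao <- a[ok]; Eo <- E[ok]
    l1 <- log(p) + stats::dnbinom(ao, size = a1, prob = b1 / (b1 + Eo), log = TRUE)
    l2 <- log1p(-p) + stats::dnbinom(ao, size = a2, prob = b2 / (b2 + Eo), log = TRUE)
    Qo <- 1 / (1 + exp(l2 - l1))
    ebgm[ok] <- exp(Qo * (digamma(a1 + ao) - log(b1 + Eo)) +
                      (1 - Qo) * (digamma(a2 + ao) - log(b2 + Eo)))
    eb05[ok] <- mixture_gamma_quantile(0.05, Qo, a1 + ao, b1 + Eo, a2 + ao, b2 + Eo)
    Q[ok] <- Qo
  }
  data.frame(ebgm = ebgm, eb05 = eb05)
}

# vectorized bisection for the q-quantile of
# Q * Gamma(shape1, rate1) + (1-Q) * Gamma(shape2, rate2)
mixture_gamma_quantile <- function(q, Q, shape1, rate1, shape2, rate2,
                                   rel_tol = 1e-8) {
  lo <- pmin(stats::qgamma(q, shape1, rate = rate1),
             stats::qgamma(q, shape2, rate = rate2))
  hi <- pmax(stats::qgamma(q, shape1, rate = rate1),
             stats::qgamma(q, shape2, rate = rate2))
  # widen marginally so F(lo) <= q <= F(hi) holds exactly
  lo <- lo * (1 - 1e-12)
  hi <- hi * (1 + 1e-12)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    f <- Q * stats::pgamma(mid, shape1, rate = rate1) +
      (1 - Q) * stats::pgamma(mid, shape2, rate = rate2)
    below <- f < q
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (all(hi - lo <= rel_tol * pmax(lo, .Machine$double.xmin))) break
  }
  (lo + hi) / 2
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat("MGPS gamma-Poisson mixture prior\n")
  cat(sprintf("  component 1: Gamma(shape = %.4g, rate = %.4g)\n", x$alpha1, x$beta1))
  cat(sprintf("  component 2: Gamma(shape = %.4g, rate = %.4g)\n", x$alpha2, x$beta2))
  cat(sprintf("  mixture weight (component 1): %.4g\n", x$p_mix))
  cat(sprintf("  fitted on %d cells, logLik = %.2f%s\n", x$n, x$logLik,
              if (x$fallback) " [fallback to start values]" else ""))
  invisible(x)
}

#' @export
coef.mgps_prior <- function(object, ...) {
  c(alpha1 = object$alpha1, beta1 = object$beta1,
    alpha2 = object$alpha2, beta2 = object$beta2, p_mix = object$p_mix)
}

#' @export
logLik.mgps_prior <- function(object, ...) {
  structure(object$logLik, df = 5L, nobs = object$n, class = "logLik")
}
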