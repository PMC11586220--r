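#' Reporting odds ratio with Woolf confidence interval
#'
#' ROR = (a d) / (b c), with the 95% CI computed on the log scale:
#' `exp(log(ror) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' Degenerate cells: when `a = 0` the pair cannot be a signal and the ROR is
#' reported as 0 with an undefined CI (`zero_flag = "undefined_ci"`). When
#' `a > 0` but any of b, c, d is 0, the Haldane-Anscombe correction adds 0.5
#' to all four cells and the row is flagged `"haldane"`.
#'
#' @param a,b,c,d cell counts (vectors recycle as usual).
#' @return data.frame with columns `ror, ror_ci_low, ror_ci_high, zero_flag`.
#' @export
compute_ror <- function(a, b, c, d) {
  k <- check_cells(a, b, c, d)
  a <- k$a; b <- k$b; c <- k$c; d <- k$d
  flag <- rep("", length(a))
  undef <- a == 0
  hald <- !undef & (b == 0 | c == 0 | d == 0)
  flag[undef] <- "undefined_ci"
  flag[hald] <- "haldane"

  aa <- a + 0.5 * hald; bb <- b + 0.5 * hald
  cc <- c + 0.5 * hald; dd <- d + 0.5 * hald
  ror <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  lo <- exp(log(ror) - 1.96 * se)
  hi <- exp(log(ror) + 1.96 * se)
  ror[undef] <- 0
  lo[undef] <- NA_real_
  hi[undef] <- NA_real_
  data.frame(ror = ror, ror_ci_low = lo, ror_ci_high = hi,
             zero_flag = flag, stringsAsFactors = FALSE)
}

#' Proportional reporting ratio with Yates-corrected chi-square
#'
#' PRR = (a / (a+b)) / (c / (c+d)); the companion statistic is the
#' continuity-corrected chi-square
#' `N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`,
#' where the correction term N/2 is truncated at `|ad - bc|` so the statistic
#' never goes negative. Zero cells among b, c, d (with a > 0) take the same
#' +0.5 correction as [compute_ror()]; `a = 0` gives PRR 0.
#'
#' @inheritParams compute_ror
#' @return data.frame with columns `prr, chi2, zero_flag`.
#' @export
compute_prr <- function(a, b, c, d) {
  k <- check_cells(a, b, c, d)
  a <- k$a; b <- k$b; c <- k$c; d <- k$d
  flag <- rep("", length(a))
  undef <- a == 0
  hald <- !undef & (b == 0 | c == 0 | d == 0)
  flag[undef] <- "undefined_ci"
  flag[hald] <- "haldane"

  aa <- a + 0.5 * hald; bb <- b + 0.5 * hald
  cc <- c + 0.5 * hald; dd <- d + 0.5 * hald
  prr <- (aa / (aa + bb)) / (cc / (cc + dd))
  prr[undef] <- 0

  nn <- aa + bb + cc + dd
  dev <- abs(aa * dd - bb * cc)
  corr <- pmin(nn / 2, dev)
  chi2 <- nn * (dev - corr)^2 /
    ((aa + bb) * (cc + dd) * (aa + cc) * (bb + dd))
  data.frame(prr = prr, chi2 = chi2, zero_flag = flag,
             stringsAsFactors = FALSE)
}

#' BCPNN information component (closed-form posterior moments)
#'
#' The information component IC = log2 of the Bayesian-smoothed
#' observed-to-expected reporting ratio, with the closed-form posterior
#' mean and variance of the early BCPNN formulation (Dirichlet/beta priors
#' with gamma11 = 1, alpha1 = beta1 = 1, alpha = beta = 2):
#'
#' `gamma = (N + 2)(N + 2) / ((a + b + 1)(a + c + 1))`
#'
#' `E(IC) = log2[ (a + 1)(N + 2)(N + 2) / ((N + gamma)(a + b + 1)(a + c + 1)) ]`
#'
#' `V(IC) = (ln 2)^-2 [ (N - a + gamma - 1)/((a + 1)(1 + N + gamma))`
#' `       + (N - (a+b) + 1)/((a + b + 1)(1 + N + 2))`
#' `       + (N - (a+c) + 1)/((a + c + 1)(1 + N + 2)) ]`
#'
#' The signal criterion uses `ic - 2 sqrt(V)`, the "IC - 2SD" lower bound.
#' Defined for all valid tables including a = 0.
#'
#' @inheritParams compute_ror
#' @return data.frame with columns `ic, ic_minus_2sd` (bits).
#' @export
compute_bcpnn <- function(a, b, c, d) {
  k <- check_cells(a, b, c, d)
  a <- k$a; b <- k$b; c <- k$c; d <- k$d
  n <- a + b + c + d
  g11 <- 1; a1 <- 1; b1 <- 1; al <- 2; be <- 2
  gam <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  ic <- log2((a + g11) * (n + al) * (n + be) /
               ((n + gam) * (a + b + a1) * (a + c + b1)))
  v <- (1 / log(2)^2) * (
    (n - a + gam - g11) / ((a + g11) * (1 + n + gam)) +
      (n - (a + b) + al - a1) / ((a + b + a1) * (1 + n + al)) +
      (n - (a + c) + be - b1) / ((a + c + b1) * (1 + n + be))
  )
  data.frame(ic = ic, ic_minus_2sd = ic - 2 * sqrt(v))
}

check_cells <- function(a, b, c, d) {
  m <- cbind(a, b, c, d)
  if (any(!is.finite(m)) || any(m < 0) || any(m != floor(m))) {
    stopf("contingency cells must be non-negative integers")
  }
  list(a = m[, 1], b = m[, 2], c = m[, 3], d = m[, 4])
}
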