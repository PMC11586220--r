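#' Per-method signal flags and the combined signal call
#'
#' Applies the standard screening thresholds to the four disproportionality
#' statistics:
#' \itemize{
#'   \item ROR: lower 95% CI limit > 1 and a >= 3
#'   \item PRR: PRR >= 2 and chi-square >= 4 and a >= 3
#'   \item BCPNN: a >= 3 and IC - 2SD > 0
#'   \item MGPS: EB05 > 2
#' }
#' PRR and chi-square thresholds are inclusive; the CI lower limits and
#' IC - 2SD are strict. The combined `signal` column follows `policy`:
#' `"all"` (the default) requires all four methods to flag, `"any"` requires
#' at least one, `"per-method"` leaves `signal` NA so callers work from the
#' per-method flags.
#'
#' @param stats data.frame with columns `a, ror_ci_low, prr, chi2,
#'   ic_minus_2sd, eb05` (as assembled by [disprop()]).
#' @param policy one of `"all"`, `"any"`, `"per-method"`.
#' @return `stats` with logical columns `ror_sig, prr_sig, bcpnn_sig,
#'   mgps_sig, signal` appended.
#' @export
classify_signals <- function(stats, policy = c("all", "any", "per-method")) {
  policy <- match.arg(policy)
  need <- c("a", "ror_ci_low", "prr", "chi2", "ic_minus_2sd", "eb05")
  missing_cols <- setdiff(need, names(stats))
  if (length(missing_cols)) {
    stopf("classify_signals: missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  a3 <- stats$a >= 3
  stats$ror_sig <- a3 & !is.na(stats$ror_ci_low) & stats$ror_ci_low > 1
  stats$prr_sig <- a3 & stats$prr >= 2 & stats$chi2 >= 4
  stats$bcpnn_sig <- a3 & stats$ic_minus_2sd > 0
  stats$mgps_sig <- !is.na(stats$eb05) & stats$eb05 > 2
  flags <- cbind(stats$ror_sig, stats$prr_sig, stats$bcpnn_sig, stats$mgps_sig)
  stats$signal <- switch(policy,
    "all" = rowSums(flags) == 4L,
    "any" = rowSums(flags) >= 1L,
    "per-method" = NA
  )
  stats
}

#' Strong-signal conditions A-D
#'
#' Classifies positive signals into the four strong-signal conditions:
#' \describe{
#'   \item{A}{ROR, PRR and EBGM all exceed 10}
#'   \item{B}{the information component (IC) exceeds 3}
#'   \item{C}{A and B hold simultaneously}
#'   \item{D}{this drug's signal strength for the PT strictly exceeds every
#'     other drug's for the same PT, among drugs with a positive signal
#'     there; strength is measured by IC by default (EBGM optional)}
#' }
#' When several hold, the label returned follows the priority
#' C > D > A > B > none; the full boolean set is also returned.
#'
#' @param stats data.frame with columns `ror, prr, ebgm, ic, signal` (and
#'   `pt` when `cross_ic` is used).
#' @param cross_ic optional data.frame of the same PTs across other drugs,
#'   with columns `pt, ic` (or `ebgm`), restricted to positive signals, used
#'   for condition D. NULL disables D.
#' @param strength `"ic"` or `"ebgm"`: the metric compared in condition D.
#' @return `stats` with logical columns `cond_A, cond_B, cond_C, cond_D` and
#'   a character column `strong_condition` in `{"none","A","B","C","D"}`
#'   appended. Non-signals are always `"none"`.
#' @export
strong_condition <- function(stats, cross_ic = NULL,
                             strength = c("ic", "ebgm")) {
  strength <- match.arg(strength)
  sig <- !is.na(stats$signal) & stats$signal
  A <- sig & stats$ror > 10 & stats$prr > 10 & stats$ebgm > 10
  B <- sig & stats$ic > 3
  C <- A & B
  D <- rep(FALSE, nrow(stats))
  if (!is.null(cross_ic) && nrow(stats) > 0) {
    own <- stats[[strength]]
    for (i in which(sig)) {
      others <- cross_ic[[strength]][cross_ic$pt == stats$pt[i]]
      others <- others[is.finite(others)]
      D[i] <- length(others) == 0 || all(own[i] > others)
    }
    D <- D & sig
  }
  lab <- rep("none", nrow(stats))
  lab[B] <- "B"
  lab[A] <- "A"
  lab[D] <- "D"
  lab[C] <- "C"
  stats$cond_A <- A
  stats$cond_B <- B
  stats$cond_C <- C
  stats$cond_D <- D
  stats$strong_condition <- lab
  stats
}

#' Top-k signals by case count
#'
#' Orders signals by decreasing case count `a`, breaking ties by decreasing
#' IC and then by PT name (ascending), and returns the first `k`.
#'
#' @param signals data.frame with columns `pt, a, ic` (typically the signal
#'   rows of a [disprop()] fit).
#' @param k positive integer; when fewer than `k` rows exist, all are
#'   returned.
#' @return the reordered head of `signals`.
#' @export
rank_top_k <- function(signals, k = 15L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) stopf("'k' must be >= 1")
  ord <- order(-signals$a, -signals$ic, signals$pt)
  out <- signals[ord, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n = as.integer(k))
}
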