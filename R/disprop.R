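#' Fit a disproportionality analysis for one drug group
#'
#' The central model-fitting function. Builds the drug-event 2x2 tables for
#' the drug group's cohort against all other reports, computes all four
#' disproportionality statistics per preferred term (PT) -- reporting odds
#' ratio (ROR) with Woolf 95% CI, proportional reporting ratio (PRR) with
#' Yates-corrected chi-square, the BCPNN information component (IC) with its
#' IC - 2SD lower bound, and the MGPS empirical-Bayes geometric mean (EBGM)
#' with its EB05 lower percentile -- then applies the signal thresholds and
#' the strong-signal conditions.
#'
#' The MGPS prior is fitted once per database on all (primary-suspect drug,
#' PT) pairs with count >= 1; pass a prefitted `prior` when fitting several
#' drugs from the same case set to avoid refitting (and to guarantee all
#' drugs share one prior, as the model intends).
#'
#' @param cases a `faers_cases` object from [assemble_cases()].
#' @param drug drug group id.
#' @param prior optional `mgps_prior`; fitted from `cases` when NULL.
#' @param policy combined-signal policy passed to [classify_signals()].
#' @param meddra optional `meddra_map` from [load_meddra_map()]; adds HLGT
#'   and SOC columns to the statistics table.
#' @return an object of class `disprop`: list with `drug`, `stats` (one row
#'   per PT with cells, all statistics, flags and strong-condition labels),
#'   `prior`, `n` (database case total), `cohort_size`, and `policy`.
#' @examples
#' cfg <- synthetic_config(n_cases = 400, seed = 42)
#' sim <- generate_dataset(cfg)
#' cases <- assemble_cases(sim$tables, synonyms = synthetic_synonyms(cfg))
#' fit <- disprop(cases, drug = names(cfg$drug_catalog)[1])
#' summary(fit)
#' @export
disprop <- function(cases, drug, prior = NULL,
                    policy = c("all", "any", "per-method"), meddra = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(cases, "faers_cases"))
  tab <- build_tables(cases, drug)
  if (is.null(prior)) prior <- fit_database_prior(cases)

  stats <- cbind(
    tab,
    compute_ror(tab$a, tab$b, tab$c, tab$d)[, c("ror", "ror_ci_low", "ror_ci_high", "zero_flag")],
    compute_prr(tab$a, tab$b, tab$c, tab$d)[, c("prr", "chi2")],
    compute_bcpnn(tab$a, tab$b, tab$c, tab$d)
  )
  E <- expected_count(tab$a, tab$b, tab$c, tab$d)
  stats <- cbind(stats, E = E, compute_ebgm(tab$a, E, prior))
  stats <- classify_signals(stats, policy = policy)
  stats <- strong_condition(stats)  # A/B/C only; D needs cross-drug context

  if (!is.null(meddra)) {
    hit <- match(stats$pt, meddra$entries$pt)
    stats$hlgt <- meddra$entries$hlgt[hit]
    stats$soc <- meddra$entries$soc[hit]
  }

  out <- list(
    drug = drug,
    stats = stats,
    prior = prior,
    n = if (nrow(tab)) tab$n[1] else nrow(cases$demo),
    cohort_size = length(cohort_primaryids(cases, drug)),
    policy = policy
  )
  class(out) <- "disprop"
  out
}

#' Fit the MGPS prior from a whole case database
#'
#' Collects all (primary-suspect drug, PT) pair counts with a >= 1 from the
#' deduplicated cases (using the normalized drug group when available, the
#' raw name otherwise) and fits the gamma-Poisson mixture prior on them.
#'
#' @param cases a `faers_cases` object.
#' @return an `mgps_prior`.
#' @export
fit_database_prior <- function(cases) {
  pc <- pair_counts(cases)
  fit_mgps_prior(pc$a, pc$E)
}

# (PS drug, PT) pair counts a and expected counts E over the database
pair_counts <- function(cases) {
  dr <- cases$drugs
  ps <- dr[dr$role_code == "PS", c("primaryid", "drug_group", "raw_name")]
  ps$drug <- ifelse(is.na(ps$drug_group), toupper(ps$raw_name), ps$drug_group)
  ps <- unique(ps[, c("primaryid", "drug")])
  ev <- cases$events
  m <- merge(ps, ev, by = "primaryid")
  if (nrow(m) == 0L) stopf("no drug-event pairs in case set")
  n <- nrow(cases$demo)
  pair <- stats::aggregate(list(a = m$primaryid), by = list(drug = m$drug, pt = m$pt),
                           FUN = function(x) length(unique(x)))
  drug_tot <- table(ps$drug)[pair$drug]
  pt_tot <- table(unique(ev[, c("primaryid", "pt")])$pt)[pair$pt]
  pair$E <- as.numeric(drug_tot) * as.numeric(pt_tot) / n
  pair
}

#' Strong-signal condition D across several fitted drugs
#'
#' Condition D compares one drug's signal strength for a PT with every other
#' drug's strength for the same PT. Given the `disprop` fits of all drugs
#' from one database, this re-labels each fit's strong conditions with D
#' resolved.
#'
#' @param fits named list of `disprop` objects fitted from the same case set.
#' @param strength `"ic"` (default) or `"ebgm"`.
#' @return the list of fits, strong-condition columns updated in place.
#' @export
resolve_condition_d <- function(fits, strength = c("ic", "ebgm")) {
  strength <- match.arg(strength)
  for (i in seq_along(fits)) {
    own <- fits[[i]]$stats
    cross <- do.call(rbind, lapply(fits[-i], function(f) {
      s <- f$stats
      s[!is.na(s$signal) & s$signal, c("pt", "ic", "ebgm"), drop = FALSE]
    }))
    if (is.null(cross)) cross <- data.frame(pt = character(), ic = numeric(), ebgm = numeric())
    fits[[i]]$stats <- strong_condition(own, cross_ic = cross, strength = strength)
  }
  fits
}

#' @export
print.disprop <- function(x, ...) {
  ns <- sum(x$stats$signal, na.rm = TRUE)
  cat(sprintf("Disproportionality analysis for drug group '%s'\n", x$drug))
  cat(sprintf("  database: %d deduplicated cases; cohort: %d cases\n", x$n, x$cohort_size))
  cat(sprintf("  PTs evaluated: %d; positive signals (policy '%s'): %d\n",
              nrow(x$stats), x$policy, ns))
  invisible(x)
}

#' @export
summary.disprop <- function(object, k = 15L, ...) {
  sig <- object$stats[!is.na(object$stats$signal) & object$stats$signal, , drop = FALSE]
  top <- rank_top_k(sig, k = k)
  out <- list(
    drug = object$drug, n = object$n, cohort_size = object$cohort_size,
    n_pts = nrow(object$stats), n_signals = nrow(sig),
    signal_cases = sum(sig$a), top = top, policy = object$policy
  )
  class(out) <- "summary.disprop"
  out
}

#' @export
print.summary.disprop <- function(x, ...) {
  cat(sprintf("Drug group '%s': %d signals (%d cases) among %d PTs [policy '%s']\n",
              x$drug, x$n_signals, x$signal_cases, x$n_pts, x$policy))
  cat(sprintf("Database N = %d, cohort = %d\n", x$n, x$cohort_size))
  if (nrow(x$top)) {
    cat(sprintf("Top %d signals by case count:\n", nrow(x$top)))
    cols <- intersect(c("pt", "a", "ror", "ror_ci_low", "prr", "chi2",
                        "ic", "ic_minus_2sd", "ebgm", "eb05", "strong_condition"),
                      names(x$top))
    print(format(x$top[, cols], digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.disprop <- function(object, ...) {
  m <- as.matrix(object$stats[, c("ror", "prr", "chi2", "ic", "ebgm")])
  rownames(m) <- object$stats$pt
  m
}

#' @export
as.data.frame.disprop <- function(x, ...) x$stats

#' Signal-strength overview plot
#'
#' Plots IC - 2SD against log10 case count per PT, highlighting positive
#' signals; the standard diagnostic view of a disproportionality run.
#'
#' @param x a `disprop` object.
#' @param ... passed to `plot`.
#' @export
plot.disprop <- function(x, ...) {
  s <- x$stats
  sig <- !is.na(s$signal) & s$signal
  plot(log10(pmax(s$a, 0.5)), s$ic_minus_2sd,
       pch = ifelse(sig, 19, 1), col = ifelse(sig, "firebrick", "grey40"),
       xlab = "log10 case count (a)", ylab = "IC - 2SD (bits)",
       main = sprintf("Signals for %s", x$drug), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
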