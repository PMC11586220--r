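#' Demographic summary of a drug cohort
#'
#' The standard demographic table of a spontaneous-report cohort: case
#' count; age median and quartiles (linear interpolation between order
#' statistics) plus strata counts `[0, 18)`, `[18, 60)`, `[60, 100)` and
#' unknown; sex counts, percentages and the female/male ratio (1 decimal,
#' half-up); the reporter-occupation distribution; the top-5 reporting
#' countries; yearly report counts; and single/cumulative dose medians and
#' quartiles (cases with a parseable dose in the cohort's modal unit only).
#'
#' @param cases a `faers_cases` object.
#' @param drug drug group id; the cohort is every case with a
#'   primary-suspect mention of this group.
#' @return object of class `cohort_summary`.
#' @export
summarize_cohort <- function(cases, drug) {
  stopifnot(inherits(cases, "faers_cases"))
  ids <- cohort_primaryids(cases, drug)
  if (length(ids) == 0L) stopf("empty cohort for drug group '%s'", drug)
  d <- cases$demo[cases$demo$primaryid %in% ids, , drop = FALSE]
  n <- nrow(d)

  age <- d$age_years
  age_strata <- c(
    "[0-18)" = sum(!is.na(age) & age < 18),
    "[18-60)" = sum(!is.na(age) & age >= 18 & age < 60),
    "[60-100)" = sum(!is.na(age) & age >= 60 & age < 100),
    "unknown" = sum(is.na(age) | age >= 100)
  )
  sex_counts <- c(F = sum(d$sex == "F"), M = sum(d$sex == "M"),
                  unknown = sum(d$sex == "unknown"))
  fm_ratio <- if (sex_counts["M"] > 0) {
    round_half_up(sex_counts[["F"]] / sex_counts[["M"]], 1)
  } else {
    NA_real_
  }

  country_tab <- sort(table(d$country), decreasing = TRUE)
  top5 <- utils::head(country_tab, 5)
  year_tab <- table(d$report_year)

  ps <- cases$drugs[cases$drugs$primaryid %in% ids &
                      !is.na(cases$drugs$drug_group) &
                      cases$drugs$drug_group == drug &
                      cases$drugs$role_code == "PS", , drop = FALSE]
  ps <- ps[!duplicated(ps$primaryid), , drop = FALSE]
  single <- dose_summary(ps$dose_amt, ps$dose_unit)
  cumulative <- dose_summary(ps$cum_dose, ps$cum_dose_unit)

  out <- list(
    drug = drug,
    n_cases = n,
    age = c(median_q1_q3(age)),
    age_strata = age_strata,
    sex_counts = sex_counts,
    sex_pct = round_half_up(100 * sex_counts / n, 2),
    female_male_ratio = fm_ratio,
    reporter = tabulate_pct(d$reporter, n),
    top_countries = data.frame(country = names(top5),
                               proportion_pct = round_half_up(100 * as.numeric(top5) / n, 2),
                               stringsAsFactors = FALSE),
    year_counts = stats::setNames(as.integer(year_tab), names(year_tab)),
    year_pct = round_half_up(100 * as.integer(year_tab) / n, 2),
    single_dose = single,
    cumulative_dose = cumulative
  )
  class(out) <- "cohort_summary"
  out
}

tabulate_pct <- function(x, n) {
  tab <- table(x)
  data.frame(category = names(tab), count = as.integer(tab),
             proportion_pct = round_half_up(100 * as.integer(tab) / n, 2),
             stringsAsFactors = FALSE)
}

# median/Q1/Q3 over values in the cohort's modal unit; mismatched units
# are excluded and counted
dose_summary <- function(amount, unit) {
  ok <- !is.na(amount) & !is.na(unit) & nzchar(unit)
  if (!any(ok)) {
    return(list(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                unit = NA_character_, n = 0L, excluded_unit_mismatch = 0L))
  }
  modal <- names(sort(table(unit[ok]), decreasing = TRUE))[1]
  use <- ok & unit == modal
  q <- median_q1_q3(amount[use])
  list(median = q[["median"]], q1 = q[["q1"]], q3 = q[["q3"]],
       unit = modal, n = sum(use),
       excluded_unit_mismatch = sum(ok) - sum(use))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary for '%s': %d cases\n", x$drug, x$n_cases))
  cat(sprintf("  age (years): median %.4g (Q1 %.4g, Q3 %.4g); strata: %s\n",
              x$age[["median"]], x$age[["q1"]], x$age[["q3"]],
              paste(sprintf("%s=%d", names(x$age_strata), x$age_strata), collapse = ", ")))
  cat(sprintf("  sex: F=%d (%.2f%%), M=%d (%.2f%%), unknown=%d; F/M ratio %.1f\n",
              x$sex_counts[["F"]], x$sex_pct[["F"]], x$sex_counts[["M"]],
              x$sex_pct[["M"]], x$sex_counts[["unknown"]], x$female_male_ratio))
  if (x$single_dose$n > 0) {
    cat(sprintf("  single dose: median %.4g (Q1 %.4g, Q3 %.4g) %s [n=%d]\n",
                x$single_dose$median, x$single_dose$q1, x$single_dose$q3,
                x$single_dose$unit, x$single_dose$n))
  }
  if (x$cumulative_dose$n > 0) {
    cat(sprintf("  cumulative dose: median %.4g (Q1 %.4g, Q3 %.4g) %s [n=%d]\n",
                x$cumulative_dose$median, x$cumulative_dose$q1,
                x$cumulative_dose$q3, x$cumulative_dose$unit, x$cumulative_dose$n))
  }
  invisible(x)
}

#' Outcome summary of a drug cohort
#'
#' Tallies the seven seriousness outcomes (Death, Life-Threatening,
#' Hospitalization, Disability, Congenital Anomaly, Required Intervention,
#' Other Serious). The proportion denominator is the sum of outcome records,
#' not the cohort size: a case reporting two outcome codes contributes two
#' records. Proportions are percentages, 2 decimals, half-up.
#'
#' @param cases a `faers_cases` object.
#' @param drug drug group id.
#' @return object of class `outcome_summary`: data.frame
#'   `code, outcome, count, proportion_pct`.
#' @export
summarize_outcomes <- function(cases, drug) {
  stopifnot(inherits(cases, "faers_cases"))
  ids <- cohort_primaryids(cases, drug)
  oc <- cases$outcomes[cases$outcomes$primaryid %in% ids, , drop = FALSE]
  codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
  labels <- c("Death", "Life-Threatening", "Hospitalization - Initial or Prolonged",
              "Disability", "Congenital Anomaly",
              "Required Intervention to Prevent Permanent Impairment/Damage",
              "Other Serious (Important Medical Event)")
  counts <- vapply(codes, function(k) sum(oc$outc_cod == k), integer(1))
  total <- sum(counts)
  if (total == 0L) stopf("no outcome data for drug group '%s'", drug)
  out <- data.frame(code = codes, outcome = labels, count = counts,
                    proportion_pct = round_half_up(100 * counts / total, 2),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("outcome_summary", "data.frame")
  out
}
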