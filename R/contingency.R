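#' Build drug-event 2x2 contingency tables
#'
#' For one drug group, tabulates every preferred term (PT) ever reported in
#' the case set against cohort membership. Cohort membership means the case
#' has at least one primary-suspect (PS) mention of the drug group. Cell
#' counts follow the usual disproportionality layout:
#' \describe{
#'   \item{a}{cases in the drug cohort reporting the PT}
#'   \item{b}{cohort cases not reporting the PT}
#'   \item{c}{cases outside the cohort reporting the PT}
#'   \item{d}{cases outside the cohort not reporting the PT}
#' }
#' so that `a + b` is the cohort size, `a + c` the PT total, and
#' `a + b + c + d = N` the deduplicated case total, identically for every PT.
#' The comparator is "all other drugs": the cohort is excluded from c and d.
#'
#' @param cases a `faers_cases` object from [assemble_cases()].
#' @param drug_group drug group id (string) as used in the synonym config.
#' @return data.frame with columns `pt, a, b, c, d, n`, one row per PT,
#'   ordered by decreasing `a`. Empty case set gives a zero-row frame.
#' @seealso [disprop()] which computes all four statistics from these tables.
#' @export
build_tables <- function(cases, drug_group) {
  stopifnot(inherits(cases, "faers_cases"))
  n <- nrow(cases$demo)
  empty <- data.frame(
    pt = character(), a = integer(), b = integer(),
    c = integer(), d = integer(), n = integer(),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(empty)

  cohort_ids <- cohort_primaryids(cases, drug_group)
  n_cohort <- length(cohort_ids)
  ev <- cases$events
  if (nrow(ev) == 0L) return(empty)

  pt_total <- table(ev$pt)
  in_cohort <- ev$primaryid %in% cohort_ids
  a_tab <- table(factor(ev$pt[in_cohort], levels = names(pt_total)))

  a <- as.integer(a_tab)
  tot <- as.integer(pt_total)
  out <- data.frame(
    pt = names(pt_total),
    a = a,
    b = n_cohort - a,
    c = tot - a,
    d = n - n_cohort - (tot - a),
    n = n,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$a, out$pt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# primaryids of cases with >=1 PS mention of the group
cohort_primaryids <- function(cases, drug_group) {
  dr <- cases$drugs
  unique(dr$primaryid[!is.na(dr$drug_group) &
                        dr$drug_group == drug_group &
                        dr$role_code == "PS"])
}

# expected count under row/column independence, the MGPS baseline
expected_count <- function(a, b, c, d) {
  n <- a + b + c + d
  (a + b) * (a + c) / n
}
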