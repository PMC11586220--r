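#' Load a drug synonym configuration
#'
#' Maps each drug group to the generic and brand name strings that identify
#' it in DRUG.drugname. Accepts a named list (group -> character vector) or
#' a YAML/JSON file holding one. Names are matched case-insensitively after
#' whitespace trimming and stripping of a trailing parenthetical strength,
#' so the config can list either case.
#'
#' @param x named list, or path to a YAML/JSON file.
#' @return object of class `drug_synonyms` (named list plus a normalized
#'   lookup table).
#' @export
load_drug_synonyms <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) config_error("synonym config file '%s' not found", x)
    x <- if (grepl("\\.ya?ml$", x, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        config_error("reading YAML synonym configs requires the 'yaml' package")
      }
      yaml::read_yaml(x)
    } else {
      jsonlite::read_json(x, simplifyVector = TRUE)
    }
  }
  if (inherits(x, "drug_synonyms")) return(x)
  if (!is.list(x) || is.null(names(x)) || any(names(x) == "")) {
    config_error("synonym config must be a named list: group -> name strings")
  }
  groups <- rep(names(x), lengths(x))
  keys <- normalize_drug_name(unlist(x, use.names = FALSE))
  dup <- keys[duplicated(keys)]
  conflict <- unique(dup[vapply(dup, function(k) {
    length(unique(groups[keys == k])) > 1
  }, logical(1))])
  if (length(conflict)) {
    config_error("synonym claimed by more than one group: %s",
                 paste(conflict, collapse = ", "))
  }
  keep <- !duplicated(keys)
  out <- list(groups = x,
              lookup = stats::setNames(groups[keep], keys[keep]))
  class(out) <- "drug_synonyms"
  out
}

# canonical form used for matching: trim, strip one trailing
# parenthetical (strength), collapse inner whitespace, uppercase
normalize_drug_name <- function(x) {
  x <- trimws(x)
  x <- sub("\\s*\\([^()]*\\)\\s*$", "", x)
  x <- gsub("\\s+", " ", x)
  toupper(x)
}

#' Normalize a raw drug name to its drug group
#'
#' Case-insensitive, whitespace-trimmed exact match after stripping a
#' trailing parenthetical strength; returns NA for unmatched names.
#'
#' @param raw_name character vector of DRUG.drugname strings.
#' @param synonyms a `drug_synonyms` object or named list (see
#'   [load_drug_synonyms()]).
#' @return character vector of group ids, NA where unmatched.
#' @examples
#' syn <- load_drug_synonyms(list(pitolisant = c("PITOLISANT", "WAKIX")))
#' normalize_drug(c("wakix ", "ASPIRIN"), syn)
#' @export
normalize_drug <- function(raw_name, synonyms) {
  synonyms <- load_drug_synonyms(synonyms)
  unname(synonyms$lookup[normalize_drug_name(raw_name)])
}

#' Deduplicate case versions
#'
#' Spontaneous-report databases carry several versions of the same case
#' (same caseid, increasing version); analyses count each case once. Keeps,
#' per caseid, the row with the highest version, breaking ties by the
#' highest primaryid (compared as zero-padded numerics).
#'
#' @param demo data.frame with columns `caseid`, `primaryid` and
#'   `caseversion` (or `version`).
#' @return list with `kept` (the surviving rows, original order) and
#'   `removed` (count of dropped rows).
#' @export
deduplicate <- function(demo) {
  if (nrow(demo) == 0L) return(list(kept = demo, removed = 0L))
  ver_col <- if ("caseversion" %in% names(demo)) "caseversion" else "version"
  ver <- suppressWarnings(as.numeric(demo[[ver_col]]))
  ver[is.na(ver)] <- -Inf
  pid <- suppressWarnings(as.numeric(demo$primaryid))
  # ids compare as zero-padded numerics; non-numeric ids fall back to
  # lexicographic order
  pid_key <- if (anyNA(pid)) xtfrm(demo$primaryid) else pid
  ord <- order(demo$caseid, -ver, -pid_key)
  first <- !duplicated(demo$caseid[ord])
  keep_rows <- sort(seq_len(nrow(demo))[ord][first])
  list(kept = demo[keep_rows, , drop = FALSE],
       removed = nrow(demo) - length(keep_rows))
}

#' Assemble deduplicated report cases from raw tables
#'
#' The ingest workhorse: deduplicates DEMO to one row per caseid, joins the
#' child tables onto the surviving primaryids, normalizes drug names to drug
#' groups, harmonizes demographics (age units to years, implausible ages
#' > 120 y to missing; sex, reporter occupation and country to explicit
#' `unknown` categories), dedupes reaction PTs within case, restricts
#' outcome codes to the seven-code set, and derives per-mention cumulative
#' dose (dose_amt x administration days when therapy dates and a daily
#' regimen are present, else the reported cumulative field, else missing).
#' Cases with no reaction PTs are dropped and counted.
#'
#' @param tables a `faers_tables` object from [read_faers_tables()], or the
#'   `tables` element of a [generate_dataset()] result.
#' @param synonyms drug synonym config (see [load_drug_synonyms()]).
#' @param role_filter role codes establishing cohort membership; kept as
#'   metadata (cohorts are always defined on PS mentions downstream).
#' @return object of class `faers_cases`: list with `demo`, `drugs`,
#'   `events`, `outcomes` data.frames and a `log` of exclusion counters.
#' @export
assemble_cases <- function(tables, synonyms, role_filter = "PS") {
  if (inherits(tables, "synthetic_faers")) tables <- tables$tables
  synonyms <- load_drug_synonyms(synonyms)
  for (nm in c("DEMO", "DRUG", "REAC")) {
    if (is.null(tables[[nm]]) || nrow(tables[[nm]]) == 0L) {
      stopf("mandatory table '%s' is missing or empty", nm)
    }
  }
  prior_log <- if (!is.null(tables$log)) tables$log else list()

  dd <- deduplicate(tables$DEMO)
  demo_raw <- dd$kept
  kept_ids <- demo_raw$primaryid

  ver_col <- if ("caseversion" %in% names(demo_raw)) "caseversion" else "version"
  age_years <- convert_age_years(demo_raw$age, demo_raw$age_cod)
  demo <- data.frame(
    primaryid = demo_raw$primaryid,
    caseid = demo_raw$caseid,
    version = suppressWarnings(as.integer(demo_raw[[ver_col]])),
    age_years = age_years,
    sex = ifelse(demo_raw$sex %in% c("F", "M"), demo_raw$sex, "unknown"),
    reporter = code_to_reporter(demo_raw$occp_cod),
    country = normalize_country(demo_raw$reporter_country),
    report_year = suppressWarnings(as.integer(substr(demo_raw$fda_dt, 1, 4))),
    stringsAsFactors = FALSE
  )

  drug <- tables$DRUG[tables$DRUG$primaryid %in% kept_ids, , drop = FALSE]
  role <- drug$role_cod
  role[!role %in% c("PS", "SS", "C", "I")] <- NA
  ther <- tables$THER
  cum <- derive_cumulative_dose(drug, ther)
  drugs <- data.frame(
    primaryid = drug$primaryid,
    raw_name = drug$drugname,
    drug_group = normalize_drug(drug$drugname, synonyms),
    role_code = role,
    dose_amt = suppressWarnings(as.numeric(drug$dose_amt)),
    dose_unit = toupper(trimws(drug$dose_unit %||% "")),
    cum_dose = cum$amount,
    cum_dose_unit = cum$unit,
    stringsAsFactors = FALSE
  )

  reac <- tables$REAC[tables$REAC$primaryid %in% kept_ids, , drop = FALSE]
  events <- unique(data.frame(primaryid = reac$primaryid, pt = reac$pt,
                              stringsAsFactors = FALSE))
  events <- events[nzchar(events$pt), , drop = FALSE]

  no_events <- setdiff(demo$primaryid, events$primaryid)
  demo <- demo[!demo$primaryid %in% no_events, , drop = FALSE]
  drugs <- drugs[!drugs$primaryid %in% no_events, , drop = FALSE]

  outcomes <- data.frame(primaryid = character(), outc_cod = character(),
                         stringsAsFactors = FALSE)
  if (!is.null(tables$OUTC) && nrow(tables$OUTC)) {
    oc <- tables$OUTC[tables$OUTC$primaryid %in% demo$primaryid, , drop = FALSE]
    oc <- oc[oc$outc_cod %in% c("DE", "LT", "HO", "DS", "CA", "RI", "OT"), , drop = FALSE]
    outcomes <- data.frame(primaryid = oc$primaryid, outc_cod = oc$outc_cod,
                           stringsAsFactors = FALSE)
  }

  rownames(demo) <- rownames(drugs) <- rownames(events) <- rownames(outcomes) <- NULL
  out <- list(
    demo = demo, drugs = drugs, events = events, outcomes = outcomes,
    role_filter = role_filter,
    log = c(prior_log, list(
      removed_duplicates = dd$removed,
      dropped_no_events = length(no_events),
      unmatched_drug_names = sum(is.na(drugs$drug_group))
    ))
  )
  class(out) <- "faers_cases"
  out
}

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf("faers_cases: %d deduplicated cases (%d drug rows, %d reaction rows, %d outcome rows)\n",
              nrow(x$demo), nrow(x$drugs), nrow(x$events), nrow(x$outcomes)))
  cat(sprintf("  removed duplicate versions: %d; dropped (no reactions): %d\n",
              x$log$removed_duplicates, x$log$dropped_no_events))
  invisible(x)
}

# FAERS age units to years; implausible (> 120 y) to missing
convert_age_years <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(age_cod %||% rep("", length(v))))
  mult <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
            DY = 1 / 365.25, HR = 1 / (24 * 365.25))
  f <- mult[cod]
  f[is.na(f) & nzchar(cod)] <- NA       # unknown unit: treat as missing
  f[!nzchar(cod)] <- 1                   # blank unit: assume years
  out <- v * f
  out[!is.finite(out) | out < 0 | out > 120] <- NA_real_
  out
}

code_to_reporter <- function(code) {
  map <- c(CN = "consumer", HP = "health-professional", LW = "lawyer",
           MD = "physician", OT = "other health-professional", PH = "pharmacist")
  out <- unname(map[toupper(trimws(code))])
  out[is.na(out)] <- "unknown"
  out
}

normalize_country <- function(x) {
  x <- toupper(trimws(x))
  ifelse(grepl("^[A-Z]{2}$", x), x, "unknown")
}

# cumulative dose per drug row: dose_amt x administration days when therapy
# dates and a daily regimen are present; else the reported cumulative field
derive_cumulative_dose <- function(drug, ther) {
  n <- nrow(drug)
  amount <- rep(NA_real_, n)
  unit <- rep(NA_character_, n)
  dose_amt <- suppressWarnings(as.numeric(drug$dose_amt))
  freq <- toupper(trimws(drug$dose_freq %||% rep("", n)))

  days <- rep(NA_real_, n)
  if (!is.null(ther) && NROW(ther) > 0 && all(c("start_dt", "end_dt") %in% names(ther))) {
    key_d <- paste(drug$primaryid, drug$drug_seq)
    key_t <- paste(ther$primaryid, ther$dsg_drug_seq)
    hit <- match(key_d, key_t)
    start <- as.Date(ther$start_dt[hit], format = "%Y%m%d")
    end <- as.Date(ther$end_dt[hit], format = "%Y%m%d")
    days <- as.numeric(end - start) + 1
    days[!is.finite(days) | days <= 0] <- NA_real_
  }

  from_ther <- !is.na(dose_amt) & !is.na(days) & freq == "QD"
  amount[from_ther] <- dose_amt[from_ther] * days[from_ther]
  unit[from_ther] <- toupper(trimws(drug$dose_unit[from_ther]))

  cum_chr <- suppressWarnings(as.numeric(drug$cum_dose_chr %||% rep("", n)))
  use_cum <- !from_ther & !is.na(cum_chr)
  amount[use_cum] <- cum_chr[use_cum]
  unit[use_cum] <- toupper(trimws((drug$cum_dose_unit %||% rep("", n))[use_cum]))
  list(amount = amount, unit = unit)
}
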