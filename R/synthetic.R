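#' Default drug catalog for the synthetic generator
#'
#' Four wake-promoting / anti-cataplectic drug groups with their generic and
#' brand names, mirroring the naming structure of a real spontaneous-report
#' extract (generic, salt form, brand).
#' @return named list: group id -> character vector of name strings.
#' @export
default_drug_catalog <- function() {
  list(
    pitolisant = c("PITOLISANT", "PITOLISANT HYDROCHLORIDE", "WAKIX"),
    sodium_oxybate = c("SODIUM OXYBATE", "LUMRYZ", "XYREM", "XYWAV"),
    solriamfetol = c("SOLRIAMFETOL", "SOLRIAMFETOL HYDROCHLORIDE", "SUNOSI"),
    modafinil = c("MODAFINIL", "PROVIGIL")
  )
}

#' Default event catalog for the synthetic generator
#'
#' A toy MedDRA-like hierarchy: 24 preferred terms (PT), each under one high
#' level group term (HLGT) and one system organ class (SOC). This is a
#' synthetic stand-in for licensed dictionary content.
#' @return data.frame with columns `pt, hlgt, soc`.
#' @export
default_event_catalog <- function() {
  ct <- function(pt, hlgt, soc) data.frame(pt = pt, hlgt = hlgt, soc = soc,
                                           stringsAsFactors = FALSE)
  rbind(
    ct(c("Anxiety", "Panic attack"),
       "Anxiety disorders and symptoms", "Psychiatric disorders"),
    ct(c("Insomnia", "Abnormal dreams", "Middle insomnia", "Initial insomnia",
         "Somnambulism"),
       "Sleep disorders and disturbances", "Psychiatric disorders"),
    ct("Depression", "Depressive mood disorders and disturbances",
       "Psychiatric disorders"),
    ct("Suicidal ideation", "Suicidal and self-injurious behaviour",
       "Psychiatric disorders"),
    ct(c("Headache", "Migraine"), "Headaches", "Nervous system disorders"),
    ct(c("Somnolence", "Hypersomnia"), "Disturbances in consciousness",
       "Nervous system disorders"),
    ct("Seizure", "Seizures", "Nervous system disorders"),
    ct(c("Sleep apnoea syndrome", "Respiratory depression", "Dyspnoea"),
       "Breathing abnormalities",
       "Respiratory, thoracic and mediastinal disorders"),
    ct(c("Nausea", "Vomiting"), "Nausea and vomiting symptoms",
       "Gastrointestinal disorders"),
    ct(c("Diarrhoea", "Constipation"), "Gastrointestinal motility disorders",
       "Gastrointestinal disorders"),
    ct(c("Drug ineffective", "Condition aggravated"),
       "Therapeutic and nontherapeutic responses",
       "General disorders and administration site conditions"),
    ct("Pyrexia", "Body temperature conditions",
       "General disorders and administration site conditions")
  )
}

#' Configuration of the synthetic spontaneous-report generator
#'
#' Declares the study conditions of a simulated reporting database: the drug
#' and event catalogs, baseline drug-event co-reporting rates, planted signal
#' pairs of known strength, the demographic mixture, and the duplication
#' rate. All randomness downstream derives from the single `seed`.
#'
#' @param n_cases number of unique cases (>= 1).
#' @param duplicate_fraction proportion in `[0, 1)` of cases emitted a second
#'   time as a later case version (same caseid, new primaryid).
#' @param drug_catalog named list: drug group -> character vector of generic
#'   and brand names.
#' @param drug_probs probability of each group being the case's
#'   primary-suspect drug; uniform when NULL.
#' @param event_catalog data.frame `pt, hlgt, soc`.
#' @param background_rates baseline per-case probability that a given event
#'   PT is reported; a single number or a drugs x events matrix.
#' @param planted_signals data.frame with columns `drug, event, rr`: for
#'   these pairs the event probability is `background * rr` (rr > 0).
#' @param sex_probs named probabilities for `F, M, unknown` (sum 1).
#' @param age_missing_rate proportion of cases with missing age.
#' @param age_strata_probs probabilities of the child/adult/elderly strata
#'   among cases with known age (sum 1).
#' @param age_ranges list of integer ranges (years) per stratum.
#' @param reporter_probs named probabilities over the reporter occupations
#'   `consumer, health-professional, lawyer, physician,
#'   other health-professional, pharmacist, unknown` (sum 1).
#' @param country_probs named probabilities over ISO-3166 alpha-2 codes (sum 1).
#' @param year_range integer vector `c(first, last)` of FDA receipt years.
#' @param outcome_probs named probabilities over the seven outcome codes
#'   `DE, LT, HO, DS, CA, RI, OT` plus `none` (sum 1); one outcome record is
#'   drawn per case.
#' @param dose_model named list per drug group:
#'   `list(dose_amt =, dose_unit =, duration =c(min, max) days)`.
#' @param secondary_suspect_prob probability a case carries an additional
#'   secondary-suspect (SS) mention of another drug group. How often real
#'   reports list multiple suspect drugs is not well characterized, so it is
#'   a parameter, defaulting low.
#' @param concomitant_rate Poisson mean of concomitant (role C) mentions.
#' @param seed integer root seed.
#' @return validated object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 1000,
                             duplicate_fraction = 0.05,
                             drug_catalog = default_drug_catalog(),
                             drug_probs = NULL,
                             event_catalog = default_event_catalog(),
                             background_rates = 0.02,
                             planted_signals = NULL,
                             sex_probs = c("F" = 0.62, "M" = 0.33, "unknown" = 0.05),
                             age_missing_rate = 0.30,
                             age_strata_probs = c(child = 0.05, adult = 0.80, elderly = 0.15),
                             age_ranges = list(child = c(1, 17), adult = c(18, 59),
                                               elderly = c(60, 95)),
                             reporter_probs = c("consumer" = 0.55,
                                                "health-professional" = 0.15,
                                                "lawyer" = 0.001,
                                                "physician" = 0.20,
                                                "other health-professional" = 0.02,
                                                "pharmacist" = 0.03,
                                                "unknown" = 0.049),
                             country_probs = c(US = 0.85, FR = 0.05, GB = 0.04,
                                               CA = 0.03, DE = 0.02, JP = 0.01),
                             year_range = c(2019, 2023),
                             outcome_probs = c(DE = 0.01, LT = 0.02, HO = 0.12,
                                               DS = 0.02, CA = 0.005, RI = 0.005,
                                               OT = 0.42, none = 0.40),
                             dose_model = NULL,
                             secondary_suspect_prob = 0.10,
                             concomitant_rate = 0.30,
                             seed = 1) {
  if (!is.numeric(n_cases) || length(n_cases) != 1 || n_cases < 1 ||
      n_cases != floor(n_cases)) {
    config_error("'n_cases' must be a positive integer (got %s)", format(n_cases))
  }
  if (!is.numeric(duplicate_fraction) || duplicate_fraction < 0 ||
      duplicate_fraction >= 1) {
    config_error("'duplicate_fraction' must be in [0, 1)")
  }
  if (!is.list(drug_catalog) || is.null(names(drug_catalog)) ||
      any(names(drug_catalog) == "") || any(lengths(drug_catalog) < 1)) {
    config_error("'drug_catalog' must be a named list with >= 1 name per group")
  }
  if (!is.data.frame(event_catalog) ||
      !all(c("pt", "hlgt", "soc") %in% names(event_catalog)) ||
      anyDuplicated(event_catalog$pt)) {
    config_error("'event_catalog' must be a data.frame(pt, hlgt, soc) with unique PTs")
  }
  drugs <- names(drug_catalog)
  events <- event_catalog$pt
  if (is.null(drug_probs)) {
    drug_probs <- stats::setNames(rep(1 / length(drugs), length(drugs)), drugs)
  }
  check_prob_vector(drug_probs, "drug_probs")
  if (!setequal(names(drug_probs), drugs)) {
    config_error("'drug_probs' names must match the drug catalog")
  }
  check_prob_vector(sex_probs, "sex_probs")
  check_prob_vector(age_strata_probs, "age_strata_probs")
  check_prob_vector(reporter_probs, "reporter_probs")
  check_prob_vector(country_probs, "country_probs")
  check_prob_vector(outcome_probs, "outcome_probs")
  if (age_missing_rate < 0 || age_missing_rate > 1) {
    config_error("'age_missing_rate' must be in [0, 1]")
  }

  # background rates to a full drugs x events matrix
  if (is.matrix(background_rates)) {
    if (!identical(dim(background_rates), c(length(drugs), length(events)))) {
      config_error("'background_rates' matrix must be drugs x events")
    }
    bg <- background_rates
  } else if (is.numeric(background_rates) && length(background_rates) == 1) {
    bg <- matrix(background_rates, length(drugs), length(events))
  } else {
    config_error("'background_rates' must be a scalar or drugs x events matrix")
  }
  dimnames(bg) <- list(drugs, events)
  if (any(bg < 0) || any(bg > 1)) config_error("'background_rates' must be in [0, 1]")

  if (is.null(planted_signals)) {
    planted_signals <- data.frame(drug = character(), event = character(),
                                  rr = numeric(), stringsAsFactors = FALSE)
  }
  if (!is.data.frame(planted_signals) ||
      !all(c("drug", "event", "rr") %in% names(planted_signals))) {
    config_error("'planted_signals' must be a data.frame(drug, event, rr)")
  }
  if (nrow(planted_signals)) {
    if (!all(planted_signals$drug %in% drugs)) {
      config_error("planted signal drug not in 'drug_catalog': %s",
                   paste(setdiff(planted_signals$drug, drugs), collapse = ", "))
    }
    if (!all(planted_signals$event %in% events)) {
      config_error("planted signal event not in 'event_catalog': %s",
                   paste(setdiff(planted_signals$event, events), collapse = ", "))
    }
    if (any(planted_signals$rr <= 0)) config_error("planted 'rr' must be > 0")
  }

  if (is.null(dose_model)) {
    dose_model <- lapply(stats::setNames(drugs, drugs), function(d) {
      list(dose_amt = 100, dose_unit = "MG", duration = c(5, 60))
    })
  }
  if (!all(drugs %in% names(dose_model))) {
    config_error("'dose_model' must cover every drug group")
  }
  if (length(year_range) != 2 || year_range[1] > year_range[2]) {
    config_error("'year_range' must be c(first, last) with first <= last")
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    config_error("'seed' must be a single integer")
  }

  # per-(drug, event) probability actually used for sampling
  pmat <- bg
  if (nrow(planted_signals)) {
    for (i in seq_len(nrow(planted_signals))) {
      pmat[planted_signals$drug[i], planted_signals$event[i]] <-
        min(1, bg[planted_signals$drug[i], planted_signals$event[i]] *
              planted_signals$rr[i])
    }
  }

  out <- list(
    n_cases = as.integer(n_cases),
    duplicate_fraction = duplicate_fraction,
    drug_catalog = drug_catalog,
    drug_probs = drug_probs[drugs],
    event_catalog = event_catalog,
    background_rates = bg,
    event_prob = pmat,
    planted_signals = planted_signals,
    sex_probs = sex_probs,
    age_missing_rate = age_missing_rate,
    age_strata_probs = age_strata_probs,
    age_ranges = age_ranges,
    reporter_probs = reporter_probs,
    country_probs = country_probs,
    year_range = as.integer(year_range),
    outcome_probs = outcome_probs,
    dose_model = dose_model,
    secondary_suspect_prob = secondary_suspect_prob,
    concomitant_rate = concomitant_rate,
    seed = as.integer(seed)
  )
  class(out) <- "synthetic_config"
  out
}

# derived per-stage seed so adding a stage does not perturb the others;
# kept inside 32-bit range
stage_seed <- function(root, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root) * 7919 + h * 104729) %% 2147483647)
}

with_stage_seed <- function(root, stage, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stage_seed(root, stage))
  expr
}

#' Generate a synthetic FAERS-style dataset
#'
#' Draws a spontaneous-report database under the configured study
#' conditions. For each case one drug group is drawn as the primary suspect
#' (role PS, exactly one per case); each event PT is then reported with
#' probability `background_rate * rr` for planted (drug, event) pairs and
#' `background_rate` otherwise, independently across PTs, so cases can carry
#' zero, one, or several reactions (zero-reaction cases are later dropped at
#' ingest, as in the real extraction). A configurable fraction of cases is
#' re-emitted as a later version (same caseid, new primaryid, possibly
#' perturbed demographics) to exercise deduplication.
#'
#' Output is deterministic for a fixed seed; each table uses its own RNG
#' stream derived from the root seed.
#'
#' @param config a `synthetic_config`.
#' @return object of class `synthetic_faers`: list with `tables` (the seven
#'   FAERS-style data.frames: DEMO, DRUG, REAC, OUTC, RPSR, THER, INDI) and
#'   `ground_truth` (planted signals, duplicate caseids, per-drug cohort
#'   sizes, case total).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config_error("'config' must be a synthetic_config object")
  }
  n <- config$n_cases
  drugs <- names(config$drug_catalog)
  events <- config$event_catalog$pt

  caseid <- sprintf("%08d", 10000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")

  demo <- with_stage_seed(config$seed, "demo", {
    sex <- sample(names(config$sex_probs), n, TRUE, config$sex_probs)
    sex <- ifelse(sex == "unknown", "", sex)
    known_age <- stats::runif(n) >= config$age_missing_rate
    stratum <- sample(names(config$age_strata_probs), n, TRUE, config$age_strata_probs)
    lo <- vapply(config$age_ranges[stratum], `[`, numeric(1), 1)
    hi <- vapply(config$age_ranges[stratum], `[`, numeric(1), 2)
    age <- ifelse(known_age, floor(stats::runif(n, lo, hi + 1)), NA_real_)
    occp <- sample(names(config$reporter_probs), n, TRUE, config$reporter_probs)
    occp_cod <- reporter_to_code(occp)
    country <- sample(names(config$country_probs), n, TRUE, config$country_probs)
    year <- sample(seq(config$year_range[1], config$year_range[2]), n, TRUE)
    fda_dt <- sprintf("%04d%02d%02d", year,
                      sample(1:12, n, TRUE), sample(1:28, n, TRUE))
    data.frame(primaryid = primaryid, caseid = caseid, caseversion = 1L,
               fda_dt = fda_dt,
               age = ifelse(is.na(age), "", format(age, trim = TRUE)),
               age_cod = ifelse(is.na(age), "", "YR"),
               sex = sex, occp_cod = occp_cod, reporter_country = country,
               stringsAsFactors = FALSE)
  })

  ps_drug <- with_stage_seed(config$seed, "drug-assignment",
                             sample(drugs, n, TRUE, config$drug_probs))

  sample_names <- function(groups) {
    # one brand/generic string per row, drawn within each row's group
    out <- character(length(groups))
    for (d in unique(groups)) {
      i <- which(groups == d)
      nm <- config$drug_catalog[[d]]
      out[i] <- nm[sample.int(length(nm), length(i), replace = TRUE)]
    }
    out
  }
  drug_tab <- with_stage_seed(config$seed, "drug", {
    raw <- sample_names(ps_drug)
    amt <- vapply(config$dose_model, function(m) m$dose_amt, numeric(1))[ps_drug]
    unit <- vapply(config$dose_model, function(m) m$dose_unit, character(1))[ps_drug]
    ps_rows <- data.frame(primaryid = primaryid, caseid = caseid, drug_seq = 1L,
                          role_cod = "PS", drugname = raw,
                          dose_amt = format(amt, trim = TRUE), dose_unit = unit,
                          dose_freq = "QD", cum_dose_chr = "", cum_dose_unit = "",
                          stringsAsFactors = FALSE)
    # optional secondary suspect + concomitants from other groups
    extra <- list()
    ss <- which(stats::runif(n) < config$secondary_suspect_prob)
    if (length(ss) && length(drugs) > 1) {
      shift <- sample.int(length(drugs) - 1, length(ss), replace = TRUE)
      other <- drugs[(match(ps_drug[ss], drugs) + shift - 1L) %% length(drugs) + 1L]
      extra[["ss"]] <- data.frame(
        primaryid = primaryid[ss], caseid = caseid[ss], drug_seq = 2L,
        role_cod = "SS",
        drugname = sample_names(other),
        dose_amt = "", dose_unit = "", dose_freq = "",
        cum_dose_chr = "", cum_dose_unit = "", stringsAsFactors = FALSE)
    }
    ncon <- stats::rpois(n, config$concomitant_rate)
    ci <- rep(seq_len(n), ncon)
    if (length(ci)) {
      cg <- sample(drugs, length(ci), TRUE)
      extra[["con"]] <- data.frame(
        primaryid = primaryid[ci], caseid = caseid[ci],
        drug_seq = 10L + stats::ave(ci, ci, FUN = seq_along),
        role_cod = "C",
        drugname = sample_names(cg),
        dose_amt = "", dose_unit = "", dose_freq = "",
        cum_dose_chr = "", cum_dose_unit = "", stringsAsFactors = FALSE)
    }
    do.call(rbind, c(list(ps_rows), extra))
  })

  reac <- with_stage_seed(config$seed, "reac", {
    p <- config$event_prob[ps_drug, , drop = FALSE]
    hit <- matrix(stats::runif(n * length(events)), n) < p
    idx <- which(hit, arr.ind = TRUE)
    data.frame(primaryid = primaryid[idx[, 1]], caseid = caseid[idx[, 1]],
               pt = events[idx[, 2]], stringsAsFactors = FALSE)[order(idx[, 1]), ]
  })

  outc <- with_stage_seed(config$seed, "outc", {
    code <- sample(names(config$outcome_probs), n, TRUE, config$outcome_probs)
    keep <- code != "none"
    data.frame(primaryid = primaryid[keep], caseid = caseid[keep],
               outc_cod = code[keep], stringsAsFactors = FALSE)
  })

  rpsr <- with_stage_seed(config$seed, "rpsr", {
    code <- sample(c("FGN", "HP", "CSM", "OTH"), n, TRUE, c(0.1, 0.3, 0.5, 0.1))
    data.frame(primaryid = primaryid, caseid = caseid, rpsr_cod = code,
               stringsAsFactors = FALSE)
  })

  ther <- with_stage_seed(config$seed, "ther", {
    dlo <- vapply(config$dose_model, function(m) m$duration[1], numeric(1))[ps_drug]
    dhi <- vapply(config$dose_model, function(m) m$duration[2], numeric(1))[ps_drug]
    dur <- floor(stats::runif(n, dlo, dhi + 1))
    start <- as.Date(paste0(substr(demo$fda_dt, 1, 4), "-01-15")) -
      floor(stats::runif(n, 30, 200))
    data.frame(primaryid = primaryid, caseid = caseid, dsg_drug_seq = 1L,
               start_dt = format(start, "%Y%m%d"),
               end_dt = format(start + dur - 1, "%Y%m%d"),
               stringsAsFactors = FALSE)
  })

  indi <- data.frame(primaryid = primaryid, caseid = caseid,
                     indi_drug_seq = 1L, indi_pt = "Narcolepsy",
                     stringsAsFactors = FALSE)

  # duplicate versions: same caseid, version 2, new primaryid, children copied
  n_dup <- round(config$duplicate_fraction * n)
  dup_caseids <- character(0)
  if (n_dup > 0) {
    dup_idx <- with_stage_seed(config$seed, "duplicates", {
      idx <- sort(sample(n, n_dup))
      perturb <- stats::runif(n_dup) < 0.5
      list(idx = idx, perturb = perturb)
    })
    idx <- dup_idx$idx
    dup_caseids <- caseid[idx]
    pid2 <- paste0(caseid[idx], "2")
    d2 <- demo[idx, ]
    d2$primaryid <- pid2
    d2$caseversion <- 2L
    d2$age[dup_idx$perturb] <- ""
    d2$age_cod[dup_idx$perturb] <- ""
    demo <- rbind(demo, d2)
    copy2 <- function(tab) {
      t2 <- tab[tab$primaryid %in% primaryid[idx], , drop = FALSE]
      if (nrow(t2) == 0) return(tab)
      t2$primaryid <- paste0(t2$caseid, "2")
      rbind(tab, t2)
    }
    drug_tab <- copy2(drug_tab)
    reac <- copy2(reac)
    outc <- copy2(outc)
    rpsr <- copy2(rpsr)
    ther <- copy2(ther)
    indi <- copy2(indi)
  }

  rownames(demo) <- rownames(drug_tab) <- rownames(reac) <- rownames(outc) <-
    rownames(rpsr) <- rownames(ther) <- rownames(indi) <- NULL

  out <- list(
    tables = list(DEMO = demo, DRUG = drug_tab, REAC = reac, OUTC = outc,
                  RPSR = rpsr, THER = ther, INDI = indi),
    ground_truth = list(
      planted_signals = config$planted_signals,
      duplicate_caseids = dup_caseids,
      n_unique_cases = n,
      ps_drug_counts = as.list(table(ps_drug)),
      seed = config$seed
    )
  )
  class(out) <- "synthetic_faers"
  out
}

reporter_to_code <- function(x) {
  map <- c("consumer" = "CN", "health-professional" = "HP", "lawyer" = "LW",
           "physician" = "MD", "other health-professional" = "OT",
           "pharmacist" = "PH", "unknown" = "")
  unname(map[x])
}

#' @export
print.synthetic_faers <- function(x, ...) {
  cat("Synthetic FAERS-style dataset\n")
  for (nm in names(x$tables)) {
    cat(sprintf("  %s: %d rows\n", nm, nrow(x$tables[[nm]])))
  }
  cat(sprintf("  unique cases: %d; duplicated caseids: %d; planted signals: %d\n",
              x$ground_truth$n_unique_cases,
              length(x$ground_truth$duplicate_caseids),
              nrow(x$ground_truth$planted_signals)))
  invisible(x)
}

#' Scheme-implied true reporting odds ratio for a (drug, event) pair
#'
#' The generator plants signals on the risk scale (event probability
#' multiplied by `rr`), while the ROR is an odds ratio estimated on the
#' ingested database, which keeps only cases with at least one reported
#' reaction. Both effects are computable in closed form from the config:
#' expected filtered cell counts are
#' `a* = n pi_D p_DE`, `b* = n pi_D (P1_D - p_DE)`,
#' `c* = sum_{D' != D} n pi_D' p_D'E`, `d* = sum_{D' != D} n pi_D' (P1_D' - p_D'E)`,
#' with `P1_D = 1 - prod_e (1 - p_De)` the probability a case on drug D
#' reports any event; the implied ROR is `(a* d*) / (b* c*)`. It approaches
#' `rr` in the rare-event, no-filtering limit.
#'
#' @param config a `synthetic_config`.
#' @param drug,event the pair.
#' @return the implied ROR (single number).
#' @export
true_ror <- function(config, drug, event) {
  p <- config$event_prob
  pi_d <- config$drug_probs
  p1 <- 1 - apply(1 - p, 1, prod)
  a <- pi_d[drug] * p[drug, event]
  b <- pi_d[drug] * (p1[drug] - p[drug, event])
  others <- setdiff(rownames(p), drug)
  cc <- sum(pi_d[others] * p[others, event])
  dd <- sum(pi_d[others] * (p1[others] - p[others, event]))
  unname((a * dd) / (b * cc))
}

#' Synonym config matching a synthetic catalog
#'
#' @param config a `synthetic_config`.
#' @return named list usable as the `synonyms` argument of
#'   [assemble_cases()] / [normalize_drug()].
#' @export
synthetic_synonyms <- function(config) config$drug_catalog

#' MedDRA-style map matching a synthetic catalog
#'
#' @param config a `synthetic_config`.
#' @return a `meddra_map` built from the config's event catalog.
#' @export
synthetic_meddra <- function(config) {
  new_meddra_map(config$event_catalog, version_label = "synthetic")
}
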