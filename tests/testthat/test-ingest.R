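test_that("read_tables enforces mandatory tables and skips malformed lines", {
  cfg <- tiny_config(n_cases = 100, seed = 3)
  sim <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_faers_ascii(sim, dir)

  # a REAC line with too few fields is skipped and counted
  cat("badline$only-two\n", file = file.path(dir, "REAC.txt"), append = TRUE)
  tabs <- read_faers_tables(dir)
  expect_equal(tabs$log$skipped_lines$REAC, 1L)
  expect_equal(nrow(tabs$REAC), nrow(sim$tables$REAC))

  file.remove(file.path(dir, "DRUG.txt"))
  expect_error(read_faers_tables(dir), "DRUG")
})

test_that("window filtering drops rows by FDA receipt year and reconciles", {
  cfg <- tiny_config(n_cases = 400, seed = 8)
  sim <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_faers_ascii(sim, dir)

  all_years <- read_faers_tables(dir, window = c(2019, 2023))
  expect_equal(all_years$log$outside_window, 0L)

  narrow <- read_faers_tables(dir, window = c(2020, 2021))
  yr <- as.integer(substr(narrow$DEMO$fda_dt, 1, 4))
  expect_true(all(yr >= 2020 & yr <= 2021))
  # conservation: rows in = rows kept + rows outside window
  expect_equal(nrow(narrow$DEMO) + narrow$log$outside_window,
               nrow(sim$tables$DEMO))
  # children restricted to surviving primaryids
  expect_true(all(narrow$REAC$primaryid %in% narrow$DEMO$primaryid))
})

test_that("deduplication keeps the latest version with documented tie-breaks", {
  demo <- data.frame(
    primaryid = c("X1", "X2", "X3", "Y1", "Z1", "Z9"),
    caseid = c("X", "X", "X", "Y", "Z", "Z"),
    caseversion = c(1L, 2L, 3L, 1L, 2L, 2L),
    stringsAsFactors = FALSE
  )
  dd <- deduplicate(demo)
  expect_equal(dd$removed, 3L)
  kept <- dd$kept
  expect_equal(kept$primaryid[kept$caseid == "X"], "X3")   # max version wins
  expect_equal(kept$primaryid[kept$caseid == "Z"], "Z9")   # tie: highest primaryid
  expect_equal(kept$primaryid[kept$caseid == "Y"], "Y1")

  # idempotence and the no-duplicate identity
  dd2 <- deduplicate(dd$kept)
  expect_equal(dd2$removed, 0L)
  expect_equal(dd2$kept, dd$kept)
  expect_equal(deduplicate(demo[0, ])$removed, 0L)
})

test_that("drug-name normalization matches case-insensitively after cleanup", {
  syn <- load_drug_synonyms(list(
    pitolisant = c("PITOLISANT", "PITOLISANT HYDROCHLORIDE", "WAKIX")
  ))
  expect_equal(normalize_drug("WAKIX", syn), "pitolisant")
  expect_equal(normalize_drug("wakix ", syn), "pitolisant")
  expect_equal(normalize_drug("  Pitolisant  Hydrochloride ", syn), "pitolisant")
  expect_equal(normalize_drug("WAKIX (17.8 MG)", syn), "pitolisant")
  expect_true(is.na(normalize_drug("ASPIRIN", syn)))

  expect_error(
    load_drug_synonyms(list(g1 = "WAKIX", g2 = c("wakix", "OTHER"))),
    "WAKIX", class = "pvsignal_config_error"
  )
  # the same synonym twice in one group is not a conflict
  expect_silent(load_drug_synonyms(list(g1 = c("WAKIX", "wakix"))))
})

test_that("case assembly: roles, within-case PT dedup, demographic harmonization", {
  tabs <- make_tables(
    case_drugs = data.frame(
      caseid = c("C1", "C2", "C2", "C3"),
      name = c("DRUG A", "DRUG A", "DRUG B", "DRUG B"),
      role = c("PS", "SS", "PS", "PS"),
      stringsAsFactors = FALSE
    ),
    case_events = data.frame(
      caseid = c("C1", "C1", "C2", "C3"),
      pt = c("Headache", "Headache", "Nausea", "Insomnia"),
      stringsAsFactors = FALSE
    )
  )
  tabs$DEMO$age <- c("480", "4", "130")
  tabs$DEMO$age_cod <- c("MON", "DEC", "YR")
  tabs$DEMO$sex <- c("F", "", "M")
  cases <- assemble_cases(tabs, tiny_synonyms)

  # C2 mentions drugA only as SS: not in drugA's cohort
  expect_equal(build_tables(cases, "drugA")["Headache" ==
                 build_tables(cases, "drugA")$pt, "a"], 1)
  ids_a <- cases$drugs$primaryid[!is.na(cases$drugs$drug_group) &
                                   cases$drugs$drug_group == "drugA" &
                                   cases$drugs$role_code == "PS"]
  expect_equal(ids_a, "C11")

  # duplicated PT within C1 collapses to one event row
  expect_equal(sum(cases$events$primaryid == "C11"), 1L)

  # age units: 480 months = 40 y; 4 decades = 40 y; 130 y -> missing
  expect_equal(cases$demo$age_years, c(40, 40, NA_real_))
  expect_equal(cases$demo$sex, c("F", "unknown", "M"))
})

test_that("cumulative dose derives from therapy dates, then reported field", {
  tabs <- make_tables(
    case_drugs = data.frame(caseid = c("C1", "C2", "C3"),
                            name = "DRUG A", role = "PS",
                            stringsAsFactors = FALSE),
    case_events = data.frame(caseid = c("C1", "C2", "C3"), pt = "Headache",
                             stringsAsFactors = FALSE)
  )
  tabs$DRUG$dose_amt <- c("10", "10", "10")
  tabs$DRUG$dose_unit <- "MG"
  tabs$DRUG$dose_freq <- c("QD", "", "QD")
  tabs$DRUG$cum_dose_chr <- c("", "70", "")
  tabs$DRUG$cum_dose_unit <- c("", "MG", "")
  tabs$THER <- data.frame(
    primaryid = c("C11", "C21"), caseid = c("C1", "C2"), dsg_drug_seq = 1L,
    start_dt = "20210101", end_dt = "20210105",   # 5 administration days
    stringsAsFactors = FALSE
  )
  cases <- assemble_cases(tabs, tiny_synonyms)
  cum <- cases$drugs$cum_dose[match(c("C11", "C21", "C31"), cases$drugs$primaryid)]
  expect_equal(cum, c(50, 70, NA_real_))   # dates*dose, reported field, missing
})

test_that("ingest of a synthetic set reconciles with generator ground truth", {
  cfg <- synthetic_config(n_cases = 1000, duplicate_fraction = 0.1, seed = 21)
  sim <- generate_dataset(cfg)
  cases <- assemble_cases(sim, synthetic_synonyms(cfg))

  # conservation: unique cases = analyzed + dropped-for-no-events
  expect_equal(cases$log$removed_duplicates,
               length(sim$ground_truth$duplicate_caseids))
  expect_equal(nrow(cases$demo) + cases$log$dropped_no_events,
               sim$ground_truth$n_unique_cases)

  # per-drug cohorts equal ground truth restricted to ingested cases
  ps <- sim$tables$DRUG[sim$tables$DRUG$role_cod == "PS", ]
  for (d in names(cfg$drug_catalog)) {
    raw_names <- toupper(cfg$drug_catalog[[d]])
    gt_caseids <- unique(ps$caseid[toupper(ps$drugname) %in% raw_names])
    dr <- cases$drugs
    cohort_pids <- unique(dr$primaryid[!is.na(dr$drug_group) &
                                         dr$drug_group == d &
                                         dr$role_code == "PS"])
    cohort_caseids <- cases$demo$caseid[cases$demo$primaryid %in% cohort_pids]
    expect_equal(sort(cohort_caseids),
                 sort(intersect(gt_caseids, cases$demo$caseid)),
                 label = d)
  }

  # cohorts are disjoint under the one-PS-per-case generator rule
  all_ids <- unlist(lapply(names(cfg$drug_catalog), function(d) {
    dr <- cases$drugs
    unique(dr$primaryid[!is.na(dr$drug_group) & dr$drug_group == d &
                          dr$role_code == "PS"])
  }))
  expect_false(any(duplicated(all_ids)))
})
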