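test_that("config validation rejects bad inputs naming the field", {
  expect_error(synthetic_config(n_cases = 0), "n_cases",
               class = "pvsignal_config_error")
  expect_error(synthetic_config(duplicate_fraction = 1), "duplicate_fraction",
               class = "pvsignal_config_error")
  expect_error(synthetic_config(sex_probs = c(F = 0.5, M = 0.6, unknown = 0.1)),
               "sex_probs", class = "pvsignal_config_error")
  expect_error(
    synthetic_config(planted_signals = data.frame(drug = "nosuch",
                                                  event = "Insomnia", rr = 5)),
    "drug_catalog", class = "pvsignal_config_error")
  expect_error(
    synthetic_config(planted_signals = data.frame(drug = "pitolisant",
                                                  event = "Insomnia", rr = 0)),
    "rr", class = "pvsignal_config_error")
})

test_that("generation is deterministic and produces the configured shape", {
  cfg <- synthetic_config(n_cases = 1000, duplicate_fraction = 0.1, seed = 1)
  sim1 <- generate_dataset(cfg)
  sim2 <- generate_dataset(cfg)
  expect_identical(sim1$tables, sim2$tables)

  demo <- sim1$tables$DEMO
  expect_equal(nrow(demo), 1100)                    # 1000 + 10% duplicates
  expect_equal(length(unique(demo$caseid)), 1000)
  expect_equal(length(sim1$ground_truth$duplicate_caseids), 100)

  # different seed gives different data
  sim3 <- generate_dataset(synthetic_config(n_cases = 1000,
                                            duplicate_fraction = 0.1, seed = 2))
  expect_false(identical(sim1$tables$DEMO, sim3$tables$DEMO))
})

test_that("referential integrity and duplicate-version invariants hold", {
  cfg <- synthetic_config(n_cases = 800, duplicate_fraction = 0.15, seed = 42)
  sim <- generate_dataset(cfg)
  demo <- sim$tables$DEMO
  for (nm in c("DRUG", "REAC", "OUTC", "RPSR", "THER", "INDI")) {
    expect_true(all(sim$tables[[nm]]$primaryid %in% demo$primaryid),
                label = sprintf("%s primaryids in DEMO", nm))
  }
  # duplicated caseids carry strictly increasing versions
  for (cid in sim$ground_truth$duplicate_caseids) {
    v <- sort(as.integer(demo$caseversion[demo$caseid == cid]))
    expect_true(length(v) > 1 && all(diff(v) > 0))
  }
  # exactly one PS mention per case version
  ps <- sim$tables$DRUG[sim$tables$DRUG$role_cod == "PS", ]
  expect_equal(sort(table(ps$primaryid)), sort(table(demo$primaryid)),
               ignore_attr = TRUE)
})

test_that("ASCII round-trip reproduces the dataset and handles empty tables", {
  cfg <- tiny_config(n_cases = 200, seed = 9)
  sim <- generate_dataset(cfg)
  sim$tables$OUTC <- sim$tables$OUTC[0, ]           # force an empty table
  dir <- withr::local_tempdir()
  files <- write_faers_ascii(sim, dir)
  expect_true(all(file.exists(files)))

  # empty OUTC file is a bare header line
  outc_lines <- readLines(files[["OUTC"]])
  expect_equal(outc_lines, "primaryid$caseid$outc_cod")

  back <- read_faers_tables(dir)
  for (nm in names(sim$tables)) {
    orig <- as.data.frame(lapply(sim$tables[[nm]], as.character),
                          stringsAsFactors = FALSE)
    got <- back[[nm]]
    rownames(orig) <- rownames(got) <- NULL
    expect_equal(got, orig, label = nm)
  }
  # DEMO row count equals number of primaryids
  expect_equal(nrow(back$DEMO), length(unique(sim$tables$DEMO$primaryid)))
})

test_that("per-table RNG streams: adding planted signals leaves DEMO unchanged", {
  base <- synthetic_config(n_cases = 300, seed = 5)
  planted <- synthetic_config(n_cases = 300, seed = 5,
                              planted_signals = data.frame(
                                drug = "modafinil", event = "Headache", rr = 8))
  expect_identical(generate_dataset(base)$tables$DEMO,
                   generate_dataset(planted)$tables$DEMO)
})

test_that("scheme-implied ROR is covered by the estimated 95% CI across seeds", {
  # one planted pair at rr = 10 over a 50,000-case database; the generator's
  # own sampling scheme is the oracle for the implied ROR
  cfg0 <- synthetic_config(
    n_cases = 50000, duplicate_fraction = 0, background_rates = 0.01,
    planted_signals = data.frame(drug = "pitolisant", event = "Insomnia", rr = 10),
    seed = 1
  )
  target <- true_ror(cfg0, "pitolisant", "Insomnia")
  covered <- vapply(1:20, function(s) {
    cfg <- synthetic_config(
      n_cases = 50000, duplicate_fraction = 0, background_rates = 0.01,
      planted_signals = data.frame(drug = "pitolisant", event = "Insomnia", rr = 10),
      seed = s
    )
    cases <- assemble_cases(generate_dataset(cfg), synthetic_synonyms(cfg))
    tab <- build_tables(cases, "pitolisant")
    r <- tab[tab$pt == "Insomnia", ]
    est <- compute_ror(r$a, r$b, r$c, r$d)
    est$ror_ci_low <= target && target <= est$ror_ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
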