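test_that("contingency tables match hand counts and brute force", {
  # 5 cases: 2x(D,E), 1x(D,other), 1x(other,E), 1x(other,other)
  tabs <- make_tables(
    case_drugs = data.frame(
      caseid = paste0("C", 1:5),
      name = c("DRUG A", "DRUG A", "DRUG A", "DRUG B", "DRUG B"),
      role = "PS", stringsAsFactors = FALSE
    ),
    case_events = data.frame(
      caseid = paste0("C", 1:5),
      pt = c("Insomnia", "Insomnia", "Nausea", "Insomnia", "Nausea"),
      stringsAsFactors = FALSE
    )
  )
  cases <- assemble_cases(tabs, tiny_synonyms)
  tab <- build_tables(cases, "drugA")
  r <- tab[tab$pt == "Insomnia", ]
  expect_equal(unlist(r[c("a", "b", "c", "d")]), c(a = 2, b = 1, c = 1, d = 1))

  # PT reported by nobody in the cohort: a = 0, b = cohort size
  tb <- build_tables(cases, "drugB")
  expect_equal(tb$a[tb$pt == "Insomnia"], 1)
  tabs2 <- tabs
  tabs2$REAC$pt[tabs2$REAC$caseid %in% c("C4", "C5")] <- "Headache"
  cases2 <- assemble_cases(tabs2, tiny_synonyms)
  t2 <- build_tables(cases2, "drugB")
  r2 <- t2[t2$pt == "Insomnia", ]
  expect_equal(unlist(r2[c("a", "b")]), c(a = 0, b = 2))
})

test_that("tables on a synthetic set equal the nested-loop oracle", {
  cfg <- synthetic_config(n_cases = 1000, duplicate_fraction = 0.05, seed = 13)
  sim <- generate_dataset(cfg)
  cases <- assemble_cases(sim, synthetic_synonyms(cfg))
  drug <- "sodium_oxybate"
  tab <- build_tables(cases, drug)

  # brute force: loop over cases x PTs
  dr <- cases$drugs
  cohort <- unique(dr$primaryid[!is.na(dr$drug_group) & dr$drug_group == drug &
                                  dr$role_code == "PS"])
  n <- nrow(cases$demo)
  for (pt in tab$pt) {
    with_pt <- unique(cases$events$primaryid[cases$events$pt == pt])
    a <- 0L; b <- 0L; c <- 0L; d <- 0L
    for (pid in cases$demo$primaryid) {
      inc <- pid %in% cohort
      ine <- pid %in% with_pt
      if (inc && ine) a <- a + 1L
      else if (inc) b <- b + 1L
      else if (ine) c <- c + 1L
      else d <- d + 1L
    }
    row <- tab[tab$pt == pt, ]
    expect_equal(unlist(row[c("a", "b", "c", "d")]),
                 c(a = a, b = b, c = c, d = d), label = pt)
  }

  # margin conservation: a+b = cohort size, a+c = PT total, N constant
  expect_true(all(tab$a + tab$b == length(cohort)))
  pt_tot <- table(cases$events$pt)[tab$pt]
  expect_equal(tab$a + tab$c, as.integer(pt_tot), ignore_attr = TRUE)
  expect_true(all(tab$n == n))
})

test_that("ROR examples: symmetry, worked table, degenerate cells", {
  r1 <- compute_ror(1, 1, 1, 1)
  expect_equal(r1$ror, 1)
  expect_lt(r1$ror_ci_low, 1)
  expect_gt(r1$ror_ci_high, 1)

  r2 <- compute_ror(10, 20, 30, 6000)
  se <- sqrt(1 / 10 + 1 / 20 + 1 / 30 + 1 / 6000)
  expect_equal(r2$ror, 100)
  expect_equal(r2$ror_ci_low, exp(log(100) - 1.96 * se))   # ~ 43.2
  expect_equal(r2$ror_ci_high, exp(log(100) + 1.96 * se))  # ~ 231.6
  expect_equal(r2$ror_ci_low, 43.2, tolerance = 0.002)
  expect_equal(r2$ror_ci_high, 231.6, tolerance = 0.002)

  r3 <- compute_ror(3, 0, 5, 100)
  expect_equal(r3$zero_flag, "haldane")
  expect_equal(r3$ror, (3.5 * 100.5) / (0.5 * 5.5))

  r0 <- compute_ror(0, 5, 5, 100)
  expect_equal(r0$ror, 0)
  expect_equal(r0$zero_flag, "undefined_ci")
  expect_true(is.na(r0$ror_ci_low))
})

test_that("PRR examples: symmetry, worked table, zero handling", {
  p1 <- compute_prr(1, 1, 1, 1)
  expect_equal(p1$prr, 1)
  expect_equal(p1$chi2, 0)

  p2 <- compute_prr(10, 20, 30, 6000)
  expect_equal(p2$prr, (10 / 30) / (30 / 6030))            # ~ 67.0
  n <- 6060; dev <- abs(10 * 6000 - 20 * 30)
  chi2_expected <- n * (dev - min(n / 2, dev))^2 /
    (30 * 6030 * 40 * 6020)
  expect_equal(p2$chi2, chi2_expected)

  expect_equal(compute_prr(0, 10, 10, 100)$prr, 0)
  p3 <- compute_prr(3, 5, 0, 100)                          # c = 0: +0.5 path
  expect_equal(p3$zero_flag, "haldane")
  expect_equal(p3$prr, (3.5 / 9) / (0.5 / 101))
})

test_that("BCPNN: independence limit, worked formula, asymptotic consistency", {
  # large null table: IC ~ 0
  b0 <- compute_bcpnn(100, 9900, 9900, 980100)
  expect_lt(abs(b0$ic), 0.02)

  # worked closed form against the independent oracle implementation
  b1 <- compute_bcpnn(10, 20, 30, 6000)
  o1 <- oracle_bcpnn(10, 20, 30, 6000)
  expect_equal(b1$ic, o1[["ic"]], tolerance = 1e-12)
  expect_equal(b1$ic_minus_2sd, o1[["ic2sd"]], tolerance = 1e-12)

  # fixed margins ratio RR = 8 at large counts: IC -> log2(8) = 3
  a <- 1e5
  b2 <- compute_bcpnn(a, a, a, 3.2e6 - 3 * a)
  expect_lt(abs(b2$ic - 3), 0.01)
  # and IC -> log2(a N / ((a+b)(a+c))) generally
  expect_lt(abs(b2$ic - log2(a * 3.2e6 / (2 * a * 2 * a))), 0.01)
})

test_that("BCPNN null calibration: IC-2SD > 0 rate under independence <= 5%", {
  set.seed(2024)
  n_tab <- 1000
  N <- 1e6
  p_drug <- 0.004; p_event <- 0.005                 # expected a = 20
  probs <- c(p_drug * p_event, p_drug * (1 - p_event),
             (1 - p_drug) * p_event, (1 - p_drug) * (1 - p_event))
  cells <- stats::rmultinom(n_tab, N, probs)
  res <- compute_bcpnn(cells[1, ], cells[2, ], cells[3, ], cells[4, ])
  expect_lte(mean(res$ic_minus_2sd > 0), 0.05)
})

test_that("statistics are non-decreasing in a with b, c, d fixed", {
  a <- 0:60
  ror <- compute_ror(a, 50, 40, 5000)$ror
  prr <- compute_prr(a, 50, 40, 5000)$prr
  ic <- compute_bcpnn(a, 50, 40, 5000)$ic
  prior <- list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4, p_mix = 1 / 3)
  E <- expected_count_for_test(a, 50, 40, 5000)
  ebgm <- compute_ebgm(a, E, prior)$ebgm
  expect_true(all(diff(ror) >= 0))
  expect_true(all(diff(prr) >= 0))
  expect_true(all(diff(ic) >= 0))
  # EBGM is monotone in a at fixed E; hold E at the a=20 value
  ebgm_fixedE <- compute_ebgm(a, rep(E[21], length(a)), prior)$ebgm
  expect_true(all(diff(ebgm_fixedE) >= 0))
})

test_that("signal thresholds honor inclusive/exclusive boundaries", {
  row <- function(a, ci, prr, chi2, ic2, eb05) {
    data.frame(a = a, ror_ci_low = ci, prr = prr, chi2 = chi2,
               ic_minus_2sd = ic2, eb05 = eb05)
  }
  # everything huge but a = 2: the a >= 3 gate blocks three methods
  s <- classify_signals(row(2, 50, 50, 500, 3, 50))
  expect_false(s$signal)
  expect_false(s$ror_sig); expect_false(s$prr_sig); expect_false(s$bcpnn_sig)
  expect_true(s$mgps_sig)                            # MGPS rule has no a-gate

  # PRR and chi-square thresholds are inclusive at 2 and 4
  s2 <- classify_signals(row(3, 1.5, 2.0, 4.0, 0.5, 2.5))
  expect_true(s2$prr_sig)

  # CI lower limit exactly 1 and IC-2SD exactly 0 are NOT signals (strict >)
  s3 <- classify_signals(row(10, 1.0, 5, 50, 0.0, 2.5))
  expect_false(s3$ror_sig)
  expect_false(s3$bcpnn_sig)
  # EB05 exactly 2 is not a signal
  expect_false(classify_signals(row(10, 2, 5, 50, 1, 2.0))$mgps_sig)

  # all four inclusive-boundary-passing -> combined signal under policy "all"
  s4 <- classify_signals(row(3, 1.0001, 2.0, 4.0, 1e-9, 2.0001))
  expect_true(s4$signal)
  # policy "any"
  s5 <- classify_signals(row(3, 0.5, 2.0, 4.0, -1, 1), policy = "any")
  expect_true(s5$signal)
})

test_that("strong-signal conditions A-D classify and prioritize correctly", {
  base <- data.frame(
    pt = c("P1", "P2", "P3", "P4"),
    ror = c(11, 5, 20, 5), prr = c(12, 5, 20, 5),
    ebgm = c(10.5, 5, 15, 5), ic = c(2, 3.2, 3.5, 2),
    signal = TRUE, stringsAsFactors = FALSE
  )
  s <- strong_condition(base)
  expect_equal(s$strong_condition, c("A", "B", "C", "none"))

  # condition D: own IC strictly above every other drug's for the same PT
  cross <- data.frame(pt = c("P4", "P4"), ic = c(1.5, 1.9),
                      ebgm = c(3, 4), stringsAsFactors = FALSE)
  sd <- strong_condition(base, cross_ic = cross)
  expect_equal(sd$strong_condition[4], "D")
  # C outranks D when both hold
  expect_equal(sd$strong_condition[3], "C")
  # ties are not "strictly exceeds"
  cross_tie <- data.frame(pt = "P4", ic = 2, ebgm = 3)
  expect_equal(strong_condition(base, cross_ic = cross_tie)$strong_condition[4],
               "none")
  # non-signals never get a label
  ns <- base; ns$signal <- FALSE
  expect_true(all(strong_condition(ns)$strong_condition == "none"))
})

test_that("top-k ranking orders by count, then IC, then PT name", {
  sig <- data.frame(pt = c("Zeta", "Alpha", "Beta"), a = c(10, 9, 9),
                    ic = c(1, 3, 2), stringsAsFactors = FALSE)
  top <- rank_top_k(sig, 3)
  expect_equal(top$pt, c("Zeta", "Alpha", "Beta"))
  expect_equal(nrow(rank_top_k(sig, 10)), 3)          # k beyond length
  expect_error(rank_top_k(sig, 0), "k")

  # matches a brute-force full sort on a synthetic run
  set.seed(5)
  big <- data.frame(pt = sprintf("PT%03d", 1:50),
                    a = sample(1:10, 50, TRUE),
                    ic = round(runif(50), 3), stringsAsFactors = FALSE)
  ord <- big[order(-big$a, -big$ic, big$pt), ]
  expect_equal(rank_top_k(big, 15)$pt, head(ord$pt, 15))
})
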