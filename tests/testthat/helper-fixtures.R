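# Shared fixtures and independent oracles. Oracles are written as
# single-purpose functions, separate from the package implementation, so the
# tests check two code paths against each other.

# a small two-drug / three-event study for fast unit tests
tiny_config <- function(n_cases = 500, seed = 1, ...) {
  synthetic_config(
    n_cases = n_cases,
    drug_catalog = list(drugA = c("DRUG A", "BRAND A"),
                        drugB = c("DRUG B")),
    event_catalog = data.frame(
      pt = c("Headache", "Nausea", "Insomnia"),
      hlgt = c("Headaches", "Nausea and vomiting symptoms",
               "Sleep disorders and disturbances"),
      soc = c("Nervous system disorders", "Gastrointestinal disorders",
              "Psychiatric disorders"),
      stringsAsFactors = FALSE
    ),
    background_rates = 0.15,
    seed = seed,
    ...
  )
}

# hand-built raw tables: one row per (case, drug, role) and (case, pt);
# everything else minimal but valid
make_tables <- function(case_drugs, case_events, case_outcomes = NULL,
                        sex = NULL, ages = NULL, years = NULL) {
  ids <- unique(case_drugs$caseid)
  n <- length(ids)
  if (is.null(sex)) sex <- rep("F", n)
  if (is.null(ages)) ages <- rep("", n)
  if (is.null(years)) years <- rep(2021L, n)
  demo <- data.frame(
    primaryid = paste0(ids, "1"), caseid = ids, caseversion = 1L,
    fda_dt = sprintf("%d0615", years),
    age = as.character(ages), age_cod = ifelse(nzchar(as.character(ages)), "YR", ""),
    sex = sex, occp_cod = "CN", reporter_country = "US",
    stringsAsFactors = FALSE
  )
  drug <- data.frame(
    primaryid = paste0(case_drugs$caseid, "1"), caseid = case_drugs$caseid,
    drug_seq = ave(seq_len(nrow(case_drugs)), case_drugs$caseid, FUN = seq_along),
    role_cod = case_drugs$role, drugname = case_drugs$name,
    dose_amt = "", dose_unit = "", dose_freq = "",
    cum_dose_chr = "", cum_dose_unit = "",
    stringsAsFactors = FALSE
  )
  reac <- data.frame(
    primaryid = paste0(case_events$caseid, "1"), caseid = case_events$caseid,
    pt = case_events$pt, stringsAsFactors = FALSE
  )
  tabs <- list(DEMO = demo, DRUG = drug, REAC = reac)
  if (!is.null(case_outcomes)) {
    tabs$OUTC <- data.frame(
      primaryid = paste0(case_outcomes$caseid, "1"),
      caseid = case_outcomes$caseid, outc_cod = case_outcomes$code,
      stringsAsFactors = FALSE
    )
  }
  tabs
}

tiny_synonyms <- list(drugA = c("DRUG A", "BRAND A"), drugB = "DRUG B")

# ---- independent formula oracles ----------------------------------------

oracle_ror <- function(a, b, c, d) {
  if (a == 0) return(c(ror = 0, lo = NA_real_, hi = NA_real_))
  if (b == 0 || c == 0 || d == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(ror = or, lo = or * exp(-1.96 * se), hi = or * exp(1.96 * se))
}

oracle_prr <- function(a, b, c, d) {
  if (a == 0) return(0)
  if (b == 0 || c == 0 || d == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * (c + d)) / ((a + b) * c)
}

oracle_chi2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  if (a > 0 && (b == 0 || c == 0 || d == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  n <- a + b + c + d
  dev <- abs(a * d - b * c)
  corr <- min(n / 2, dev)
  n * (dev - corr)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

oracle_bcpnn <- function(a, b, c, d) {
  n <- a + b + c + d
  gam <- (n + 2) * (n + 2) / ((a + b + 1) * (a + c + 1))
  eic <- log((a + 1) * (n + 2) * (n + 2) /
               ((n + gam) * (a + b + 1) * (a + c + 1))) / log(2)
  vic <- ((n - a + gam - 1) / ((a + 1) * (1 + n + gam)) +
            (n - a - b + 1) / ((a + b + 1) * (n + 3)) +
            (n - a - c + 1) / ((a + c + 1) * (n + 3))) / log(2)^2
  c(ic = eic, ic2sd = eic - 2 * sqrt(vic))
}

# Monte-Carlo oracle for the MGPS posterior (gamma mixture)
oracle_ebgm_mc <- function(a, E, prior, ndraw = 1e7) {
  l1 <- log(prior$p_mix) +
    dnbinom(a, size = prior$alpha1, prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  l2 <- log(1 - prior$p_mix) +
    dnbinom(a, size = prior$alpha2, prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  Q <- 1 / (1 + exp(l2 - l1))
  z <- stats::rbinom(ndraw, 1, Q)
  lam <- ifelse(z == 1,
                stats::rgamma(ndraw, prior$alpha1 + a, rate = prior$beta1 + E),
                stats::rgamma(ndraw, prior$alpha2 + a, rate = prior$beta2 + E))
  c(ebgm = exp(mean(log(lam))), eb05 = unname(stats::quantile(lam, 0.05)))
}

# random non-degenerate 2x2 tables: cells uniform on 0..500, margins positive
random_tables <- function(n_tab, seed = 1) {
  set.seed(seed)
  out <- data.frame(a = integer(), b = integer(), c = integer(), d = integer())
  while (nrow(out) < n_tab) {
    m <- matrix(sample(0:500, 4 * n_tab, replace = TRUE), ncol = 4)
    ok <- (m[, 1] + m[, 2]) > 0 & (m[, 3] + m[, 4]) > 0 &
      (m[, 1] + m[, 3]) > 0 & (m[, 2] + m[, 4]) > 0
    out <- rbind(out, stats::setNames(as.data.frame(m[ok, , drop = FALSE]),
                                      c("a", "b", "c", "d")))
  }
  out[seq_len(n_tab), ]
}

rel_err <- function(x, y) abs(x - y) / pmax(abs(y), .Machine$double.eps)

expected_count_for_test <- function(a, b, c, d) (a + b) * (a + c) / (a + b + c + d)

# a cohort with exact sex counts / ages / outcome records for one drug
cohort_tables <- function(n_f, n_m, n_u = 0, ages = NULL, outcome_counts = NULL) {
  n <- n_f + n_m + n_u
  ids <- sprintf("C%05d", seq_len(n))
  tabs <- make_tables(
    case_drugs = data.frame(caseid = ids, name = "DRUG A", role = "PS",
                            stringsAsFactors = FALSE),
    case_events = data.frame(caseid = ids, pt = "Headache",
                             stringsAsFactors = FALSE),
    sex = c(rep("F", n_f), rep("M", n_m), rep("", n_u)),
    ages = if (is.null(ages)) rep("", n) else c(ages, rep("", n - length(ages)))
  )
  if (!is.null(outcome_counts)) {
    codes <- rep(c("DE", "LT", "HO", "DS", "CA", "RI", "OT"), outcome_counts)
    tabs$OUTC <- data.frame(primaryid = paste0(ids[seq_along(codes)], "1"),
                            caseid = ids[seq_along(codes)], outc_cod = codes,
                            stringsAsFactors = FALSE)
  }
  tabs
}

new_map_for_test <- function() {
  pvsignal:::new_meddra_map(data.frame(
    pt = c("Insomnia", "Anxiety", "Nausea"),
    hlgt = c("Sleep disorders", "Anxiety disorders", "GI symptoms"),
    soc = c("Psych", "Psych", "GI"),
    stringsAsFactors = FALSE
  ))
}
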