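---
title: "Disproportionality signal detection: models, thresholds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: models, thresholds, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event reporting systems (the FDA's FAERS being the
largest public one) collect voluntary reports, each linking one or more
drugs to one or more coded adverse events for a single patient case.
Because there is no denominator of exposed patients, safety surveillance
works by *disproportionality*: a drug-event pair is interesting when the
event is reported with the drug more often than the database as a whole
would predict under independence. `pvsignal` implements the standard
four-method screen used throughout the FAERS-mining literature, together
with the ETL steps (deduplication, drug-name normalization, event-hierarchy
aggregation, cohort summaries) that such an analysis needs, and a synthetic
report generator so the whole pipeline can be validated against known
ground truth.

## Counting unit and the 2x2 table

Everything is counted in *deduplicated cases*, not report rows. FAERS
cases arrive in multiple versions (same `caseid`, increasing version
number); `deduplicate()` keeps the highest version per caseid, breaking
ties by the highest primaryid (compared as zero-padded numerics, with a
lexicographic fallback for non-numeric ids). A case enters a drug group's
cohort iff it carries at least one *primary suspect* (PS) mention of that
group; secondary-suspect and concomitant mentions do not define cohorts.
Cases with no reaction PTs after ingest are dropped and counted: a report
with no event contributes nothing to any contingency table.

For a drug group and an event PT:

|               | event       | no event |
|---------------|-------------|----------|
| drug cohort   | a           | b        |
| all other drugs | c         | d        |

with `N = a + b + c + d` the deduplicated case total. The comparator
excludes the cohort ("all other drugs"), the convention in most published
FAERS analyses.

## The four statistics

**ROR** (reporting odds ratio): `ROR = ad / bc`, with the Woolf 95% CI
`exp(ln ROR ± 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Signal rule: CI lower
limit > 1 (strict) and `a >= 3`.

**PRR** (proportional reporting ratio):
`PRR = [a/(a+b)] / [c/(c+d)]`, with the Yates continuity-corrected
chi-square `N(|ad - bc| - N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]`; the N/2 term
is truncated at `|ad - bc|` so the statistic cannot go negative on
near-null tables. Signal rule: `PRR >= 2`, `chi2 >= 4`, `a >= 3`
(inclusive thresholds).

**BCPNN information component**: the early closed-form formulation with
hyperparameters `gamma11 = 1`, `alpha1 = beta1 = 1`, `alpha = beta = 2`:

```
gamma = (N+2)^2 / ((a+b+1)(a+c+1))
E(IC) = log2 [ (a+1)(N+2)^2 / ((N+gamma)(a+b+1)(a+c+1)) ]
V(IC) = (ln 2)^-2 [ (N-a+gamma-1)/((a+1)(1+N+gamma))
                  + (N-(a+b)+1)/((a+b+1)(N+3))
                  + (N-(a+c)+1)/((a+c+1)(N+3)) ]
```

Signal rule: `IC - 2 sqrt(V) > 0` (strict) and `a >= 3`. The tests verify
the two limiting behaviors that justify the formula: IC near 0 under
independence and IC converging to `log2` of the observed/expected ratio as
counts grow.

**MGPS / EBGM**: the observed count is modelled as Poisson with mean
`lambda * E`, `E = (a+b)(a+c)/N`, and `lambda` carries a two-component
gamma mixture prior. `fit_mgps_prior()` maximizes the marginal
negative-binomial mixture likelihood over the five hyperparameters
`(alpha1, beta1, alpha2, beta2, p)` from the classical start
`(0.2, 0.1, 2, 4, 1/3)`. The optimizer is `optim` L-BFGS-B on
log-transformed shapes/rates and a logit-transformed weight — the same
bounded quasi-Newton search, but far better conditioned than box
constraints on the raw scale. Non-convergence (and the non-identifiable
all-zero-counts case) falls back to the start values with a warning flag.
The prior is fitted once per database on all (PS-drug, PT) pairs with
`a >= 1`; zero cells are excluded because their enumeration over all
drug-by-PT combinations is unbounded. The posterior for one table is again
a two-component gamma mixture; `EBGM = exp(E[log lambda])` via the digamma
function, and `EB05` is the 5th posterior percentile found by bisection on
the mixture CDF to 1e-8 relative tolerance. Signal rule: `EB05 > 2`
(strict; the canonical one-sided-95% screening bound).

A pair is a *positive signal* under the default policy when **all four**
rules fire. Whether published analyses require all four or any one is
rarely stated; conjunction is the conservative default and
`classify_signals(policy =)` exposes `"any"` and `"per-method"` as
sensitivity switches.

### Zero cells

`a = 0` short-circuits: the pair cannot be a signal, ROR/PRR are reported
as 0 and the CI as undefined. For `a > 0` with any zero among b, c, d the
Haldane-Anscombe +0.5 is added to all four cells and the row is flagged
(`zero_flag = "haldane"`), so corrected values are always auditable. The
BCPNN moments need no correction (defined for all valid tables).

### Strong signals

Among positive signals, four conditions grade strength: **A** - ROR, PRR
and EBGM all exceed 10; **B** - IC exceeds 3; **C** - A and B together;
**D** - the drug's signal strength for the PT strictly exceeds every other
drug's for the same PT (among drugs with a positive signal there). Signal
strength for D is IC by default (`strength = "ebgm"` is the alternative),
since IC is the usual cross-drug comparison metric. When several hold the
reported label has priority C > D > A > B, and the full boolean set is kept
alongside. A PT signalled by only one drug satisfies D vacuously; the
booleans let users apply a stricter reading.

## Ingest conventions

* **Window**: filtering is by FDA receipt year (`fda_dt`); therapy dates
  play no role in windowing.
* **Age**: FAERS unit codes YR/DEC/MON/WK/DY/HR are converted to years;
  ages above 120 years are set to missing.
* **Sex / reporter / country**: unmapped or blank codes become an explicit
  `"unknown"` category rather than NA, because the demographic tables
  report Unknown rows.
* **Drug names**: matching is exact after trimming, inner-whitespace
  collapse, uppercasing and stripping one trailing parenthetical (strength
  suffix). No fuzzy matching: a synonym claimed by two groups is a
  configuration error, unmatched names stay unmapped.
* **Cumulative dose**: `dose_amt x administration days` when therapy dates
  and a daily (`QD`) regimen are present; otherwise the reported cumulative
  field; otherwise missing. Dose summaries use the cohort's modal unit and
  count excluded unit mismatches.

## Summaries

Quartiles use linear interpolation between order statistics
(`quantile` type 7); the source tables do not state a convention and this
is R's default. Ratios are rounded half-up to 1 decimal and percentages
half-up to 2 decimals (`round_half_up()`), matching how regulatory tables
are printed - banker's rounding would flip boundary cells. Outcome
proportions divide by the **sum of outcome records**, not the cohort size:
a case reporting two outcome codes contributes twice. This convention was
chosen because it is the only denominator consistent with the published
percentage cells the tests reproduce (e.g. 22 hospitalizations out of 75
outcome records = 29.33%).

## The synthetic generator

`generate_dataset()` emulates the structure the pipeline consumes: seven
FAERS-style tables keyed by primaryid/caseid; demographics drawn from a
configurable mixture (defaults: 30% missing age, 5% missing sex, a
female-predominant sex split, consumer-heavy reporters, US-dominant
countries, receipt years 2019-2023 - the shape of a real
narcolepsy-drug extract); exactly one PS drug per case with optional
SS/concomitant mentions (how often real cases carry multiple suspect drugs
is not well characterized, so `secondary_suspect_prob` is a parameter, not
a constant); per-case event draws; single-draw outcome codes; therapy
episodes driving dose derivation; and a configurable fraction of cases
re-emitted as a second version for the dedup stage to remove. Each table
draws from its own RNG stream derived from the root seed, so adding a
planted signal or another table leaves the other tables byte-identical.

Events are drawn independently per PT with probability
`background_rate * rr` for planted pairs and `background_rate` otherwise.
Two consequences matter for validation:

1. `rr` is a **risk** multiplier, while ROR estimates an **odds** ratio on
   the **ingested** database (cases with >= 1 event). `true_ror()` computes
   the scheme-implied ROR in closed form from the config - odds conversion
   and zero-event filtering included - and the recovery tests check CI
   coverage of that value, not of `rr` itself, which it only approaches in
   the rare-event limit.
2. Cases can draw zero events, as real reports cannot; ingest drops them.
   The generator is a structural emulator, not an epidemiological one: it
   has no reporting-over-time dynamics, no MedDRA coding noise, no
   free-text drug-name variants, no cross-case (fuzzy) duplicates, and
   outcome codes are at most one per case version. Passing tests therefore
   demonstrate correctness of counting, statistics and thresholds - not
   calibration against real reporting behavior.

The validation suite runs the generator at the study scale it is meant to
emulate: 50,000-case databases, a background co-reporting rate of 0.01, a
planted pair at `rr = 10`, 20 seeds for recovery (and 5 seeds for the
null false-positive rate); the MGPS recovery study uses 1e5 cells with
`E ~ Uniform(0.1, 20)`; oracle-equivalence checks use 1,000 random tables
with cells uniform on 0-500, with the Monte-Carlo posterior oracle
(1e7 draws) applied to a 20-table subset.

## Worked example

```{r example}
cfg <- synthetic_config(
  n_cases = 20000, duplicate_fraction = 0.05, background_rates = 0.01,
  planted_signals = data.frame(drug = "pitolisant", event = "Insomnia", rr = 10),
  seed = 42
)
sim <- generate_dataset(cfg)
cases <- assemble_cases(sim, synthetic_synonyms(cfg))
fit <- disprop(cases, "pitolisant", meddra = synthetic_meddra(cfg))
summary(fit)
fit$stats[fit$stats$pt == "Insomnia",
          c("a", "ror", "prr", "chi2", "ic", "ic_minus_2sd", "ebgm", "eb05", "signal")]
```

```{r aggregate}
sig <- fit$stats[!is.na(fit$stats$signal) & fit$stats$signal, ]
aggregate_signals(sig, synthetic_meddra(cfg), level = "SOC")
summarize_outcomes(cases, "pitolisant")
```

## Known limitations

* The statistics assume each case is independent; duplicate-aware
  corrections and record-linkage dedup (beyond caseid versions) are out of
  scope.
* MGPS here is the single-item shrinker; despite the family name it does
  not model drug-drug interaction triples.
* MedDRA content is licensed, so mapping tables are user-supplied; the
  package ships only a synthetic toy hierarchy
  (`default_event_catalog()`).
* Real published signal inventories depend on the full multi-gigabyte
  database and on unstated formula constants; the package validates
  against its own ground-truth generator and closed-form oracles instead.
* Whether SOC/HLGT proportions should weight by case counts or by signal
  counts is ambiguous in the literature; both are available
  (`aggregate_signals(weight =)`), with case counts the default.
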