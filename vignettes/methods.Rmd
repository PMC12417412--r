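---
title: "Disproportionality signal mining on spontaneous-report data: methods and design"
author: "vaersmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal mining: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaersmine)
```

## The problem

Passive surveillance systems such as VAERS collect spontaneous reports of
adverse events following immunization (AEFI). Because there is no exposure
denominator and reporting is voluntary, incidence cannot be estimated;
instead, *disproportionality analysis* asks whether an event is reported
relatively more often with a target vaccine than with all other products in
the same database. `vaersmine` implements that workflow for databases in
the VAERS CSV dialect: ingestion and linkage, descriptive tabulation,
four-method signal detection with false-discovery-rate control, Designated
Medical Event (DME) screening, and complete-case sensitivity analysis. A
synthetic-report generator with planted signal structure makes every stage
testable without the live database.

## The 2x2 table and the four statistics

For each MedDRA Preferred Term (PT), reports are cross-classified against
the target vaccine:

|                    | event     | no event |
|--------------------|-----------|----------|
| target vaccine     | a         | b        |
| all other vaccines | c         | d        |

with $N = a+b+c+d$. At the PT level a report counts once per PT
(`unit = "report"`); for System Organ Class (SOC) aggregation the counting
unit is the distinct (report, PT) pair (`unit = "event"`), which is why SOC
counts can exceed the report total. Both units are exposed in
`buildTables()`.

**ROR** (reporting odds ratio): $\mathrm{ROR} = ad/bc$ with the log-normal
interval $\exp(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$.

**PRR** (proportional reporting ratio):
$\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)}$, accompanied by the Pearson
chi-square on the 2x2 (1 df, no Yates correction — configurable) whose
upper tail supplies the p-value used for multiplicity control. An
algebraic consequence asserted in the tests: on all-positive tables,
$\operatorname{sign}(\mathrm{ROR}-\mathrm{PRR}) =
\operatorname{sign}(\mathrm{ROR}-1)$.

**BCPNN information component**: the posterior expectation of
$\mathrm{IC} = \log_2 \frac{p_{11}}{p_{1\cdot} p_{\cdot 1}}$ under
Beta/Dirichlet priors, in the classical closed form with constants
$\alpha=\beta=2$, $\alpha_1=\beta_1=1$, $\gamma_{11}=1$ and the dependent
$\gamma$ chosen so the prior is centred on independence. The reported lower
bound is $E(\mathrm{IC}) - 2\sqrt{V(\mathrm{IC})}$; all quantities are
finite for every table, including $a=0$.

**MGPS / EBGM**: DuMouchel's empirical-Bayes gamma-Poisson shrinker. The
relative reporting rate $\lambda = a/E$, $E = (a+b)(a+c)/N$, carries the
mixture prior $P\,\Gamma(\alpha_1,\beta_1) + (1-P)\,\Gamma(\alpha_2,\beta_2)$
whose five parameters are fitted by maximizing the marginal
negative-binomial likelihood over all PT cells of the target-vs-rest frame
(`mgpsFit()`, quasi-Newton on log/logit-transformed parameters from the
fixed start $(0.2, 0.1, 2, 4, 1/3)$ — deterministic by construction).
EBGM is the posterior geometric mean $\exp E[\ln\lambda]$ (digamma closed
form); EBGM05 is the 5th percentile of the posterior gamma mixture, solved
numerically to $|\mathrm{CDF}(q) - 0.05| < 10^{-6}$.

### Zero cells and degenerate tables

ROR and PRR receive the Haldane–Anscombe correction (0.5 added to all four
cells) *only* when some cell is zero, so nonzero tables are unbiased; the
Bayesian methods always use raw counts, their priors guaranteeing
definedness. A table with an all-zero margin is undefined and returns NA
with a reason.

### Multiplicity and positivity

Chi-square p-values are Benjamini–Hochberg adjusted across all PTs (and,
separately, across SOCs). Positivity uses the field-standard quartet
(`signalThresholds()`): ROR lower bound > 1 with $a \ge 3$; PRR $\ge 2$
with $\chi^2 \ge 4$ and $a \ge 3$; IC−2SD > 0; EBGM05 > 2. The overall
call requires all four (configurable to any-of) *and* adjusted p $\le$
0.05. Two caveats found while testing are worth recording: the BH *map* is
not idempotent on arbitrary already-adjusted vectors (only on
tie-flattened outputs), and with a target arm that is half the database
$a/E \le 2$, so the EBGM05 > 2 rule can only fire when the target cohort
is embedded in a larger background — which is the intended use.

## The synthetic stated world

`syntheticConfig()` encodes the generator's defaults as the published
composition of the pneumococcal-vaccine VAERS cohort (1990–March 2025):

* sex mix 54.29 / 36.88 / 8.83 per cent (female / male / unknown);
* age bands <18, 18–64, 65–84, ≥85 at their observed conditional mix;
* clinical outcome mix conditional on a documented outcome (recovery
  dominating at 44.2 per cent of all reports);
* dose-number mix conditional on a recorded dose;
* missing-completely-at-random masking at the observed rates — 19.23 per
  cent of ages, 41.45 per cent of dose numbers, 34.22 per cent of clinical
  outcomes;
* onset delays geometric with $p = 0.5$ capped at 365 days, matching the
  day-0 median and the concentration of real onsets near vaccination;
* receive years uniform over 1990–2025.

Each report draws every catalog PT independently; a planted relative rate
$R$ multiplies the PT's background probability in the target arm (clamped
at 1 with a warning), and the drawn set is truncated at a configurable cap
(default 10) before being stored across 5-column symptom rows on write.
The default catalog's background probabilities sum to about 2, giving a
realistic typical PT count per report; reports whose draws all come up
empty carry no symptom rows, because forcing a minimum PT would bias the
marginal frequencies that the recovery tests check. Generation is a pure
function of the config: identical config (seed included) yields
byte-identical CSV output.

What the generator does *not* emulate: duplicate or updated reports,
reporting-delay dynamics, correlated PT co-occurrence, a real MedDRA
hierarchy (the PT→SOC map is flat), and informative (MAR/MNAR)
missingness. A green end-to-end test therefore establishes that the
statistics and plumbing are correct on MCAR-masked independent-draw data,
not that the pipeline is robust to real-world reporting artifacts.

### ROR versus planted relative rate

The generator plants a relative *reporting probability* ratio; ROR
estimates an odds ratio. The two agree only for rare events, so the
parameter-recovery tests plant rates on PTs with background probability
0.002 (about 40 expected target-arm reports at n = 20,000 per arm), where
the Wald interval is in its validity regime and the odds/risk distinction
is negligible. At nominal 95 per cent coverage, a 100-replicate experiment
still carries binomial noise of about two successes; the test suite
records one such near-boundary outcome rather than reselecting seeds.

## Descriptive conventions

Age bands use completed years (17.9 → <18, 18 → 18–64, 65 → 65–84,
85 → ≥85). Onset bins are 0–30 through 181–365 days, with onsets above 365
or missing excluded from bins and from the onset summary statistics. The
six VAERS outcome flags are collapsed by severity priority (died > life
threatening > disability > prolonged hospitalization > hospitalized >
recovered; configurable). An explicit "recovered = N" with no serious flag
is kept as its own *Not recovered* stratum: real cohort tables undersum
their total when this state is folded into N/A, and keeping it separate
lets the printed categories reproduce exactly while the stratification
still partitions. Vaccine tables are dose-level (entries), never
report-level, and dose numbers bin as 1..6, 7+, N/A.

## DME screening and sensitivity analysis

The packaged `dme_list.csv` is a 62-term, user-editable reconstruction of
the public EMA Designated Medical Event list (terms normalized to
uppercase with collapsed whitespace to match VAERS PT conventions).
`screenDme()` returns both every detected DME-listed PT and the
positive-only subset, since a screening protocol may intersect before or
after positivity classification.

`dropMissing()` implements complete-case reruns for age, dose and clinical
outcome. The filter applies to both arms symmetrically — filtering only
the target arm would manufacture disproportion by construction.
`compareRankings()` ranks positive signals by report count then ROR
(mirroring frequency-ordered sensitivity tables) and reports top-k overlap
and signed rank shifts. Under MCAR masking the subset ROR is a consistent
estimate of the full-data ROR, which is what the stability tests verify.

## Numerical choices

* EBGM05 via `uniroot` on the mixture CDF, tolerance $10^{-12}$ on the
  root, bracketed by component gamma quantiles.
* The MGPS likelihood uses a log-sum-exp mixture and maps non-finite
  proposals to a large penalty; optimizer failure falls back to the start
  values with `converged = FALSE` and a warning.
* Printed percentages round half-up to 2 decimals (matching published
  tables; R's banker's rounding would differ on exact halves).
* BH ties are broken by stable input order, which provably does not
  affect the adjusted values.
* Configs are JSON (`jsonlite`); a YAML reader is not available in the
  supported dependency set.

## A worked run

```{r example}
cfg <- syntheticConfig(nTargetReports = 1000, nBackgroundReports = 10000,
                       seed = 7)
vd <- generateDatabase(cfg)
ids <- selectTargetReports(vd, cfg@targetVaccineName)
sig <- detectSignals(vd, ids,
                     ptToSoc = setNames(cfg@ptCatalog$soc_name,
                                        cfg@ptCatalog$pt_name))
head(sig[, c("pt_name", "a", "ror", "prr", "ic", "ebgm",
             "p_adjust", "positive_overall")])
scr <- screenDme(sig, loadDmeList())
scr$positive[, c("pt_name", "soc_name", "a", "ror")]
```

## Known limitations

Single-database, single-target-cohort analyses only: no stratified or
adjusted disproportionality, no time-to-onset signal methods, no
multi-item (interaction) MGPS, no duplicate detection across report ids,
and no causality assessment — a positive disproportionality signal is a
reporting association, not evidence of a causal adverse reaction.
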