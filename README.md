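# vaersmine

Disproportionality signal mining for VAERS-style spontaneous
adverse-event report databases.

## Who this is for

Pharmacovigilance analysts running post-marketing safety surveillance on
passive reporting systems (VAERS and databases in its CSV dialect). Such
systems have no exposure denominator, so safety screening rests on
*disproportionality*: is an adverse event reported relatively more often
with the target vaccine than with all other products in the database?
`vaersmine` packages that workflow end to end — ingestion and linkage of
the yearly `VAERSDATA` / `VAERSVAX` / `VAERSSYMPTOMS` CSV triplets,
descriptive tabulation, four-method signal detection with FDR control,
Designated Medical Event (DME) screening, and missing-data sensitivity
analysis — plus a synthetic-report generator with planted signal
structure, so the whole pipeline is testable offline.

## The statistics

For each MedDRA Preferred Term (PT) a 2×2 table is built (a = target
reports with the event, b = target without, c / d = the comparator arm,
N = a+b+c+d), and four complementary statistics are computed:

- **ROR** = ad/bc, with 95% CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`;
- **PRR** = [a/(a+b)]/[c/(c+d)], with the Pearson χ² (df = 1, no Yates)
  whose p-value is Benjamini–Hochberg adjusted across PTs;
- **BCPNN IC** = posterior expectation of log₂ of the observed-to-expected
  joint reporting probability under Beta/Dirichlet priors, reported with
  its lower bound IC − 2SD;
- **MGPS EBGM** = empirical-Bayes geometric mean of a/E under DuMouchel's
  fitted two-component gamma mixture prior, with the 5th posterior
  percentile EBGM05.

A PT is a positive signal when all four rules fire (a ≥ 3 & ROR lower
bound > 1; PRR ≥ 2 & χ² ≥ 4 & a ≥ 3; IC−2SD > 0; EBGM05 > 2) and the
BH-adjusted p ≤ 0.05; thresholds and the all-of/any-of rule are
configurable. PT-level signals aggregate to System Organ Class level by
occurrence (event) counting.

## A worked example

```r
library(vaersmine)
cfg <- syntheticConfig(nTargetReports = 1000, nBackgroundReports = 10000,
                       seed = 7)
vd  <- generateDatabase(cfg)
ids <- selectTargetReports(vd, cfg@targetVaccineName)
sig <- detectSignals(vd, ids,
                     ptToSoc = setNames(cfg@ptCatalog$soc_name,
                                        cfg@ptCatalog$pt_name))
head(sig[, c("pt_name", "a", "ror", "prr", "ic", "ebgm",
             "p_adjust", "positive_overall")])
#>                   pt_name   a    ror    prr      ic ebgm  p_adjust positive_overall
#> 1            IRRITABILITY 540 23.334 11.273  2.5282 5.74  0.00e+00             TRUE
#> 2                  CRYING 293 11.563  8.468  2.3117 4.95 4.71e-242             TRUE
#> 3 INJECTION SITE ERYTHEMA 190  4.125  3.532  1.5046 2.90  2.08e-60             TRUE
#> 4                 PYREXIA 190  0.964  0.971 -0.0402 0.97  8.11e-01            FALSE
#> 5                ERYTHEMA 186  4.003  3.444  1.4779 2.85  4.08e-57             TRUE
#> 6                HEADACHE 179  0.948  0.957 -0.0588 0.97  7.22e-01            FALSE
```

The generator planted elevated reporting rates on the injection-site and
pediatric-reaction terms; the pipeline recovers them (large `a`, ROR/PRR
well above 1, positive IC, EBGM shrunk toward but above the observed
ratio) while unplanted background terms like pyrexia and headache stay at
the null. Screening the detected signals against the packaged 62-term DME
list isolates the intrinsically serious ones:

```r
screenDme(sig, loadDmeList())$positive[, c("pt_name", "soc_name", "a", "ror")]
#>                           pt_name                               soc_name  a   ror
#> 1             ERYTHEMA MULTIFORME SKIN AND SUBCUTANEOUS TISSUE DISORDERS 19 4.947
#> 2 PRODUCT CONTAMINATION MICROBIAL                         PRODUCT ISSUES  8 8.056
```

The same machinery runs from the shell over a JSON config, on either
simulated or real CSV triplets:

```sh
Rscript inst/cli/vaersmine.R --step all --out run_dir --seed 1
```

which writes the descriptive tables, `signals.csv`, `soc_signals.csv`,
volcano/forest plot data, the DME report, per-field sensitivity tables and
a JSON run manifest.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the complete pipeline (simulate → describe → detect → DME →
sensitivity) on the installed package under the given seed and writes the
JSON acceptance report to `--out`.

## Scope notes

Signal detection on spontaneous reports establishes reporting
associations, not causality. The package deliberately excludes causality
assessment frameworks, stratified/adjusted disproportionality,
time-to-onset methods and cross-report duplicate detection; see the
methods vignette (`vignettes/methods.Rmd`) for the model details, the
synthetic stated world, and known limitations.
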