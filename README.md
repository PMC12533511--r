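# icuqi — computable quality indicators for intensive care medicine

The German DIVI quality indicators for intensive care are published as
clinical narrative. Hospitals that automate them interpret the narrative
differently, and those interpretation differences move measured fulfillment
rates enough to invalidate cross-site benchmarks. `icuqi` is for quality
managers and medical-informatics teams who need *one* unambiguous,
machine-readable reading of the indicators: it bundles a validated
transcription of all 10 DIVI QIs — 31 subindicators (9 structural, 17
process, 5 outcome) — and the tooling to encode, review, and evaluate them.

## The model

Each computable subindicator is a set of population–intervention plans:

* **Population**: a Boolean expression over coded criterion atoms, e.g. for
  QI3a: `intensive care patient ∧ severe ARDS ∧ (oxygenation index < 100) ∧
  invasive ventilation`. Combinators: ALL, ANY, AT LEAST *n*, EXACTLY *n*,
  NOT.
* **Intervention**: frequency actions (per day / per shift / per week /
  within *h* hours of admission / once per stay, possibly negated),
  continuous goals (`Pplat ≤ 30 cm H2O`, `RASS ∈ [−1, +1]`), or rates
  (`blood cultures ≥ 80 per 1000 patient-days`).
* **Evaluation unit**: patient-day, stay, or cohort period (rates), giving
  fulfillment fractions `numerator/denominator` and rates
  `1000 · Σ events / Σ patient-days`.

Every concept is mapped to SNOMED CT or LOINC; six ICU-specific concepts
(BPS, CAM-ICU, ICDSC, VT/IBW, intensivist qualification, daily care
objective) use the supplementary DIVI-QI-S code system. Indicators encode to
CPG-on-EBMonFHIR-shaped FHIR JSON (PlanDefinition / EvidenceVariable /
ActivityDefinition), decode back losslessly, and render into the
human-readable intermediate representation used for clinician review.

## Worked example

```r
library(icuqi)
catalog <- load_default_catalog()

counts_by_type(catalog)
#> structure   process   outcome
#>         9        17         5

unlist(concept_stats(catalog))
#>      unique_concepts mapped_international          custom_divi
#>                   58                   52                    6
#>           pct_mapped
#>                   90

backtranslate("4a")
#>   sub_id plan_id    population_text
#> 1 4a     4a-weaning intensive care patient AND invasive ventilation AND NOT home ventilation
#>   intervention_text
#> 1 1×/day: (weaning ability evaluated OR weaning attempt documented)

cohort <- generate_cohort(sim_config(n_patients = 50, compliance = 0.8, seed = 1))
report <- evaluate_catalog(cohort, catalog, selection = c("2a", "4a", "6b"))
report[, c("sub_id","plan_id","level","unit","denominator","numerator","fraction","rate","pass")]
#>   sub_id           plan_id     level          unit denominator numerator fraction rate pass
#> 1     2a       2a-sedation      plan   PATIENT_DAY         500       460    0.920   NA   NA
#> 2     2a           2a-pain      plan   PATIENT_DAY         500       476    0.952   NA   NA
#> 3     2a       2a-delirium      plan   PATIENT_DAY         500       471    0.942   NA   NA
#> 4     2a              <NA> indicator   PATIENT_DAY         500       407    0.814   NA   NA
#> 5     4a        4a-weaning      plan   PATIENT_DAY         283       228    0.806   NA   NA
#> 6     6b 6b-blood-cultures      plan COHORT_PERIOD         500       410       NA  820 TRUE
```

Reading the report: each of QI2a's three per-shift assessments is fulfilled
on ~92–95% of the 500 patient-days (50 patients × 10 days); the
indicator-level row requires all three on the same day (81%). QI4a applies
only to ventilated patients without home ventilation (283 patient-days in
its denominator). QI6b is a cohort rate — here 820 blood cultures per 1000
patient-days, passing the ≥ 80 threshold (the generator interprets
compliance 0.8 as a 0.8/day event probability; use `generate_rate_cohort()`
for calibrated rates).

The same pipeline is scriptable from the shell:

```sh
Rscript -e 'icuqi::qi_cli()' catalog stats
#> 58 unique concepts, 52 mapped to SNOMED/LOINC (90%), 6 custom DIVI-QI-S
Rscript -e 'icuqi::qi_cli()' encode --all --out fhir/
Rscript -e 'icuqi::qi_cli()' backtranslate --in fhir/4a
Rscript -e 'icuqi::qi_cli()' simulate --config sim.json --out events.jsonl
Rscript -e 'icuqi::qi_cli()' evaluate --events events.jsonl --ids 2a,3a --out report.json
```

## Package layout

* `R/` — indicator model, terminology registry, bundled DIVI catalog, FHIR
  codec, back-translation grammar, fulfillment engine, cohort generator, CLI.
* `inst/extdata/` — compiled catalog JSON and per-system code-system files
  (regenerable via `catalog_write_json()` / `write_code_systems()`).
* `vignettes/computable-icu-quality-indicators.Rmd` — model semantics,
  transcription decisions, generator assumptions and limitations.
* `tests/testthat/` — unit, property and acceptance suites.
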