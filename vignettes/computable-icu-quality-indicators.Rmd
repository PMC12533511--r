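---
title: "Computable ICU quality indicators: model, semantics, and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computable ICU quality indicators: model, semantics, and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icuqi)
```

## The problem

Quality indicators (QIs) for intensive care medicine — published by the
German Interdisciplinary Association of Critical Care and Emergency Medicine
(DIVI) — are written as clinical narrative. Every hospital that wants to
monitor them automatically must first interpret that narrative, and small
interpretation differences ("once per shift" — which shifts? "tidal volume
6–7 mL/kg" — of what weight?) change the measured fulfillment rates enough
to make cross-site benchmarks meaningless.

`icuqi` ships a fully computable transcription of the 10 DIVI QIs,
decomposed into 31 separately measurable subindicators (9 structural, 17
process, 5 outcome), together with:

* a **formal model** — Boolean population criteria over coded medical
  concepts, plus interventions that are either frequency-based actions,
  continuously applicable value goals, or per-1000-patient-day rates;
* a **terminology registry** mapping every concept to SNOMED CT or LOINC,
  with a six-code supplementary system (DIVI-QI-S) for the intensive-care
  notions those vocabularies lack;
* a **FHIR codec** emitting and consuming CPG-on-EBMonFHIR-shaped
  `PlanDefinition` / `EvidenceVariable` / `ActivityDefinition` JSON;
* a **back-translator** producing the human-readable intermediate
  representation used for clinician review, with a strict parser that
  round-trips it;
* a **fulfillment engine** evaluating the indicators against patient event
  streams; and
* a **seeded synthetic cohort generator** that makes every evaluation path
  testable without clinical data.

Structural indicators (SOP availability, staffing) are carried as narrative
only: they are not computable from clinical data and are excluded from
encoding and evaluation by design.

## The indicator model

A *population* is a Boolean expression over criterion atoms. An atom names a
concept and optionally constrains its numeric value (`oxygenation index <
100`). Combinators are `ALL`, `ANY`, `AT_LEAST n`, `EXACTLY n`,
`ONE_OR_MORE` and `NOT`; `ONE_OR_MORE` is implemented as the logically
identical `AT_LEAST 1`.

An *intervention* combines items of three kinds:

* **actions** with a timing — `PER_DAY(n)`, `PER_SHIFT` (morning
  06:00–14:00, afternoon 14:00–22:00, night 22:00–06:00 of the next day),
  `PER_WEEK`, `WITHIN_HOURS_OF_ADMISSION(h)`, `ONCE_PER_STAY`, optionally
  negated ("no transfer with ventilation at home");
* **goals** — a comparator on a measured value that must hold continuously
  (`plateau pressure ≤ 30 cm H2O`);
* **rates** — a numerator concept per 1000 patient-days with an optional
  threshold (`blood cultures ≥ 80 per 1000 patient-days`).

Each subindicator carries one or more *plans* (population–intervention
pairs) with an explicit evaluation unit: `PATIENT_DAY`, `STAY`, or
`COHORT_PERIOD` for rates. The unit is data, not inference: the source
narrative never states denominators, so keeping them editable keeps
disputes visible.

```{r}
catalog <- load_default_catalog()
counts_by_type(catalog)
backtranslate("3a")
```

## Transcription decisions

Where the two published tables disagree, the clinician-approved
operationalization (the back-translation table) supplies the executable
value and the divergent overview value is kept in the indicator's notes:

* tidal volume: "6–7 mL/kg" operationalized as **≤ 6 mL/kg ideal body
  weight**;
* hand disinfectant: ">80–100 L" operationalized as **≥ 80 L per 1000
  patient-days**;
* QI7b population: obesity is defined as BMI ≥ 30 kg/m², so the population
  bound is **BMI < 30** (the overview prints ≤ 30);
* QI7a uses the narrower **enteral** nutrition wording;
* QI5's sub-id ordering differs between the tables; ids follow the overview
  (5b disinfectant, 5c device infections, 5d ventilator-associated
  pneumonia), and the notes flag the discrepancy.

Three modeling points deserve mention:

* **QI7b's goal has no constant threshold**: sufficient calorie intake means
  intake ≥ the *individual* calorie requirement. Goals therefore accept a
  reference concept as threshold; the comparator is applied against the
  day's latest value of the referenced concept.
* **QI8's population** ("length of stay > 72 hours") has no length-of-stay
  concept in the terminology table. It is operationalized as an atom on the
  ICU-stay concept whose stay-interval event carries the length of stay in
  hours — a quantity any admission system can compute.
* **QI5c/5d have no published bound** ("low number of…"); they are computed
  as rates per 1000 matching patient-days and reported without pass/fail.
  Inventing a bound would misrepresent the source.

## Semantic annotation

Every concept carries one or more codings; 52 of the 58 unique
(system, code) pairs map to SNOMED CT or LOINC, the remaining 6 — scores and
roles specific to intensive care (BPS, CAM-ICU, ICDSC, tidal volume per
ideal body weight, the intensivist qualification, daily care objectives) —
live in DIVI-QI-S. One SNOMED code ("Indication of", 230165009) is
deliberately shared by the device-indication and antibiotic-indication
concepts and counts once:

```{r}
unlist(concept_stats(catalog))
```

Two oddities are transcribed as printed and flagged in source comments: the
RASS row's 16-digit SNOMED code and the peak-inspiratory-pressure row whose
OMOP id equals its code.

## FHIR shape

Each subindicator becomes one Recommendation `PlanDefinition`; each plan a
RecommendationPlan `PlanDefinition` referencing a
RecommendationEligibilityCriteria `EvidenceVariable` (the population as
`characteristic` elements, negation via `exclude`, nesting via
`definitionByCombination`) and, per frequency action, a RecommendationAction
`ActivityDefinition` with a FHIR `Timing`. Per-shift actions expand to three
ActivityDefinitions (morning/afternoon/night, `when` = MORN/AFT/NIGHT), so
QI2a — three assessments once per shift — yields exactly 9. Continuous goals
and rates become `goal` elements of the RecommendationPlan; rates carry an
extension fixing the 1000-patient-day denominator.

The emitted JSON follows the element names of the implementation guide and
pins its profile canonicals (v1.2.0) in `meta.profile`, but conformance
against the official validator is not asserted — the guarantee is the
documented shape plus the round-trip `decode(encode(x)) = x`, which holds
for all 22 process/outcome subindicators. Output is canonical (sorted keys,
two-space indent, UTF-8), so encoding is byte-deterministic. Internal
references use relative ids (`PlanDefinition/3a-tv`), a choice the source
leaves open.

## The intermediate representation

Statements are built only from concept display names, connectors AND/OR/NOT,
comparator symbols, ranges (`-1 to 1`), timing prefixes (`1×/day:`,
`1×/shift:`, `within 24 h of admission:`, `never during stay:`), the goal
marker `(continuous)` and the rate marker `per 1000 patient-days`. The
grammar is deliberately strict:

* mixed AND/OR without parentheses is a parse error — there is no implicit
  precedence;
* nested combinations are always parenthesized on output, so output is
  always re-parseable;
* unknown concept names fail with the token position;
* paired one-sided bounds on one concept (`RASS ≥ -1 AND RASS ≤ 1`) are
  normalized into a single range, matching the catalog's model form.

Round-trip identity (render → parse → identical model) is tested across the
whole catalog. English display names are the rendering vocabulary; German
originals are out of scope.

## Evaluation semantics

Decisions the narrative leaves open, fixed here and applied uniformly:

* **Patient-day** = calendar day overlapping the stay (timezone-naive site
  timestamps); admission and discharge days count in full, except that a
  discharge at exactly midnight does not open a new day.
* **Concept matching** is exact code equality over all of a concept's
  codings; no hierarchy expansion. Sites are expected to map local data to
  catalog codes.
* **Comparators require an exact unit match**; events without a value or
  with another unit are ignored. Units are opaque strings — the indicators
  fix their units, so conversion is out of scope.
* **Goals**: a day is fulfilled iff at least one value-bearing matching
  event exists that day *and* every such value satisfies the comparator. A
  goal without a measurement is **not** fulfilled — quality cannot be
  demonstrated without measurement.
* **Per-shift actions** apply only to shift windows lying fully inside the
  stay; a day with no fully contained window leaves the denominator. The
  night shift of day *d* is `[d 22:00, d+1 06:00)`: an event at 02:00
  satisfies the *previous* day's night shift and no shift of its own day.
* **Stay-level plans** establish their population on the admission day;
  admission-window actions need a matching event within `h` hours
  (boundary inclusive), negated actions need zero matching events in the
  stay, weekly actions need one event in every started 7-day block since
  admission including the final partial block.
* **Rates** are `1000 × numerator / matching patient-days`, where an event
  contributes its numeric value if it has one (disinfectant liters) and 1
  otherwise (blood-culture counts).
* Indicators with several plans (QI2a, QI2b) additionally report an
  indicator-level row: a day counts as fulfilled only if all plans are
  fulfilled on it.

## The synthetic cohort: what it emulates and what it does not

The generator's world is deliberately simple: all patients are admitted at
00:00 of one start date; stay lengths are fixed or geometric (default mean
7 days, the order of magnitude of ICU stays); population attributes are
independent Bernoulli draws with defaults chosen as plausible ICU
prevalences (50% ventilated, 50% of those with severe ARDS, 70% with an
invasive device, 50% on antibiotics, 5% pre-existing home ventilation, 15%
immobilization orders, 30% obesity, 40% expected insufficient intake with
15% enteral contraindications). Compliance is drawn independently per
evaluation unit — one draw per indicator-day, -shift-set or -stay — with no
temporal autocorrelation. Non-compliant goal values sit exactly one
resolution step outside the boundary (RASS 2, pain 4, plateau 31 cm H2O),
so comparator edges are exercised on every run.

Concept-sharing subindicators cannot be planted independently: a weekly
family interview in days 1–3 would also satisfy the 72-hour first-interview
window, and any day-1 mobilization serves both the 24-hour and the daily
mobilization indicator. The generator therefore lets one per-stay draw
govern QI8a and QI8b jointly, and lets the QI9a draw govern day 1 of QI9b.
Consequently **exact** compliance recovery is guaranteed for uniform
compliance maps (the configuration the acceptance tests use); heterogeneous
maps are recovered approximately, with the shared units diluting the
difference by ~1/stay-length. Rate-type subindicators interpret compliance
as a per-day event probability; calibrated rate targets use the separate
Poisson-process generator.

A green test on this cohort establishes that the engine computes the
declared semantics correctly and recovers planted parameters. It does not
establish clinical realism: no case-mix, circadian documentation patterns,
measurement error, or correlated compliance — real fulfillment rates will
differ.

## Numerical and degenerate-input choices

* Timestamps are parsed as UTC; day arithmetic never crosses DST.
* Empty denominators yield `NA` fractions with denominator 0, never errors.
* `validate_catalog` and `validate_bundle` return violations as data and
  never raise on well-formed input.
* Geometric stay lengths are `1 + rgeom(1/mean)`, so every stay has at
  least one patient-day.
* Canonical JSON uses `digits = NA` (full precision) and sorted keys.

## Known limitations

* FHIR output is shape-compatible, not validator-certified, against the
  implementation guide.
* No SNOMED hierarchy reasoning and no unit conversion — both deliberate.
* QI2b is evaluated literally: clinically sanctioned deep sedation still
  counts as out-of-range, as the source defines no exception.
* QI3d (individualized PEEP) has no reviewed operationalization; it is
  carried as a daily documentation action and flagged open in its notes.
* Device-infection indicators take coded infection events as input; no
  surveillance case definitions are applied.
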