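---
title: "A sample-communication format for biobanks: schema, generator and query engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A sample-communication format for biobanks: schema, generator and query engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioscoop)
```

## The problem

Biobanks store biological samples together with rich donor phenotype
and medical data, and research increasingly requires locating samples
*across* institutions. Each institution's information system, however,
describes donors and samples in its own vocabulary and units — the
classic temperature problem: Kelvin, Celsius and Fahrenheit all encode
the same quantity, yet naive exchange of the numbers is meaningless.
A communication format fixes one canonical representation so that a
record means the same thing everywhere. This package implements such a
format end to end: a concrete record schema with validation, the
CSV-to-JSON ingest path, a deterministic mock-cohort generator for
testing, and an in-memory Solr-style search engine over record sets.

## The record model

One record is one flat JSON document per donor–sample pair. Flatness is
a deliberate choice: sample search operates on sample-level documents,
and a flat document maps one-to-one onto both a CSV row and a search
engine's field view. The fields:

* **Identifiers and provenance** — `donor_id`, `collection_id`,
  `sample_id`, an ISO 8601 `timestamp` (day precision) for the
  measurement/event date, and `data_source`
  (`donor_questionnaire` / `medical_record` / `physical_measurement`).
* **Donor phenotype** — `birth_date`; free-text `birth_place` and
  `residence_place` ("City, Country" by convention); `sex`
  (male/female/other/unknown); free-text `ethnic_origin`; `skin_tone`
  as a Fitzpatrick-style ordinal I–VI (an ordinal enum keeps range
  queries meaningful even though no scale is mandated for the field);
  `hair_colour`, `eye_colour`, `blood_group` from fixed catalogues.
* **Anthropometry** — `height_cm`, `weight_kg`, `waist_cm`, `hip_cm`
  (centimetres/kilograms fixed as the canonical units), an `extras`
  map for additional measurements, and the derived indices `whr`,
  `bmi`, `ci`.
* **Medical events** — a list of ICD-10-coded events
  (`icd10_code` matching `^[A-Z][0-9]{2}(\.[0-9]{1,2})?$`,
  `event_type` disease/procedure, optional `event_date`). Codes are
  validated by pattern only: a full ICD-10 code list is an external
  vocabulary, and pattern validation keeps the package self-contained
  while catching the common transcription errors.
* **Sample** — `material_form` (whole blood, serum, plasma, DNA, RNA,
  saliva, tissue, urine, other).

On disk the JSON uses lowerCamelCase names (`donorId`, `birthDate`,
`heightCm`, ...); in R the records are named lists with snake_case
names. A machine-readable JSON Schema (draft 2020-12) ships in
`inst/extdata/bioscoop-schema.json` and is the single source of truth
for required fields, enum catalogues, the ICD-10 pattern and the
positivity bound; the validator loads it at run time. Rules JSON Schema
cannot express are implemented directly: birth date not after the
record timestamp, event dates not before birth, `sample_id` uniqueness
across a set (which also guarantees unique (donor, sample) pairs), and
agreement of stored derived indices with recomputation.

### Derived indices

The format names three indices and this package adopts their standard
definitions: WHR = waist/hip, BMI = weight/height², CI (the
Rohrer/ponderal corpulence index) = weight/height³, with heights
converted to metres for BMI and CI. Whether a given deployment's CI is
Rohrer's index is a documented assumption — the definition is isolated
in `corpulence_index()` so a divergent convention could be swapped in.
`enrich_record()` fills absent derived values from raw measurements;
a stored value that disagrees with recomputation is *flagged*
(`derived_inconsistent`), never overwritten — exchange software must
not silently alter payloads.

```{r}
bmi(70, 175)
corpulence_index(70, 175) * 1.75  # equals the BMI: ci * height_m = bmi
```

### Canonical form

Round-trip guarantees need byte-stable representations, so every valid
record has exactly one canonical form: dates zero-padded ISO, enums in
catalogue case (lower-case except blood group and skin tone), strings
trimmed, numbers rounded to 6 decimal places, keys sorted, and empty
containers dropped (there is deliberately no "present but empty"
state — it could not be distinguished from absence after a CSV round
trip). Canonicalization is idempotent, and derived-vs-recomputed
agreement is assessed *after* canonicalization at relative 1e-6 —
comparing a 6-decimal stored value against an unrounded recomputation
would spuriously fail for small WHR values, where 6-decimal rounding
alone can exceed 1e-6 relative.

Validation reports never throw on content: every broken (record, rule)
pair becomes one row of a `ValidationReport`, ordered by
(record_index, path, rule_id), and each rule has a targeted mutation in
the test-suite proving it fires alone. For performance, `validate_records()`
first runs a vectorized column-wise screen restating every rule; only
sets the screen cannot certify as clean go through the slower
per-record reporting pass, which remains the authority on violations.

## The CSV ingest path

Biobank test sets start life as spreadsheets, so the ingest path is
CSV → records → JSON. CSV is fixed to RFC 4180 (quoted fields may
contain delimiters, doubled quotes and newlines; UTF-8, BOM tolerated);
the reader is a small state machine because the error contract —
ragged rows reported by 1-based data-row number — is not available
from base readers. Conversion is driven by an explicit
`ColumnMapping` (column → field path, date format, missing tokens),
shipped as `inst/extdata/default-mapping.yaml`, rather than
header-name guessing: reproducibility beats convenience here. Two
schema-typed composite cells carry the repeated blocks:
`medicalEvents` as `CODE|type|date;...` and `extras` as
`name=value;...` — the narrowest encoding that lets the full record
survive a CSV round trip.

Malformed rows are skipped-and-reported, not fatal: real biobank
exports are dirty, and the report preserves auditability while the
valid subset flows through (`records out + rows rejected = rows in`).
How a production system should treat malformed rows is genuinely open;
skip-and-report was chosen because aborting a 100k-row export over one
bad date helps nobody, and silently dropping rows without a report is
worse.

## The mock-cohort generator

`generate_cohort()` emulates a hand-prepared test set: 200 records by
default, mimicking samples from 200 mock donors, with every field
populated. Design decisions, fixed once:

* All randomness flows from one integer seed through a single RNG
  (Mersenne-Twister, rejection sampling); identical configs are
  byte-identical after serialization, distinct seeds give distinct
  cohorts, and the caller's RNG state is untouched.
* Values are drawn **uniformly** from packaged pools (places —
  including "Gdansk, Poland" so the stock phrase query matches real
  records — ethnic origins, ICD-10 examples, material forms) and from
  plausible adult ranges for anthropometry: height 140–210 cm, weight
  40–150 kg, waist 50–150 cm, hip 60–160 cm, measured to 0.1.
* Each record carries 0–5 medical events with dates between birth and
  the record timestamp; derived indices are computed from the drawn
  measurements at canonical precision, so generated cohorts validate
  by construction.
* IDs are zero-padded (`DON-0001`, `SAM-0001`); `missing_rate`
  (default 0) can thin optional fields without ever breaking validity.

What the generator does **not** emulate: joint structure of real
populations — no sex-specific anthropometry, no comorbidity
correlations, no realistic ICD-10 frequencies, and waist/hip are drawn
independently so WHR spans a wider range than any clinic would see.
Passing tests therefore demonstrate the *mechanics* (schema, round
trips, query semantics) on schema-shaped data, not statistical realism.

## The query engine

The search grammar is the familiar Solr basic syntax:

```
query  := clause (("AND" | "OR") clause)*      # equal precedence, left-assoc
clause := ["NOT"] ( "(" query ")" | term )
term   := field ":" ( bare | "phrase" | "[" lo " TO " hi "]" )
```

`gender` aliases the questionnaire's `sex` field (search idiom vs.
collection idiom); snake_case spellings are accepted. Semantic
decisions, each a deliberate divergence from a full Solr deployment:

* Matching is exact full-string and case-insensitive, not
  tokenized/stemmed. For the catalogue-valued and phrase fields this
  behaves identically to Solr; it removes analyzer configuration as a
  source of silent divergence.
* Ranges `[lo TO hi]` are inclusive; `*` opens an end; numeric fields
  compare numerically, everything else lexicographically (dates are
  ISO strings, so lexicographic *is* chronological). Exclusive `{ }`
  bounds are reserved and rejected. Inverted numeric bounds are a
  parse error.
* Mixing `AND` and `OR` at one level without parentheses is rejected.
  Lucene's boolean operators are notoriously non-boolean; in a
  medical-sample setting a silently mis-grouped cohort is worse than
  an error message.
* A record lacking a queried field never matches a positive term but
  does match its negation: `NOT` is complement over the whole corpus,
  matching Lucene's missing-field behaviour.
* Unknown field names are hard errors — typos must be loud.
* Bare juxtaposition (`sex:male bmi:[18 TO 23]`) is rejected rather
  than guessing a default operator, since the default is
  deployment-configurable in real engines.

Evaluation is implemented twice, on purpose. `evaluate_query()` is the
engine: per-field value columns and set algebra (intersection, union,
complement) over record indices. `brute_force_filter()` is an
independent oracle: a per-record recursive truth evaluation of the AST
with its own scalar comparison code and no set operations. The
test-suite and the acceptance script assert their agreement on
thousands of randomly generated query/cohort pairs; boolean-algebra
properties (idempotence, double negation, De Morgan) and range
monotonicity are property-tested on top.

```{r}
cohort <- generate_cohort(cohort_config(n_records = 50, seed = 7))
evaluate_query("gender:male AND bmi:[18 TO 23]", cohort)$total
brute_force_filter("gender:male AND bmi:[18 TO 23]", cohort)$total
```

## Numerical and interface choices

* Numbers are rounded only at canonicalization (6 decimals), never
  inside the index computations; CSV cells print numbers with
  `as.character()`, whose 15-significant-digit output parses back to
  the identical double.
* Date validity is checked arithmetically (Gregorian month lengths,
  leap rule) — `strptime` differs across platforms on invalid-date
  rollover and is far slower in per-record loops.
* All indices exposed by the package — validation `record_index`,
  result-set `matched`, event positions inside violation paths — are
  1-based, following R convention.
* Problem sizes in the test-suite (cohorts of 200 for the workflow
  checks, 20 seeds for pipeline closure, 1000 query/cohort pairs for
  oracle equivalence, smaller cohorts inside property loops) were
  chosen to exercise the contracts densely while keeping the default
  test run fast.

## Known limitations

* The attribute catalogue covers the fields enumerated for the
  reference test workflow plus the `extras` map; a production
  deployment would extend the schema document rather than overload
  `extras`.
* ICD-10 codes are validated by pattern, not against the WHO code
  list; a code-list hook would slot into `validate_records()` where
  the pattern check lives.
* The query engine holds the corpus in memory and re-reads it per CLI
  invocation — appropriate for desk-scale corpora, not a replacement
  for an indexed search service.
* No cross-walks to MIABIS, BRISQ or SPREC are implemented; the
  format is compatible in spirit (minimum donor+sample information)
  but field-level mapping is out of scope.
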