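# bioscoop

Biobanks that want to exchange or co-search samples face a mundane but
stubborn obstacle: every institution describes its donors and samples in
its own dialect. `bioscoop` is an R implementation of a biobank
sample-communication format — a single JSON document per donor–sample
pair carrying donor phenotype (birth date, places of birth and
residence, sex, ethnic origin, skin tone, hair and eye colour, blood
group), anthropometry with the derived indices

- **BMI** = weight / height² (kg/m²),
- **WHR** = waist / hip (dimensionless),
- **CI** (corpulence / Rohrer index) = weight / height³ (kg/m³),

ICD-10-coded diseases and procedures, the sample material form,
identifiers (donor, collection, sample), a measurement/event timestamp
and data-source provenance. The package is aimed at biobank informatics
teams and at anyone who needs a reproducible test bed for
sample-search tooling. It provides the complete local workflow:

1. **Data preparation** — a deterministic generator of mock cohorts
   (`generate_cohort()`), and CSV export for the classic
   spreadsheet-shaped starting point (`write_cohort_csv()`).
2. **Ingest** — RFC 4180 CSV reading, mapping-driven conversion to
   records and canonical JSON output
   (`read_csv_table()`, `rows_to_records()`, `write_bioscoop_json()`,
   `read_bioscoop_json()`), with validation against a shipped JSON
   Schema (draft 2020-12) plus cross-field rules
   (`validate_records()`).
3. **Sample search** — a Lucene/Solr-style query engine evaluated
   in memory: `field:value`, `field:"a phrase"`,
   `numeric:[lo TO hi]`, combined with `AND`/`OR`/`NOT`
   (`parse_query()`, `evaluate_query()`), cross-checked by an
   independent per-record oracle (`brute_force_filter()`).

## Worked example

```r
library(bioscoop)

cohort <- generate_cohort(cohort_config(n_records = 200, seed = 7))
validate_records(cohort)
#> Validation report: all records valid (0 violations)

str(cohort[[1]][c("donor_id", "sample_id", "birth_date", "sex",
                  "height_cm", "weight_kg", "bmi", "whr")])
#> List of 8
#>  $ donor_id  : chr "DON-0001"
#>  $ sample_id : chr "SAM-0001"
#>  $ birth_date: chr "1960-10-04"
#>  $ sex       : chr "female"
#>  $ height_cm : num 185
#>  $ weight_kg : num 72.5
#>  $ bmi       : num 21.2
#>  $ whr       : num 0.994
```

Search the cohort with the three stock query forms:

```r
evaluate_query('birthPlace:"Gdansk, Poland"', cohort)$total
#> [1] 16

res <- evaluate_query("gender:male AND bmi:[18 TO 23]", cohort)
res$total
#> [1] 13
head(res$sample_ids)
#> [1] "SAM-0079" "SAM-0088" "SAM-0102" "SAM-0127" "SAM-0128" "SAM-0131"
```

`gender` is an alias for the questionnaire's `sex` field; range bounds
are inclusive and `*` leaves an end open; matching is exact full-string
and case-insensitive. Mixing `AND` and `OR` without parentheses is a
parse error rather than a silently mis-grouped cohort.

The same workflow is available from a shell via the installed
`exec/bioscoop` script:

```sh
bioscoop generate --n 200 --seed 7 --out cohort.json
bioscoop validate --in cohort.json
bioscoop search --in cohort.json --query 'bmi:[18 TO 23]' --ids-only
```

Exit codes: 0 success, 1 validation failures, 2 usage/query-parse
error, 3 I/O error.

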