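test_that("a valid record set passes validation and a generated cohort validates by construction", {
  rep <- validate_records(list(make_valid_record(), make_valid_record2()))
  expect_true(rep$valid)
  expect_identical(nrow(rep$violations), 0L)

  cohort <- generate_cohort(cohort_config(n_records = 25, seed = 11))
  expect_true(validate_records(cohort)$valid)
})

test_that("each schema rule is triggered by its targeted mutation and no other", {
  for (rule in names(rule_mutations())) {
    mut <- rule_mutations()[[rule]]
    rep <- validate_records(mut$records)
    expect_false(rep$valid, info = rule)
    expect_identical(nrow(rep$violations), 1L, info = rule)
    expect_identical(rep$violations$rule_id, rule)
    expect_identical(rep$violations$path, mut$path)
  }
})

test_that("violations are ordered by record index, path and rule", {
  recs <- list(
    make_valid_record2(sex = "unicorn", donor_id = ""),
    make_valid_record(timestamp = "not-a-date")
  )
  rep <- validate_records(recs)
  v <- rep$violations
  expect_identical(v, v[order(v$record_index, v$path, v$rule_id), ],
                   ignore_attr = TRUE)
  expect_identical(v$record_index, sort(v$record_index))
})

test_that("structural problems raise errors instead of reports", {
  expect_error(validate_records(data.frame(x = 1)), "structural")
  expect_error(validate_records(list(make_valid_record(), "not a record")),
               "structural")
  expect_error(validate_records(list(1:3)), "structural")
})

test_that("stored derived values agree with recomputation only within 1e-6 relative", {
  ok <- make_valid_record(bmi = round(70 / 1.75^2, 6))
  expect_true(validate_records(list(ok))$valid)
  off <- make_valid_record(bmi = (70 / 1.75^2) * (1 + 1e-4))
  rep <- validate_records(list(off))
  expect_identical(rep$violations$rule_id, "derived_inconsistent")
})

test_that("canonicalization zero-pads dates, fixes enum case and sorts keys", {
  messy <- make_valid_record(timestamp = "2019-1-5", sex = "Male",
                             skin_tone = "ii", blood_group = "a+")
  canon <- canonicalize_record(messy)
  expect_identical(canon$timestamp, "2019-01-05")
  expect_identical(canon$sex, "male")
  expect_identical(canon$skin_tone, "II")
  expect_identical(canon$blood_group, "A+")
  expect_identical(names(canon), sort(names(canon)))
})

test_that("canonicalization is idempotent on every generated record", {
  cohort <- generate_cohort(cohort_config(n_records = 30, seed = 7))
  once <- lapply(cohort, canonicalize_record)
  twice <- lapply(once, canonicalize_record)
  expect_identical(twice, once)
  # generator output is already canonical
  expect_identical(once, cohort)
})

test_that("canonicalization refuses invalid records and carries the report", {
  bad <- make_valid_record(donor_id = "")
  err <- tryCatch(canonicalize_record(bad), error = identity)
  expect_s3_class(err, "bioscoop_validation_error")
  expect_false(err$report$valid)
})

test_that("every attribute of the exchange format has exactly one home in the field catalogue", {
  # donor description, anthropometry + derived indices, medical events,
  # sample block, identifiers, timestamp and provenance
  expected <- c(
    "birth_date", "birth_place", "residence_place", "sex", "ethnic_origin",
    "skin_tone", "hair_colour", "eye_colour", "blood_group",
    "height_cm", "weight_kg", "waist_cm", "hip_cm", "extras",
    "whr", "bmi", "ci", "medical_events", "material_form",
    "donor_id", "collection_id", "sample_id", "timestamp", "data_source"
  )
  fields <- bioscoop_fields()
  expect_setequal(fields$internal, expected)
  expect_identical(anyDuplicated(fields$internal), 0L)
  expect_identical(anyDuplicated(fields$json), 0L)
})

test_that("the shipped JSON Schema document backs the validator's catalogues", {
  schema <- jsonlite::fromJSON(bioscoop_schema_path(), simplifyVector = FALSE)
  expect_identical(schema$type, "array")
  props <- schema$`$defs`$record$properties
  expect_setequal(names(props), bioscoop_fields()$json)
  # spot-check one enum against what the validator enforces
  expect_true(all(c("male", "female", "other", "unknown") %in%
                    unlist(props$sex$enum)))
})

test_that("calendar date parsing accepts only real dates", {
  expect_identical(bioscoop:::parse_iso_date("2019-1-5"), "2019-01-05")
  expect_identical(bioscoop:::parse_iso_date("2016-02-29"), "2016-02-29")
  expect_true(is.na(bioscoop:::parse_iso_date("2019-02-31")))
  expect_true(is.na(bioscoop:::parse_iso_date("1900-02-29")))  # not a leap year
  expect_true(is.na(bioscoop:::parse_iso_date("2019-13-01")))
  expect_true(is.na(bioscoop:::parse_iso_date("05/01/2019")))
})
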