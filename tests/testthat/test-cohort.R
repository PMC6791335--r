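test_that("the generator is deterministic per seed and distinct across seeds", {
  cfg <- cohort_config(n_records = 20, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cohort_config(n_records = 20, seed = 42))
  expect_identical(a, b)
  # byte-identical once serialized
  fa <- withr::local_tempfile(fileext = ".json")
  fb <- withr::local_tempfile(fileext = ".json")
  write_bioscoop_json(a, fa)
  write_bioscoop_json(b, fb)
  expect_identical(readLines(fa), readLines(fb))

  other <- generate_cohort(cohort_config(n_records = 20, seed = 43))
  expect_false(identical(a, other))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_cohort(cohort_config(n_records = 5, seed = 9)))
  expect_identical(runif(1), before)
})

test_that("a minimal cohort is a single fully populated valid record", {
  rec <- generate_cohort(cohort_config(n_records = 1, seed = 1))
  expect_length(rec, 1L)
  r <- rec[[1]]
  expect_true(validate_records(rec)$valid)
  for (f in c("donor_id", "collection_id", "sample_id", "timestamp",
              "data_source", "birth_date", "sex", "material_form",
              "height_cm", "weight_kg", "waist_cm", "hip_cm",
              "whr", "bmi", "ci")) {
    expect_false(is.null(r[[f]]), info = f)
  }
  expect_match(r$donor_id, "^DON-[0-9]{4}$")
  expect_match(r$sample_id, "^SAM-[0-9]{4}$")
})

test_that("anthropometry is drawn from the documented ranges with consistent indices", {
  cohort <- generate_cohort(cohort_config(n_records = 60, seed = 8))
  for (r in cohort) {
    expect_true(r$height_cm >= 140 && r$height_cm <= 210)
    expect_true(r$weight_kg >= 40 && r$weight_kg <= 150)
    expect_true(r$waist_cm >= 50 && r$waist_cm <= 150)
    expect_true(r$hip_cm >= 60 && r$hip_cm <= 160)
    # stored at canonical 6-decimal precision
    expect_identical(r$whr, round(whr(r$waist_cm, r$hip_cm), 6))
    expect_identical(r$bmi, round(bmi(r$weight_kg, r$height_cm), 6))
    expect_identical(r$ci, round(corpulence_index(r$weight_kg, r$height_cm),
                                 6))
    expect_lte(length(r$medical_events), 5L)
  }
})

test_that("cohort CSV output has one header line plus one line per record", {
  cohort <- generate_cohort(cohort_config(n_records = 12, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  expect_identical(write_cohort_csv(cohort, path), 12L)
  expect_length(readLines(path), 13L)

  write_cohort_csv(list(), path)
  expect_length(readLines(path), 1L)
})

test_that("invalid generator configs fail loudly and name the field", {
  expect_error(cohort_config(n_records = 0), "n_records")
  expect_error(cohort_config(n_records = 2.5), "n_records")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(seed = "abc"), "seed")
  pools <- default_value_pools()
  pools$places <- NULL
  expect_error(cohort_config(value_pools = pools), "places")
})

test_that("missing_rate thins optional fields but never breaks validity", {
  cohort <- generate_cohort(cohort_config(n_records = 40, seed = 5,
                                          missing_rate = 0.5))
  expect_true(validate_records(cohort)$valid)
  n_bg <- sum(vapply(cohort, function(r) !is.null(r$blood_group), TRUE))
  expect_lt(n_bg, 40L)
  expect_gt(n_bg, 0L)
})
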