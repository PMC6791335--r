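# Deterministic mock-cohort generator.
#
# Emulates a hand-prepared biobank test set: n flat sample-donor records
# with fully populated phenotype, anthropometry (with consistent derived
# indices), 0-5 ICD-10 coded medical events and a sample material form.
# All randomness flows from one seeded RNG; two runs with the same
# config are byte-identical once serialized.

#' Configuration for the mock-cohort generator
#'
#' Defaults describe the reference test set: 200 records drawn uniformly
#' from the packaged value pools (which include "Gdansk, Poland", so the
#' stock phrase-query examples match real records), anthropometry from
#' plausible adult ranges (height 140-210 cm, weight 40-150 kg, waist
#' 50-150 cm, hip 60-160 cm), and no missing values (the test set the
#' generator emulates was fully populated).
#'
#' @param n_records Number of records (>= 1; default 200).
#' @param seed Integer seed; the only source of randomness.
#' @param value_pools Named list of candidate values per field; see the
#'   packaged `value-pools.json` for the expected names.
#' @param missing_rate Probability in [0, 1) that each optional field
#'   (ethnic origin, skin tone, hair/eye colour, blood group, places,
#'   anthropometry block, event dates) is omitted.  Default 0.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_records = 200, seed = 1,
                          value_pools = default_value_pools(),
                          missing_rate = 0) {
  if (!is.numeric(n_records) || length(n_records) != 1L || is.na(n_records) ||
      n_records < 1 || n_records != floor(n_records)) {
    stop("config error: n_records must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("config error: seed must be an integer", call. = FALSE)
  }
  if (!is.numeric(missing_rate) || length(missing_rate) != 1L ||
      is.na(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop("config error: missing_rate must lie in [0, 1)", call. = FALSE)
  }
  needed <- c("places", "ethnic_origins", "sexes", "skin_tones",
              "hair_colours", "eye_colours", "blood_groups", "icd10_codes",
              "event_types", "material_forms", "data_sources", "collections",
              "extra_measurements")
  miss <- setdiff(needed, names(value_pools))
  if (length(miss)) {
    stop(sprintf("config error: value_pools missing %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  structure(list(n_records = as.integer(n_records), seed = as.integer(seed),
                 value_pools = value_pools, missing_rate = missing_rate),
            class = "cohort_config")
}

#' Packaged value pools for the generator
#'
#' @return Named list of candidate values (places, ethnic origins,
#'   ICD-10 codes, material forms, ...) read from the packaged
#'   `value-pools.json`.
#' @export
default_value_pools <- function() {
  if (is.null(.bioscoop$pools)) {
    .bioscoop$pools <- jsonlite::fromJSON(
      system.file("extdata", "value-pools.json", package = "bioscoop",
                  mustWork = TRUE),
      simplifyVector = TRUE)
  }
  .bioscoop$pools
}

# uniform draw from a pool (length-1 safe, unlike bare sample())
draw <- function(pool) pool[[sample.int(length(pool), 1L)]]

random_date <- function(from, to) {
  a <- as.integer(as.Date(from))
  b <- as.integer(as.Date(to))
  format(as.Date(a + sample.int(b - a + 1L, 1L) - 1L,
                 origin = "1970-01-01"), "%Y-%m-%d")
}

#' Generate a deterministic mock cohort
#'
#' Produces exactly `n_records` canonical records, every one of which
#' passes [validate_records()] by construction.  The same config and
#' seed always yield the same records; distinct seeds yield distinct
#' cohorts.
#'
#' @param config A [cohort_config()].
#' @return List of canonical records.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_records = 5, seed = 42))
#' validate_records(cohort)$valid
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  pools <- config$value_pools
  mr <- config$missing_rate
  keep <- function() mr == 0 || runif(1L) >= mr

  withr::with_seed(config$seed, {
    records <- lapply(seq_len(config$n_records), function(i) {
      birth <- random_date("1940-01-01", "2004-12-31")
      stamp <- random_date("2015-01-01", "2019-06-30")
      r <- list(
        donor_id = sprintf("DON-%04d", i),
        collection_id = draw(pools$collections),
        sample_id = sprintf("SAM-%04d", i),
        timestamp = stamp,
        data_source = draw(pools$data_sources),
        birth_date = birth,
        sex = draw(pools$sexes),
        material_form = draw(pools$material_forms)
      )
      if (keep()) r$birth_place <- draw(pools$places)
      if (keep()) r$residence_place <- draw(pools$places)
      if (keep()) r$ethnic_origin <- draw(pools$ethnic_origins)
      if (keep()) r$skin_tone <- draw(pools$skin_tones)
      if (keep()) r$hair_colour <- draw(pools$hair_colours)
      if (keep()) r$eye_colour <- draw(pools$eye_colours)
      if (keep()) r$blood_group <- draw(pools$blood_groups)
      if (keep()) {
        r$height_cm <- round(runif(1L, 140, 210), 1)
        r$weight_kg <- round(runif(1L, 40, 150), 1)
        r$waist_cm <- round(runif(1L, 50, 150), 1)
        r$hip_cm <- round(runif(1L, 60, 160), 1)
        n_extra <- sample.int(3L, 1L) - 1L
        if (n_extra > 0L) {
          nms <- sample(pools$extra_measurements, n_extra)
          r$extras <- stats::setNames(
            lapply(seq_len(n_extra), function(k) round(runif(1L, 20, 80), 1)),
            nms)
          r$extras <- r$extras[order(names(r$extras))]
        }
        # derived indices from the just-drawn measurements, at the
        # canonical 6-decimal precision
        r$whr <- round(whr(r$waist_cm, r$hip_cm), 6)
        r$bmi <- round(bmi(r$weight_kg, r$height_cm), 6)
        r$ci <- round(corpulence_index(r$weight_kg, r$height_cm), 6)
      }
      n_ev <- sample.int(6L, 1L) - 1L
      if (n_ev > 0L) {
        r$medical_events <- lapply(seq_len(n_ev), function(k) {
          e <- list(icd10_code = draw(pools$icd10_codes),
                    event_type = draw(pools$event_types))
          if (keep()) e$event_date <- random_date(birth, stamp)
          e[order(names(e))]
        })
      }
      # canonical by construction: pool values are already in catalogue
      # case, dates ISO, numbers carry <= 6 decimals; sorting the keys
      # completes the canonical form (asserted by the test-suite's
      # canonicalize-idempotence property)
      r[order(names(r))]
    })
    records
  },
  .rng_kind = "Mersenne-Twister",
  .rng_normal_kind = "Inversion",
  .rng_sample_kind = "Rejection")
}

#' Write a cohort as RFC 4180 CSV
#'
#' One header row plus one data row per record, columns matching the
#' default column mapping, so `write_cohort_csv()` ->
#' [read_csv_table()] -> [rows_to_records()] recovers the cohort
#' exactly.  Cells containing the delimiter (e.g. the place value
#' "Gdansk, Poland") are quoted.
#'
#' @param cohort List of valid records.
#' @param path Destination file path.
#' @param mapping A `bioscoop_mapping` defining the columns; default
#'   [default_column_mapping()].
#' @param delimiter Field separator (default comma).
#' @return (Invisibly) the number of data rows written.
#' @export
write_cohort_csv <- function(cohort, path, mapping = default_column_mapping(),
                             delimiter = ",") {
  cohort <- canonicalize_records(cohort, check = TRUE)
  cols <- names(mapping$entries)
  targets <- unname(mapping$entries)
  types <- .FIELD_TABLE$type[match(targets, .FIELD_TABLE$internal)]
  rows <- lapply(cohort, function(r) {
    vapply(seq_along(cols), function(k) {
      format_cell(r[[targets[k]]], types[k])
    }, "")
  })
  write_csv_lines(cols, rows, path, delimiter)
  invisible(length(cohort))
}
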