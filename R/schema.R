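# Record schema: field catalogue, validation, canonicalization.
#
# The machine-readable schema (JSON Schema draft 2020-12) ships in
# inst/extdata/bioscoop-schema.json and is the single source of truth for
# required fields, enum catalogues, the ICD-10 code pattern and the
# positivity bound on measurements.  The validator loads it at run time;
# cross-field rules (date ordering, uniqueness, derived-index consistency)
# are implemented here because JSON Schema cannot express them.

# field catalogue: internal (R) name, on-disk JSON name, value type
.FIELD_TABLE <- data.frame(
  internal = c(
    "donor_id", "collection_id", "sample_id", "timestamp", "data_source",
    "birth_date", "birth_place", "residence_place", "sex", "ethnic_origin",
    "skin_tone", "hair_colour", "eye_colour", "blood_group",
    "height_cm", "weight_kg", "waist_cm", "hip_cm", "extras",
    "whr", "bmi", "ci", "medical_events", "material_form"
  ),
  json = c(
    "donorId", "collectionId", "sampleId", "timestamp", "dataSource",
    "birthDate", "birthPlace", "residencePlace", "sex", "ethnicOrigin",
    "skinTone", "hairColour", "eyeColour", "bloodGroup",
    "heightCm", "weightKg", "waistCm", "hipCm", "extras",
    "whr", "bmi", "ci", "medicalEvents", "materialForm"
  ),
  type = c(
    "id", "id", "id", "date", "enum",
    "date", "string", "string", "enum", "string",
    "enum", "enum", "enum", "enum",
    "number", "number", "number", "number", "extras",
    "number", "number", "number", "events", "enum"
  ),
  stringsAsFactors = FALSE
)

# enum fields whose canonical case is the catalogue's own (not lower-case)
.CASE_PRESERVING_ENUMS <- c("blood_group", "skin_tone")

# trimws minus its per-call match.arg/sub overhead: strings are usually
# already trimmed, so test before stripping
fast_trim <- function(x) {
  if (grepl("^[ \t\r\n]|[ \t\r\n]$", x, useBytes = TRUE)) {
    gsub("^[ \t\r\n]+|[ \t\r\n]+$", "", x)
  } else x
}

# internal field name -> type, as a named list for O(1) lookup
field_type_map <- function() {
  if (is.null(.bioscoop$typemap)) {
    .bioscoop$typemap <- as.list(stats::setNames(.FIELD_TABLE$type,
                                                 .FIELD_TABLE$internal))
  }
  .bioscoop$typemap
}

#' Path to the shipped JSON Schema document
#'
#' @return Path to the draft 2020-12 JSON Schema describing a record set.
#' @export
bioscoop_schema_path <- function() {
  system.file("extdata", "bioscoop-schema.json", package = "bioscoop",
              mustWork = TRUE)
}

# parsed schema document, cached per session
bioscoop_schema <- function() {
  if (is.null(.bioscoop$schema)) {
    .bioscoop$schema <- jsonlite::fromJSON(bioscoop_schema_path(),
                                           simplifyVector = FALSE)
  }
  .bioscoop$schema
}

#' Field catalogue of the record schema
#'
#' One row per schema field with its internal (snake_case) R name, its
#' on-disk lowerCamelCase JSON name, its value type and whether it is
#' required.
#'
#' @return A data.frame with columns `internal`, `json`, `type`, `required`.
#' @export
bioscoop_fields <- function() {
  if (is.null(.bioscoop$fields)) {
    tab <- .FIELD_TABLE
    req <- vapply(bioscoop_schema()$`$defs`$record$required, identity, "")
    tab$required <- tab$json %in% req
    .bioscoop$fields <- tab
  }
  .bioscoop$fields
}

# enum catalogue for an internal field name, read from the schema document
enum_values <- function(internal) {
  if (is.null(.bioscoop$enums)) {
    props <- bioscoop_schema()$`$defs`$record$properties
    enums <- list()
    for (k in which(.FIELD_TABLE$type == "enum")) {
      vals <- props[[.FIELD_TABLE$json[k]]]$enum
      enums[[.FIELD_TABLE$internal[k]]] <- vapply(vals, identity, "")
    }
    .bioscoop$enums <- enums
  }
  .bioscoop$enums[[internal]]
}

event_enum_values <- function(json_name) {
  if (is.null(.bioscoop$event_enums)) {
    props <- bioscoop_schema()$`$defs`$medicalEvent$properties
    .bioscoop$event_enums <- lapply(
      Filter(function(p) !is.null(p$enum), props),
      function(p) vapply(p$enum, identity, ""))
  }
  .bioscoop$event_enums[[json_name]]
}

icd10_pattern <- function() {
  if (is.null(.bioscoop$icd10_pattern)) {
    .bioscoop$icd10_pattern <-
      bioscoop_schema()$`$defs`$medicalEvent$properties$icd10Code$pattern
  }
  .bioscoop$icd10_pattern
}

# --- dates ------------------------------------------------------------------

# Parse an ISO-style date ("2019-1-5" tolerated), return canonical
# "YYYY-MM-DD" or NA if the string is not a valid calendar date.
# Pure arithmetic (Gregorian month lengths + leap rule) rather than
# strptime: this runs on every date of every record during validation.
.DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

parse_iso_date <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) return(NA_character_)
  x <- fast_trim(x)
  if (!grepl("^[0-9]{4}-[0-9]{1,2}-[0-9]{1,2}$", x, useBytes = TRUE)) {
    return(NA_character_)
  }
  parts <- as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
  y <- parts[1]; m <- parts[2]; d <- parts[3]
  if (m < 1L || m > 12L || d < 1L) return(NA_character_)
  dim <- .DAYS_IN_MONTH[m]
  if (m == 2L && y %% 4L == 0L && (y %% 100L != 0L || y %% 400L == 0L)) {
    dim <- 29L
  }
  if (d > dim) return(NA_character_)
  if (nchar(x) == 10L) x else sprintf("%04d-%02d-%02d", y, m, d)
}

# zero-pad a date already known to be valid (canonicalization fast path)
pad_iso_date <- function(x) {
  if (nchar(x) == 10L) return(x)
  parts <- as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
  sprintf("%04d-%02d-%02d", parts[1], parts[2], parts[3])
}

# Parse a date in an arbitrary strptime format, return canonical ISO or NA.
parse_date_format <- function(x, format) {
  if (identical(format, "%Y-%m-%d")) return(parse_iso_date(x))
  d <- as.Date(trimws(x), format = format)
  if (is.na(d)) return(NA_character_)
  format(d, "%Y-%m-%d")
}

# --- validation -------------------------------------------------------------

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
is_scalar_num <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && is.finite(x)
}

new_report <- function(violations) {
  if (length(violations) == 0L) {
    df <- data.frame(record_index = integer(), path = character(),
                     rule_id = character(), message = character(),
                     stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, violations)
    df <- df[order(df$record_index, df$path, df$rule_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(list(valid = nrow(df) == 0L, violations = df),
            class = "bioscoop_report")
}

violation <- function(index, path, rule, message) {
  data.frame(record_index = as.integer(index), path = path, rule_id = rule,
             message = message, stringsAsFactors = FALSE)
}

lowered_enums <- function() {
  if (is.null(.bioscoop$lenums)) {
    ens <- list()
    for (f in .FIELD_TABLE$internal[.FIELD_TABLE$type == "enum"]) {
      ens[[f]] <- tolower(enum_values(f))
    }
    .bioscoop$lenums <- ens
  }
  .bioscoop$lenums
}

enum_ok <- function(value, catalogue) {
  tolower(value) %in% tolower(catalogue)
}

#' Validate records against the schema
#'
#' Checks a list of records (internal snake_case form, as produced by
#' [generate_cohort()], [read_bioscoop_json()] or [rows_to_records()])
#' against the shipped schema plus the cross-field rules JSON Schema
#' cannot express: timestamps not before birth date, event dates not
#' before birth date, sample_id uniqueness across the set, and agreement
#' of stored WHR/BMI/CI with recomputation from the raw measurements
#' (relative tolerance 1e-6).
#'
#' Content problems never raise an error: each failed (record, rule)
#' pair becomes one violation row, ordered by (record_index, path,
#' rule_id).  Only structural problems (input not a list of record
#' objects) stop with an error.
#'
#' @param records A list of record objects (named lists).
#' @return A `bioscoop_report`: list with `valid` (logical) and
#'   `violations` (data.frame with columns `record_index` (1-based),
#'   `path`, `rule_id`, `message`).
#' @examples
#' rep <- validate_records(generate_cohort(cohort_config(n_records = 3)))
#' rep$valid
#' @export
validate_records <- function(records) {
  if (!is.list(records) || !is.null(names(records))) {
    stop("structural error: input must be an unnamed list (JSON array) of records",
         call. = FALSE)
  }
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (!is.list(r) || (length(r) > 0L && is.null(names(r)))) {
      stop(sprintf("structural error: element %d is not a record object", i),
           call. = FALSE)
    }
  }
  # vectorized clean-path screen: most sets validate, and the per-record
  # reporting pass below is an order of magnitude slower than these
  # column-wise checks.  The screen errs on the side of "dirty"; the
  # detailed pass is always the authority on actual violations.
  if (records_definitely_clean(records)) {
    return(new_report(list()))
  }

  v <- list()
  add <- function(x) v[[length(v) + 1L]] <<- x

  for (i in seq_along(records)) {
    for (row in validate_one(records[[i]], i)) add(row)
  }

  # cross-record uniqueness: sample_id unique across the set (this also
  # guarantees uniqueness of (donor_id, sample_id) pairs)
  sids <- vapply(records, function(r) {
    if (is_scalar_chr(r$sample_id)) fast_trim(r$sample_id) else NA_character_
  }, "")
  dup <- !is.na(sids) & duplicated(sids)
  for (i in which(dup)) {
    add(violation(i, "sample_id", "sample_id_duplicate",
                  sprintf("sample_id '%s' already used by an earlier record",
                          sids[i])))
  }

  new_report(v)
}

# all rule checks for a single record; returns a list of violation rows
validate_one <- function(r, i) {
  v <- list()
  add <- function(index, path, rule, msg) {
    v[[length(v) + 1L]] <<- violation(index, path, rule, msg)
  }
  fields <- bioscoop_fields()
  lenums <- lowered_enums()

  unknown <- setdiff(names(r), fields$internal)
  for (f in unknown) {
    add(i, f, "unknown_field", sprintf("field '%s' is not in the schema", f))
  }

  required <- fields$internal[fields$required]
  for (f in required) {
    x <- r[[f]]
    if (is.null(x) || (is_scalar_chr(x) && !nzchar(fast_trim(x))) ||
        (is.character(x) && length(x) == 1L && is.na(x))) {
      add(i, f, "required_nonempty",
          sprintf("required field '%s' is missing or empty", f))
    }
  }

  dates <- list()  # canonical dates needed for ordering rules
  for (k in seq_len(nrow(fields))) {
    f <- fields$internal[k]
    x <- r[[f]]
    if (is.null(x)) next
    switch(fields$type[k],
      id = , string = {
        if (!is_scalar_chr(x)) {
          add(i, f, "type", sprintf("'%s' must be a single string", f))
        }
      },
      date = {
        if (!is_scalar_chr(x)) {
          add(i, f, "type", sprintf("'%s' must be a date string", f))
        } else {
          d <- parse_iso_date(x)
          if (is.na(d)) {
            add(i, f, "date_parse",
                sprintf("'%s' value '%s' is not a valid calendar date", f, x))
          } else {
            dates[[f]] <- d
          }
        }
      },
      enum = {
        if (!is_scalar_chr(x)) {
          add(i, f, "type", sprintf("'%s' must be a single string", f))
        } else if (!(tolower(x) %in% lenums[[f]])) {
          add(i, f, "enum_value",
              sprintf("'%s' value '%s' is not in the catalogue", f, x))
        }
      },
      number = {
        if (!is_scalar_num(x)) {
          add(i, f, "type", sprintf("'%s' must be a single finite number", f))
        } else if (x <= 0) {
          add(i, f, "positive_number",
              sprintf("'%s' must be strictly positive, got %g", f, x))
        }
      },
      extras = {
        ok <- is.list(x) || is.numeric(x)
        nm <- names(x)
        if (!ok || (length(x) > 0L && (is.null(nm) || any(!nzchar(nm))))) {
          add(i, f, "type", "'extras' must be a named map of measurements")
        } else {
          for (j in seq_along(x)) {
            val <- x[[j]]
            p <- paste0("extras.", nm[j])
            if (!is_scalar_num(val)) {
              add(i, p, "type", "extra measurement must be a finite number")
            } else if (val <= 0) {
              add(i, p, "positive_number",
                  sprintf("extra measurement must be positive, got %g", val))
            }
          }
        }
      },
      events = NULL  # handled below, needs the birth date
    )
  }

  # medical events
  ev <- r$medical_events
  if (!is.null(ev)) {
    if (!is.list(ev) || !is.null(names(ev))) {
      add(i, "medical_events", "type",
          "'medical_events' must be an array of event objects")
      ev <- NULL
    }
  }
  for (j in seq_along(ev)) {
    e <- ev[[j]]
    p <- sprintf("medical_events[%d]", j)
    if (!is.list(e) || is.null(names(e))) {
      add(i, p, "type", "event must be an object")
      next
    }
    for (f in setdiff(names(e), c("icd10_code", "event_type", "event_date"))) {
      add(i, paste0(p, ".", f), "unknown_field",
          sprintf("field '%s' is not in the schema", f))
    }
    code <- e$icd10_code
    if (!is_scalar_chr(code)) {
      add(i, paste0(p, ".icd10_code"), "required_nonempty",
          "event is missing its ICD-10 code")
    } else if (!grepl(icd10_pattern(), code)) {
      add(i, paste0(p, ".icd10_code"), "icd10_pattern",
          sprintf("'%s' does not match the ICD-10 code pattern", code))
    }
    et <- e$event_type
    if (!is_scalar_chr(et)) {
      add(i, paste0(p, ".event_type"), "required_nonempty",
          "event is missing its type (disease/procedure)")
    } else if (!enum_ok(et, event_enum_values("eventType"))) {
      add(i, paste0(p, ".event_type"), "enum_value",
          sprintf("event_type '%s' is not in the catalogue", et))
    }
    ed <- e$event_date
    if (!is.null(ed)) {
      if (!is_scalar_chr(ed)) {
        add(i, paste0(p, ".event_date"), "type",
            "event_date must be a date string")
      } else {
        d <- parse_iso_date(ed)
        if (is.na(d)) {
          add(i, paste0(p, ".event_date"), "date_parse",
              sprintf("event_date '%s' is not a valid calendar date", ed))
        } else if (!is.null(dates$birth_date) && d < dates$birth_date) {
          add(i, paste0(p, ".event_date"), "event_before_birth",
              sprintf("event_date %s precedes donor birth date %s",
                      d, dates$birth_date))
        }
      }
    }
  }

  # date ordering: birth not in the future relative to the record timestamp
  if (!is.null(dates$birth_date) && !is.null(dates$timestamp) &&
      dates$birth_date > dates$timestamp) {
    add(i, "birth_date", "birth_after_timestamp",
        sprintf("birth date %s is later than record timestamp %s",
                dates$birth_date, dates$timestamp))
  }

  # stored derived indices must agree with recomputation within relative
  # 1e-6 after canonicalization (both sides carry <= 6 decimals)
  check_derived <- function(name, stored, recomputed) {
    stored <- round(stored, 6)
    recomputed <- round(recomputed, 6)
    if (abs(stored - recomputed) / abs(recomputed) > 1e-6) {
      add(i, name, "derived_inconsistent",
          sprintf("stored %s %g disagrees with recomputed %g",
                  name, stored, recomputed))
    }
  }
  if (is_scalar_num(r$whr) && is_scalar_num(r$waist_cm) &&
      is_scalar_num(r$hip_cm) && r$waist_cm > 0 && r$hip_cm > 0) {
    check_derived("whr", r$whr, whr(r$waist_cm, r$hip_cm))
  }
  if (is_scalar_num(r$weight_kg) && is_scalar_num(r$height_cm) &&
      r$weight_kg > 0 && r$height_cm > 0) {
    if (is_scalar_num(r$bmi)) check_derived("bmi", r$bmi, bmi(r$weight_kg, r$height_cm))
    if (is_scalar_num(r$ci)) {
      check_derived("ci", r$ci, corpulence_index(r$weight_kg, r$height_cm))
    }
  }

  v
}

#' @export
print.bioscoop_report <- function(x, ...) {
  if (x$valid) {
    cat("Validation report: all records valid (0 violations)\n")
  } else {
    cat(sprintf("Validation report: %d violation(s) in %d record(s)\n",
                nrow(x$violations), length(unique(x$violations$record_index))))
    print(x$violations, ...)
  }
  invisible(x)
}

# --- canonicalization -------------------------------------------------------

canonical_enum <- function(value, internal) {
  catalogue <- enum_values(internal)
  hit <- catalogue[match(tolower(value), tolower(catalogue))]
  if (is.na(hit)) value else hit
}

#' Canonicalize a record
#'
#' Normalizes a valid record to its unique exchange form: dates as ISO
#' 8601 `YYYY-MM-DD`; enum values in catalogue case (lower-case, except
#' blood group and skin tone which keep their catalogue spelling);
#' strings trimmed; numeric values rounded to 6 decimal places; extras
#' and event keys sorted; top-level fields in sorted (internal) name
#' order.  Canonicalization is idempotent.
#'
#' @param record A record (named list) that passes validation.
#' @param check Validate first and refuse invalid records (default TRUE).
#' @return The canonical record.
#' @export
canonicalize_record <- function(record, check = TRUE) {
  if (check) {
    rep <- validate_records(list(record))
    if (!rep$valid) {
      stop(structure(
        class = c("bioscoop_validation_error", "error", "condition"),
        list(message = paste0(
               "cannot canonicalize an invalid record; first violation: ",
               rep$violations$rule_id[1], " at ", rep$violations$path[1]),
             call = NULL, report = rep)))
    }
  }
  types <- field_type_map()
  if (is_canonical_record(record, types)) return(record)
  out <- list()
  for (f in intersect(.FIELD_TABLE$internal, names(record))) {
    x <- record[[f]]
    if (is.null(x)) next
    out[[f]] <- switch(types[[f]],
      id = , string = fast_trim(x),
      date = pad_iso_date(fast_trim(x)),
      enum = canonical_enum(fast_trim(x), f),
      number = round(as.numeric(x), 6),
      extras = {
        x <- as.list(x)
        x <- x[order(names(x))]
        lapply(x, function(val) round(as.numeric(val), 6))
      },
      events = lapply(x, function(e) {
        e <- e[!vapply(e, is.null, TRUE)]
        e$icd10_code <- fast_trim(e$icd10_code)
        e$event_type <- tolower(fast_trim(e$event_type))
        if (!is.null(e$event_date)) e$event_date <- pad_iso_date(fast_trim(e$event_date))
        e[order(names(e))]
      })
    )
  }
  # empty containers are dropped: canonical form has no "present but empty"
  # state, so JSON and CSV representations round-trip identically
  if (!is.null(out$extras) && length(out$extras) == 0L) out$extras <- NULL
  if (!is.null(out$medical_events) && length(out$medical_events) == 0L) {
    out$medical_events <- NULL
  }
  out[order(names(out))]
}

# canonicalize a whole set (records assumed individually valid when
# check = FALSE, e.g. straight out of the generator)
canonicalize_records <- function(records, check = TRUE) {
  if (check) {
    rep <- validate_records(records)
    if (!rep$valid) {
      stop(structure(
        class = c("bioscoop_validation_error", "error", "condition"),
        list(message = sprintf("%d record(s) fail validation",
                               length(unique(rep$violations$record_index))),
             call = NULL, report = rep)))
    }
  }
  lapply(records, canonicalize_record, check = FALSE)
}

# --- clean-path screen ------------------------------------------------------
# Column-wise re-statement of every validation rule, used only to decide
# whether the detailed (and much slower) per-record reporting pass can be
# skipped.  Any doubt returns FALSE; the detailed pass is the authority.
# The targeted-mutation test-suite guarantees the screen never reports a
# rule-breaking set as clean.

.BAD_CELL <- "\x01malformed"

col_chr <- function(records, f) {
  vapply(records, function(r) {
    x <- r[[f]]
    if (is.null(x)) NA_character_
    else if (is.character(x) && length(x) == 1L && !is.na(x)) x
    else .BAD_CELL
  }, "", USE.NAMES = FALSE)
}

col_num <- function(records, f) {
  vapply(records, function(r) {
    x <- r[[f]]
    if (is.null(x)) NA_real_
    else if (is.numeric(x) && length(x) == 1L && !is.na(x) && is.finite(x)) {
      as.numeric(x)
    } else -Inf
  }, 0, USE.NAMES = FALSE)
}

# all elements are valid zero-padded ISO calendar dates (vectorized)
iso_dates_ok <- function(x) {
  if (!all(grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x, useBytes = TRUE))) {
    return(FALSE)
  }
  y <- as.integer(substr(x, 1L, 4L))
  m <- as.integer(substr(x, 6L, 7L))
  d <- as.integer(substr(x, 9L, 10L))
  if (any(m < 1L | m > 12L | d < 1L)) return(FALSE)
  dim <- .DAYS_IN_MONTH[m]
  dim[m == 2L & y %% 4L == 0L & (y %% 100L != 0L | y %% 400L == 0L)] <- 29L
  all(d <= dim)
}

records_definitely_clean <- function(records) {
  n <- length(records)
  if (n == 0L) return(TRUE)
  fields <- bioscoop_fields()
  internal <- fields$internal
  lenums <- lowered_enums()

  for (r in records) {
    nm <- names(r)
    if (length(r) && (is.null(nm) || anyNA(match(nm, internal)))) {
      return(FALSE)
    }
  }

  # identifiers: present, scalar, non-blank, sample_id unique
  for (f in c("donor_id", "collection_id", "sample_id")) {
    x <- col_chr(records, f)
    if (anyNA(x) || any(x == .BAD_CELL) ||
        any(grepl("^[ \t\r\n]*$", x, useBytes = TRUE))) {
      return(FALSE)
    }
    if (f == "sample_id" && anyDuplicated(trimws(x))) return(FALSE)
  }

  # dates: valid, and birth precedes (or equals) the record timestamp
  ts <- col_chr(records, "timestamp")
  bd <- col_chr(records, "birth_date")
  if (anyNA(ts) || anyNA(bd) || any(ts == .BAD_CELL) || any(bd == .BAD_CELL)) {
    return(FALSE)
  }
  ts <- trimws(ts)
  bd <- trimws(bd)
  if (!iso_dates_ok(ts) || !iso_dates_ok(bd)) return(FALSE)
  if (any(bd > ts)) return(FALSE)

  for (f in internal[fields$type == "string"]) {
    x <- col_chr(records, f)
    if (any(x == .BAD_CELL, na.rm = TRUE)) return(FALSE)
  }

  for (k in which(fields$type == "enum")) {
    f <- internal[k]
    x <- col_chr(records, f)
    if (any(x == .BAD_CELL, na.rm = TRUE)) return(FALSE)
    pres <- !is.na(x)
    if (fields$required[k] && !all(pres)) return(FALSE)
    if (!all(tolower(trimws(x[pres])) %in% lenums[[f]])) return(FALSE)
  }

  nums <- list()
  for (f in internal[fields$type == "number"]) {
    x <- col_num(records, f)
    if (any(x <= 0, na.rm = TRUE)) return(FALSE)  # sentinel -Inf included
    nums[[f]] <- x
  }

  # derived indices vs recomputation, canonical 6-decimal precision
  derived_ok <- function(stored, num, den, cube = FALSE) {
    idx <- !is.na(stored) & !is.na(num) & !is.na(den)
    if (!any(idx)) return(TRUE)
    scale <- den[idx] / 100
    ref <- round(num[idx] / if (cube) scale^3 else scale^2, 6)
    all(abs(round(stored[idx], 6) - ref) / ref <= 1e-6)
  }
  w_idx <- !is.na(nums$whr) & !is.na(nums$waist_cm) & !is.na(nums$hip_cm)
  if (any(w_idx)) {
    ref <- round(nums$waist_cm[w_idx] / nums$hip_cm[w_idx], 6)
    if (!all(abs(round(nums$whr[w_idx], 6) - ref) / ref <= 1e-6)) {
      return(FALSE)
    }
  }
  if (!derived_ok(nums$bmi, nums$weight_kg, nums$height_cm)) return(FALSE)
  if (!derived_ok(nums$ci, nums$weight_kg, nums$height_cm, cube = TRUE)) {
    return(FALSE)
  }

  # extras and medical events: loop only where present
  codes <- list(); types <- list(); edates <- list(); ebirth <- list()
  for (i in seq_len(n)) {
    x <- records[[i]]$extras
    if (!is.null(x)) {
      if (!(is.list(x) || is.numeric(x))) return(FALSE)
      nm <- names(x)
      if (length(x) && (is.null(nm) || any(!nzchar(nm)))) return(FALSE)
      for (val in x) {
        if (!(is.numeric(val) && length(val) == 1L && !is.na(val) &&
              is.finite(val) && val > 0)) {
          return(FALSE)
        }
      }
    }
    ev <- records[[i]]$medical_events
    if (is.null(ev)) next
    if (!is.list(ev) || !is.null(names(ev))) return(FALSE)
    for (e in ev) {
      if (!is.list(e) || is.null(names(e)) ||
          anyNA(match(names(e), c("icd10_code", "event_type",
                                  "event_date")))) {
        return(FALSE)
      }
      if (!is_scalar_chr(e$icd10_code) || !is_scalar_chr(e$event_type)) {
        return(FALSE)
      }
      codes[[length(codes) + 1L]] <- e$icd10_code
      types[[length(types) + 1L]] <- e$event_type
      if (!is.null(e$event_date)) {
        if (!is_scalar_chr(e$event_date)) return(FALSE)
        edates[[length(edates) + 1L]] <- e$event_date
        ebirth[[length(ebirth) + 1L]] <- bd[i]
      }
    }
  }
  if (length(codes)) {
    if (!all(grepl(icd10_pattern(), unlist(codes)))) return(FALSE)
    if (!all(tolower(unlist(types)) %in%
               tolower(event_enum_values("eventType")))) {
      return(FALSE)
    }
  }
  if (length(edates)) {
    ed <- trimws(unlist(edates))
    if (!iso_dates_ok(ed)) return(FALSE)
    if (any(ed < unlist(ebirth))) return(FALSE)
  }
  TRUE
}

# TRUE when a record is already in canonical form, so canonicalize_record
# can return it unchanged without rebuilding
is_canonical_record <- function(r, types) {
  nm <- names(r)
  if (length(nm) > 1L && is.unsorted(nm, strictly = TRUE)) return(FALSE)
  for (f in nm) {
    x <- r[[f]]
    ok <- switch(types[[f]],
      id = , string = !grepl("^[ \t\r\n]|[ \t\r\n]$", x, useBytes = TRUE),
      date = nchar(x) == 10L,
      enum = x %in% enum_values(f),
      # canonical numbers are doubles (JSON integers parse as integer)
      number = is.double(x) && x == round(x, 6),
      extras = {
        good <- is.list(x) && length(x) > 0L &&
          !(length(x) > 1L && is.unsorted(names(x), strictly = TRUE))
        if (good) {
          for (v in x) {
            if (!is.double(v) || v != round(v, 6)) { good <- FALSE; break }
          }
        }
        good
      },
      events = {
        good <- length(x) > 0L
        if (good) {
          for (e in x) {
            enm <- names(e)
            if ((length(enm) > 1L && is.unsorted(enm, strictly = TRUE)) ||
                grepl("^[ \t\r\n]|[ \t\r\n]$", e$icd10_code,
                      useBytes = TRUE) ||
                e$event_type != tolower(e$event_type) ||
                (!is.null(e$event_date) && nchar(e$event_date) != 10L)) {
              good <- FALSE
              break
            }
          }
        }
        good
      }
    )
    if (!ok) return(FALSE)
  }
  TRUE
}
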