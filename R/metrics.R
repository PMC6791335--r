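# Derived anthropometric indices carried by the record format.
#
# The format names three indices; the standard definitions are used:
# WHR = waist/hip (dimensionless), BMI = weight/height^2 (kg/m^2),
# corpulence (Rohrer/ponderal) index = weight/height^3 (kg/m^3).
# Heights are stored in centimetres but the indices are computed on
# metres, the conventional unit.

check_positive <- function(..., .names) {
  vals <- list(...)
  for (k in seq_along(vals)) {
    x <- vals[[k]]
    if (!is.numeric(x) || length(x) == 0L || anyNA(x) ||
        any(!is.finite(x)) || any(x <= 0)) {
      stop(sprintf("%s must be strictly positive and finite", .names[k]),
           call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Body mass index (kg/m^2)
#'
#' @param weight_kg Body weight in kilograms (strictly positive).
#' @param height_cm Standing height in centimetres (strictly positive).
#' @return `weight_kg / (height_cm / 100)^2`, unrounded.
#' @examples
#' bmi(70, 175)  # 22.857...
#' @export
bmi <- function(weight_kg, height_cm) {
  check_positive(weight_kg, height_cm, .names = c("weight_kg", "height_cm"))
  weight_kg / (height_cm / 100)^2
}

#' Waist-to-hip ratio (dimensionless)
#'
#' @param waist_cm Waist circumference (strictly positive).
#' @param hip_cm Hip circumference (strictly positive).
#' @return `waist_cm / hip_cm`; any common length unit cancels.
#' @examples
#' whr(80, 100)  # 0.8
#' @export
whr <- function(waist_cm, hip_cm) {
  check_positive(waist_cm, hip_cm, .names = c("waist_cm", "hip_cm"))
  waist_cm / hip_cm
}

#' Corpulence (Rohrer / ponderal) index (kg/m^3)
#'
#' @inheritParams bmi
#' @return `weight_kg / (height_cm / 100)^3`.
#' @examples
#' corpulence_index(70, 175)  # 13.06...
#' @export
corpulence_index <- function(weight_kg, height_cm) {
  check_positive(weight_kg, height_cm, .names = c("weight_kg", "height_cm"))
  weight_kg / (height_cm / 100)^3
}

#' Fill derived indices from raw measurements
#'
#' Computes WHR, BMI and CI from the raw measurements present on a
#' record and fills each derived field that is absent.  A stored
#' derived value that disagrees with recomputation beyond relative
#' 1e-6 is never overwritten: the field name is recorded in the
#' `"derived_inconsistent"` attribute of the returned record (and
#' [validate_records()] reports the same disagreement).  Records
#' without the relevant raw measurements are returned unchanged.
#'
#' Enrichment is idempotent on consistent records.
#'
#' @param record A valid record (named list, snake_case fields).
#' @return The record, with derived fields filled where possible.
#' @export
enrich_record <- function(record) {
  rep <- validate_records(list(record))
  # a derived/stored disagreement is precisely what enrichment flags, so
  # it is tolerated here; any other violation is a hard error
  if (!all(rep$violations$rule_id == "derived_inconsistent")) {
    stop(structure(
      class = c("bioscoop_validation_error", "error", "condition"),
      list(message = "enrich_record requires a valid record", call = NULL,
           report = rep)))
  }
  flags <- character()
  fill <- function(name, value) {
    stored <- record[[name]]
    if (is.null(stored)) {
      record[[name]] <<- value
    } else if (abs(round(stored, 6) - round(value, 6)) /
                 abs(round(value, 6)) > 1e-6) {
      # compared after canonicalization (6-decimal rounding), matching
      # the validator's derived_inconsistent rule
      flags <<- c(flags, name)
    }
  }
  if (is_scalar_num(record$waist_cm) && is_scalar_num(record$hip_cm)) {
    fill("whr", whr(record$waist_cm, record$hip_cm))
  }
  if (is_scalar_num(record$weight_kg) && is_scalar_num(record$height_cm)) {
    fill("bmi", bmi(record$weight_kg, record$height_cm))
    fill("ci", corpulence_index(record$weight_kg, record$height_cm))
  }
  if (length(flags)) attr(record, "derived_inconsistent") <- flags
  record
}
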