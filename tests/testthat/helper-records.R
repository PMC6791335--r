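# Shared fixtures: a reference valid record and one targeted mutator per
# validation rule (each mutator breaks exactly its own rule).

make_valid_record <- function(...) {
  rec <- list(
    donor_id = "DON-0001", collection_id = "COL-01", sample_id = "SAM-0001",
    timestamp = "2018-05-04", data_source = "donor_questionnaire",
    birth_date = "1980-01-15", birth_place = "Gdansk, Poland",
    residence_place = "Lodz, Poland", sex = "male", ethnic_origin = "Polish",
    skin_tone = "II", hair_colour = "brown", eye_colour = "blue",
    blood_group = "A+", height_cm = 175, weight_kg = 70,
    waist_cm = 80, hip_cm = 100, whr = 0.8,
    bmi = 70 / 1.75^2, ci = 70 / 1.75^3,
    extras = list(head_circumference_cm = 56.5),
    medical_events = list(list(icd10_code = "E11.9", event_type = "disease",
                               event_date = "2010-03-02")),
    material_form = "serum")
  mods <- list(...)
  # single-bracket assignment so an explicit NULL removes the field
  for (f in names(mods)) rec[f] <- mods[f]
  rec
}

# a second record so multi-record sets have distinct IDs
make_valid_record2 <- function(...) {
  make_valid_record(donor_id = "DON-0002", sample_id = "SAM-0002",
                    sex = "female", ...)
}

# rule_id -> list(records, path): mutated record set expected to trigger
# exactly one violation of that rule at that path
rule_mutations <- function() {
  list(
    required_nonempty = list(
      records = list(make_valid_record(donor_id = "  ")),
      path = "donor_id"),
    unknown_field = list(
      records = list(make_valid_record(favourite_colour = "mauve")),
      path = "favourite_colour"),
    type = list(
      records = list(make_valid_record(weight_kg = "seventy", bmi = NULL,
                                       ci = NULL)),
      path = "weight_kg"),
    date_parse = list(
      records = list(make_valid_record(timestamp = "2019-02-31")),
      path = "timestamp"),
    enum_value = list(
      records = list(make_valid_record(blood_group = "H+")),
      path = "blood_group"),
    positive_number = list(
      records = list(make_valid_record(waist_cm = -80, whr = NULL)),
      path = "waist_cm"),
    icd10_pattern = list(
      records = list(make_valid_record(
        medical_events = list(list(icd10_code = "X123",
                                   event_type = "disease")))),
      path = "medical_events[1].icd10_code"),
    birth_after_timestamp = list(
      records = list(make_valid_record(birth_date = "2018-06-01",
                                       medical_events = NULL)),
      path = "birth_date"),
    event_before_birth = list(
      records = list(make_valid_record(
        medical_events = list(list(icd10_code = "I10",
                                   event_type = "disease",
                                   event_date = "1970-01-01")))),
      path = "medical_events[1].event_date"),
    derived_inconsistent = list(
      records = list(make_valid_record(bmi = 30)),
      path = "bmi"),
    sample_id_duplicate = list(
      records = list(make_valid_record(),
                     make_valid_record(donor_id = "DON-0002",
                                       sex = "female")),
      path = "sample_id")
  )
}
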