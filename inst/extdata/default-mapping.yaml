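# Default CSV column mapping for cohort exports.
# Column headers follow the on-disk JSON field names; targets are the
# internal (snake_case) record field paths.  `medical_events` and `extras`
# are composite cells: events as "CODE|type|date;CODE|type|date" (date may
# be empty), extras as "name=value;name=value".
mapping:
  donorId: donor_id
  collectionId: collection_id
  sampleId: sample_id
  timestamp: timestamp
  dataSource: data_source
  birthDate: birth_date
  birthPlace: birth_place
  residencePlace: residence_place
  sex: sex
  ethnicOrigin: ethnic_origin
  skinTone: skin_tone
  hairColour: hair_colour
  eyeColour: eye_colour
  bloodGroup: blood_group
  heightCm: height_cm
  weightKg: weight_kg
  waistCm: waist_cm
  hipCm: hip_cm
  whr: whr
  bmi: bmi
  ci: ci
  extras: extras
  medicalEvents: medical_events
  materialForm: material_form
dateFormat: "%Y-%m-%d"
missingTokens: ["", "NA", "null"]
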