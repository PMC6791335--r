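{
  "places": [
    "Gdansk, Poland", "Warsaw, Poland", "Lodz, Poland", "Krakow, Poland",
    "Wroclaw, Poland", "Poznan, Poland", "Szczecin, Poland", "Lublin, Poland",
    "Vilnius, Lithuania", "Prague, Czech Republic", "Berlin, Germany",
    "Lviv, Ukraine"
  ],
  "ethnic_origins": [
    "Polish", "Kashubian", "Silesian", "Ukrainian", "Lithuanian",
    "German", "Belarusian", "Roma"
  ],
  "sexes": ["male", "female"],
  "skin_tones": ["I", "II", "III", "IV", "V", "VI"],
  "hair_colours": ["black", "brown", "blond", "red", "grey", "other"],
  "eye_colours": ["brown", "blue", "green", "grey", "other"],
  "blood_groups": ["A+", "A-", "B+", "B-", "AB+", "AB-", "O+", "O-"],
  "icd10_codes": [
    "E11.9", "I10", "J45.0", "E66.9", "K21.0", "M54.5", "F32.1",
    "C50.9", "N20.0", "Z01.8", "H52.1", "L20.9", "G43.0", "D50.9"
  ],
  "event_types": ["disease", "procedure"],
  "material_forms": [
    "whole_blood", "serum", "plasma", "dna", "rna", "saliva",
    "tissue", "urine"
  ],
  "data_sources": ["donor_questionnaire"],
  "collections": ["COL-01", "COL-02", "COL-03", "COL-04", "COL-05"],
  "extra_measurements": ["head_circumference_cm", "shoulder_width_cm", "arm_span_cm"]
}
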