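{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "https://example.org/bioscoop/record-set.schema.json",
  "title": "Biobank sample-communication record set",
  "description": "A UTF-8 JSON array of flat sample-level documents, one object per donor-sample pair, combining donor phenotype, anthropometry, coded medical events, sample material and provenance.",
  "type": "array",
  "items": { "$ref": "#/$defs/record" },
  "$defs": {
    "isoDate": {
      "type": "string",
      "format": "date",
      "pattern": "^[0-9]{4}-[0-9]{2}-[0-9]{2}$"
    },
    "positiveNumber": {
      "type": "number",
      "exclusiveMinimum": 0
    },
    "nonEmptyString": {
      "type": "string",
      "pattern": "^\\s*\\S[\\s\\S]*$"
    },
    "medicalEvent": {
      "type": "object",
      "required": ["icd10Code", "eventType"],
      "properties": {
        "icd10Code": {
          "type": "string",
          "pattern": "^[A-Z][0-9]{2}(\\.[0-9]{1,2})?$"
        },
        "eventType": { "enum": ["disease", "procedure"] },
        "eventDate": { "$ref": "#/$defs/isoDate" }
      },
      "additionalProperties": false
    },
    "record": {
      "type": "object",
      "required": [
        "donorId", "collectionId", "sampleId", "timestamp",
        "dataSource", "birthDate", "sex", "materialForm"
      ],
      "properties": {
        "donorId": { "$ref": "#/$defs/nonEmptyString" },
        "collectionId": { "$ref": "#/$defs/nonEmptyString" },
        "sampleId": { "$ref": "#/$defs/nonEmptyString" },
        "timestamp": { "$ref": "#/$defs/isoDate" },
        "dataSource": {
          "enum": ["donor_questionnaire", "medical_record", "physical_measurement"]
        },
        "birthDate": { "$ref": "#/$defs/isoDate" },
        "birthPlace": { "type": "string" },
        "residencePlace": { "type": "string" },
        "sex": { "enum": ["male", "female", "other", "unknown"] },
        "ethnicOrigin": { "type": "string" },
        "skinTone": { "enum": ["I", "II", "III", "IV", "V", "VI"] },
        "hairColour": { "enum": ["black", "brown", "blond", "red", "grey", "other"] },
        "eyeColour": { "enum": ["brown", "blue", "green", "grey", "other"] },
        "bloodGroup": { "enum": ["A+", "A-", "B+", "B-", "AB+", "AB-", "O+", "O-", "unknown"] },
        "heightCm": { "$ref": "#/$defs/positiveNumber" },
        "weightKg": { "$ref": "#/$defs/positiveNumber" },
        "waistCm": { "$ref": "#/$defs/positiveNumber" },
        "hipCm": { "$ref": "#/$defs/positiveNumber" },
        "extras": {
          "type": "object",
          "additionalProperties": { "$ref": "#/$defs/positiveNumber" }
        },
        "whr": { "$ref": "#/$defs/positiveNumber" },
        "bmi": { "$ref": "#/$defs/positiveNumber" },
        "ci": { "$ref": "#/$defs/positiveNumber" },
        "medicalEvents": {
          "type": "array",
          "items": { "$ref": "#/$defs/medicalEvent" }
        },
        "materialForm": {
          "enum": ["whole_blood", "serum", "plasma", "dna", "rna", "saliva", "tissue", "urine", "other"]
        }
      },
      "additionalProperties": false
    }
  }
}
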