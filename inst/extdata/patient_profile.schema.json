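{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/afdecide/patient_profile.schema.json",
  "title": "Patient profile",
  "description": "Data-entry record for the atrial-fibrillation decision aid: age, comorbidity flags and current antithrombotic medication. All fields are required; no defaults are assumed.",
  "type": "object",
  "additionalProperties": false,
  "required": [
    "age", "chf", "hypertension", "diabetes", "prior_stroke_tia",
    "hepatic_or_renal_disease", "ethanol_abuse", "malignancy",
    "reduced_platelets", "prior_major_bleed", "uncontrolled_hypertension",
    "anemia", "genetic_factors", "fall_risk", "cad", "current_medication"
  ],
  "properties": {
    "age": {
      "type": "integer",
      "minimum": 18,
      "maximum": 120,
      "description": "Age in years"
    },
    "chf": { "type": "boolean", "description": "Congestive heart failure" },
    "hypertension": { "type": "boolean", "description": "History of hypertension" },
    "diabetes": { "type": "boolean" },
    "prior_stroke_tia": { "type": "boolean", "description": "Prior stroke or TIA" },
    "hepatic_or_renal_disease": { "type": "boolean" },
    "ethanol_abuse": { "type": "boolean" },
    "malignancy": { "type": "boolean" },
    "reduced_platelets": { "type": "boolean", "description": "Reduced platelet count or function" },
    "prior_major_bleed": { "type": "boolean", "description": "Prior major bleed (rebleeding risk)" },
    "uncontrolled_hypertension": { "type": "boolean" },
    "anemia": { "type": "boolean" },
    "genetic_factors": { "type": "boolean" },
    "fall_risk": { "type": "boolean", "description": "Excessive fall risk" },
    "cad": { "type": "boolean", "description": "Coexisting coronary artery disease" },
    "current_medication": {
      "type": "string",
      "enum": ["none", "aspirin", "warfarin"],
      "description": "Antithrombotic the patient currently takes"
    }
  }
}
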