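{
  "version": "1.0",
  "comment": "Canonical parameter name -> LOINC code, UCUM unit, FHIR value type. Provenance 'printed' = code printed in the source system description; 'external-standard' = filled from the public LOINC table.",
  "entries": {
    "HR":    {"loinc": "8867-4",  "unit": "{beats}/min", "display": "Heart rate",                          "type": "decimal", "provenance": "printed"},
    "SaO2":  {"loinc": "2708-6",  "unit": "%",           "display": "Oxygen saturation in Arterial blood", "type": "decimal", "provenance": "printed"},
    "SpO2":  {"loinc": "59408-5", "unit": "%",           "display": "Oxygen saturation by Pulse oximetry", "type": "decimal", "provenance": "external-standard"},
    "RR":    {"loinc": "9279-1",  "unit": "{breaths}/min","display": "Respiratory rate",                   "type": "decimal", "provenance": "external-standard"},
    "SBP":   {"loinc": "8480-6",  "unit": "mm[Hg]",      "display": "Systolic blood pressure",             "type": "decimal", "provenance": "external-standard"},
    "DBP":   {"loinc": "8462-4",  "unit": "mm[Hg]",      "display": "Diastolic blood pressure",            "type": "decimal", "provenance": "external-standard"},
    "Vt":    {"loinc": "76222-4", "unit": "mL",          "display": "Tidal volume expired",                "type": "decimal", "provenance": "external-standard"},
    "Ve":    {"loinc": "20139-2", "unit": "L/min",       "display": "Minute volume expired",               "type": "decimal", "provenance": "external-standard"},
    "FiO2":  {"loinc": "19994-3", "unit": "1",           "display": "Inspired oxygen fraction",            "type": "decimal", "provenance": "external-standard"},
    "PCO2":  {"loinc": "2019-8",  "unit": "mm[Hg]",      "display": "Carbon dioxide partial pressure, Arterial blood", "type": "decimal", "provenance": "external-standard"},
    "PO2":   {"loinc": "2703-1",  "unit": "mm[Hg]",      "display": "Oxygen partial pressure, Arterial blood",         "type": "decimal", "provenance": "external-standard"},
    "CO":    {"loinc": "8741-1",  "unit": "L/min",       "display": "Cardiac output",                      "type": "decimal", "provenance": "external-standard"},
    "SV":    {"loinc": "8774-2",  "unit": "mL",          "display": "Stroke volume",                       "type": "decimal", "provenance": "external-standard"},
    "INF_RATE": {"loinc": "33747-0", "unit": "mL/h",     "display": "Infusion rate",                       "type": "decimal", "provenance": "external-standard"},
    "INF_DOSE": {"loinc": "3126-0",  "unit": "mL",       "display": "Infused volume",                      "type": "decimal", "provenance": "external-standard"},
    "WBC":   {"loinc": "6690-2",  "unit": "10*3/uL",     "display": "Leukocytes in Blood",                 "type": "decimal", "provenance": "external-standard"},
    "RBC":   {"loinc": "789-8",   "unit": "10*6/uL",     "display": "Erythrocytes in Blood",               "type": "decimal", "provenance": "external-standard"},
    "HGB":   {"loinc": "718-7",   "unit": "g/dL",        "display": "Hemoglobin in Blood",                 "type": "decimal", "provenance": "external-standard"},
    "HCT":   {"loinc": "4544-3",  "unit": "%",           "display": "Hematocrit in Blood",                 "type": "decimal", "provenance": "external-standard"},
    "PLT":   {"loinc": "777-3",   "unit": "10*3/uL",     "display": "Platelets in Blood",                  "type": "decimal", "provenance": "external-standard"}
  }
}
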