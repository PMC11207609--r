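{
  "version": "1.0",
  "comment": "Device feature (DF) registry: one entry per mappable datum of a device dialect. locator is dialect-specific: OBX-3 identifier for hl7v2, key path for json, token label for proprietary.",
  "features": [
    {"category": "patient_monitor", "name": "HR",   "dialect": "hl7v2", "locator": "HR",   "value_type": "decimal", "range": [0, 300]},
    {"category": "patient_monitor", "name": "SpO2", "dialect": "hl7v2", "locator": "SPO2", "value_type": "decimal", "range": [0, 100]},
    {"category": "patient_monitor", "name": "RR",   "dialect": "hl7v2", "locator": "RR",   "value_type": "decimal", "range": [0, 80]},
    {"category": "patient_monitor", "name": "SBP",  "dialect": "hl7v2", "locator": "SBP",  "value_type": "decimal", "range": [0, 350]},
    {"category": "patient_monitor", "name": "DBP",  "dialect": "hl7v2", "locator": "DBP",  "value_type": "decimal", "range": [0, 250]},

    {"category": "ventilator", "name": "Vt",   "dialect": "proprietary", "locator": "VT",   "value_type": "decimal", "range": [0, 2000], "delimiter": "|", "kv_delim": ":"},
    {"category": "ventilator", "name": "Ve",   "dialect": "proprietary", "locator": "VE",   "value_type": "decimal", "range": [0, 60],   "delimiter": "|", "kv_delim": ":"},
    {"category": "ventilator", "name": "FiO2", "dialect": "proprietary", "locator": "FIO2", "value_type": "decimal", "range": [0, 1],    "delimiter": "|", "kv_delim": ":"},

    {"category": "hemodynamics_monitor", "name": "SaO2", "dialect": "proprietary", "locator": "SAO2", "value_type": "decimal", "range": [0, 100], "delimiter": "|", "kv_delim": ":"},
    {"category": "hemodynamics_monitor", "name": "CO",   "dialect": "proprietary", "locator": "CO",   "value_type": "decimal", "range": [0, 20],  "delimiter": "|", "kv_delim": ":"},
    {"category": "hemodynamics_monitor", "name": "SV",   "dialect": "proprietary", "locator": "SV",   "value_type": "decimal", "range": [0, 250], "delimiter": "|", "kv_delim": ":"},

    {"category": "infusion_pump", "name": "INF_RATE", "dialect": "json", "locator": "rate",   "value_type": "decimal", "range": [0, 1500]},
    {"category": "infusion_pump", "name": "INF_DOSE", "dialect": "json", "locator": "volume", "value_type": "decimal", "range": [0, 10000]},

    {"category": "hematology_analyzer", "name": "WBC",  "dialect": "proprietary", "locator": "WBC",  "value_type": "decimal", "range": [0, 500],  "delimiter": ";", "kv_delim": "="},
    {"category": "hematology_analyzer", "name": "RBC",  "dialect": "proprietary", "locator": "RBC",  "value_type": "decimal", "range": [0, 10],   "delimiter": ";", "kv_delim": "="},
    {"category": "hematology_analyzer", "name": "HGB",  "dialect": "proprietary", "locator": "HGB",  "value_type": "decimal", "range": [0, 25],   "delimiter": ";", "kv_delim": "="},
    {"category": "hematology_analyzer", "name": "HCT",  "dialect": "proprietary", "locator": "HCT",  "value_type": "decimal", "range": [0, 70],   "delimiter": ";", "kv_delim": "="},
    {"category": "hematology_analyzer", "name": "PLT",  "dialect": "proprietary", "locator": "PLT",  "value_type": "decimal", "range": [0, 2000], "delimiter": ";", "kv_delim": "="},
    {"category": "hematology_analyzer", "name": "PCO2", "dialect": "proprietary", "locator": "PCO2", "value_type": "decimal", "range": [0, 150],  "delimiter": ";", "kv_delim": "="},
    {"category": "hematology_analyzer", "name": "PO2",  "dialect": "proprietary", "locator": "PO2",  "value_type": "decimal", "range": [0, 700],  "delimiter": ";", "kv_delim": "="}
  ]
}
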