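{
  "template_id": "patient_admission",
  "concept_set_name": "Patient admission",
  "composition_id": "composition.patient_admission",
  "timestamp_path": "/patient_admission/admission_time",
  "archetypes": [
    {
      "archetype_id": "openEHR-EHR-ADMIN_ENTRY.Patient_Admission.v2",
      "concept_name": "patient_admission",
      "root": {
        "id": "at0000", "name": "Patient admission", "rm_type": "ENTRY",
        "path": "/patient_admission",
        "children": [
          {"id": "at0001", "name": "Admission time", "rm_type": "DV_DATE_TIME",
           "path": "/patient_admission/admission_time"},
          {"id": "at0002", "name": "Discharge time", "rm_type": "DV_DATE_TIME",
           "path": "/patient_admission/discharge_time"},
          {"id": "at0003", "name": "Ward", "rm_type": "DV_TEXT",
           "path": "/patient_admission/ward"},
          {"id": "at0004", "name": "Admission type", "rm_type": "DV_CODED_TEXT",
           "path": "/patient_admission/admission_type",
           "defining_codes": [
             {"terminology": "local", "code": "E", "label": "emergency"},
             {"terminology": "local", "code": "P", "label": "planned"}
           ]}
        ]
      }
    }
  ]
}
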