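{
  "template_id": "problem_diagnosis",
  "concept_set_name": "Problem diagnosis",
  "composition_id": "composition.problem_diagnosis",
  "timestamp_path": "/problem_diagnosis/date_of_onset",
  "archetypes": [
    {
      "archetype_id": "openEHR-EHR-EVALUATION.problem_diagnosis.v1",
      "concept_name": "problem_diagnosis",
      "root": {
        "id": "at0000", "name": "Problem diagnosis", "rm_type": "ENTRY",
        "path": "/problem_diagnosis",
        "children": [
          {"id": "at0001", "name": "Diagnosis", "rm_type": "DV_CODED_TEXT",
           "path": "/problem_diagnosis/diagnosis",
           "defining_codes": [
             {"terminology": "ICD10", "code": "I61",
              "label": "cerebral hemorrhage"},
             {"terminology": "ICD10", "code": "I63",
              "label": "cerebral infarction"},
             {"terminology": "ICD10", "code": "I60",
              "label": "subarachnoid hemorrhage"},
             {"terminology": "ICD10", "code": "E66", "label": "obesity"},
             {"terminology": "ICD10", "code": "G20",
              "label": "parkinson disease"},
             {"terminology": "ICD10", "code": "I10",
              "label": "essential hypertension"}
           ]},
          {"id": "at0002", "name": "Date of onset", "rm_type": "DV_DATE_TIME",
           "path": "/problem_diagnosis/date_of_onset"},
          {"id": "at0003", "name": "Clinical description", "rm_type": "DV_TEXT",
           "path": "/problem_diagnosis/clinical_description"},
          {"id": "at0004", "name": "Body site", "rm_type": "DV_TEXT",
           "path": "/problem_diagnosis/body_site"}
        ]
      }
    }
  ]
}
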