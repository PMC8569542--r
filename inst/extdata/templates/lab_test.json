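{
  "template_id": "lab_test",
  "concept_set_name": "Laboratory test",
  "composition_id": "composition.lab_test",
  "timestamp_path": "/lab_test/result_time",
  "archetypes": [
    {
      "archetype_id": "openEHR-EHR-OBSERVATION.lab_test_single.v1",
      "concept_name": "lab_test",
      "root": {
        "id": "at0000", "name": "Laboratory test", "rm_type": "ENTRY",
        "path": "/lab_test",
        "children": [
          {"id": "at0001", "name": "WBC count", "rm_type": "DV_QUANTITY",
           "units": "10^9/L", "path": "/lab_test/wbc_count"},
          {"id": "at0002", "name": "Platelet count", "rm_type": "DV_QUANTITY",
           "units": "10^9/L", "path": "/lab_test/platelet_count"},
          {"id": "at0003", "name": "Hemoglobin", "rm_type": "DV_QUANTITY",
           "units": "g/L", "path": "/lab_test/hemoglobin"},
          {"id": "at0004", "name": "Result time", "rm_type": "DV_DATE_TIME",
           "path": "/lab_test/result_time"},
          {"id": "at0005", "name": "Specimen", "rm_type": "DV_TEXT",
           "path": "/lab_test/specimen"},
          {"id": "at0006", "name": "Analyte panel", "rm_type": "CLUSTER",
           "is_collection": true, "path": "/lab_test/analyte_panel",
           "children": [
             {"id": "at0007", "name": "Analyte name", "rm_type": "DV_TEXT",
              "path": "/lab_test/analyte_panel/analyte_name"},
             {"id": "at0008", "name": "Analyte value", "rm_type": "DV_QUANTITY",
              "units": "1", "path": "/lab_test/analyte_panel/analyte_value"}
           ]}
        ]
      }
    }
  ]
}
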