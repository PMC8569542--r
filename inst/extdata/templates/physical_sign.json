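{
  "template_id": "physical_sign",
  "concept_set_name": "Physical sign",
  "composition_id": "composition.physical_sign",
  "timestamp_path": "/physical_sign/sign_time",
  "archetypes": [
    {
      "archetype_id": "openEHR-EHR-OBSERVATION.physical_sign.v1",
      "concept_name": "physical_sign",
      "root": {
        "id": "at0000", "name": "Physical sign", "rm_type": "ENTRY",
        "path": "/physical_sign",
        "children": [
          {"id": "at0001", "name": "Systolic blood pressure",
           "rm_type": "DV_QUANTITY", "units": "mmHg",
           "path": "/physical_sign/systolic_blood_pressure"},
          {"id": "at0002", "name": "Heart rate", "rm_type": "DV_QUANTITY",
           "units": "/min", "path": "/physical_sign/heart_rate"},
          {"id": "at0003", "name": "Body temperature",
           "rm_type": "DV_QUANTITY", "units": "Cel",
           "path": "/physical_sign/body_temperature"},
          {"id": "at0004", "name": "Blood oxygen saturation",
           "rm_type": "DV_QUANTITY", "units": "%",
           "path": "/physical_sign/blood_oxygen_saturation"},
          {"id": "at0005", "name": "Height", "rm_type": "DV_QUANTITY",
           "units": "cm", "path": "/physical_sign/height"},
          {"id": "at0006", "name": "Weight", "rm_type": "DV_QUANTITY",
           "units": "kg", "path": "/physical_sign/weight"},
          {"id": "at0007", "name": "MMSE score", "rm_type": "DV_COUNT",
           "path": "/physical_sign/mmse_score"},
          {"id": "at0008", "name": "MoCA score", "rm_type": "DV_COUNT",
           "path": "/physical_sign/moca_score"},
          {"id": "at0009", "name": "Sign time", "rm_type": "DV_DATE_TIME",
           "path": "/physical_sign/sign_time"}
        ]
      }
    }
  ]
}
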