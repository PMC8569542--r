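{
  "template_id": "imaging_examination",
  "concept_set_name": "Imaging examination",
  "composition_id": "composition.imaging_examination",
  "timestamp_path": "/imaging_examination/examination_time",
  "archetypes": [
    {
      "archetype_id": "openEHR-EHR-OBSERVATION.Imaging_examination_report.v2",
      "concept_name": "imaging_examination",
      "root": {
        "id": "at0000", "name": "Imaging examination", "rm_type": "ENTRY",
        "path": "/imaging_examination",
        "children": [
          {"id": "at0001", "name": "Examination name", "rm_type": "DV_TEXT",
           "path": "/imaging_examination/examination_name"},
          {"id": "at0002", "name": "Findings", "rm_type": "DV_TEXT",
           "path": "/imaging_examination/findings"},
          {"id": "at0003", "name": "Examination time",
           "rm_type": "DV_DATE_TIME",
           "path": "/imaging_examination/examination_time"}
        ]
      }
    }
  ]
}
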