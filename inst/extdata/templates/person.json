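{
  "template_id": "person",
  "concept_set_name": "Person",
  "composition_id": "composition.person",
  "archetypes": [
    {
      "archetype_id": "openEHR-EHR-ADMIN_ENTRY.person.v1",
      "concept_name": "person",
      "root": {
        "id": "at0000", "name": "Person", "rm_type": "ENTRY", "path": "/person",
        "children": [
          {"id": "at0001", "name": "Sex", "rm_type": "DV_CODED_TEXT",
           "path": "/person/sex",
           "defining_codes": [
             {"terminology": "local", "code": "F", "label": "Female"},
             {"terminology": "local", "code": "M", "label": "Male"}
           ]},
          {"id": "at0002", "name": "Birth date", "rm_type": "DV_DATE",
           "path": "/person/birth_date"},
          {"id": "at0003", "name": "Full name", "rm_type": "DV_TEXT",
           "path": "/person/full_name"},
          {"id": "at0004", "name": "National id", "rm_type": "DV_IDENTIFIER",
           "path": "/person/national_id"}
        ]
      }
    }
  ]
}
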