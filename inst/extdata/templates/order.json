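{
  "template_id": "order",
  "concept_set_name": "Order",
  "composition_id": "composition.order",
  "timestamp_path": "/order/start_time",
  "archetypes": [
    {
      "archetype_id": "openEHR-EHR-INSTRUCTION.order.v1",
      "concept_name": "order",
      "root": {
        "id": "at0000", "name": "Order", "rm_type": "ENTRY", "path": "/order",
        "children": [
          {"id": "at0001", "name": "Order item", "rm_type": "DV_CODED_TEXT",
           "path": "/order/order_item",
           "defining_codes": [
             {"terminology": "ATC", "code": "B01AC06", "label": "aspirin"},
             {"terminology": "ATC", "code": "B01AC04", "label": "clopidogrel"},
             {"terminology": "ATC", "code": "B01AB01", "label": "heparin"},
             {"terminology": "ATC", "code": "N02BE01", "label": "paracetamol"},
             {"terminology": "ATC", "code": "N05AL01", "label": "sulpiride"},
             {"terminology": "ATC", "code": "N05AX08", "label": "risperidone"},
             {"terminology": "local-proc", "code": "P0124",
              "label": "evacuation of intracerebral hematoma"}
           ]},
          {"id": "at0002", "name": "Start time", "rm_type": "DV_DATE_TIME",
           "path": "/order/start_time"},
          {"id": "at0003", "name": "Stop time", "rm_type": "DV_DATE_TIME",
           "path": "/order/stop_time"},
          {"id": "at0004", "name": "Dose", "rm_type": "DV_QUANTITY",
           "units": "mg", "path": "/order/dose"}
        ]
      }
    }
  ]
}
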