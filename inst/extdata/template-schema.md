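# Template JSON dialect

A template is the unit from which screening concepts are defined and an
index schema is generated. The dialect captures exactly the fields those
rules consume; it is not a full ADL/OPT serialisation.

Top level:

```json
{
  "template_id": "problem_diagnosis",        // unique; index name = lowercase id
  "concept_set_name": "Problem diagnosis",   // display name of the concept set
  "composition_id": "composition.problem_diagnosis",
  "timestamp_path": "/problem_diagnosis/date_of_onset",  // optional; default:
                                             // first date/date-time node
  "archetypes": [ { "archetype_id": "...", "concept_name": "...",
                    "root": <node> } ]
}
```

Node (`root` and every descendant):

| field            | meaning                                                    |
|------------------|------------------------------------------------------------|
| `id`             | archetype node id (informational)                          |
| `name`           | ontology name; becomes the concept name and field name part|
| `rm_type`        | `DV_BOOLEAN DV_CODED_TEXT DV_COUNT DV_DATE DV_DATE_TIME DV_DURATION DV_IDENTIFIER DV_QUANTITY DV_TEXT DV_URI` or structural `ENTRY CLUSTER SLOT` |
| `path`           | slash-delimited, unique in the template; children extend the parent path |
| `units`          | DV_QUANTITY only                                           |
| `defining_codes` | DV_CODED_TEXT only: `[{"terminology","code","label"}, ...]`|
| `is_collection`  | structural nodes: `true` maps to a nested field            |
| `children`       | ordered list of nodes                                      |

Validation errors name the offending path. Registry concept paths are the
template paths prefixed with `/<template_id>`.
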