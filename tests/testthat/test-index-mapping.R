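# Template -> index schema mapping, naming, ES mapping emission,
# document flattening.

test_that("data-type mapping covers every reference-model type", {
  types <- c("DV_BOOLEAN", "DV_CODED_TEXT", "DV_COUNT", "DV_DATE",
             "DV_DATE_TIME", "DV_DURATION", "DV_IDENTIFIER", "DV_QUANTITY",
             "DV_TEXT", "DV_URI")
  rows <- lapply(types, map_data_type)
  names(rows) <- types
  expect_length(types, 10)
  # 12 attribute rows across the table (value+code, magnitude+units, ...)
  attr_rows <- sum(vapply(rows, function(r) length(unique(r$attribute)),
                          integer(1)))
  expect_identical(attr_rows, 12L)

  q <- map_data_type("DV_QUANTITY")
  expect_identical(q$attribute, c("magnitude", "units"))
  expect_identical(q$kind, c("generic", "keyword"))
  expect_identical(q$value_type, c("double", "string"))

  # dual annotation: coded/free text strings get keyword AND fulltext
  for (t in c("DV_CODED_TEXT", "DV_TEXT")) {
    r <- rows[[t]]
    val <- r[r$attribute == "value", ]
    expect_setequal(val$kind, c("keyword", "fulltext"))
    expect_gte(nrow(r), 2)
  }
  b <- map_data_type("DV_BOOLEAN")
  expect_identical(nrow(b), 1L)
  expect_identical(b$kind, "generic")
  expect_identical(b$value_type, "boolean")
  expect_error(map_data_type("DV_WIBBLE"), "unsupported")
})

test_that("field naming prefixes the archetype concept and joins with underscores", {
  expect_identical(name_field("Body site", "problem_diagnosis"),
                   "problem_diagnosis_Body_site")
  # recursive naming through cluster parents
  expect_identical(name_field("Analyte value", c("lab_test", "Analyte panel")),
                   "lab_test_Analyte_panel_Analyte_value")
  # sanitization collapses non-alphanumeric runs
  expect_identical(sanitize_field_name("SpO2 (%) -- rest"), "SpO2_rest")
})

test_that("the problem-diagnosis schema carries id/timestamp and dual string fields", {
  schema <- map_template_to_schema(demo_templates()$problem_diagnosis)
  fields <- names(ehrscreen:::schema_flat_fields(schema))
  expect_true(all(c("id", "patient_id", "timestamp") %in% fields))
  expect_true(all(c("problem_diagnosis_Diagnosis_keyword",
                    "problem_diagnosis_Diagnosis_code",
                    "problem_diagnosis_Clinical_description_keyword",
                    "problem_diagnosis_Clinical_description_text",
                    "problem_diagnosis_Body_site_keyword",
                    "problem_diagnosis_Body_site_text") %in% fields))
  expect_identical(anyDuplicated(fields), 0L)
  expect_identical(schema$timestamp_source, "/problem_diagnosis/date_of_onset")
})

test_that("collection clusters map to nested fields keeping their structure", {
  schema <- map_template_to_schema(demo_templates()$lab_test)
  flat <- ehrscreen:::schema_flat_fields(schema)
  nested <- flat[["lab_test_Analyte_panel"]]
  expect_identical(nested$kind, "nested")
  child_names <- vapply(nested$children, `[[`, character(1), "name")
  expect_setequal(child_names,
                  c("lab_test_Analyte_panel_Analyte_name_keyword",
                    "lab_test_Analyte_panel_Analyte_name_text",
                    "lab_test_Analyte_panel_Analyte_value",
                    "lab_test_Analyte_panel_Analyte_value_units"))
})

test_that("sibling name collisions and empty templates are rejected", {
  dup <- '{
    "template_id": "dup", "concept_set_name": "Dup",
    "composition_id": "composition.dup",
    "archetypes": [{
      "archetype_id": "openEHR-EHR-EVALUATION.dup.v1",
      "concept_name": "dup",
      "root": {"id": "at0000", "name": "Dup", "rm_type": "ENTRY",
               "path": "/dup",
               "children": [
                 {"id": "a1", "name": "Flag", "rm_type": "DV_BOOLEAN",
                  "path": "/dup/flag"},
                 {"id": "a2", "name": "Flag", "rm_type": "DV_BOOLEAN",
                  "path": "/dup/flag2"}
               ]}
    }]
  }'
  expect_error(map_template_to_schema(load_template(dup)), "collision")

  empty <- '{
    "template_id": "none", "concept_set_name": "None",
    "composition_id": "composition.none",
    "archetypes": [{
      "archetype_id": "openEHR-EHR-EVALUATION.none.v1",
      "concept_name": "none",
      "root": {"id": "at0000", "name": "None", "rm_type": "ENTRY",
               "path": "/none", "children": []}
    }]
  }'
  expect_error(map_template_to_schema(load_template(empty)),
               "no entry attributes")
})

test_that("ES mappings are byte-stable and list every field exactly once", {
  schema <- map_template_to_schema(demo_templates()$lab_test)
  j1 <- emit_es_mapping(schema)
  j2 <- emit_es_mapping(schema)
  expect_identical(j1, j2)
  parsed <- jsonlite::parse_json(j1)
  expect_identical(
    parsed$mappings$properties$lab_test_WBC_count_units$type, "keyword")
  expect_identical(parsed$mappings$properties$lab_test_Specimen_text$type,
                   "text")
  expect_identical(parsed$mappings$properties$lab_test_Analyte_panel$type,
                   "nested")
  # every schema field name appears exactly once in the JSON text
  for (nm in names(ehrscreen:::schema_flat_fields(schema))) {
    expect_identical(
      lengths(regmatches(j1, gregexpr(paste0('"', nm, '"'), j1))), 1L)
  }
})

test_that("flattening passes values through under the mapped names", {
  tpl <- demo_templates()$problem_diagnosis
  doc <- flatten_entry(tpl,
                       list(`Diagnosis` = "I61",
                            `Date of onset` = "2020-03-04T10:00:00",
                            `Body site` = "left hemisphere"),
                       patient_id = "p1", doc_id = "d1")
  expect_identical(doc$fields$problem_diagnosis_Diagnosis_code, "I61")
  expect_identical(doc$fields$problem_diagnosis_Diagnosis_keyword,
                   "cerebral hemorrhage")
  expect_identical(doc$fields$problem_diagnosis_Diagnosis_text,
                   "cerebral hemorrhage")
  # dual fields share one value
  expect_identical(doc$fields$problem_diagnosis_Body_site_keyword,
                   doc$fields$problem_diagnosis_Body_site_text)
  # timestamp read from the declared source node
  expect_identical(doc$timestamp, "2020-03-04T10:00:00")

  lab <- flatten_entry(demo_templates()$lab_test,
                       list(`Result time` = "2020-01-01T08:00:00",
                            `WBC count` = 9.1,
                            `Analyte panel` = list(
                              list(`Analyte name` = "CRP",
                                   `Analyte value` = 3),
                              list(`Analyte name` = "urea",
                                   `Analyte value` = 5.2),
                              list(`Analyte name` = "creatinine",
                                   `Analyte value` = 71))),
                       patient_id = "p1", doc_id = "d2")
  expect_length(lab$fields$lab_test_Analyte_panel, 3)
  expect_identical(lab$fields$lab_test_WBC_count_units, "10^9/L")

  expect_error(
    flatten_entry(tpl, list(`Diagnosis` = 42), "p1", "d3"),
    "flattening error at /problem_diagnosis/diagnosis")
  expect_error(
    flatten_entry(tpl, list(`Diagnosis` = "NOPE"), "p1", "d4"),
    "unknown code")
})

test_that("generated documents always validate against their schemas", {
  gen <- get_gen(60, 11)
  store <- gen$store
  for (index in names(store$docs)) {
    schema <- store$schemas[[index]]
    for (doc in store$docs[[index]]) {
      expect_true(validate_document(schema, doc))
    }
  }
  # leaf losslessness: a value written once appears exactly once per field
  doc <- store$docs$person[[1]]
  expect_length(doc$fields$person_Sex_keyword, 1)
})
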