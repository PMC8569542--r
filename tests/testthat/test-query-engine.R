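# Compilation, ES emission, the reference evaluator and the IR
# interpreter.

test_that("demographic conditions compile to pure index predicates", {
  gen <- get_gen(60, 11)
  store <- gen$store
  ir <- compile_condition(gen$conditions$query2, store)
  kinds <- character(0)
  walk <- function(n) {
    kinds <<- c(kinds, n$kind)
    for (ch in n$children %||% list()) walk(ch)
    if (!is.null(n$candidate)) walk(n$candidate)
  }
  walk(ir$tree)
  expect_false("post" %in% kinds) # sex term + birth-date ranges, no post-filter
  expect_identical(sum(kinds == "pred"), 3L)
  expect_identical(ir$indexes, "person")
})

test_that("collection comparisons compile to exists-candidates plus a post-filter", {
  gen <- get_gen(60, 11)
  store <- gen$store
  ir <- compile_condition(
    screening_condition(screening_group(
      "[WBC count].last() < [WBC count].first()")), store)
  expect_identical(ir$tree$kind, "post")
  expect_identical(ir$tree$candidate$kind, "exists")
  expect_identical(ir$tree$candidate$field, "lab_test_WBC_count")

  # vacuously satisfiable expressions fall back to a match-all candidate
  ir2 <- compile_condition(
    screening_condition(screening_group("[WBC count].count() = 0")), store)
  expect_identical(ir2$tree$kind, "post")
  expect_identical(ir2$tree$candidate$kind, "match_all")

  expect_error(screening_condition())
  expect_error(compile_condition(
    screening_condition(screening_group("no_such_concept > 1")), store),
    "unresolved")
})

test_that("emitted Query DSL has the documented clause shapes", {
  gen <- get_gen(60, 11)
  store <- gen$store
  term_ir <- compile_condition(
    screening_condition(screening_group("[cerebral hemorrhage]")), store)
  q <- jsonlite::parse_json(emit_es_query(term_ir))
  expect_identical(q$query$term$problem_diagnosis_Diagnosis_code, "I61")

  range_ir <- compile_condition(
    screening_condition(screening_group("20 <= [MMSE score] <= 26")), store)
  q2 <- jsonlite::parse_json(emit_es_query(range_ir))
  musts <- q2$query$bool$must
  expect_identical(musts[[1]]$range$physical_sign_MMSE_score$gte, 20L)
  expect_identical(musts[[2]]$range$physical_sign_MMSE_score$lte, 26L)

  # byte stability
  expect_identical(emit_es_query(range_ir), emit_es_query(range_ir))

  # post-filter-only IR emits a match-all candidate
  only_post <- compile_condition(
    screening_condition(screening_group("[WBC count].count() = 0")), store)
  q3 <- jsonlite::parse_json(emit_es_query(only_post))
  expect_true("match_all" %in% names(q3$query))

  # multi-index conditions emit one candidate query per index
  multi <- compile_condition(gen$conditions$query4, store)
  q4 <- jsonlite::parse_json(emit_es_query(multi))
  expect_setequal(names(q4), multi$indexes)
})

test_that("bare comparisons use existential semantics over repeated entries", {
  reg <- demo_registry()
  store <- patient_store(reg)
  sign <- function(pid, id, mmse, t) {
    store_add_entry(store, "physical_sign",
                    list(`MMSE score` = mmse, `Sign time` = t), pid, id)
  }
  sign("pa", "d1", 23, "2020-05-01T09:00:00")
  sign("pa", "d2", 25, "2020-06-01T09:00:00")
  sign("pb", "d3", 27, "2020-05-01T09:00:00")
  store_add_entry(store, "person", list(`Sex` = "F",
                                        `Birth date` = "1950-01-01"),
                  "pc", "d4", timestamp = "1950-01-01")

  # pa has entries [23, 25]: some entry < 24
  expect_identical(evaluate("[MMSE score] < 24", store), "pa")
  # missing data: pc has no MMSE records at all
  expect_false(evaluate_patient("[MMSE score] < 24", store, "pc"))
  expect_false(evaluate_patient("attached([MMSE score])", store, "pc"))
  # count on missing concept is zero, so vacuous conditions hold
  expect_true(evaluate_patient("[MMSE score].count() = 0", store, "pc"))
  # first/last respect StartTime order
  expect_true(evaluate_patient("[MMSE score].first() = 23", store, "pa"))
  expect_true(evaluate_patient("[MMSE score].last() = 25", store, "pa"))
})

test_that("the stable-condition expression matches a satisfying patient", {
  reg <- demo_registry()
  store <- patient_store(reg)
  store_add_entry(store, "physical_sign",
                  list(`Systolic blood pressure` = 130, `Heart rate` = 70,
                       `Blood oxygen saturation` = 95,
                       `Body temperature` = 37,
                       `Sign time` = "2020-07-01T12:00:00"),
                  "ps", "d1")
  stable <- paste(
    "([Systolic blood pressure] >= 120 and",
    "[Systolic blood pressure] <= 220) and",
    "(40 <= [Heart rate] <= 100) and",
    "[Blood oxygen saturation] >= 92 and [Body temperature] <= 38.5")
  expect_identical(evaluate(stable, store), "ps")
  store_add_entry(store, "physical_sign",
                  list(`Systolic blood pressure` = 110, `Heart rate` = 130,
                       `Blood oxygen saturation` = 89,
                       `Body temperature` = 39.2,
                       `Sign time` = "2020-07-01T12:00:00"),
                  "pu", "d2")
  expect_identical(evaluate(stable, store), "ps")
})

test_that("comparing quantities with different units is an error", {
  reg <- demo_registry()
  store <- patient_store(reg)
  store_add_entry(store, "lab_test",
                  list(`WBC count` = 8, `Hemoglobin` = 140,
                       `Result time` = "2020-01-01T00:00:00"), "px", "d1")
  expect_error(evaluate("[WBC count] < [Hemoglobin]", store),
               "unit mismatch")
})

test_that("chain desugaring equals the explicit conjunction on real cohorts", {
  gen <- get_gen(60, 11)
  store <- gen$store
  cases <- list(
    c("5 <= [WBC count] <= 9",
      "(5 <= [WBC count]) and ([WBC count] <= 9)"),
    c("100 < [Systolic blood pressure] < 150",
      "(100 < [Systolic blood pressure]) and ([Systolic blood pressure] < 150)"),
    c("10 <= [MMSE score] <= 24 ",
      "(10 <= [MMSE score]) and ([MMSE score] <= 24)"))
  for (cs in cases) {
    expect_identical(evaluate(cs[1], store), evaluate(cs[2], store))
  }
})

test_that("screen intersects groups and reports per-group counts", {
  gen <- get_gen(60, 11)
  store <- gen$store
  g1 <- screening_group('Sex = "Female"')
  g2 <- screening_group("[WBC count]")
  res <- screen(screening_condition(g1, g2), store)
  a <- evaluate(screening_condition(g1), store)
  b <- evaluate(screening_condition(g2), store)
  expect_setequal(res$result, intersect(a, b))
  expect_identical(res$group_counts, c(length(a), length(b)))

  # appending an AND group can only shrink the result
  res3 <- screen(screening_condition(g1, g2, screening_group("aspirin")),
                 store)
  expect_true(all(res3$result %in% res$result))
  # adding an OR member can only grow a group
  res4 <- screen(screening_condition(
    screening_group(c('Sex = "Female"', 'Sex = "Male"')), g2), store)
  expect_true(all(res$result %in% res4$result))
})

test_that("run_ir agrees with the evaluator and candidates over-approximate", {
  gen <- get_gen(200, 101)
  store <- gen$store
  set.seed(77)
  for (i in 1:40) {
    cond <- rand_condition()
    expected <- evaluate(cond, store)
    ir <- compile_condition(cond, store)
    expect_identical(run_ir(ir, store), expected,
                     info = paste(utils::capture.output(print(cond)),
                                  collapse = " "))
    candidates <- run_ir(ir, store, drop_post_filters = TRUE)
    expect_true(all(expected %in% candidates))
  }
})

test_that("nested-scope predicates match only qualifying sub-documents", {
  reg <- demo_registry()
  store <- patient_store(reg)
  lab <- function(pid, id, panel) {
    store_add_entry(store, "lab_test",
                    list(`Result time` = "2020-02-02T08:00:00",
                         `Analyte panel` = panel), pid, id)
  }
  # p_hit: one sub-document satisfies both predicates together
  lab("p_hit", "d1", list(list(`Analyte name` = "CRP", `Analyte value` = 20)))
  # p_split: predicates only hold across different sub-documents
  lab("p_split", "d2", list(list(`Analyte name` = "CRP", `Analyte value` = 1),
                            list(`Analyte name` = "urea",
                                 `Analyte value` = 50)))
  ir <- structure(list(
    tree = ehrscreen:::.ir_nested(
      "lab_test", "lab_test_Analyte_panel",
      list(ehrscreen:::.ir_pred("lab_test",
                                "lab_test_Analyte_panel_Analyte_name_keyword",
                                "term", "CRP", "str"),
           ehrscreen:::.ir_pred("lab_test",
                                "lab_test_Analyte_panel_Analyte_value",
                                "gt", 10, "num"))),
    indexes = "lab_test"), class = "query_ir")
  expect_identical(run_ir(ir, store), "p_hit")
  q <- jsonlite::parse_json(emit_es_query(ir))
  expect_identical(q$query$nested$path, "lab_test_Analyte_panel")

  # match-all IR returns every patient
  ma <- structure(list(tree = ehrscreen:::.ir_match_all(),
                       indexes = character(0)), class = "query_ir")
  expect_setequal(run_ir(ma, store), store_patients(store))
})

test_that("nested derived concepts evaluate the same as their full inline expansion", {
  reg <- demo_registry()
  define_derived_concept(reg, "BMI := [Weight] / ([Height] / 100) ^ 2")
  define_derived_concept(reg, "bmi_obesity := BMI >= 28")
  define_derived_concept(reg, "icd_10_obesity := attached([obesity])")
  define_derived_concept(reg, "obesity_any := icd_10_obesity or bmi_obesity")
  store <- patient_store(reg)
  store_add_entry(store, "physical_sign",
                  list(`Weight` = 95, `Height` = 170,
                       `Sign time` = "2020-01-01T00:00:00"), "p_bmi", "d1")
  store_add_entry(store, "problem_diagnosis",
                  list(`Diagnosis` = "E66",
                       `Date of onset` = "2020-01-01T00:00:00"),
                  "p_icd", "d2")
  store_add_entry(store, "physical_sign",
                  list(`Weight` = 60, `Height` = 180,
                       `Sign time` = "2020-01-01T00:00:00"), "p_thin", "d3")

  nested <- resolve_references(parse_el("obesity_any"), reg)
  inlined <- inline_derived(nested, reg)
  # the inlined tree references only registry concepts
  expect_length(Filter(function(n) isTRUE(n$derived),
                       ehrscreen:::el_concept_nodes(inlined)), 0)
  expect_identical(evaluate(nested, store), evaluate(inlined, store))
  expect_setequal(evaluate(nested, store), c("p_bmi", "p_icd"))

  # compiled form agrees too
  ir <- compile_condition(screening_condition(screening_group("obesity_any")),
                          store)
  expect_identical(run_ir(ir, store), evaluate(nested, store))
})
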