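# Shared fixtures: tiny templates built in code, a memoised synthetic
# store, a grammar-driven random expression generator, a random
# screening-condition generator over the demo concepts, and independent
# brute-force oracles used to cross-check the engine.

.fixtures <- new.env(parent = emptyenv())

# memoised generated store so several test files can share one cohort
get_gen <- function(n = 200, seed = 101) {
  key <- paste0("gen_", n, "_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_store(generator_config(n_patients = n,
                                                        seed = seed))
  }
  .fixtures[[key]]
}

minimal_template_json <- function() {
  '{
    "template_id": "mini", "concept_set_name": "Mini",
    "composition_id": "composition.mini",
    "archetypes": [{
      "archetype_id": "openEHR-EHR-EVALUATION.mini.v1",
      "concept_name": "mini",
      "root": {"id": "at0000", "name": "Mini", "rm_type": "ENTRY",
               "path": "/mini",
               "children": [
                 {"id": "at0001", "name": "Flag", "rm_type": "DV_BOOLEAN",
                  "path": "/mini/flag"}
               ]}
    }]
  }'
}

# template with a units attribute on a text node (invalid)
bad_units_template_json <- function() {
  '{
    "template_id": "badu", "concept_set_name": "Bad",
    "composition_id": "composition.badu",
    "archetypes": [{
      "archetype_id": "openEHR-EHR-EVALUATION.badu.v1",
      "concept_name": "badu",
      "root": {"id": "at0000", "name": "Bad", "rm_type": "ENTRY",
               "path": "/badu",
               "children": [
                 {"id": "at0001", "name": "Note", "rm_type": "DV_TEXT",
                  "units": "kg", "path": "/badu/note"}
               ]}
    }]
  }'
}

# ---- random expression generator (grammar-driven) ---------------------

.rand_from <- function(x) x[[sample.int(length(x), 1)]]

.rand_name <- function() {
  .rand_from(list("wbc", "mmse", "heart_rate", "sbp", "x1", "WBC count",
                  "Body site", "drug_a"))
}

.rand_literal <- function() {
  switch(sample.int(4, 1),
    ehrscreen:::el_literal("number",
                           .rand_from(list(0, 1, 7, 24, 38.5, 92, -3, 0.25))),
    ehrscreen:::el_literal("string", .rand_from(list("female", "I61", "icu"))),
    ehrscreen:::el_literal("boolean", sample(c(TRUE, FALSE), 1)),
    ehrscreen:::el_literal("duration",
                           .rand_from(list(3600, 7200, 172800, 86400 * 14,
                                           20 * 365.25 * 86400))))
}

# value-position expression
rand_value_expr <- function(depth) {
  if (depth <= 0) {
    return(switch(sample.int(3, 1),
      .rand_literal(),
      ehrscreen:::el_concept(.rand_name()),
      ehrscreen:::el_attr(ehrscreen:::el_concept(.rand_name()),
                          .rand_from(list("StartTime", "EndTime", "Value")))))
  }
  switch(sample.int(6, 1),
    ehrscreen:::el_binary(.rand_from(list("+", "-", "*", "/", "^")),
                          rand_value_expr(depth - 1),
                          rand_value_expr(depth - 1)),
    {
      op <- rand_value_expr(depth - 1)
      # unary minus over a bare number folds into the literal at parse
      if (op$kind == "literal" && op$ltype == "number")
        op <- ehrscreen:::el_binary("+", op, .rand_literal())
      ehrscreen:::el_unary("-", op)
    },
    ehrscreen:::el_call(.rand_from(list("count", "max", "min", "first",
                                        "last")),
                        list(ehrscreen:::el_concept(.rand_name()))),
    ehrscreen:::el_call("diff", list(rand_value_expr(depth - 1),
                                     rand_value_expr(depth - 1))),
    ehrscreen:::el_call("current_date_time", list()),
    rand_value_expr(depth - 1))
}

rand_bool_expr <- function(depth) {
  if (depth <= 0) {
    return(ehrscreen:::el_binary(
      .rand_from(list("<", "<=", ">", ">=", "=", "!=")),
      rand_value_expr(1), rand_value_expr(1)))
  }
  switch(sample.int(5, 1),
    ehrscreen:::el_binary(.rand_from(list("and", "or")),
                          rand_bool_expr(depth - 1),
                          rand_bool_expr(depth - 1)),
    ehrscreen:::el_unary("not", rand_bool_expr(depth - 1)),
    {
      k <- sample(2:3, 1)
      dir_ops <- if (sample(c(TRUE, FALSE), 1)) c("<", "<=", "=")
                 else c(">", ">=", "=")
      ehrscreen:::el_chain(
        lapply(seq_len(k + 1), function(i) rand_value_expr(1)),
        vapply(seq_len(k), function(i) .rand_from(as.list(dir_ops)),
               character(1)))
    },
    ehrscreen:::el_call("attached",
                        list(ehrscreen:::el_concept(.rand_name()))),
    rand_bool_expr(depth - 1))
}

rand_expr <- function(depth = 3) {
  if (sample(c(TRUE, FALSE), 1)) rand_bool_expr(depth)
  else rand_value_expr(depth)
}

# ---- random screening conditions over the demo concepts ----------------

rand_member_text <- function() {
  qty <- function() {
    pick <- .rand_from(list(
      c("[WBC count]", 4, 15), c("[Platelet count]", 150, 420),
      c("[Hemoglobin]", 95, 175), c("[Systolic blood pressure]", 100, 185),
      c("[Heart rate]", 50, 110), c("[Weight]", 45, 100),
      c("[MMSE score]", 8, 30), c("[Dose]", 10, 600)))
    sprintf("%s %s %s", pick[1],
            .rand_from(list("<", "<=", ">", ">=")),
            round(stats::runif(1, as.numeric(pick[2]), as.numeric(pick[3])),
                  1))
  }
  .rand_from(list(
    qty(), qty(),
    .rand_from(list('Sex = "Female"', 'Sex = "Male"', 'Sex != "Female"')),
    .rand_from(list("[cerebral hemorrhage]", "[cerebral infarction]",
                    "aspirin", "heparin", "clopidogrel", "[WBC count]",
                    "[evacuation of intracerebral hematoma]", "Ward")),
    sprintf("P%dY <= diff(current_date_time(), [Birth date]) <= P%dY",
            sample(10:40, 1), sample(41:80, 1)),
    sprintf("%d <= [Systolic blood pressure] <= %d",
            sample(85:120, 1), sample(121:200, 1)),
    .rand_from(list("[WBC count].count() >= 2", "[WBC count].count() = 0",
                    "[WBC count].last() < [WBC count].first()",
                    "[WBC count].max() - [WBC count].min() < 3",
                    "[MMSE score] < 24",
                    "not attached(sulpiride)",
                    'contains([Findings], "stenosis")',
                    "diff(current_date_time(), [Admission time]) <= P1Y"))))
}

rand_condition <- function(max_groups = 3) {
  n_groups <- sample.int(max_groups, 1)
  groups <- lapply(seq_len(n_groups), function(i) {
    members <- vapply(seq_len(sample.int(2, 1)), function(j)
      rand_member_text(), character(1))
    constraints <- if (stats::runif(1) < 0.3) list(rand_member_text())
                   else list()
    screening_group(members, constraints)
  })
  do.call(screening_condition, groups)
}

# ---- independent oracles ----------------------------------------------

# Allen relations written directly as endpoint predicates (the printed
# inequality chains), independent of the package classifier.
allen_oracle <- list(
  Before       = function(s1, e1, s2, e2) s1 < e1 && e1 < s2 && s2 < e2,
  Meets        = function(s1, e1, s2, e2) s1 < e1 && e1 == s2 && s2 < e2,
  Overlaps     = function(s1, e1, s2, e2) s1 < s2 && s2 < e1 && e1 < e2,
  Begins       = function(s1, e1, s2, e2) s1 == s2 && s2 < e1 && e1 < e2,
  BegunBy      = function(s1, e1, s2, e2) s1 == s2 && s2 < e2 && e2 < e1,
  During       = function(s1, e1, s2, e2) s2 < s1 && s1 < e1 && e1 < e2,
  Contains     = function(s1, e1, s2, e2) s1 < s2 && s2 < e2 && e2 < e1,
  Equals       = function(s1, e1, s2, e2) s1 == s2 && s2 < e2 && e2 == e1,
  OverlappedBy = function(s1, e1, s2, e2) s2 < s1 && s1 < e2 && e2 < e1,
  Ends         = function(s1, e1, s2, e2) s2 < s1 && s1 < e1 && e1 == e2,
  EndedBy      = function(s1, e1, s2, e2) s1 < s2 && s2 < e2 && e2 == e1,
  MetBy        = function(s1, e1, s2, e2) s2 < e2 && e2 == s1 && s1 < e1,
  After        = function(s1, e1, s2, e2) s2 < e2 && e2 < s1 && s1 < e1
)

# all strict intervals with integer endpoints on [0, hi]
grid_intervals <- function(hi = 4) {
  out <- list()
  for (s in 0:(hi - 1)) for (e in (s + 1):hi) {
    out[[length(out) + 1L]] <- list(start = s, end = e)
  }
  out
}

# ---- brute-force benchmark-query oracles (document-level) --------------

bf_docs <- function(store, index) store$docs[[index]] %||% list()
`%||%` <- function(a, b) if (is.null(a)) b else a

bf_patient_field <- function(store, index, pid, field) {
  out <- list()
  for (d in bf_docs(store, index)) {
    if (d$patient_id == pid && !is.null(d$fields[[field]]))
      out <- c(out, list(d$fields[[field]]))
  }
  out
}

bf_person <- function(store, pid) {
  for (d in bf_docs(store, "person")) {
    if (d$patient_id == pid) return(d$fields)
  }
  NULL
}

bf_age_years <- function(store, pid) {
  p <- bf_person(store, pid)
  if (is.null(p) || is.null(p$person_Birth_date)) return(NA_real_)
  (store$clock - parse_timestamp(p$person_Birth_date)) / (365.25 * 86400)
}

bf_has_order_code <- function(store, pid, code) {
  any(unlist(bf_patient_field(store, "order", pid,
                              "order_Order_item_code")) == code)
}

bf_has_diagnosis <- function(store, pid, codes) {
  any(unlist(bf_patient_field(store, "problem_diagnosis", pid,
                              "problem_diagnosis_Diagnosis_code")) %in% codes)
}

bf_is_female <- function(store, pid) {
  p <- bf_person(store, pid)
  !is.null(p) && identical(p$person_Sex_keyword, "Female")
}

bf_last_wbc <- function(store, pid) {
  recs <- list()
  for (d in bf_docs(store, "lab_test")) {
    if (d$patient_id == pid && !is.null(d$fields$lab_test_WBC_count)) {
      recs[[length(recs) + 1L]] <- list(
        v = d$fields$lab_test_WBC_count,
        t = parse_timestamp(d$fields$lab_test_Result_time %||% d$timestamp),
        id = d$id)
    }
  }
  if (length(recs) == 0) return(NA_real_)
  ts <- vapply(recs, `[[`, numeric(1), "t")
  ids <- vapply(recs, `[[`, character(1), "id")
  recs[[order(ts, ids)[length(recs)]]]$v
}

# the six benchmark queries, evaluated purely over raw documents
bf_query <- function(store, pid, label) {
  age <- function(lo, hi) {
    a <- bf_age_years(store, pid)
    !is.na(a) && a >= lo && a <= hi
  }
  switch(label,
    query1 = bf_has_order_code(store, pid, "P0124"),
    query2 = bf_is_female(store, pid) && age(20, 60),
    query3 = bf_is_female(store, pid) && age(60, 70) &&
      bf_has_diagnosis(store, pid, c("I61", "I63")),
    query4 = bf_is_female(store, pid) && age(60, 70) &&
      bf_has_diagnosis(store, pid, c("I61", "I63")) &&
      bf_has_order_code(store, pid, "B01AC06"),
    query5 = bf_is_female(store, pid) && age(60, 70) &&
      bf_has_diagnosis(store, pid, c("I61", "I63")) &&
      bf_has_order_code(store, pid, "B01AC06") &&
      length(bf_patient_field(store, "lab_test", pid,
                              "lab_test_WBC_count")) > 0,
    query6 = { v <- bf_last_wbc(store, pid); !is.na(v) && v > 10 },
    stop("unknown label ", label))
}

bf_query_set <- function(store, label) {
  pids <- store_patients(store)
  sort(pids[vapply(pids, function(p) isTRUE(bf_query(store, p, label)),
                   logical(1))])
}
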