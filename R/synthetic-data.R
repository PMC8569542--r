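# Seeded synthetic patient stores over the bundled 7-template demo set
# (person, patient admission, laboratory test, order, imaging
# examination, physical sign, problem diagnosis). The generator emulates
# a stroke-care data repository at desk scale: coded diagnoses on a tiny
# ICD-10-like list (cerebral hemorrhage/infarction among them), cell
# counts with units, medication/procedure orders (aspirin, heparin,
# evacuation of intracerebral hematoma), vital signs and cognitive
# scores. Scenario plants force a known minimum of eligible patients for
# the benchmark queries; ground truth comes from the reference evaluator
# and is independently recomputable by brute force over the documents.

#' Paths of the bundled demo templates
#' @return character vector of 7 JSON paths.
#' @export
demo_template_files <- function() {
  dir <- system.file("extdata", "templates", package = "ehrscreen")
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  sort(files)
}

#' Load the bundled demo templates
#' @return named list of 7 `template` objects.
#' @export
demo_templates <- function() {
  out <- lapply(demo_template_files(), load_template)
  names(out) <- vapply(out, `[[`, character(1), "template_id")
  out
}

#' Demo concept registry
#'
#' Registry over the 7 demo templates with the screening-relevant time
#' bindings applied: laboratory concepts anchor to the result time,
#' order concepts to their start/stop times.
#'
#' @return a `concept_registry`.
#' @export
demo_registry <- function() {
  reg <- concept_registry(demo_templates())
  for (p in c("/lab_test/lab_test/wbc_count",
              "/lab_test/lab_test/platelet_count",
              "/lab_test/lab_test/hemoglobin")) {
    bind_time_attributes(reg, p,
                         start_path = "/lab_test/lab_test/result_time")
  }
  bind_time_attributes(reg, "/order/order/order_item",
                       start_path = "/order/order/start_time",
                       end_path = "/order/order/stop_time")
  reg
}

#' Generator configuration
#'
#' Defaults describe the study conditions the generator emulates: a
#' mixed-sex stroke-flavoured cohort born 1936-2005, WBC counts
#' log-normal around 7.5e9/L, diagnosis prevalences concentrated on
#' cerebrovascular codes, and a drug/procedure mix dominated by
#' antiplatelets. `plant` lists benchmark queries that must have at
#' least k eligible patients by construction.
#'
#' @param n_patients cohort size.
#' @param seed RNG seed; fully determines the output.
#' @param clock "now" for the store (age computations are relative to it).
#' @param plant named list, e.g. `list(query1 = 5)`; supported labels
#'   query1..query6.
#' @return a `generator_config`.
#' @export
generator_config <- function(n_patients = 300, seed = 1,
                             clock = "2021-01-01T00:00:00",
                             plant = list(query1 = 5, query4 = 6,
                                          query5 = 4)) {
  if (n_patients < 0) stop("n_patients must be >= 0", call. = FALSE)
  for (k in names(plant)) {
    if (plant[[k]] > n_patients)
      stop("infeasible plant: ", k, " needs ", plant[[k]],
           " eligible patients but n_patients = ", n_patients,
           call. = FALSE)
  }
  structure(list(
    n_patients = n_patients, seed = seed, clock = clock, plant = plant,
    birth_range = c("1936-01-01", "2005-12-31"),
    event_range = c("2019-06-01T00:00:00", "2020-12-01T00:00:00"),
    sex_ratio = 0.5,
    mean_admissions = 1.0, mean_labs = 1.6, mean_orders = 1.3,
    mean_diagnoses = 1.0, mean_imaging = 0.5, mean_signs = 1.2,
    wbc_meanlog = log(7.5), wbc_sdlog = 0.28,
    diagnosis_codes = c(I61 = 0.12, I63 = 0.18, I60 = 0.05, E66 = 0.12,
                        G20 = 0.05, I10 = 0.48),
    order_codes = c(B01AC06 = 0.30, B01AC04 = 0.15, B01AB01 = 0.10,
                    N02BE01 = 0.27, N05AL01 = 0.05, N05AX08 = 0.05,
                    P0124 = 0.08)
  ), class = "generator_config")
}

.rand_time <- function(n, from, to) {
  a <- parse_timestamp(from); b <- parse_timestamp(to)
  secs <- a + floor(stats::runif(n) * (b - a))
  format_timestamp(secs - secs %% 60) # whole minutes keep output stable
}

.rand_date <- function(n, from, to) {
  substr(.rand_time(n, from, to), 1, 10)
}

.r1 <- function(x) round(x, 1)

.gen_person_entry <- function(cfg, sex = NULL, birth = NULL) {
  sex <- sex %||% if (stats::runif(1) < cfg$sex_ratio) "F" else "M"
  birth <- birth %||% .rand_date(1, cfg$birth_range[1], cfg$birth_range[2])
  list(`Sex` = sex, `Birth date` = birth,
       `Full name` = paste0("patient ", substr(birth, 1, 4)),
       `National id` = paste0("nid-", floor(stats::runif(1) * 1e8)))
}

.gen_lab_entry <- function(cfg, wbc = NULL) {
  t <- .rand_time(1, cfg$event_range[1], cfg$event_range[2])
  entry <- list(`Result time` = t, `Specimen` = "venous blood")
  entry$`WBC count` <- .r1(wbc %||% stats::rlnorm(1, cfg$wbc_meanlog,
                                                  cfg$wbc_sdlog))
  if (stats::runif(1) < 0.4)
    entry$`Platelet count` <- .r1(stats::rnorm(1, 250, 60))
  if (stats::runif(1) < 0.4)
    entry$`Hemoglobin` <- .r1(stats::rnorm(1, 135, 15))
  n_panel <- stats::rpois(1, 0.7)
  if (n_panel > 0) {
    entry$`Analyte panel` <- lapply(seq_len(n_panel), function(i)
      list(`Analyte name` = sample(c("CRP", "urea", "creatinine"), 1),
           `Analyte value` = .r1(stats::runif(1, 0.5, 20))))
  }
  entry
}

.gen_order_entry <- function(cfg, code = NULL) {
  code <- code %||% sample(names(cfg$order_codes), 1, prob = cfg$order_codes)
  start <- .rand_time(1, cfg$event_range[1], cfg$event_range[2])
  stop_t <- format_timestamp(parse_timestamp(start) +
                               sample(1:30, 1) * 86400)
  list(`Order item` = code, `Start time` = start, `Stop time` = stop_t,
       `Dose` = .r1(sample(c(25, 50, 100, 250, 500), 1)))
}

.gen_diagnosis_entry <- function(cfg, code = NULL) {
  code <- code %||% sample(names(cfg$diagnosis_codes), 1,
                           prob = cfg$diagnosis_codes)
  list(`Diagnosis` = code,
       `Date of onset` = .rand_time(1, cfg$event_range[1],
                                    cfg$event_range[2]),
       `Clinical description` = sample(
         c("acute onset with focal deficit", "found on routine screening",
           "progressive over weeks", "recurrent episode"), 1),
       `Body site` = sample(c("left hemisphere", "right hemisphere",
                              "brainstem", "not applicable"), 1))
}

.gen_sign_entry <- function(cfg) {
  list(`Systolic blood pressure` = .r1(stats::rnorm(1, 135, 20)),
       `Heart rate` = .r1(stats::rnorm(1, 76, 12)),
       `Body temperature` = .r1(stats::rnorm(1, 36.8, 0.4)),
       `Blood oxygen saturation` = .r1(pmin(100, stats::rnorm(1, 96, 2))),
       `Height` = .r1(stats::rnorm(1, 165, 8)),
       `Weight` = .r1(stats::rnorm(1, 67, 13)),
       `MMSE score` = sample(8:30, 1),
       `MoCA score` = sample(8:30, 1),
       `Sign time` = .rand_time(1, cfg$event_range[1], cfg$event_range[2]))
}

.gen_imaging_entry <- function(cfg) {
  list(`Examination name` = sample(c("CT head", "MRI brain", "CT angiography"),
                                   1),
       `Findings` = sample(
         c("no acute abnormality", "hypodense lesion left MCA territory",
           "intracerebral hematoma with mass effect",
           "severe coronary stenosis incidentally noted"), 1),
       `Examination time` = .rand_time(1, cfg$event_range[1],
                                       cfg$event_range[2]))
}

#' The six benchmark screening conditions
#'
#' Screening conditions over the demo concept set: a procedure cohort
#' (evacuation of intracerebral hematoma), two demographic cohorts
#' (female 20-60, female 60-70 with cerebral hemorrhage/infarction),
#' their refinements with aspirin exposure and a WBC laboratory test,
#' and a collection query on the last WBC count exceeding 10 (in units
#' of 10^9/L).
#'
#' @return named list of six `screening_condition` objects.
#' @export
table_queries <- function() {
  age_between <- function(lo, hi) {
    sprintf("P%dY <= diff(current_date_time(), [Birth date]) <= P%dY", lo, hi)
  }
  list(
    query1 = screening_condition(
      screening_group("[evacuation of intracerebral hematoma]")),
    query2 = screening_condition(
      screening_group('Sex = "Female"'),
      screening_group(age_between(20, 60))),
    query3 = screening_condition(
      screening_group('Sex = "Female"'),
      screening_group(age_between(60, 70)),
      screening_group(c("[cerebral hemorrhage]", "[cerebral infarction]"))),
    query4 = screening_condition(
      screening_group('Sex = "Female"'),
      screening_group(age_between(60, 70)),
      screening_group(c("[cerebral hemorrhage]", "[cerebral infarction]")),
      screening_group("aspirin")),
    query5 = screening_condition(
      screening_group('Sex = "Female"'),
      screening_group(age_between(60, 70)),
      screening_group(c("[cerebral hemorrhage]", "[cerebral infarction]")),
      screening_group("[WBC count]"),
      screening_group("aspirin")),
    query6 = screening_condition(
      screening_group("[WBC count].last() > 10"))
  )
}

#' Generate a synthetic patient store
#'
#' Fully seeded: the same configuration yields byte-identical NDJSON.
#' Planted patients are rewritten after random generation so the target
#' queries have at least the requested number of eligible patients;
#' ground truth (planted ids plus incidental matches) is computed with
#' the reference evaluator for all six benchmark queries.
#'
#' @param config a `generator_config`.
#' @return list(store, ground_truth, conditions, planted).
#' @export
generate_store <- function(config = generator_config()) {
  set.seed(config$seed)
  cfg <- config
  registry <- demo_registry()
  store <- patient_store(registry, clock = cfg$clock)
  pids <- sprintf("p%04d", seq_len(cfg$n_patients))
  doc_n <- 0L
  nid <- function() { doc_n <<- doc_n + 1L; sprintf("d%06d", doc_n) }
  add <- function(tpl, entry, pid, ts = NULL) {
    store_add_entry(store, tpl, entry, pid, nid(), timestamp = ts)
  }
  for (pid in pids) {
    person <- .gen_person_entry(cfg)
    add("person", person, pid, ts = person$`Birth date`)
    for (i in seq_len(stats::rpois(1, cfg$mean_admissions))) {
      adm_t <- .rand_time(1, cfg$event_range[1], cfg$event_range[2])
      add("patient_admission",
          list(`Admission time` = adm_t,
               `Discharge time` = format_timestamp(
                 parse_timestamp(adm_t) + sample(2:21, 1) * 86400),
               `Ward` = sample(c("neurology", "icu", "general"), 1),
               `Admission type` = sample(c("E", "P"), 1)),
          pid)
    }
    for (i in seq_len(stats::rpois(1, cfg$mean_labs)))
      add("lab_test", .gen_lab_entry(cfg), pid)
    for (i in seq_len(stats::rpois(1, cfg$mean_orders)))
      add("order", .gen_order_entry(cfg), pid)
    for (i in seq_len(stats::rpois(1, cfg$mean_diagnoses)))
      add("problem_diagnosis", .gen_diagnosis_entry(cfg), pid)
    for (i in seq_len(stats::rpois(1, cfg$mean_signs)))
      add("physical_sign", .gen_sign_entry(cfg), pid)
    for (i in seq_len(stats::rpois(1, cfg$mean_imaging)))
      add("imaging_examination", .gen_imaging_entry(cfg), pid)
  }
  # plants: force eligibility by rewriting/adding records for chosen ids
  planted <- list()
  if (cfg$n_patients > 0 && length(cfg$plant) > 0) {
    shuffled <- sample(pids)
    taken <- 0L
    force_demographics <- function(pid, sex, age_years) {
      birth <- substr(format_timestamp(
        parse_timestamp(cfg$clock) - age_years * .SECONDS_PER_YEAR), 1, 10)
      person <- .gen_person_entry(cfg, sex = sex, birth = birth)
      docs <- store$docs$person
      for (i in seq_along(docs)) {
        if (docs[[i]]$patient_id == pid) {
          store$docs$person[[i]] <- flatten_entry(
            registry$templates$person, person, pid, docs[[i]]$id,
            timestamp = birth)
        }
      }
    }
    for (label in names(cfg$plant)) {
      k <- cfg$plant[[label]]
      ids <- shuffled[seq_len(k) + taken]
      taken <- taken + k
      for (pid in ids) {
        switch(label,
          query1 = add("order", .gen_order_entry(cfg, code = "P0124"), pid),
          query2 = force_demographics(pid, "F", stats::runif(1, 25, 55)),
          query3 = {
            force_demographics(pid, "F", stats::runif(1, 61, 69))
            add("problem_diagnosis",
                .gen_diagnosis_entry(cfg, code = sample(c("I61", "I63"), 1)),
                pid)
          },
          query4 = , query5 = {
            force_demographics(pid, "F", stats::runif(1, 61, 69))
            add("problem_diagnosis",
                .gen_diagnosis_entry(cfg, code = sample(c("I61", "I63"), 1)),
                pid)
            add("order", .gen_order_entry(cfg, code = "B01AC06"), pid)
            if (label == "query5")
              add("lab_test", .gen_lab_entry(cfg), pid)
          },
          query6 = add("lab_test",
                       .gen_lab_entry(cfg, wbc = stats::runif(1, 10.5, 18)),
                       pid),
          stop("unknown plant label: ", label, call. = FALSE))
      }
      planted[[label]] <- sort(ids)
    }
  }
  conditions <- table_queries()
  ground_truth <- lapply(conditions, evaluate, store = store)
  list(store = store, ground_truth = ground_truth, conditions = conditions,
       planted = planted)
}

#' Benchmark scenario fixtures
#'
#' One fixture per benchmark query over a shared seeded store:
#' `list(label, condition, store, expected)` where `expected` is the
#' reference evaluator's result set.
#'
#' @param seed generator seed.
#' @param n_patients cohort size.
#' @return list of six fixtures.
#' @export
scenario_suite <- function(seed = 1, n_patients = 300) {
  gen <- generate_store(generator_config(n_patients = n_patients,
                                         seed = seed))
  lapply(names(gen$conditions), function(label) {
    list(label = label, condition = gen$conditions[[label]],
         store = gen$store, expected = gen$ground_truth[[label]])
  })
}

#' Write a generated store with its ground truth
#'
#' @param gen result of [generate_store()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_generated_store <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  store_write_ndjson(gen$store, file.path(dir, "store.ndjson"))
  jsonlite::write_json(gen$ground_truth,
                       file.path(dir, "ground_truth.json"))
  for (s in gen$store$schemas) {
    emit_es_mapping(s, file.path(dir, paste0(s$index_name, ".mapping.json")))
  }
  invisible(dir)
}
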