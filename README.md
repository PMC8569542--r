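# ehrscreen

Cohort selection ("patient screening") for clinical research over
electronic health records modelled with openEHR-style templates.

Recruiting for a study means executing eligibility criteria — *female,
60–70 years, cerebral hemorrhage or infarction, taking aspirin* —
against an EHR repository. The two standing obstacles are **concept
mismatch** (criteria reference derived concepts such as BMI or
"cognitive impairment" that are not stored fields) and **query cost**
(collection constraints like "WBC count decreasing" and temporal
constraints like "heparin within 48 hours" translate into joins and
subqueries that relational storage handles poorly). ehrscreen
implements a template-driven screening pipeline that addresses both:

1. **Concepts from templates.** Clinical templates (a documented JSON
   dialect of openEHR composition templates) are parsed and every
   attribute node becomes a screening concept with the attributes
   *Name, Parent, Path, Type, Unit, StartTime, EndTime, Value*; coded
   values (e.g. ICD-10 I61) become sub-concepts, and time anchors are
   bound per study (`load_template()`, `define_concepts()`,
   `bind_time_attributes()`).
2. **Criteria in an expression language.** A subset of the openEHR
   Expression Language with arithmetic, comparison chains
   (`27 < mmse < 30`), durations (`PT48H`, `P20Y`), collection
   functions (`count/max/min/first/last`), `diff()`,
   `current_date_time()` and `attached()`; derived concepts are
   defined with `:=` and inline recursively
   (`BMI := weight / height ^ 2`).
3. **Temporal algebra.** The 13 Allen interval relations as both
   expression templates and an executable classifier, plus a
   duration-gap extension `diff(a, b) ⋛ interval`.
4. **Hierarchical index mapping.** Each template maps to one document
   index: generic/keyword/fulltext leaf fields (coded and free-text
   strings get both `_keyword` and `_text` fields), recursive
   underscore naming (`problem_diagnosis_Body_site`), object fields
   for slotted archetypes and nested fields for collections —
   join-free storage emitted as Elasticsearch 7.x mappings.
5. **Two-phase execution.** Conditions (AND-connected groups with OR
   within a group) compile to index predicates wherever exact — term,
   range, exists, clock-anchored date ranges — and to client-side
   post-filters for collection/temporal residue. A reference in-memory
   engine defines the semantics; the compiled route must return the
   identical result set, and per-group hit counts are reported as in
   interactive condition building.
6. **Synthetic cohorts.** A seeded generator over the bundled
   7-template demo set (person, admission, lab, order, imaging,
   physical sign, problem diagnosis) with planted eligible patients
   and brute-force-checkable ground truth for six benchmark queries.

## Worked example

```r
library(ehrscreen)

reg <- demo_registry()          # concepts from the 7 bundled templates
length(reg$concepts)
#> [1] 67

# seeded synthetic cohort of 300 patients
gen <- generate_store(generator_config(n_patients = 300, seed = 1))

# "women 60-70 with cerebral hemorrhage/infarction taking aspirin"
screen(gen$conditions$query4, gen$store)
#> patients matched: 11
#> per-group counts: 147, 50, 81, 103
```

The per-group counts are the independent hit counts of the four
condition groups (female; age 60–70; stroke diagnosis; aspirin); 11
patients satisfy all four. A collection query compiles to a candidate
plus a client-side post-filter:

```r
ir <- compile_condition(gen$conditions$query6, gen$store)
ir
#> <query_ir> indexes: lab_test
#>   post-filter: [WBC count].last() > 10
#>     exists lab_test.lab_test_WBC_count
length(run_ir(ir, gen$store))   # identical to evaluate() on the store
#> [1] 30
```

`emit_es_query(ir)` prints the Elasticsearch Query DSL for the
candidate side, and `emit_es_mapping()` the index mappings. A thin
command-line wrapper with subcommands `concepts`, `parse`,
`constraints`, `map`, `generate`, `compile`, `screen`, `counts` is
installed at `inst/cli/ehrscreen`.

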