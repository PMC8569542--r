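---
title: "Screening patients from openEHR-modelled records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening patients from openEHR-modelled records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrscreen)
```

## The problem

Recruiting patients for clinical research means turning free-text
eligibility criteria ("female, 60–70, cerebral hemorrhage or infarction,
on aspirin") into queries over an EHR repository. Two things make this
hard. First, *concept mismatch*: many criteria reference derived
concepts — BMI, "cognitive impairment", "chemotherapy exposure" — that
are not stored fields but combinations of stored fields. Second, *query
expressiveness and cost*: collection constraints ("WBC count
decreasing") and temporal constraints ("heparin within 48 hours") are
awkward in SQL, and normalised relational storage forces joins and
subqueries that scale poorly.

ehrscreen addresses both within the openEHR modelling tradition: the
clinical templates that define the EHR's structure are reused as the
source of screening concepts, a subset of the openEHR Expression
Language (EL) expresses criteria over those concepts, and each template
is mapped to a single hierarchical document index (Elasticsearch-style)
so that one patient's data for one concept family never needs a join.

## From templates to concepts

A template is treated as a *concept set*; every attribute node in it
becomes a screening concept described by eight attributes: Name,
Parent, Path, Type, Unit, StartTime, EndTime, Value. The derivation
rules are mechanical:

* the node's ontology name becomes the concept Name, its data type the
  Type, its template path the Path (paths are the identifiers; display
  names may repeat across templates and must then be referenced by
  path);
* the parent concept is recovered from the path prefix;
* `units` of a DV_QUANTITY node becomes the Unit;
* each `defining_code` of a DV_CODED_TEXT node becomes a sub-concept
  under the node's concept, carrying its code as Value — this is how
  "cerebral hemorrhage" (ICD-10 I61) exists as a referenceable concept;
* StartTime/EndTime are deliberately *not* extracted: which clinical
  time anchors a concept (result time vs specimen time of a lab test)
  depends on the study, so bindings are applied per scenario with
  `bind_time_attributes()`.

Template-level default values are recorded on `Concept$value` but never
applied during screening; nothing in the screening semantics consumes
them.

## The expression subset

The grammar covers what screening conditions actually use: arithmetic
(`+ - * / ^`), comparisons with inequality chains (`27 < mmse < 30`),
boolean connectives, ISO-8601 duration literals (`PT48H`, `P20Y`),
attribute access (`.StartTime .EndTime .Value`), the collection
functions `count/max/min/first/last`, and `diff()`,
`current_date_time()`, `attached()`, `contains()`. Precedence, tightest
first: `^`, unary `-`, `* /`, `+ -`, comparisons, `not`, `and`, `or`.
`:=` introduces derived-concept definitions (`BMI := weight /
height ^ 2`); `=` is equality.

Decisions worth recording:

* **Chains may contain `=`.** The Allen relation patterns are written
  as chains like `a.StartTime < a.EndTime = b.StartTime < b.EndTime`,
  so chain operators are one direction of `< <=` (or `> >=`) freely
  mixed with `=`.
* **Chains desugar to conjunctions.** `a < b < c` is *defined* as
  `(a < b) and (b < c)`. Under the existential semantics below this
  means a chain over a repeated concept does not force one entry to
  satisfy both bounds; the property suite checks the equivalence
  explicitly.
* **Durations are a fixed linear scale**: months count 30.4375 days,
  years 365.25 days. Ages are computed as
  `diff(current_date_time(), birth_date)` compared against `PnY`
  literals; the clock is injectable so results are reproducible.
* **`diff()` is signed** (first argument minus second); an
  antisymmetry property covers the choice, and `within_constraint()`
  provides the absolute-value reading of "within d" prose.
* **Forward references are rejected at definition time**, so a derived
  concept library is acyclic by construction; `dependency_order()`
  still detects cycles in hand-built libraries and orders definitions
  so intermediates are generated first.

## Temporal and collection constraints

The 13 Allen relations between two strict intervals are shipped both
as expression templates (`relation_expression()`) and as an executable
classifier (`classify_relation()`). Point events (start = end) are
rejected rather than silently classified, because the defining chains
compare an interval's own endpoints with strict `<`; callers may pad
point events by an epsilon of their choosing. An exhaustive enumeration
over integer endpoints verifies that the relations are jointly
exhaustive and pairwise disjoint and that inverse symmetry holds.

Collection constraints are predefined as four templates — First time
(`x.count()=1`), Stable (`x.max()-x.min()<v`), Increase
(`x.last()>x.first()`), Decrease (`x.last()<x.first()`) — plus
user-registered ones. The Stable threshold is a required parameter: it
is self-defined knowledge, and inventing a default would smuggle in a
clinical judgement.

## Index mapping

Each composition template maps to exactly one index. Leaf fields come
in three kinds: generic (typed by the value), keyword (exact-match
strings) and fulltext (tokenised strings); coded and free-text string
values get *both* a keyword and a fulltext field (`..._keyword`,
`..._text`) so the same value can be queried as a code or as text.
Field names join the archetype concept name and the ontology name with
underscores ("Body site" in the problem-diagnosis archetype becomes
`problem_diagnosis_Body_site`), recursively through cluster parents;
non-alphanumeric runs collapse to `_`. Non-collection clusters/slots
are object fields whose attributes are flattened; collection clusters
become nested fields that keep sub-document structure. Every index
carries injected `id`, `patient_id` and `timestamp` fields; the
timestamp source is declared per template (or defaults to the first
date/date-time node in document order).

One design choice deserves emphasis: **one document per clinical
entry**, not one per patient. A patient's repeated labs are separate
documents sharing `patient_id`, and collection functions read across
them ordered by bound StartTime (ties broken by document id). The
per-patient alternative would push every repeated entry into nested
arrays and complicate the reference semantics without changing any
result set; the trade-off is that per-patient conjunctions cannot be a
single per-document index query — which the two-phase execution below
absorbs anyway.

## Execution semantics and the two-phase compiler

The in-memory reference engine *is* the semantics:

* a bare comparison over a repeated concept is true iff **some** entry
  satisfies it (existential); two concept references in one comparison
  pair up by cross product;
* a missing concept or attribute makes comparisons false, `attached()`
  false and `count()` zero;
* quantities compare by magnitude; two unit-carrying quantities with
  different unit strings raise an error (no UCUM conversion — unit
  strings must match exactly);
* `current_date_time()` reads the store clock.

Conditions are ordered groups: members within a group are ORed,
constraints and groups are ANDed, and `screen()` reports per-group
counts alongside the intersection, mirroring interactive condition
building where each group's hit count is shown immediately.

Compilation is two-phase because no index query language expresses
cross-entry collection comparisons (`max - min`, `last < first`) or
two-concept temporal chains per document. Whatever compiles exactly to
index predicates does so: concept-vs-literal comparisons become
term/range predicates, coded-concept membership becomes a term on the
code field, and clock-relative duration comparisons over date concepts
rewrite to date ranges anchored at the compile-time clock (this is why
a pure demographic query compiles with no client-side residue).
Everything else becomes a *candidate* — exists-predicates over the
referenced concepts when the expression demands at least one entry of
each, match-all when it can hold vacuously (`count() = 0`, negations) —
plus a post-filter that re-evaluates the exact expression per candidate
patient. Dropping the post-filters therefore always yields a superset;
the randomized property suite checks `run_ir(compile(c)) = evaluate(c)`
exactly, which is the package's correctness criterion: both execution
routes must return identical result sets.

The Elasticsearch emitter serialises the candidate side as 7.x Query
DSL (`bool`/`term`/`range`/`exists`/`nested`); for a condition spanning
several indexes it emits one over-approximating candidate query per
index, and exactness lives in the client-side combination — the IR
interpreter documents precisely what a driver against a live cluster
must do.

## The synthetic cohort

The generator emulates a stroke-care repository at desk scale over the
seven bundled templates. Defaults (chosen once as plausible for such a
cohort, and fixed): births uniform 1936–2005 so the 20–60 and 60–70
windows are well populated; WBC counts log-normal with median
7.5×10⁹/L and σ(log) = 0.28, putting roughly one patient in seven
above the 10×10⁹/L threshold; diagnosis prevalences concentrated on
cerebrovascular codes (I63 18 %, I61 12 %); orders dominated by
antiplatelets with the hematoma-evacuation procedure at 8 % of orders;
event counts Poisson with means around 1–1.6 per record family. Plants
rewrite a few patients post hoc so the rarest benchmark queries are
guaranteed non-empty; ground truth is whatever the reference evaluator
returns (planted plus incidental matches) and is recomputed
independently by brute-force document scans in the test suite.

What the generator does *not* emulate: longitudinal disease
trajectories, correlated vitals, realistic code co-occurrence, missing
person records, or free-text clinical narrative beyond a small phrase
pool. Passing tests therefore demonstrate engine correctness on
structurally faithful data, not clinical realism, and say nothing
about representability of criteria beyond the constructs the grammar
covers.

## Problem sizes and numerical choices

The shipped suites use cohorts of 200–300 patients (a few thousand
documents), 100 random conditions for the compiler-equivalence
property, 1000+ random expressions for the parser round-trip, and the
full 10×10-interval grid for the temporal algebra — sizes at which
every property is checked exhaustively or with comfortable margins on
a single CPU. Cross-product expansion in the evaluator is capped at
10⁴ value pairs per operator as a guard against pathological
expressions. Timestamps are whole seconds; document order is made
deterministic by sorting on (StartTime, document id).

## Known limitations

* No AQL, no archetype specialization, no terminology-service lookup;
  templates arrive in the package's JSON dialect, not ADL/OPT.
* Aggregations beyond count/max/min/first/last (e.g. averages per time
  window) are out of scope, as is per-entry field coupling ("value
  where name = X" within one comparison) — model such analytes as
  separate template nodes instead.
* Unit handling is strict string equality.
* The ES emitter is pinned to the 7.x dialect and is an output format;
  result-set semantics are defined by the in-memory engine.
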