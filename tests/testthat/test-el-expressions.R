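# Expression language: parsing, unparsing, resolution, dependencies.

test_that("documented screening expressions parse to the expected shapes", {
  d <- parse_el("BMI := weight/height^2")
  expect_identical(d$kind, "definition")
  expect_identical(d$name, "BMI")
  expect_identical(d$expr$op, "/")
  expect_identical(d$expr$rhs$op, "^") # exponent binds tighter than division

  ch <- parse_el("27<mmse<30")
  expect_identical(ch$kind, "chain")
  expect_length(ch$terms, 3)
  expect_identical(ch$ops, c("<", "<"))
  desugared <- ehrscreen:::el_desugar_chain(ch)
  expect_true(el_equal(desugared, parse_el("(27 < mmse) and (mmse < 30)")))

  dual <- parse_el("attached(aspirin) or attached(clopidogrel)")
  expect_identical(dual$op, "or")
  expect_identical(dual$lhs$fname, "attached")

  # typographic comparators normalise
  expect_true(el_equal(parse_el("mmse ≤ 24"), parse_el("mmse <= 24")))
})

test_that("malformed input produces located syntax errors", {
  expect_error(parse_el("a <<"), "syntax error at line 1")
  expect_error(parse_el("foo(1)"), "unknown function")
  expect_error(parse_el("diff(a)"), "takes 2 argument")
  expect_error(parse_el("a.count"), "expected '\\('")
  expect_error(parse_el("1 < 2 > 3"), "one direction")
  expect_error(parse_el("(a"), "expected '\\)'")
  expect_error(parse_el('"open'), "unterminated string")
})

test_that("operator precedence follows the documented order", {
  # ^  >  unary -  >  * /  >  + -  >  comparisons  >  not  >  and  >  or
  expect_identical(el_unparse(parse_el("1+2*3")), "1 + 2 * 3")
  expect_identical(el_unparse(parse_el("(1+2)*3")), "(1 + 2) * 3")
  e <- parse_el("-2^2") # = -(2^2)
  expect_identical(e$kind, "unary")
  expect_identical(e$operand$op, "^")
  e2 <- parse_el("2^3^2") # right-associative
  expect_identical(e2$rhs$op, "^")
  e3 <- parse_el("not a < 1 and b > 2")
  expect_identical(e3$op, "and")
  expect_identical(e3$lhs$kind, "unary")
  e4 <- parse_el("a and b or c")
  expect_identical(e4$op, "or")
})

test_that("unparse is canonical and round-trips", {
  expect_identical(el_unparse(parse_el("BMI:=weight/height^2")),
                   "BMI := weight / height ^ 2")
  expect_identical(el_unparse(parse_el("38.5")), "38.5")
  expect_identical(el_unparse(parse_el("[WBC count].count()=1")),
                   "[WBC count].count() = 1")
  # canonical text is a fixed point after one pass
  for (txt in c(
    "current_date_time() - encounter.StartTime",
    paste("([Systolic blood pressure] >= 120 and",
          "[Systolic blood pressure] <= 220) and",
          "(40 <= [Heart rate] <= 100) and",
          "[Blood oxygen saturation] >= 92 and [Body temperature] <= 38.5"),
    "27 < mmse < 30",
    "attached(aspirin) or attached(clopidogrel)",
    "cognitive_impairment_diagnosis or mmse < 24 or moca < 26",
    "obesity_diagnosis or icd_10_obesity or bmi_obesity",
    "attached(sulpiride) or attached(risperidone)")) {
    once <- el_unparse(parse_el(txt))
    expect_identical(el_unparse(parse_el(once)), once)
    expect_true(el_equal(parse_el(once), parse_el(txt)))
  }
})

test_that("random expression trees survive parse(unparse(.)) structurally", {
  set.seed(42)
  for (i in 1:400) {
    ast <- rand_expr(depth = sample(1:4, 1))
    txt <- el_unparse(ast)
    back <- parse_el(txt)
    expect_true(el_equal(back, ast), info = txt)
  }
})

test_that("references resolve to unique paths, with ambiguity reported", {
  reg <- demo_registry()
  r <- resolve_references(parse_el("[MMSE score] < 24"), reg)
  expect_identical(r$lhs$path, "/physical_sign/physical_sign/mmse_score")

  expect_error(resolve_references(parse_el("no_such_thing < 1"), reg),
               "unresolved reference")

  # same display name registered under two templates -> ambiguity listing
  # both candidate paths
  t1 <- load_template(minimal_template_json())
  t2 <- load_template(gsub("mini", "mini2", minimal_template_json()))
  reg2 <- concept_registry(list(t1, t2))
  expect_error(resolve_references(parse_el("Flag = true"), reg2),
               "ambiguous.*'Flag'.*(/mini/mini/flag).*(/mini2/mini2/flag)")
  # full paths stay unambiguous
  r2 <- resolve_references(parse_el("[/mini/mini/flag] = true"), reg2)
  expect_identical(r2$lhs$path, "/mini/mini/flag")
})

test_that("derived concepts record dependencies and order topologically", {
  reg <- demo_registry()
  define_derived_concept(reg, "BMI := [Weight] / ([Height] / 100) ^ 2")
  define_derived_concept(reg, "bmi_obesity := BMI >= 28")
  define_derived_concept(reg, "icd_10_obesity := attached([obesity])")
  define_derived_concept(reg,
    "obesity_any := icd_10_obesity or bmi_obesity")

  expect_true("BMI" %in% reg$derived$bmi_obesity$dependencies)
  ordered <- names(dependency_order(reg$derived))
  expect_lt(match("BMI", ordered), match("bmi_obesity", ordered))
  expect_lt(match("bmi_obesity", ordered), match("obesity_any", ordered))

  # any topological order must respect brute-force reachability
  reach <- function(from, acc = character(0)) {
    for (d in intersect(reg$derived[[from]]$dependencies,
                        names(reg$derived))) {
      if (!d %in% acc) acc <- reach(d, c(acc, d))
    }
    acc
  }
  for (nm in ordered) {
    for (dep in reach(nm)) expect_lt(match(dep, ordered), match(nm, ordered))
  }

  # name collision with a registered simple concept is rejected
  expect_error(define_derived_concept(reg, "Weight := 1"), "collides")
  # forward references are rejected at definition time, so a dependency
  # cycle can only arise in a hand-built library; the orderer names it
  expect_error(define_derived_concept(reg, "a1 := b1 + 0"),
               "unresolved reference")
  cyc <- list(
    a = structure(list(name = "a", expression = parse_el("b"),
                       dependencies = "b"), class = "derived_concept"),
    b = structure(list(name = "b", expression = parse_el("a"),
                       dependencies = "a"), class = "derived_concept"))
  expect_error(dependency_order(cyc), "cyclic.*a.*b")
})

test_that("derived-concept libraries persist as JSON and reload", {
  reg <- demo_registry()
  define_derived_concept(reg, "BMI := [Weight] / ([Height] / 100) ^ 2")
  define_derived_concept(reg, "bmi_obesity := BMI >= 28")
  f <- tempfile(fileext = ".json")
  derived_to_json(reg, f)
  reg2 <- demo_registry()
  derived_from_json(reg2, f)
  expect_setequal(names(reg2$derived), names(reg$derived))
  expect_true(el_equal(reg2$derived$BMI$expression,
                       reg$derived$BMI$expression))
})
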