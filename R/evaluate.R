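# Reference in-memory evaluator. This engine is the executable
# definition of the screening semantics:
#   * a bare comparison over a repeated concept is TRUE iff SOME entry
#     satisfies it (existential semantics);
#   * collection functions (count/max/min/first/last) operate on the
#     patient's entries ordered by bound StartTime, ties by document id;
#   * a missing concept or attribute makes any comparison FALSE,
#     attached() FALSE and count() zero;
#   * current_date_time() reads the store's injectable clock;
#   * quantities compare by magnitude; two unit-carrying quantities with
#     different unit strings raise an evaluation error (no conversion).

.tv <- function(t, v, unit = NULL) list(t = t, v = v, unit = unit)

# ---- concept bindings -------------------------------------------------

# Resolve how a registry concept is physically stored: which index,
# which main/code fields, its value type, and its effective time fields
# (own binding, else nearest ancestor's, else the document timestamp).
.binding_info <- function(store, path) {
  cached <- store$bindings[[path]]
  if (!is.null(cached)) return(cached)
  registry <- store$registry
  cpt <- registry_get(registry, path)
  index <- tolower(cpt$template_id)
  schema <- store$schemas[[index]]
  if (is.null(schema))
    stop("concept ", path, " has no mapped index", call. = FALSE)
  by_path <- schema_fields_by_path(schema)
  tpl_prefix <- paste0("/", cpt$template_id)
  node_path_of <- function(reg_path) substring(reg_path, nchar(tpl_prefix) + 1)
  field_for_path <- function(reg_path, want_suffixless = TRUE) {
    fs <- by_path[[node_path_of(reg_path)]]
    if (is.null(fs)) return(NULL)
    fs
  }
  main_field_of <- function(fs) {
    # the "value" field: bare name for single-field types, _keyword for
    # dual-annotated strings
    nm <- vapply(fs, `[[`, character(1), "name")
    bare <- fs[vapply(fs, function(f) !grepl("(_keyword|_text|_units|_code)$",
                                             f$name), logical(1))]
    if (length(bare) > 0) return(bare[[1]])
    kw <- fs[vapply(fs, function(f) endsWith(f$name, "_keyword"), logical(1))]
    if (length(kw) > 0) return(kw[[1]])
    fs[[1]]
  }
  eff_binding <- function(p, which) {
    cur <- p
    while (!is.null(cur)) {
      cc <- registry$concepts[[cur]]
      b <- cc[[which]]
      if (!is.null(b)) return(b)
      cur <- cc$parent
    }
    NULL
  }
  time_field <- function(reg_path) {
    if (is.null(reg_path)) return(NULL)
    fs <- field_for_path(reg_path)
    if (is.null(fs)) stop("time binding path not mapped: ", reg_path,
                          call. = FALSE)
    main_field_of(fs)$name
  }
  info <- if (cpt$type == "CODED_VALUE") {
    parent_fs <- field_for_path(cpt$parent)
    code_field <- NULL; kw_field <- NULL
    for (f in parent_fs) {
      if (endsWith(f$name, "_code")) code_field <- f$name
      if (endsWith(f$name, "_keyword")) kw_field <- f$name
    }
    list(index = index, kind = "coded_value", code = cpt$code,
         code_field = code_field, main_field = kw_field, vtype = "str",
         unit = NULL,
         start_field = time_field(eff_binding(path, "start_time_binding")),
         end_field = time_field(eff_binding(path, "end_time_binding")))
  } else if (cpt$type %in% .RM_DATA_TYPES) {
    fs <- field_for_path(path)
    vtype <- switch(cpt$type,
      DV_QUANTITY = "qty", DV_COUNT = "num", DV_BOOLEAN = "bool",
      DV_DATE = "ts", DV_DATE_TIME = "ts", DV_DURATION = "dur",
      "str")
    list(index = index, kind = "data", code = NULL, code_field = NULL,
         main_field = main_field_of(fs)$name, vtype = vtype,
         unit = cpt$unit,
         start_field = time_field(eff_binding(path, "start_time_binding")),
         end_field = time_field(eff_binding(path, "end_time_binding")))
  } else {
    stop("concept at ", path, " (", cpt$type,
         ") is structural and has no stored values", call. = FALSE)
  }
  store$bindings[[path]] <- info
  info
}

# All raw values stored under a field name in one document, searching
# object sub-maps and nested sub-document lists (field names are unique
# across a schema so recursive search is unambiguous).
.gather_field <- function(fields, name) {
  out <- list()
  rec <- function(fs) {
    for (nm in names(fs)) {
      v <- fs[[nm]]
      if (nm == name) {
        if (is.list(v) && is.null(names(v))) out <<- c(out, v)
        else out <<- c(out, list(v))
      } else if (is.list(v) && is.null(names(v))) {
        for (sub in v) rec(sub)
      } else if (is.list(v)) {
        rec(v)
      }
    }
  }
  rec(fields)
  out
}

.raw_to_tv <- function(raw, vtype, unit) {
  switch(vtype,
    num = .tv("num", as.numeric(raw)),
    bool = .tv("bool", as.logical(raw)),
    ts = .tv("ts", parse_timestamp(raw)),
    dur = .tv("dur", as.numeric(raw)),
    qty = .tv("qty", as.numeric(raw), unit = unit),
    str = .tv("str", as.character(raw)))
}

# entries of a concept for one patient: list of
# list(value = tv, start = secs, end = secs, ord = doc id)
.concept_entries <- function(store, path, patient_id) {
  b <- .binding_info(store, path)
  docs <- store_patient_docs(store, b$index, patient_id)
  entries <- list()
  for (doc in docs) {
    times_of <- function(field) {
      if (is.null(field)) return(NULL)
      vs <- .gather_field(doc$fields, field)
      if (length(vs) == 0) NULL else parse_timestamp(as.character(vs[[1]]))
    }
    t_start <- times_of(b$start_field) %||% parse_timestamp(doc$timestamp)
    t_end <- times_of(b$end_field) %||% t_start
    if (b$kind == "coded_value") {
      codes <- .gather_field(doc$fields, b$code_field)
      labels <- .gather_field(doc$fields, b$main_field)
      for (i in seq_along(codes)) {
        if (identical(as.character(codes[[i]]), b$code)) {
          lab <- if (i <= length(labels)) as.character(labels[[i]]) else b$code
          entries[[length(entries) + 1L]] <-
            list(value = .tv("str", lab), start = t_start, end = t_end,
                 ord = doc$id)
        }
      }
    } else {
      unit <- b$unit
      if (b$vtype == "qty") {
        us <- .gather_field(doc$fields, paste0(b$main_field, "_units"))
        if (length(us) > 0) unit <- as.character(us[[1]])
      }
      for (raw in .gather_field(doc$fields, b$main_field)) {
        entries[[length(entries) + 1L]] <-
          list(value = .raw_to_tv(raw, b$vtype, unit), start = t_start,
               end = t_end, ord = doc$id)
      }
    }
  }
  if (length(entries) > 1) {
    starts <- vapply(entries, `[[`, numeric(1), "start")
    ords <- vapply(entries, `[[`, character(1), "ord")
    entries <- entries[order(starts, ords)]
  }
  entries
}

# ---- typed-value operations -------------------------------------------

.eval_error <- function(...) stop("evaluation error: ", ..., call. = FALSE)

.cmp_tv <- function(op, a, b) {
  pair <- paste(a$t, b$t)
  if (a$t == "qty" && b$t == "qty") {
    if (!identical(a$unit %||% "", b$unit %||% ""))
      .eval_error("unit mismatch: '", a$unit %||% "", "' vs '",
                  b$unit %||% "", "'")
  }
  numlike <- function(x) x$t %in% c("num", "qty")
  xa <- a$v; xb <- b$v
  comparable <- (numlike(a) && numlike(b)) ||
    (a$t == b$t && a$t %in% c("ts", "dur", "num", "qty"))
  if (comparable) {
    return(switch(op, "<" = xa < xb, "<=" = xa <= xb, ">" = xa > xb,
                  ">=" = xa >= xb, "=" = xa == xb, "!=" = xa != xb))
  }
  if (a$t == "str" && b$t == "str") {
    if (!op %in% c("=", "!=")) .eval_error("strings only support = and !=")
    return(if (op == "=") xa == xb else xa != xb)
  }
  if (a$t == "bool" && b$t == "bool") {
    if (!op %in% c("=", "!=")) .eval_error("booleans only support = and !=")
    return(if (op == "=") xa == xb else xa != xb)
  }
  .eval_error("cannot compare ", a$t, " with ", b$t)
}

.arith_tv <- function(op, a, b) {
  t <- paste(a$t, op, b$t)
  num <- function(v) .tv("num", v)
  qty <- function(v, u) .tv("qty", v, unit = u)
  same_unit <- function() {
    if (!identical(a$unit %||% "", b$unit %||% ""))
      .eval_error("unit mismatch in arithmetic: '", a$unit %||% "",
                  "' vs '", b$unit %||% "", "'")
  }
  switch(t,
    "num + num" = num(a$v + b$v), "num - num" = num(a$v - b$v),
    "num * num" = num(a$v * b$v), "num / num" = num(a$v / b$v),
    "num ^ num" = num(a$v^b$v),
    "qty + qty" = { same_unit(); qty(a$v + b$v, a$unit) },
    "qty - qty" = { same_unit(); qty(a$v - b$v, a$unit) },
    "qty * num" = qty(a$v * b$v, a$unit),
    "num * qty" = qty(a$v * b$v, b$unit),
    "qty / num" = qty(a$v / b$v, a$unit),
    "qty / qty" = num(a$v / b$v), # magnitude ratio; unit check relaxed
    "qty ^ num" = num(a$v^b$v),   # unit dropped (e.g. height^2 in BMI)
    "ts - ts" = .tv("dur", a$v - b$v),
    "ts + dur" = .tv("ts", a$v + b$v), "ts - dur" = .tv("ts", a$v - b$v),
    "dur + ts" = .tv("ts", a$v + b$v),
    "dur + dur" = .tv("dur", a$v + b$v),
    "dur - dur" = .tv("dur", a$v - b$v),
    "dur * num" = .tv("dur", a$v * b$v),
    "num * dur" = .tv("dur", a$v * b$v),
    "dur / num" = .tv("dur", a$v / b$v),
    "dur / dur" = num(a$v / b$v),
    .eval_error("unsupported arithmetic: ", a$t, " ", op, " ", b$t))
}

.neg_tv <- function(a) {
  if (!a$t %in% c("num", "dur", "qty")) .eval_error("cannot negate ", a$t)
  a$v <- -a$v
  a
}

.to_bool <- function(x) {
  if (is.logical(x)) return(isTRUE(x))
  length(x) > 0 # a bare value expression is truthy when it has values
}

.MAX_CROSS <- 10000L

.cross_apply <- function(f, xs, ys) {
  if (length(xs) * length(ys) > .MAX_CROSS)
    .eval_error("expression expands to too many value pairs")
  out <- vector("list", length(xs) * length(ys))
  k <- 0L
  for (x in xs) for (y in ys) { k <- k + 1L; out[[k]] <- f(x, y) }
  out
}

# ---- the evaluator ----------------------------------------------------

.eval_node <- function(ast, ctx) {
  ev <- function(n) .eval_node(n, ctx)
  vals <- function(n) {
    r <- ev(n)
    if (is.logical(r))
      .eval_error("expected a value expression, got a boolean")
    r
  }
  switch(ast$kind,
    literal = list(switch(ast$ltype,
      number = .tv("num", ast$value),
      string = .tv("str", ast$value),
      boolean = .tv("bool", ast$value),
      duration = .tv("dur", ast$value))),
    concept = {
      if (isTRUE(ast$derived)) {
        dc <- ctx$store$registry$derived[[ast$name]]
        if (is.null(dc)) .eval_error("unknown derived concept ", ast$name)
        ev(dc$expression)
      } else {
        if (is.null(ast$path)) .eval_error("unresolved concept ", ast$name)
        lapply(.concept_entries(ctx$store, ast$path, ctx$patient_id),
               `[[`, "value")
      }
    },
    attr = {
      base <- ast$base
      if (is.null(base$path)) .eval_error("unresolved concept ", base$name)
      entries <- .concept_entries(ctx$store, base$path, ctx$patient_id)
      switch(ast$attr,
        Value = lapply(entries, `[[`, "value"),
        StartTime = lapply(entries, function(e) .tv("ts", e$start)),
        EndTime = lapply(entries, function(e) .tv("ts", e$end)))
    },
    call = switch(ast$fname,
      current_date_time = list(.tv("ts", ctx$store$clock)),
      attached = {
        base <- ast$args[[1]]
        if (base$kind != "concept") .eval_error("attached() takes a concept")
        if (isTRUE(base$derived)) .to_bool(ev(base))
        else length(.concept_entries(ctx$store, base$path,
                                     ctx$patient_id)) > 0
      },
      count = {
        base <- ast$args[[1]]
        list(.tv("num",
                 length(.concept_entries(ctx$store, base$path,
                                         ctx$patient_id))))
      },
      max = , min = {
        vs <- vals(ast$args[[1]])
        if (length(vs) == 0) return(list())
        ts <- unique(vapply(vs, `[[`, character(1), "t"))
        if (!all(ts %in% c("num", "qty", "ts", "dur")))
          .eval_error(ast$fname, "() needs ordered values")
        units <- unique(vapply(vs, function(v) v$unit %||% "", character(1)))
        if (length(units) > 1)
          .eval_error("unit mismatch inside ", ast$fname, "()")
        mags <- vapply(vs, `[[`, numeric(1), "v")
        pick <- if (ast$fname == "max") which.max(mags) else which.min(mags)
        list(vs[[pick]])
      },
      first = , last = {
        base <- ast$args[[1]]
        entries <- .concept_entries(ctx$store, base$path, ctx$patient_id)
        if (length(entries) == 0) return(list())
        e <- if (ast$fname == "first") entries[[1]]
             else entries[[length(entries)]]
        list(e$value)
      },
      diff = {
        xs <- vals(ast$args[[1]]); ys <- vals(ast$args[[2]])
        .cross_apply(function(x, y) {
          if (x$t != "ts" || y$t != "ts")
            .eval_error("diff() takes two time points")
          .tv("dur", x$v - y$v)
        }, xs, ys)
      },
      contains = {
        base <- ast$args[[1]]; pat <- ast$args[[2]]
        if (pat$kind != "literal" || pat$ltype != "string")
          .eval_error("contains() needs a string literal pattern")
        vs <- vals(base)
        any(vapply(vs, function(v)
          v$t == "str" && grepl(tolower(pat$value), tolower(v$v),
                                fixed = TRUE), logical(1)))
      },
      .eval_error("unknown function ", ast$fname)),
    unary = {
      if (ast$op == "not") !.to_bool(ev(ast$operand))
      else lapply(vals(ast$operand), .neg_tv)
    },
    binary = {
      op <- ast$op
      if (op %in% c("and", "or")) {
        l <- .to_bool(ev(ast$lhs)); r <- .to_bool(ev(ast$rhs))
        if (op == "and") l && r else l || r
      } else if (op %in% c("<", "<=", ">", ">=", "=", "!=")) {
        xs <- vals(ast$lhs); ys <- vals(ast$rhs)
        if (length(xs) == 0 || length(ys) == 0) return(FALSE)
        any(unlist(.cross_apply(function(x, y) .cmp_tv(op, x, y), xs, ys)))
      } else {
        xs <- vals(ast$lhs); ys <- vals(ast$rhs)
        .cross_apply(function(x, y) .arith_tv(op, x, y), xs, ys)
      }
    },
    chain = .eval_node(el_desugar_chain(ast), ctx),
    definition = .eval_error("cannot evaluate a definition; reference its name"),
    .eval_error("unknown node kind ", ast$kind)
  )
}

.as_resolved_ast <- function(x, registry) {
  ast <- if (is.character(x)) parse_el(x) else x
  needs <- FALSE
  el_map(ast, function(n) {
    if (n$kind == "concept" && is.null(n$path) && !isTRUE(n$derived))
      needs <<- TRUE
    n
  })
  if (needs) ast <- resolve_references(ast, registry)
  ast
}

#' Evaluate an expression or screening condition over a store
#'
#' Runs the reference engine patient by patient and returns the ids of
#' matching patients. Expressions may be text or parsed ASTs; unresolved
#' references are resolved against the store's registry.
#'
#' @param x expression text, an `el_ast`, or a `screening_condition`.
#' @param store a `patient_store`.
#' @param patients optional subset of patient ids to test.
#' @return sorted character vector of matching patient ids.
#' @export
evaluate <- function(x, store, patients = NULL) {
  pids <- patients %||% store_patients(store)
  if (inherits(x, "screening_condition")) {
    return(.evaluate_condition(x, store, pids))
  }
  ast <- .as_resolved_ast(x, store$registry)
  hits <- character(0)
  for (pid in pids) {
    ctx <- list(store = store, patient_id = pid)
    if (.to_bool(.eval_node(ast, ctx))) hits <- c(hits, pid)
  }
  sort(hits)
}

#' Evaluate an expression for a single patient
#' @param x expression text or `el_ast`.
#' @param store a `patient_store`.
#' @param patient_id one patient id.
#' @return logical scalar.
#' @export
evaluate_patient <- function(x, store, patient_id) {
  ast <- .as_resolved_ast(x, store$registry)
  .to_bool(.eval_node(ast, list(store = store, patient_id = patient_id)))
}
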