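# Screening conditions and their two-phase execution.
#
# A screening condition is an ordered list of groups. Within a group the
# members are connected by OR; a group's constraints and the groups
# themselves are connected by AND. Conditions compile to a
# backend-agnostic boolean query IR whose leaves are index predicates
# (exactly compilable comparisons, coded-term and exists tests) and whose
# inexpressible parts (collection functions, temporal chains, arithmetic
# over fields) travel as client-side post-filters over a candidate set.
# Index predicates always over-approximate: dropping the post-filters can
# only grow the result, never lose a matching patient. The in-memory
# interpreter run_ir() executes the IR and must agree exactly with the
# reference evaluator.

#' Construct a screening-condition group
#'
#' @param members expression texts (or ASTs) connected by OR; a bare
#'   concept reference means "has at least one record of this concept".
#' @param constraints expression texts (or ASTs) ANDed with the members.
#' @return a `screening_group`.
#' @export
screening_group <- function(members, constraints = list()) {
  as_list <- function(x) if (is.character(x)) as.list(x) else x
  structure(list(members = as_list(members),
                 constraints = as_list(constraints)),
            class = "screening_group")
}

#' Construct a screening condition
#'
#' @param ... `screening_group` objects (or lists of member texts, which
#'   are promoted to groups), connected by AND.
#' @return a `screening_condition`.
#' @export
screening_condition <- function(...) {
  groups <- lapply(list(...), function(g) {
    if (inherits(g, "screening_group")) g else screening_group(g)
  })
  if (length(groups) == 0)
    stop("a screening condition needs at least one group", call. = FALSE)
  structure(list(groups = groups), class = "screening_condition")
}

#' @export
print.screening_condition <- function(x, ...) {
  cat("<screening_condition> ", length(x$groups), " group(s)\n", sep = "")
  for (i in seq_along(x$groups)) {
    g <- x$groups[[i]]
    mtxt <- vapply(g$members, function(m)
      if (is.character(m)) m else el_unparse(m), character(1))
    cat("  group ", i, ": ", paste(mtxt, collapse = " or "), sep = "")
    if (length(g$constraints) > 0) {
      ctxt <- vapply(g$constraints, function(m)
        if (is.character(m)) m else el_unparse(m), character(1))
      cat(" | ", paste(ctxt, collapse = " and "), sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

# bare concept members mean "patient has a record of this concept"
.normalize_member <- function(ast) {
  if (ast$kind == "concept" && !isTRUE(ast$derived)) {
    cpt_call <- el_call("attached", list(ast))
    return(cpt_call)
  }
  ast
}

# one resolved boolean AST per group: (m1 or m2 ...) and c1 and c2 ...
.group_ast <- function(group, registry) {
  res <- function(x) .as_resolved_ast(x, registry)
  members <- lapply(group$members, function(m) .normalize_member(res(m)))
  if (length(members) == 0)
    stop("a group needs at least one member", call. = FALSE)
  acc <- members[[1]]
  for (m in members[-1]) acc <- el_binary("or", acc, m)
  for (cst in group$constraints) acc <- el_binary("and", acc, res(cst))
  acc
}

.evaluate_condition <- function(condition, store, pids) {
  asts <- lapply(condition$groups, .group_ast, registry = store$registry)
  hits <- character(0)
  for (pid in pids) {
    ctx <- list(store = store, patient_id = pid)
    ok <- all(vapply(asts, function(a) .to_bool(.eval_node(a, ctx)),
                     logical(1)))
    if (ok) hits <- c(hits, pid)
  }
  sort(hits)
}

# ---- IR construction --------------------------------------------------

.ir <- function(kind, ...) structure(list(kind = kind, ...), class = "ir_node")
.ir_and <- function(children) .ir("and", children = children)
.ir_or <- function(children) .ir("or", children = children)
.ir_pred <- function(index, field, op, value, vtype) {
  .ir("pred", index = index, field = field, op = op, value = value,
      vtype = vtype)
}
.ir_exists <- function(index, field) .ir("exists", index = index, field = field)
.ir_nested <- function(index, path, children) {
  .ir("nested", index = index, path = path, children = children)
}
.ir_match_all <- function() .ir("match_all")
.ir_post <- function(expr, candidate) .ir("post", expr = expr,
                                          candidate = candidate)

# does truth of this (boolean) expression require at least one stored
# entry of every referenced concept? count() can be satisfied vacuously
# (count = 0), and "not" flips polarity, so both force a match-all
# candidate.
.entry_demanding <- function(ast) {
  has_count_or_not <- FALSE
  has_ref <- FALSE
  scan <- function(n) {
    if (n$kind == "call" && n$fname == "count") has_count_or_not <<- TRUE
    if (n$kind == "unary" && n$op == "not") has_count_or_not <<- TRUE
    if (n$kind == "concept") has_ref <<- TRUE
    switch(n$kind,
      attr = scan(n$base),
      call = for (a in n$args) scan(a),
      unary = scan(n$operand),
      binary = { scan(n$lhs); scan(n$rhs) },
      chain = for (t in n$terms) scan(t),
      invisible(NULL))
  }
  scan(ast)
  has_ref && !has_count_or_not
}

.referenced_paths <- function(ast) {
  paths <- character(0)
  rec <- function(n) {
    if (n$kind == "concept" && !is.null(n$path))
      paths <<- union(paths, n$path)
    switch(n$kind,
      attr = rec(n$base),
      call = for (a in n$args) rec(a),
      unary = rec(n$operand),
      binary = { rec(n$lhs); rec(n$rhs) },
      chain = for (t in n$terms) rec(t),
      invisible(NULL))
  }
  rec(ast)
  paths
}

# candidate leaf guaranteeing >= 1 entry of a concept
.exists_leaf <- function(store, path) {
  b <- .binding_info(store, path)
  if (b$kind == "coded_value") {
    .ir_pred(b$index, b$code_field, "term", b$code, "str")
  } else {
    .ir_exists(b$index, b$main_field)
  }
}

.flip_op <- function(op) {
  switch(op, "<" = ">", "<=" = ">=", ">" = "<", ">=" = "<=", op)
}

.range_op <- function(op) {
  switch(op, "<" = "lt", "<=" = "lte", ">" = "gt", ">=" = "gte", NULL)
}

.is_simple_concept <- function(n) {
  n$kind == "concept" && !isTRUE(n$derived) && !is.null(n$path)
}

.is_cdt <- function(n) n$kind == "call" && n$fname == "current_date_time"

.compile_fallback <- function(store, ast) {
  if (.entry_demanding(ast)) {
    leaves <- lapply(.referenced_paths(ast),
                     function(p) .exists_leaf(store, p))
    cand <- if (length(leaves) == 1) leaves[[1]] else .ir_and(leaves)
    .ir_post(ast, cand)
  } else {
    .ir_post(ast, .ir_match_all())
  }
}

# try to compile "concept cmp literal" to an exact index predicate
.compile_field_cmp <- function(store, op, cref, lit) {
  b <- tryCatch(.binding_info(store, cref$path), error = function(e) NULL)
  if (is.null(b) || b$kind == "coded_value") return(NULL)
  if (lit$ltype == "number" && b$vtype %in% c("num", "qty")) {
    if (op %in% c("=", "!="))
      return(.ir_pred(b$index, b$main_field,
                      if (op == "=") "term" else "ne", lit$value, "num"))
    ro <- .range_op(op)
    if (!is.null(ro))
      return(.ir_pred(b$index, b$main_field, ro, lit$value, "num"))
  }
  if (lit$ltype == "duration" && b$vtype == "dur") {
    if (op %in% c("=", "!="))
      return(.ir_pred(b$index, b$main_field,
                      if (op == "=") "term" else "ne", lit$value, "num"))
    ro <- .range_op(op)
    if (!is.null(ro))
      return(.ir_pred(b$index, b$main_field, ro, lit$value, "num"))
  }
  if (lit$ltype == "string" && b$vtype == "str" && op %in% c("=", "!="))
    return(.ir_pred(b$index, b$main_field,
                    if (op == "=") "term" else "ne", lit$value, "str"))
  if (lit$ltype == "boolean" && b$vtype == "bool" && op %in% c("=", "!="))
    return(.ir_pred(b$index, b$main_field,
                    if (op == "=") "term" else "ne", lit$value, "bool"))
  NULL
}

# age-style rewrite: diff(current_date_time(), X) cmp D  with X a
# date-typed concept becomes a date-range predicate on X's field,
# evaluated against the store clock at compile time.
.compile_diff_cmp <- function(store, op, lhs, rhs) {
  if (!(lhs$kind == "call" && lhs$fname == "diff")) return(NULL)
  if (!(rhs$kind == "literal" && rhs$ltype == "duration")) return(NULL)
  a <- lhs$args[[1]]; bb <- lhs$args[[2]]
  now <- store$clock
  d <- rhs$value
  mk <- function(cref, threshold, cmp_op) {
    b <- tryCatch(.binding_info(store, cref$path), error = function(e) NULL)
    if (is.null(b) || b$vtype != "ts" || b$kind != "data") return(NULL)
    if (cmp_op %in% c("=", "!="))
      return(.ir_pred(b$index, b$main_field,
                      if (cmp_op == "=") "term" else "ne",
                      format_timestamp(threshold), "date"))
    ro <- .range_op(cmp_op)
    if (is.null(ro)) return(NULL)
    .ir_pred(b$index, b$main_field, ro, format_timestamp(threshold), "date")
  }
  if (.is_cdt(a) && .is_simple_concept(bb)) {
    # now - x op d  <=>  x flip(op) now - d
    return(mk(bb, now - d, .flip_op(op)))
  }
  if (.is_simple_concept(a) && .is_cdt(bb)) {
    # x - now op d  <=>  x op now + d
    return(mk(a, now + d, op))
  }
  NULL
}

.compile_expr <- function(store, ast) {
  k <- ast$kind
  if (k == "chain") return(.compile_expr(store, el_desugar_chain(ast)))
  if (k == "binary" && ast$op == "and") {
    return(.ir_and(list(.compile_expr(store, ast$lhs),
                        .compile_expr(store, ast$rhs))))
  }
  if (k == "binary" && ast$op == "or") {
    return(.ir_or(list(.compile_expr(store, ast$lhs),
                       .compile_expr(store, ast$rhs))))
  }
  if (k == "binary" && ast$op %in% c("<", "<=", ">", ">=", "=", "!=")) {
    l <- ast$lhs; r <- ast$rhs
    if (.is_simple_concept(l) && r$kind == "literal") {
      p <- .compile_field_cmp(store, ast$op, l, r)
      if (!is.null(p)) return(p)
    }
    if (.is_simple_concept(r) && l$kind == "literal") {
      p <- .compile_field_cmp(store, .flip_op(ast$op), r, l)
      if (!is.null(p)) return(p)
    }
    p <- .compile_diff_cmp(store, ast$op, l, r)
    if (!is.null(p)) return(p)
    if (r$kind == "call" && r$fname == "diff" && l$kind == "literal") {
      p <- .compile_diff_cmp(store, .flip_op(ast$op), r, l)
      if (!is.null(p)) return(p)
    }
    return(.compile_fallback(store, ast))
  }
  if (k == "call" && ast$fname == "attached" &&
      .is_simple_concept(ast$args[[1]])) {
    return(.exists_leaf(store, ast$args[[1]]$path))
  }
  if (k == "call" && ast$fname == "contains" &&
      .is_simple_concept(ast$args[[1]])) {
    b <- tryCatch(.binding_info(store, ast$args[[1]]$path),
                  error = function(e) NULL)
    if (!is.null(b) && b$vtype == "str" && endsWith(b$main_field, "_keyword")) {
      f <- sub("_keyword$", "_text", b$main_field)
      return(.ir_pred(b$index, f, "match", ast$args[[2]]$value, "str"))
    }
  }
  if (k == "literal" && ast$ltype == "boolean") {
    return(if (isTRUE(ast$value)) .ir_match_all()
           else .ir_post(ast, .ir_match_all()))
  }
  .compile_fallback(store, ast)
}

#' Compile a screening condition to the query IR
#'
#' Resolves and inlines the condition's expressions, then builds a
#' boolean IR: groups are ANDed, members within a group are ORed, and
#' each expression is either compiled to exact index predicates
#' (comparisons of a concept with a literal, coded-term membership,
#' record-existence, clock-relative date ranges) or to an
#' over-approximating candidate (exists predicates over the referenced
#' concepts, or match-all when the expression can hold vacuously) plus a
#' client-side post-filter that restores exactness.
#'
#' @param condition a `screening_condition` (or a single expression).
#' @param store a `patient_store` (provides registry, schemas and the
#'   clock used to anchor date-range rewrites).
#' @return a `query_ir`.
#' @export
compile_condition <- function(condition, store) {
  registry <- store$registry
  prep <- function(x) {
    ast <- .as_resolved_ast(x, registry)
    inline_derived(ast, registry)
  }
  tree <- if (inherits(condition, "screening_condition")) {
    if (length(condition$groups) == 0)
      stop("empty screening condition", call. = FALSE)
    gs <- lapply(condition$groups, function(g)
      .compile_expr(store, prep(.group_ast(g, registry))))
    if (length(gs) == 1) gs[[1]] else .ir_and(gs)
  } else {
    .compile_expr(store, prep(condition))
  }
  idx <- character(0)
  walk <- function(n) {
    if (!is.null(n$index)) idx <<- union(idx, n$index)
    for (ch in n$children %||% list()) walk(ch)
    if (!is.null(n$candidate)) walk(n$candidate)
  }
  walk(tree)
  structure(list(tree = tree, indexes = sort(idx)), class = "query_ir")
}

#' @export
print.query_ir <- function(x, ...) {
  rec <- function(n, depth) {
    pad <- strrep("  ", depth)
    switch(n$kind,
      and = , or = {
        cat(pad, n$kind, "\n", sep = "")
        for (ch in n$children) rec(ch, depth + 1)
      },
      pred = cat(pad, "pred ", n$index, ".", n$field, " ", n$op, " ",
                 as.character(n$value), "\n", sep = ""),
      exists = cat(pad, "exists ", n$index, ".", n$field, "\n", sep = ""),
      nested = {
        cat(pad, "nested ", n$index, ".", n$path, "\n", sep = "")
        for (ch in n$children) rec(ch, depth + 1)
      },
      match_all = cat(pad, "match_all\n", sep = ""),
      post = {
        cat(pad, "post-filter: ", el_unparse(n$expr), "\n", sep = "")
        rec(n$candidate, depth + 1)
      })
  }
  cat("<query_ir> indexes: ", paste(x$indexes, collapse = ", "), "\n", sep = "")
  rec(x$tree, 1)
  invisible(x)
}

# ---- IR interpretation ------------------------------------------------

.pred_cmp_raw <- function(op, raw, value, vtype) {
  x <- switch(vtype,
    num = as.numeric(raw),
    date = parse_timestamp(as.character(raw)),
    bool = as.logical(raw),
    str = as.character(raw))
  v <- if (vtype == "date") parse_timestamp(as.character(value)) else value
  switch(op,
    term = x == v, ne = x != v,
    gt = x > v, gte = x >= v, lt = x < v, lte = x <= v,
    match = is.character(x) && grepl(tolower(v), tolower(x), fixed = TRUE),
    stop("unknown predicate op: ", op, call. = FALSE))
}

.run_node <- function(node, store, pids) {
  per_index_hits <- function(index, doc_test) {
    docs <- store$docs[[index]] %||% list()
    hits <- character(0)
    for (doc in docs) {
      if (doc_test(doc)) hits <- union(hits, doc$patient_id)
    }
    intersect(pids, hits)
  }
  switch(node$kind,
    match_all = pids,
    pred = per_index_hits(node$index, function(doc) {
      vs <- .gather_field(doc$fields, node$field)
      any(vapply(vs, function(raw)
        isTRUE(.pred_cmp_raw(node$op, raw, node$value, node$vtype)),
        logical(1)))
    }),
    exists = per_index_hits(node$index, function(doc) {
      length(.gather_field(doc$fields, node$field)) > 0
    }),
    nested = per_index_hits(node$index, function(doc) {
      subs <- doc$fields[[node$path]]
      if (is.null(subs)) return(FALSE)
      any(vapply(subs, function(sub)
        all(vapply(node$children, function(p) {
          vs <- .gather_field(sub, p$field)
          any(vapply(vs, function(raw)
            isTRUE(.pred_cmp_raw(p$op, raw, p$value, p$vtype)), logical(1)))
        }, logical(1))), logical(1)))
    }),
    and = {
      out <- pids
      for (ch in node$children) out <- intersect(out, .run_node(ch, store, out))
      out
    },
    or = {
      out <- character(0)
      for (ch in node$children) out <- union(out, .run_node(ch, store, pids))
      sort(out)
    },
    post = {
      cand <- .run_node(node$candidate, store, pids)
      keep <- vapply(cand, function(pid)
        .to_bool(.eval_node(node$expr, list(store = store,
                                            patient_id = pid))),
        logical(1))
      cand[keep]
    },
    stop("unknown IR node kind: ", node$kind, call. = FALSE)
  )
}

#' Execute a query IR against an in-memory store
#'
#' Runs the index predicates, combines the per-leaf patient sets through
#' the boolean tree, then applies the client-side post-filters. For any
#' compiled condition this equals [evaluate()] on the same store.
#'
#' @param ir a `query_ir`.
#' @param store a `patient_store`.
#' @param drop_post_filters when TRUE, post-filters are skipped and the
#'   raw candidate (an over-approximation) is returned.
#' @return sorted character vector of patient ids.
#' @export
run_ir <- function(ir, store, drop_post_filters = FALSE) {
  tree <- ir$tree
  if (drop_post_filters) {
    strip <- function(n) {
      if (n$kind == "post") return(strip(n$candidate))
      if (!is.null(n$children)) n$children <- lapply(n$children, strip)
      if (!is.null(n$candidate)) n$candidate <- strip(n$candidate)
      n
    }
    tree <- strip(tree)
  }
  sort(.run_node(tree, store, store_patients(store)))
}

#' Screen a patient store
#'
#' Evaluates the condition and, mirroring interactive condition building
#' where the result count of every group is reported immediately, also
#' evaluates each group independently.
#'
#' @param condition a `screening_condition`.
#' @param store a `patient_store`.
#' @return a `screen_result`: list(result, n, group_counts).
#' @export
screen <- function(condition, store) {
  pids <- store_patients(store)
  result <- .evaluate_condition(condition, store, pids)
  counts <- vapply(seq_along(condition$groups), function(i) {
    length(.evaluate_condition(
      structure(list(groups = condition$groups[i]),
                class = "screening_condition"), store, pids))
  }, integer(1))
  structure(list(result = result, n = length(result),
                 group_counts = counts),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("patients matched: ", x$n, "\n", sep = "")
  cat("per-group counts: ", paste(x$group_counts, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# ---- Elasticsearch emission -------------------------------------------

.es_clause <- function(node, index) {
  other_index <- function(n) !is.null(n$index) && n$index != index
  switch(node$kind,
    match_all = list(match_all = structure(list(), names = character(0))),
    pred = {
      if (other_index(node)) return(.es_clause(.ir_match_all(), index))
      f <- node$field
      switch(node$op,
        term = list(term = structure(list(node$value), names = f)),
        ne = list(bool = list(
          must = list(list(exists = list(field = f))),
          must_not = list(list(term = structure(list(node$value),
                                                names = f))))),
        match = list(match = structure(list(node$value), names = f)),
        {
          rng <- structure(list(structure(list(node$value),
                                          names = node$op)), names = f)
          list(range = rng)
        })
    },
    exists = {
      if (other_index(node)) return(.es_clause(.ir_match_all(), index))
      list(exists = list(field = node$field))
    },
    nested = {
      if (other_index(node)) return(.es_clause(.ir_match_all(), index))
      list(nested = list(
        path = node$path,
        query = list(bool = list(
          must = lapply(node$children, .es_clause, index = index)))))
    },
    and = list(bool = list(
      must = lapply(node$children, .es_clause, index = index))),
    or = list(bool = list(
      should = lapply(node$children, .es_clause, index = index),
      minimum_should_match = 1)),
    post = .es_clause(node$candidate, index),
    stop("cannot emit ES clause for IR node: ", node$kind, call. = FALSE)
  )
}

#' Emit Elasticsearch 7.x Query DSL for a query IR
#'
#' Post-filters are NOT emitted — they run client-side after candidate
#' retrieval. For an IR spanning several indexes, one candidate query is
#' emitted per index (predicates of other indexes relax to match-all so
#' each per-index query over-approximates). Output is byte-stable for a
#' fixed IR.
#'
#' @param ir a `query_ir`.
#' @param index emit the query for this index only; default: the IR's
#'   single index, or all of them as a named object.
#' @return JSON string: `{"query": ...}` for a single index, or an
#'   object keyed by index name.
#' @export
emit_es_query <- function(ir, index = NULL) {
  one <- function(ix) list(query = .es_clause(ir$tree, ix))
  body <- if (!is.null(index)) {
    one(index)
  } else if (length(ir$indexes) <= 1) {
    ix <- if (length(ir$indexes) == 1) ir$indexes[[1]] else "_all"
    one(ix)
  } else {
    out <- list()
    for (ix in ir$indexes) out[[ix]] <- one(ix)
    out
  }
  as.character(jsonlite::toJSON(body, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA))
}
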