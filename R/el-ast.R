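# Abstract syntax tree for the screening expression language (an openEHR
# Expression Language subset). Nodes are tagged lists of class "el_ast":
#   literal  : ltype in number|string|boolean|duration, value
#              (durations are stored in seconds)
#   concept  : name (display name or /path), path (set by resolution),
#              derived (TRUE when bound to a derived concept)
#   attr     : base (concept node), attr in StartTime|EndTime|Value
#   call     : fname, args (list of nodes)
#   unary    : op in "-"|"not", operand
#   binary   : op, lhs, rhs
#   chain    : terms (list, length >= 3), ops (character, length terms-1)
#   definition : name, expr  (from "name := expr")

.EL_FUNCTIONS <- c(
  count = 1L, max = 1L, min = 1L, first = 1L, last = 1L, attached = 1L,
  diff = 2L, current_date_time = 0L, contains = 2L
)
.EL_METHODS <- c("count", "max", "min", "first", "last")
.EL_ATTRS <- c("StartTime", "EndTime", "Value")

el_node <- function(kind, ...) structure(list(kind = kind, ...), class = "el_ast")

el_literal <- function(ltype, value) el_node("literal", ltype = ltype, value = value)
el_concept <- function(name) el_node("concept", name = name, path = NULL, derived = FALSE)
el_attr <- function(base, attr) el_node("attr", base = base, attr = attr)
el_call <- function(fname, args) el_node("call", fname = fname, args = args)
el_unary <- function(op, operand) el_node("unary", op = op, operand = operand)
el_binary <- function(op, lhs, rhs) el_node("binary", op = op, lhs = lhs, rhs = rhs)
el_chain <- function(terms, ops) el_node("chain", terms = terms, ops = ops)
el_definition <- function(name, expr) el_node("definition", name = name, expr = expr)

is_el_ast <- function(x) inherits(x, "el_ast")

#' Structural equality of expression trees
#'
#' Compares two ASTs node by node, ignoring resolution metadata
#' (bound paths) so that a freshly parsed tree equals its resolved twin
#' only when the shapes agree.
#'
#' @param a,b `el_ast` nodes.
#' @param ignore_resolution drop bound paths before comparing (default TRUE).
#' @return logical scalar.
#' @export
el_equal <- function(a, b, ignore_resolution = TRUE) {
  if (!is_el_ast(a) || !is_el_ast(b)) return(identical(a, b))
  if (a$kind != b$kind) return(FALSE)
  switch(a$kind,
    literal = a$ltype == b$ltype && isTRUE(all.equal(a$value, b$value)),
    concept = if (ignore_resolution) a$name == b$name
              else a$name == b$name && identical(a$path, b$path) &&
                   identical(a$derived, b$derived),
    attr = a$attr == b$attr && el_equal(a$base, b$base, ignore_resolution),
    call = a$fname == b$fname && length(a$args) == length(b$args) &&
      all(vapply(seq_along(a$args), function(i)
        el_equal(a$args[[i]], b$args[[i]], ignore_resolution), logical(1))),
    unary = a$op == b$op && el_equal(a$operand, b$operand, ignore_resolution),
    binary = a$op == b$op && el_equal(a$lhs, b$lhs, ignore_resolution) &&
      el_equal(a$rhs, b$rhs, ignore_resolution),
    chain = length(a$terms) == length(b$terms) && identical(a$ops, b$ops) &&
      all(vapply(seq_along(a$terms), function(i)
        el_equal(a$terms[[i]], b$terms[[i]], ignore_resolution), logical(1))),
    definition = a$name == b$name && el_equal(a$expr, b$expr, ignore_resolution),
    stop("unknown node kind: ", a$kind)
  )
}

# Precedence levels used by the unparser (higher binds tighter). A
# negative number literal prints with a leading "-", so it carries the
# precedence of unary minus (it must be parenthesised under "^").
.el_precedence <- function(node) {
  if (node$kind == "literal" && node$ltype == "number" &&
      is.finite(node$value) && node$value < 0) return(7)
  switch(node$kind,
    binary = switch(node$op,
      "or" = 1, "and" = 2,
      "<" = 4, "<=" = 4, ">" = 4, ">=" = 4, "=" = 4, "!=" = 4,
      "+" = 5, "-" = 5, "*" = 6, "/" = 6, "^" = 8),
    chain = 4,
    unary = if (node$op == "not") 3 else 7,
    9)
}

.fmt_number <- function(x) {
  if (is.finite(x) && x == round(x) && abs(x) < 1e15) {
    format(x, scientific = FALSE)
  } else {
    format(x, digits = 15, scientific = FALSE)
  }
}

.fmt_name <- function(name) {
  if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", name)) name else paste0("[", name, "]")
}

#' Unparse an expression tree to canonical text
#'
#' Produces the canonical surface form: single spaces around binary
#' operators, minimal parentheses (driven by operator precedence),
#' collection functions in method form (`wbc.count()`), and `[bracketed]`
#' names only where a name is not a plain identifier.
#' `parse_el(el_unparse(x))` is structurally equal to `x`.
#'
#' @param ast an `el_ast` node.
#' @return single character string.
#' @export
el_unparse <- function(ast) {
  stopifnot(is_el_ast(ast))
  wrap <- function(child, min_prec) {
    s <- el_unparse(child)
    if (.el_precedence(child) < min_prec) paste0("(", s, ")") else s
  }
  switch(ast$kind,
    literal = switch(ast$ltype,
      number = .fmt_number(ast$value),
      string = paste0('"', ast$value, '"'),
      boolean = if (isTRUE(ast$value)) "true" else "false",
      duration = format_duration(ast$value)),
    concept = .fmt_name(ast$name),
    attr = paste0(wrap(ast$base, 9), ".", ast$attr),
    call = {
      if (ast$fname %in% .EL_METHODS) {
        paste0(wrap(ast$args[[1]], 9), ".", ast$fname, "()")
      } else {
        paste0(ast$fname, "(",
               paste(vapply(ast$args, el_unparse, character(1)), collapse = ", "),
               ")")
      }
    },
    unary = if (ast$op == "not") paste0("not ", wrap(ast$operand, 4))
            else paste0("-", wrap(ast$operand, 8)),
    binary = {
      p <- .el_precedence(ast)
      if (ast$op %in% c("<", "<=", ">", ">=", "=", "!=")) {
        # comparisons are non-associative: an unparenthesised comparison
        # operand would re-parse as an inequality chain
        paste(wrap(ast$lhs, p + 1), ast$op, wrap(ast$rhs, p + 1))
      } else {
        right_assoc <- ast$op == "^"
        lhs <- wrap(ast$lhs, if (right_assoc) p + 1 else p)
        rhs <- wrap(ast$rhs, if (right_assoc) p else p + 1)
        paste(lhs, ast$op, rhs)
      }
    },
    chain = {
      parts <- wrap(ast$terms[[1]], 5)
      for (i in seq_along(ast$ops)) {
        parts <- paste(parts, ast$ops[[i]], wrap(ast$terms[[i + 1]], 5))
      }
      parts
    },
    definition = paste(ast$name, ":=", el_unparse(ast$expr)),
    stop("unknown node kind: ", ast$kind)
  )
}

#' @export
print.el_ast <- function(x, ...) {
  cat("<el> ", el_unparse(x), "\n", sep = "")
  invisible(x)
}

# Desugar a chained comparison into the conjunction of adjacent pairs.
# "a < b = c" becomes (a < b) and (b = c); evaluation of the chain is
# defined as evaluation of this desugared form.
el_desugar_chain <- function(node) {
  stopifnot(node$kind == "chain")
  out <- el_binary(node$ops[[1]], node$terms[[1]], node$terms[[2]])
  for (i in seq_along(node$ops)[-1]) {
    out <- el_binary("and", out,
                     el_binary(node$ops[[i]], node$terms[[i]], node$terms[[i + 1]]))
  }
  out
}

# Walk helper: apply f to every node bottom-up, rebuilding the tree.
el_map <- function(ast, f) {
  rec <- function(n) {
    n2 <- switch(n$kind,
      attr = { n$base <- rec(n$base); n },
      call = { n$args <- lapply(n$args, rec); n },
      unary = { n$operand <- rec(n$operand); n },
      binary = { n$lhs <- rec(n$lhs); n$rhs <- rec(n$rhs); n },
      chain = { n$terms <- lapply(n$terms, rec); n },
      definition = { n$expr <- rec(n$expr); n },
      n)
    f(n2)
  }
  rec(ast)
}

# Collect all concept nodes in an expression.
el_concept_nodes <- function(ast) {
  acc <- list()
  el_map(ast, function(n) {
    if (n$kind == "concept") acc[[length(acc) + 1]] <<- n
    n
  })
  acc
}
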