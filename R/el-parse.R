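# Tokenizer and recursive-descent parser for the screening expression
# language. The grammar covers exactly the constructs the screening
# conditions use: arithmetic, comparisons (including inequality chains
# such as 27 < mmse < 30), boolean connectives, duration literals,
# collection methods (.count()/.max()/.min()/.first()/.last()), attribute
# access (.StartTime/.EndTime/.Value), and the functions diff(),
# current_date_time(), attached(), contains().
#
# Precedence (tight to loose): ^  unary-  * /  + -  comparisons  not  and  or
# Comparison chains may mix "=" with one direction of "<"/"<=" (or
# ">"/">="), which is how the Allen interval patterns are written.

.tokenize_el <- function(text) {
  # normalise typographic comparators
  text <- gsub("\u2264", "<=", text, fixed = TRUE)
  text <- gsub("\u2265", ">=", text, fixed = TRUE)
  text <- gsub("\u2260", "!=", text, fixed = TRUE)
  toks <- list()
  i <- 1L; n <- nchar(text); line <- 1L; col <- 1L
  push <- function(type, value) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value,
                                       line = line, col = col)
  }
  err <- function(msg) {
    stop(sprintf("EL syntax error at line %d, column %d: %s", line, col, msg),
         call. = FALSE)
  }
  advance <- function(k) {
    for (j in seq_len(k)) {
      ch <- substr(text, i, i)
      if (ch == "\n") { line <<- line + 1L; col <<- 1L } else col <<- col + 1L
      i <<- i + 1L
    }
  }
  dur_re <- "^P(?:[0-9]+Y)?(?:[0-9]+M)?(?:[0-9]+W)?(?:[0-9]+D)?(?:T(?:[0-9]+H)?(?:[0-9]+M)?(?:[0-9]+(?:\\.[0-9]+)?S)?)?"
  while (i <= n) {
    rest <- substr(text, i, n)
    ch <- substr(rest, 1, 1)
    if (grepl("^[ \t\r\n]", ch)) { advance(1L); next }
    two <- substr(rest, 1, 2)
    if (two %in% c(":=", "<=", ">=", "!=")) { push("op", two); advance(2L); next }
    if (ch %in% c("<", ">", "=", "+", "-", "*", "/", "^", "(", ")", ",", ".")) {
      push("op", ch); advance(1L); next
    }
    if (ch == "[") {
      close <- regexpr("]", rest, fixed = TRUE)
      if (close < 0) err("unterminated [bracketed name]")
      name <- trimws(substr(rest, 2, close - 1))
      if (name == "") err("empty [bracketed name]")
      push("name", name); advance(close); next
    }
    if (ch == '"') {
      m <- regexpr('^"[^"]*"', rest)
      if (m < 0) err("unterminated string literal")
      len <- attr(m, "match.length")
      push("string", substr(rest, 2, len - 1)); advance(len); next
    }
    if (ch == "P") {
      m <- regexpr(dur_re, rest, perl = TRUE)
      len <- attr(m, "match.length")
      lex <- substr(rest, 1, len)
      after <- substr(rest, len + 1, len + 1)
      if (len > 1 && grepl("[0-9]", lex) && !grepl("^[A-Za-z0-9_]$", after)) {
        push("duration", parse_duration(lex)); advance(len); next
      }
      # fall through: identifier starting with P
    }
    if (grepl("^[0-9]", ch)) {
      m <- regexpr("^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?", rest)
      len <- attr(m, "match.length")
      lex <- substr(rest, 1, len)
      if (grepl("^[A-Za-z_]", substr(rest, len + 1, len + 1)))
        err(paste0("malformed number near '", lex, "'"))
      push("number", as.numeric(lex)); advance(len); next
    }
    if (grepl("^[A-Za-z_]", ch)) {
      m <- regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest)
      len <- attr(m, "match.length")
      lex <- substr(rest, 1, len)
      if (lex %in% c("and", "or", "not", "true", "false")) push("keyword", lex)
      else push("ident", lex)
      advance(len); next
    }
    err(paste0("unexpected character '", ch, "'"))
  }
  push("eof", "")
  toks
}

.el_parser <- function(tokens) {
  pos <- 1L
  peek <- function() tokens[[pos]]
  err <- function(msg, tok = peek()) {
    stop(sprintf("EL syntax error at line %d, column %d: %s",
                 tok$line, tok$col, msg), call. = FALSE)
  }
  take <- function() { t <- tokens[[pos]]; pos <<- pos + 1L; t }
  at_op <- function(...) {
    t <- peek(); t$type == "op" && t$value %in% c(...)
  }
  at_kw <- function(kw) { t <- peek(); t$type == "keyword" && t$value == kw }
  expect_op <- function(v) {
    if (!at_op(v)) err(paste0("expected '", v, "'"))
    take()
  }

  parse_args <- function() {
    expect_op("(")
    args <- list()
    if (!at_op(")")) {
      repeat {
        args[[length(args) + 1L]] <- parse_or()
        if (at_op(",")) { take(); next }
        break
      }
    }
    expect_op(")")
    args
  }

  parse_primary <- function() {
    t <- peek()
    if (t$type == "number") { take(); return(el_literal("number", t$value)) }
    if (t$type == "string") { take(); return(el_literal("string", t$value)) }
    if (t$type == "duration") { take(); return(el_literal("duration", t$value)) }
    if (t$type == "name") { take(); return(el_concept(t$value)) }
    if (t$type == "keyword" && t$value %in% c("true", "false")) {
      take(); return(el_literal("boolean", t$value == "true"))
    }
    if (t$type == "ident") {
      take()
      if (at_op("(")) {
        if (!t$value %in% names(.EL_FUNCTIONS) || t$value %in% .EL_METHODS)
          err(paste0("unknown function '", t$value, "'"), t)
        args <- parse_args()
        want <- .EL_FUNCTIONS[[t$value]]
        if (length(args) != want)
          err(sprintf("%s() takes %d argument(s), got %d",
                      t$value, want, length(args)), t)
        return(el_call(t$value, args))
      }
      return(el_concept(t$value))
    }
    if (at_op("(")) {
      take()
      e <- parse_or()
      expect_op(")")
      return(e)
    }
    err(paste0("unexpected token '", t$value, "'"))
  }

  parse_postfix <- function() {
    e <- parse_primary()
    while (at_op(".")) {
      dot <- take()
      t <- peek()
      if (t$type != "ident") err("expected attribute or method after '.'", dot)
      take()
      if (t$value %in% .EL_ATTRS) {
        if (e$kind != "concept") err("attribute access requires a concept", t)
        e <- el_attr(e, t$value)
      } else if (t$value %in% .EL_METHODS) {
        expect_op("("); expect_op(")")
        if (e$kind != "concept")
          err(paste0(".", t$value, "() applies to a concept"), t)
        e <- el_call(t$value, list(e))
      } else {
        err(paste0("unknown attribute or method '", t$value, "'"), t)
      }
    }
    e
  }

  parse_power <- function() {
    e <- parse_postfix()
    if (at_op("^")) {
      take()
      e <- el_binary("^", e, parse_unary())
    }
    e
  }

  parse_unary <- function() {
    if (at_op("-")) {
      take()
      operand <- parse_unary()
      if (operand$kind == "literal" && operand$ltype == "number") {
        return(el_literal("number", -operand$value))
      }
      return(el_unary("-", operand))
    }
    parse_power()
  }

  parse_mul <- function() {
    e <- parse_unary()
    while (at_op("*", "/")) {
      op <- take()$value
      e <- el_binary(op, e, parse_unary())
    }
    e
  }

  parse_add <- function() {
    e <- parse_mul()
    while (at_op("+", "-")) {
      op <- take()$value
      e <- el_binary(op, e, parse_mul())
    }
    e
  }

  parse_comparison <- function() {
    first <- parse_add()
    ops <- character(0)
    terms <- list(first)
    while (at_op("<", "<=", ">", ">=", "=", "!=")) {
      tok <- peek()
      ops <- c(ops, take()$value)
      terms[[length(terms) + 1L]] <- parse_add()
      if (length(ops) > 1) {
        non_eq <- setdiff(ops, "=")
        if ("!=" %in% ops ||
            (any(non_eq %in% c("<", "<=")) && any(non_eq %in% c(">", ">="))))
          err("comparison chain must run in one direction", tok)
      }
    }
    if (length(ops) == 0) return(first)
    if (length(ops) == 1) return(el_binary(ops[[1]], terms[[1]], terms[[2]]))
    el_chain(terms, ops)
  }

  parse_not <- function() {
    if (at_kw("not")) {
      take()
      return(el_unary("not", parse_not()))
    }
    parse_comparison()
  }

  parse_and <- function() {
    e <- parse_not()
    while (at_kw("and")) {
      take()
      e <- el_binary("and", e, parse_not())
    }
    e
  }

  parse_or <- function() {
    e <- parse_and()
    while (at_kw("or")) {
      take()
      e <- el_binary("or", e, parse_and())
    }
    e
  }

  parse_top <- function() {
    # "name := expr" introduces a derived-concept definition
    t <- peek()
    if ((t$type == "ident" || t$type == "name") &&
        tokens[[pos + 1L]]$type == "op" && tokens[[pos + 1L]]$value == ":=") {
      take(); take()
      e <- parse_or()
      node <- el_definition(t$value, e)
    } else {
      node <- parse_or()
    }
    if (peek()$type != "eof") err("unexpected trailing input")
    node
  }

  parse_top()
}

#' Parse screening-expression text
#'
#' Parses one expression (or a derived-concept definition of the form
#' `name := expression`) into an abstract syntax tree. Syntax errors
#' report line and column. Typographic comparators (≤ ≥ ≠)
#' are accepted and normalised to `<=` `>=` `!=`.
#'
#' @param text a single character string of expression text.
#' @return an `el_ast` node; a `definition` node when `:=` is used.
#' @examples
#' parse_el("BMI := weight / height ^ 2")
#' parse_el("27 < mmse < 30")
#' parse_el("attached(aspirin) or attached(clopidogrel)")
#' @export
parse_el <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  .el_parser(.tokenize_el(text))
}
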