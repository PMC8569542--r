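# Temporal and collection constraints.
#
# The 13 Allen relations between two strict intervals are each written as
# an inequality chain over the four endpoints; classify_relation() is the
# executable classifier and relation_expression() produces the chain as
# expression text. Point events (start = end) are rejected because the
# chains compare an interval's own endpoints with strict "<".

.ALLEN_LABELS <- c("Before", "Meets", "Overlaps", "Begins", "BegunBy",
                   "During", "Contains", "Equals", "OverlappedBy", "Ends",
                   "EndedBy", "MetBy", "After")

# endpoint chains, written over c1 = (s1,e1) and c2 = (s2,e2); each row is
# the sequence term, op, term, op, ... of the defining chain.
.ALLEN_CHAINS <- list(
  Before       = c("s1", "<", "e1", "<", "s2", "<", "e2"),
  Meets        = c("s1", "<", "e1", "=", "s2", "<", "e2"),
  Overlaps     = c("s1", "<", "s2", "<", "e1", "<", "e2"),
  Begins       = c("s1", "=", "s2", "<", "e1", "<", "e2"),
  BegunBy      = c("s1", "=", "s2", "<", "e2", "<", "e1"),
  During       = c("s2", "<", "s1", "<", "e1", "<", "e2"),
  Contains     = c("s1", "<", "s2", "<", "e2", "<", "e1"),
  Equals       = c("s1", "=", "s2", "<", "e2", "=", "e1"),
  OverlappedBy = c("s2", "<", "s1", "<", "e2", "<", "e1"),
  Ends         = c("s2", "<", "s1", "<", "e1", "=", "e2"),
  EndedBy      = c("s1", "<", "s2", "<", "e2", "=", "e1"),
  MetBy        = c("s2", "<", "e2", "=", "s1", "<", "e1"),
  After        = c("s2", "<", "e2", "<", "s1", "<", "e1")
)

#' Create an event interval
#' @param start,end interval endpoints (numeric, or ISO-8601 timestamp
#'   strings); `start < end` strictly.
#' @return an `event_interval`.
#' @export
event_interval <- function(start, end) {
  if (is.character(start)) start <- parse_timestamp(start)
  if (is.character(end)) end <- parse_timestamp(end)
  if (!is.finite(start) || !is.finite(end))
    stop("interval endpoints must be finite", call. = FALSE)
  if (start >= end)
    stop("degenerate interval: start must be strictly before end",
         call. = FALSE)
  structure(list(start = start, end = end), class = "event_interval")
}

#' Classify the temporal relation between two intervals
#'
#' Returns the unique one of the 13 Allen relation labels whose endpoint
#' inequality chain holds for the pair. The labels are jointly exhaustive
#' and pairwise disjoint over strict intervals.
#'
#' @param i1,i2 `event_interval` objects (or `list(start=, end=)`).
#' @return one of `allen_labels()`.
#' @examples
#' classify_relation(event_interval(0, 5), event_interval(10, 20)) # Before
#' @export
classify_relation <- function(i1, i2) {
  chk <- function(i) {
    if (is.null(i$start) || is.null(i$end) || i$start >= i$end)
      stop("degenerate interval: start must be strictly before end",
           call. = FALSE)
  }
  chk(i1); chk(i2)
  env <- list(s1 = i1$start, e1 = i1$end, s2 = i2$start, e2 = i2$end)
  for (label in .ALLEN_LABELS) {
    chain <- .ALLEN_CHAINS[[label]]
    ok <- TRUE
    for (k in seq(1, length(chain) - 2, by = 2)) {
      a <- env[[chain[[k]]]]; op <- chain[[k + 1]]; b <- env[[chain[[k + 2]]]]
      holds <- if (op == "<") a < b else a == b
      if (!holds) { ok <- FALSE; break }
    }
    if (ok) return(label)
  }
  stop("no Allen relation matched (unreachable for strict intervals)",
       call. = FALSE)
}

#' The 13 Allen relation labels
#' @return character vector of length 13.
#' @export
allen_labels <- function() .ALLEN_LABELS

#' Expression text for an Allen relation
#'
#' Substitutes two concept references into the endpoint chain defining
#' the relation, yielding parseable expression text such as
#' `"a.StartTime < a.EndTime = b.StartTime < b.EndTime"` for Meets.
#'
#' @param label one of `allen_labels()`.
#' @param c1,c2 concept reference names.
#' @return expression text (string).
#' @export
relation_expression <- function(label, c1, c2) {
  if (!label %in% .ALLEN_LABELS)
    stop("unknown temporal relation: ", label, call. = FALSE)
  chain <- .ALLEN_CHAINS[[label]]
  ref <- function(endpoint) {
    who <- if (endsWith(endpoint, "1")) c1 else c2
    attr <- if (startsWith(endpoint, "s")) "StartTime" else "EndTime"
    paste0(.fmt_name(who), ".", attr)
  }
  parts <- character(0)
  for (k in seq_along(chain)) {
    parts <- c(parts, if (k %% 2 == 1) ref(chain[[k]]) else chain[[k]])
  }
  paste(parts, collapse = " ")
}

#' Interval (duration-gap) constraint between two event attributes
#'
#' Builds `diff(a, b) <cmp> <duration>` where `diff` is the signed
#' duration first-minus-second. `within_constraint()` is the
#' absolute-value helper for "within d" prose: it expands to
#' `diff(a,b) <= d and diff(a,b) >= -d` ... expressed with the signed
#' diff in both directions.
#'
#' @param a_expr,b_expr attribute reference text (e.g.
#'   `"heparin.StartTime"`) or `"current_date_time()"`.
#' @param cmp one of `<`, `<=`, `>`, `>=`, `=`.
#' @param duration ISO-8601 duration literal (e.g. `"PT48H"`); must be
#'   non-negative.
#' @return expression text.
#' @examples
#' interval_constraint("current_date_time()", "heparin.StartTime", "<=", "PT48H")
#' @export
interval_constraint <- function(a_expr, b_expr, cmp, duration) {
  if (!cmp %in% c("<", "<=", ">", ">=", "="))
    stop("invalid comparator: ", cmp, call. = FALSE)
  secs <- parse_duration(duration)
  if (secs < 0) stop("negative duration", call. = FALSE)
  text <- paste0("diff(", a_expr, ", ", b_expr, ") ", cmp, " ", duration)
  parse_el(text) # must parse
  text
}

#' @rdname interval_constraint
#' @export
within_constraint <- function(a_expr, b_expr, duration) {
  secs <- parse_duration(duration)
  if (secs < 0) stop("negative duration", call. = FALSE)
  d <- paste0("diff(", a_expr, ", ", b_expr, ")")
  text <- paste0(d, " <= ", duration, " and -", duration, " <= ", d)
  parse_el(text)
  text
}

# ---- collection constraints -------------------------------------------

# Built-in constraint templates over repeated measurements of a concept.
.BUILTIN_CONSTRAINTS <- list(
  `First time` = list(
    name = "First time",
    parameters = list(list(name = "concept", kind = "concept")),
    el_pattern = "[concept].count()=1"),
  Stable = list(
    name = "Stable",
    parameters = list(list(name = "concept", kind = "concept"),
                      list(name = "value", kind = "value")),
    el_pattern = "[concept].max()-[concept].min()<[value]"),
  Increase = list(
    name = "Increase",
    parameters = list(list(name = "concept", kind = "concept")),
    el_pattern = "[concept].last()>[concept].first()"),
  Decrease = list(
    name = "Decrease",
    parameters = list(list(name = "concept", kind = "concept")),
    el_pattern = "[concept].last()<[concept].first()")
)

#' Create a collection-constraint registry
#'
#' Holds the built-in constraint templates (First time, Stable, Increase,
#' Decrease) plus any self-defined ones.
#'
#' @return a `constraint_registry`.
#' @export
constraint_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$templates <- .BUILTIN_CONSTRAINTS
  reg$builtin <- names(.BUILTIN_CONSTRAINTS)
  class(reg) <- "constraint_registry"
  reg
}

.substitute_pattern <- function(pattern, params) {
  out <- pattern
  for (nm in names(params)) {
    val <- params[[nm]]
    rep <- if (nm == "concept") .fmt_name(val) else as.character(val)
    out <- gsub(paste0("[", nm, "]"), rep, out, fixed = TRUE)
  }
  out
}

#' Expand a collection constraint to expression text
#'
#' Substitutes the concept reference (and any self-defined parameters,
#' e.g. the Stable threshold) into the constraint's expression pattern.
#'
#' @param reg a `constraint_registry`.
#' @param name constraint name (built-in or registered).
#' @param concept concept reference name.
#' @param ... further named parameters required by the template (e.g.
#'   `value = 10` for Stable, which has no default).
#' @return expression text, guaranteed parseable.
#' @examples
#' reg <- constraint_registry()
#' expand_collection_constraint(reg, "First time", "wbc")  # "wbc.count()=1"
#' @export
expand_collection_constraint <- function(reg, name, concept, ...) {
  tpl <- reg$templates[[name]]
  if (is.null(tpl)) stop("unknown constraint: ", name, call. = FALSE)
  params <- c(list(concept = concept), list(...))
  wanted <- vapply(tpl$parameters, `[[`, character(1), "name")
  missing <- setdiff(wanted, names(params))
  if (length(missing) > 0)
    stop("missing parameter(s) for ", name, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  text <- .substitute_pattern(tpl$el_pattern, params)
  parse_el(text) # guaranteed parseable by registration invariant
  text
}

#' Register a self-defined collection constraint
#'
#' The pattern must parse after dummy substitution of its parameters and
#' must not collide with a built-in name.
#'
#' @param reg a `constraint_registry`.
#' @param name constraint name.
#' @param parameters list of `list(name=, kind=)` parameter descriptors;
#'   kinds: concept, value, duration, comparator.
#' @param el_pattern expression text with `[param]` placeholders.
#' @return the constraint name, invisibly.
#' @export
register_custom_constraint <- function(reg, name, parameters, el_pattern) {
  if (name %in% reg$builtin)
    stop("constraint name collides with a built-in: ", name, call. = FALSE)
  dummy <- list()
  for (p in parameters) {
    dummy[[p$name]] <- switch(p$kind,
      concept = "x", value = "1", duration = "PT1H", comparator = "<",
      stop("unknown parameter kind: ", p$kind, call. = FALSE))
  }
  text <- .substitute_pattern(el_pattern, dummy)
  ok <- tryCatch({ parse_el(text); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("constraint pattern does not parse after substitution: ",
         el_pattern, call. = FALSE)
  reg$templates[[name]] <- list(name = name, parameters = parameters,
                                el_pattern = el_pattern)
  invisible(name)
}

#' List registered constraints
#' @param reg a `constraint_registry`.
#' @return data.frame of name, pattern, parameters.
#' @export
list_constraints <- function(reg) {
  rows <- lapply(reg$templates, function(t) data.frame(
    name = t$name, pattern = t$el_pattern,
    parameters = paste(vapply(t$parameters, `[[`, character(1), "name"),
                       collapse = ";"),
    builtin = t$name %in% reg$builtin,
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
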