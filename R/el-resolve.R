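# Reference resolution: bind every concept reference in an expression to
# a unique registry path or to a derived-concept name. Names are display
# labels and may collide across templates; ambiguous references must be
# qualified with a full /template/... path.

#' Resolve concept references in an expression
#'
#' Binds each concept reference to either a registry concept path or a
#' derived concept. References may be a display name, a `[bracketed name]`
#' or a full registry path starting with `/`. Unknown names raise an
#' unresolved-reference error; names mapping to several paths raise an
#' ambiguity error listing the candidates.
#'
#' @param ast an `el_ast` (expression or definition).
#' @param registry a `concept_registry`.
#' @return the AST with concept nodes annotated with `$path` (registry
#'   concepts) or `$derived = TRUE` (derived concepts), carrying an
#'   attribute `dependencies` (character vector of paths and derived names).
#' @export
resolve_references <- function(ast, registry) {
  deps <- character(0)
  out <- el_map(ast, function(n) {
    if (n$kind != "concept") return(n)
    nm <- n$name
    if (startsWith(nm, "/")) {
      if (is.null(registry$concepts[[nm]]))
        stop("unresolved reference: no concept at path ", nm, call. = FALSE)
      n$path <- nm
      deps <<- union(deps, nm)
      return(n)
    }
    if (!is.null(registry$derived[[nm]])) {
      n$derived <- TRUE
      deps <<- union(deps, nm)
      return(n)
    }
    paths <- registry$name_index[[nm]]
    if (is.null(paths))
      stop("unresolved reference: unknown concept '", nm, "'", call. = FALSE)
    if (length(paths) > 1)
      stop("ambiguous concept name '", nm, "': candidates ",
           paste(paths, collapse = ", "), call. = FALSE)
    n$path <- paths[[1]]
    deps <<- union(deps, paths[[1]])
    n
  })
  attr(out, "dependencies") <- deps
  out
}

#' Define a derived concept
#'
#' Parses and resolves `name := expression` (or takes a parsed definition
#' node), records it in the registry's derived-concept table and returns
#' it. The name must not collide with a registered simple-concept name,
#' and the definition must not create a dependency cycle.
#'
#' @param registry a `concept_registry`.
#' @param text expression text `"name := expr"`, or an `el_ast`
#'   definition node.
#' @return a `derived_concept` (name, expression, dependencies), invisibly.
#' @export
define_derived_concept <- function(registry, text) {
  node <- if (is_el_ast(text)) text else parse_el(text)
  if (node$kind != "definition")
    stop("expected a definition of the form 'name := expression'",
         call. = FALSE)
  if (!is.null(registry$name_index[[node$name]]))
    stop("derived-concept name collides with registered concept: ",
         node$name, call. = FALSE)
  resolved <- resolve_references(node$expr, registry)
  dc <- structure(list(name = node$name, expression = resolved,
                       dependencies = attr(resolved, "dependencies")),
                  class = "derived_concept")
  registry$derived[[node$name]] <- dc
  # reject cycles immediately so the registry invariant always holds
  tryCatch(dependency_order(registry$derived),
           error = function(e) {
             registry$derived[[node$name]] <- NULL
             stop(e)
           })
  invisible(dc)
}

#' @export
print.derived_concept <- function(x, ...) {
  cat("<derived> ", x$name, " := ", el_unparse(x$expression), "\n", sep = "")
  invisible(x)
}

#' Topologically order derived concepts
#'
#' Orders definitions so every derived concept appears after the derived
#' concepts it references (intermediate concepts are generated first).
#' Registry-path dependencies are ignored — only derived-to-derived edges
#' order the result.
#'
#' @param derived named list of `derived_concept` objects.
#' @return the input list, reordered.
#' @export
dependency_order <- function(derived) {
  names_all <- names(derived)
  # Kahn's algorithm over derived-to-derived edges
  dep_of <- lapply(derived, function(d) intersect(d$dependencies, names_all))
  ordered <- character(0)
  remaining <- names_all
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(nm)
      all(dep_of[[nm]] %in% ordered), logical(1))]
    if (length(ready) == 0)
      stop("cyclic derived-concept dependencies among: ",
           paste(remaining, collapse = ", "), call. = FALSE)
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  derived[ordered]
}

#' Inline derived concepts into an expression
#'
#' Replaces every reference to a derived concept with its (recursively
#' inlined) defining expression, in dependency order, so the result only
#' references registry concepts.
#'
#' @param ast a resolved `el_ast`.
#' @param registry a `concept_registry`.
#' @return the fully inlined AST.
#' @export
inline_derived <- function(ast, registry) {
  expand <- function(name) {
    dc <- registry$derived[[name]]
    if (is.null(dc)) stop("unknown derived concept: ", name, call. = FALSE)
    inline_derived(dc$expression, registry)
  }
  rec <- function(n) {
    # attached(derived) means the derived expression itself holds, so the
    # whole call is replaced (attached() must keep a concept argument)
    if (n$kind == "call" && n$fname == "attached" &&
        n$args[[1]]$kind == "concept" && isTRUE(n$args[[1]]$derived)) {
      return(expand(n$args[[1]]$name))
    }
    if (n$kind == "concept" && isTRUE(n$derived)) return(expand(n$name))
    switch(n$kind,
      attr = { n$base <- rec(n$base); n },
      call = { n$args <- lapply(n$args, rec); n },
      unary = { n$operand <- rec(n$operand); n },
      binary = { n$lhs <- rec(n$lhs); n$rhs <- rec(n$rhs); n },
      chain = { n$terms <- lapply(n$terms, rec); n },
      definition = { n$expr <- rec(n$expr); n },
      n)
  }
  rec(ast)
}

#' Persist / load the derived-concept library as JSON
#'
#' @param registry a `concept_registry`.
#' @param file JSON path.
#' @return `file` (write) or the registry (read), invisibly.
#' @export
derived_to_json <- function(registry, file) {
  lst <- lapply(dependency_order(registry$derived), function(d)
    list(name = d$name,
         expression = el_unparse(d$expression),
         dependencies = as.list(d$dependencies)))
  jsonlite::write_json(unname(lst), file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' @rdname derived_to_json
#' @export
derived_from_json <- function(registry, file) {
  for (d in jsonlite::read_json(file)) {
    define_derived_concept(registry, paste(d$name, ":=", d$expression))
  }
  invisible(registry)
}
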