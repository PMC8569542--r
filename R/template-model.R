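# Clinical templates in a documented JSON dialect (see
# inst/extdata/template-schema.md). A template composes one or more entry
# archetypes under a composition container; attribute nodes carry an
# openEHR reference-model data type. Screening concepts are derived from
# the attribute nodes by five rules:
#   1. a template is one concept set;
#   2. each attribute node becomes a sub-concept (name = ontology name,
#      type = rm type, path = template path, parent = longest prefix);
#   3. DV_QUANTITY "units" becomes the concept's unit;
#   4. each DV_CODED_TEXT defining code becomes a sub-concept under the
#      node's concept;
#   5. all remaining data types map by rule 2 unchanged.
# StartTime/EndTime are left unbound at definition time and bound later
# per screening scenario (bind_time_attributes).

.RM_DATA_TYPES <- c("DV_BOOLEAN", "DV_CODED_TEXT", "DV_COUNT", "DV_DATE",
                    "DV_DATE_TIME", "DV_DURATION", "DV_IDENTIFIER",
                    "DV_QUANTITY", "DV_TEXT", "DV_URI")
.RM_STRUCTURAL <- c("ENTRY", "CLUSTER", "SLOT")
.RM_TEMPORAL <- c("DV_DATE", "DV_DATE_TIME")

.validate_node <- function(node, parent_path, seen_paths) {
  for (f in c("name", "rm_type", "path")) {
    if (is.null(node[[f]]))
      stop("template node missing field '", f, "' under path ",
           parent_path %||% "<root>", call. = FALSE)
  }
  if (!node$rm_type %in% c(.RM_DATA_TYPES, .RM_STRUCTURAL))
    stop("unsupported rm_type '", node$rm_type, "' at ", node$path,
         call. = FALSE)
  if (node$path %in% seen_paths)
    stop("duplicate template path: ", node$path, call. = FALSE)
  if (!is.null(parent_path) && !startsWith(node$path, paste0(parent_path, "/")))
    stop("node path ", node$path, " does not extend parent path ",
         parent_path, call. = FALSE)
  if (!is.null(node$units) && node$rm_type != "DV_QUANTITY")
    stop("'units' is only valid on DV_QUANTITY nodes (at ", node$path, ")",
         call. = FALSE)
  if (!is.null(node$defining_codes) && node$rm_type != "DV_CODED_TEXT")
    stop("'defining_codes' is only valid on DV_CODED_TEXT nodes (at ",
         node$path, ")", call. = FALSE)
  seen_paths <- c(seen_paths, node$path)
  for (child in node$children %||% list()) {
    seen_paths <- .validate_node(child, node$path, seen_paths)
  }
  seen_paths
}

.as_template_node <- function(x) {
  node <- list(
    node_id = x$id %||% NA_character_,
    name = x$name,
    rm_type = x$rm_type,
    path = x$path,
    units = x$units,
    defining_codes = x$defining_codes,
    is_collection = isTRUE(x$is_collection),
    children = lapply(x$children %||% list(), .as_template_node)
  )
  class(node) <- "template_node"
  node
}

#' Load a clinical template from its JSON form
#'
#' Reads a template in the package's JSON dialect (a composition container
#' importing entry archetypes whose attribute nodes carry reference-model
#' data types) and validates its structural invariants: unique
#' slash-delimited paths, child paths extending the parent path, `units`
#' only on DV_QUANTITY nodes, `defining_codes` only on DV_CODED_TEXT nodes.
#'
#' @param source path to a template JSON file, or a JSON string.
#' @return a `template` object.
#' @seealso [define_concepts()], [map_template_to_schema()]
#' @export
load_template <- function(source) {
  raw <- if (length(source) == 1 && !grepl("[{\n]", source) && file.exists(source)) {
    jsonlite::read_json(source)
  } else {
    jsonlite::parse_json(source)
  }
  for (f in c("template_id", "concept_set_name", "composition_id", "archetypes")) {
    if (is.null(raw[[f]])) stop("template missing field '", f, "'", call. = FALSE)
  }
  if (length(raw$archetypes) < 1)
    stop("template must import at least one archetype", call. = FALSE)
  ids <- vapply(raw$archetypes, function(a) a$archetype_id %||% "", character(1))
  if (anyDuplicated(ids))
    stop("duplicate archetype_id in template ", raw$template_id, call. = FALSE)
  seen <- character(0)
  archetypes <- lapply(raw$archetypes, function(a) {
    for (f in c("archetype_id", "concept_name", "root")) {
      if (is.null(a[[f]]))
        stop("archetype entry missing field '", f, "'", call. = FALSE)
    }
    seen <<- .validate_node(a$root, NULL, seen)
    list(archetype_id = a$archetype_id, concept_name = a$concept_name,
         root = .as_template_node(a$root))
  })
  structure(list(template_id = raw$template_id,
                 concept_set_name = raw$concept_set_name,
                 composition_id = raw$composition_id,
                 archetypes = archetypes,
                 timestamp_path = raw$timestamp_path),
            class = "template")
}

#' @export
print.template <- function(x, ...) {
  cat("<template> ", x$template_id, " (", x$concept_set_name, ")\n", sep = "")
  for (a in x$archetypes) {
    cat("  archetype ", a$archetype_id, "\n", sep = "")
  }
  invisible(x)
}

# Depth-first walk over template nodes; f(node, archetype) for each node.
walk_template_nodes <- function(template, f) {
  rec <- function(node, archetype) {
    f(node, archetype)
    for (child in node$children) rec(child, archetype)
  }
  for (a in template$archetypes) rec(a$root, a)
  invisible(NULL)
}

.new_concept <- function(name, path, type, parent = NULL, unit = NULL,
                         value = NULL, template_id = NULL, code = NULL,
                         terminology = NULL) {
  structure(list(name = name, parent = parent, path = path, type = type,
                 unit = unit, start_time_binding = NULL,
                 end_time_binding = NULL, value = value,
                 template_id = template_id, code = code,
                 terminology = terminology),
            class = "concept")
}

#' @export
print.concept <- function(x, ...) {
  cat("<concept> ", x$name, " [", x$type, "] ", x$path, "\n", sep = "")
  invisible(x)
}

#' Derive screening concepts from a template
#'
#' Applies the concept-definition rules: the template is one concept set;
#' every attribute node yields a concept whose name is the node's ontology
#' name, type its data type and path its template path; parents follow
#' from path prefixes; DV_QUANTITY units become the concept unit; every
#' DV_CODED_TEXT defining code becomes a sub-concept under that node's
#' concept (carrying the code as its value). StartTime/EndTime are left
#' unbound.
#'
#' @param template a `template` object.
#' @return list of `concept` objects in stable (document) order.
#' @export
define_concepts <- function(template) {
  concepts <- list()
  root_path <- paste0("/", template$template_id)
  concepts[[root_path]] <- .new_concept(
    name = template$concept_set_name, path = root_path, type = "CONCEPT_SET",
    template_id = template$template_id)
  defined_paths <- root_path
  parent_of <- function(path) {
    pre <- sub("/[^/]*$", "", path)
    while (nchar(pre) > 0) {
      if (pre %in% defined_paths) return(pre)
      pre <- sub("/[^/]*$", "", pre)
    }
    root_path
  }
  walk_template_nodes(template, function(node, archetype) {
    path <- paste0(root_path, node$path)
    c_new <- .new_concept(
      name = node$name, path = path, type = node$rm_type,
      parent = parent_of(path),
      unit = if (node$rm_type == "DV_QUANTITY") node$units else NULL,
      template_id = template$template_id)
    concepts[[path]] <<- c_new
    defined_paths <<- c(defined_paths, path)
    if (node$rm_type == "DV_CODED_TEXT") {
      for (dc in node$defining_codes %||% list()) {
        sub_path <- paste0(path, "/", dc$code)
        concepts[[sub_path]] <<- .new_concept(
          name = dc$label, path = sub_path, type = "CODED_VALUE",
          parent = path, value = dc$code, template_id = template$template_id,
          code = dc$code, terminology = dc$terminology)
        defined_paths <<- c(defined_paths, sub_path)
      }
    }
  })
  unname(concepts)
}

#' Create a concept registry
#'
#' The registry holds every concept keyed by path (paths are the
#' identifiers; display names may collide across templates and are kept
#' in a name index for reference resolution), plus derived-concept
#' definitions and the templates they came from.
#'
#' @param templates optional list of `template` objects to register.
#' @return a `concept_registry` object.
#' @export
concept_registry <- function(templates = list()) {
  reg <- new.env(parent = emptyenv())
  reg$concepts <- list()
  reg$name_index <- list()
  reg$derived <- list()
  reg$templates <- list()
  class(reg) <- "concept_registry"
  for (t in templates) registry_add_template(reg, t)
  reg
}

#' Register a template's concepts
#'
#' @param registry a `concept_registry`.
#' @param template a `template`.
#' @return the registry, invisibly.
#' @export
registry_add_template <- function(registry, template) {
  concepts <- define_concepts(template)
  for (cpt in concepts) {
    if (!is.null(registry$concepts[[cpt$path]]))
      stop("registry collision: concept path already defined: ", cpt$path,
           call. = FALSE)
  }
  for (cpt in concepts) {
    registry$concepts[[cpt$path]] <- cpt
    registry$name_index[[cpt$name]] <- c(registry$name_index[[cpt$name]],
                                         cpt$path)
  }
  registry$templates[[template$template_id]] <- template
  invisible(registry)
}

#' @export
print.concept_registry <- function(x, ...) {
  cat("<concept_registry> ", length(x$concepts), " concepts from ",
      length(x$templates), " template(s), ", length(x$derived),
      " derived\n", sep = "")
  invisible(x)
}

registry_get <- function(registry, path) {
  cpt <- registry$concepts[[path]]
  if (is.null(cpt)) stop("no concept at path ", path, call. = FALSE)
  cpt
}

# Look up the rm_type of a template path (concept-registry path includes
# the leading /template_id segment).
.registry_node_type <- function(registry, path) {
  cpt <- registry$concepts[[path]]
  if (is.null(cpt)) return(NULL)
  cpt$type
}

#' Bind StartTime/EndTime of a concept to temporal template paths
#'
#' A clinical concept (say a white-blood-cell count) can be anchored to
#' different event times — result time, specimen time — depending on the
#' screening scenario, so time bindings are chosen at screening time
#' rather than extracted from the template. Both target paths must exist
#' in the registry and carry a date/date-time type. The registry entry is
#' replaced.
#'
#' @param registry a `concept_registry`.
#' @param path path of the concept to bind.
#' @param start_path,end_path registry paths of date/date-time concepts
#'   (either may be NULL to leave that side unbound).
#' @return the updated `concept`, invisibly.
#' @export
bind_time_attributes <- function(registry, path, start_path = NULL,
                                 end_path = NULL) {
  cpt <- registry_get(registry, path)
  for (p in c(start_path, end_path)) {
    tp <- .registry_node_type(registry, p)
    if (is.null(tp)) stop("binding target path not found: ", p, call. = FALSE)
    if (!tp %in% .RM_TEMPORAL)
      stop("binding target is not date/date-time typed: ", p, " (", tp, ")",
           call. = FALSE)
  }
  cpt$start_time_binding <- start_path %||% cpt$start_time_binding
  cpt$end_time_binding <- end_path %||% cpt$end_time_binding
  registry$concepts[[path]] <- cpt
  invisible(cpt)
}

#' Export the registry as a data frame
#'
#' One row per concept with the standard concept attributes
#' (Name, Parent, Path, Type, Unit, StartTime, EndTime, Value).
#'
#' @param registry a `concept_registry`.
#' @return data.frame.
#' @export
registry_to_df <- function(registry) {
  rows <- lapply(registry$concepts, function(cpt) {
    data.frame(Name = cpt$name, Parent = cpt$parent %||% NA_character_,
               Path = cpt$path, Type = cpt$type,
               Unit = cpt$unit %||% NA_character_,
               StartTime = cpt$start_time_binding %||% NA_character_,
               EndTime = cpt$end_time_binding %||% NA_character_,
               Value = if (is.null(cpt$value)) NA_character_ else as.character(cpt$value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the registry to CSV
#' @param registry a `concept_registry`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
registry_to_csv <- function(registry, file) {
  utils::write.csv(registry_to_df(registry), file, row.names = FALSE)
  invisible(file)
}
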