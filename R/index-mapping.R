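# Template -> hierarchical document-index schema.
#
# Every reference-model data type maps to one or more index fields of
# three leaf kinds (generic, keyword, fulltext); string values of
# DV_CODED_TEXT and DV_TEXT get BOTH a keyword and a fulltext field so
# they can be queried as exact codes or as free text. Entry attributes
# are named "<archetype concept name>_<ontology name>" with spaces (and
# other non-alphanumeric runs) collapsed to "_"; attributes under cluster
# or slotted archetypes are named recursively through their parents.
# Non-collection clusters/slots are object fields whose attributes are
# flattened; collection-typed clusters become nested fields that keep the
# sub-document structure. Every index carries an id field, a patient_id
# field and a timestamp field.

.DATA_TYPE_MAP <- list(
  DV_BOOLEAN = list(list(attribute = "value", suffix = "", kind = "generic",
                         value_type = "boolean")),
  DV_CODED_TEXT = list(
    list(attribute = "value", suffix = "_keyword", kind = "keyword",
         value_type = "string"),
    list(attribute = "value", suffix = "_text", kind = "fulltext",
         value_type = "string"),
    list(attribute = "code", suffix = "_code", kind = "keyword",
         value_type = "string")),
  DV_COUNT = list(list(attribute = "magnitude", suffix = "", kind = "generic",
                       value_type = "integer")),
  DV_DATE = list(list(attribute = "dateTime", suffix = "", kind = "generic",
                      value_type = "date")),
  DV_DATE_TIME = list(list(attribute = "dateTime", suffix = "",
                           kind = "generic", value_type = "date")),
  DV_DURATION = list(list(attribute = "duration", suffix = "",
                          kind = "generic", value_type = "duration")),
  DV_IDENTIFIER = list(list(attribute = "id", suffix = "", kind = "keyword",
                            value_type = "id")),
  DV_QUANTITY = list(
    list(attribute = "magnitude", suffix = "", kind = "generic",
         value_type = "double"),
    list(attribute = "units", suffix = "_units", kind = "keyword",
         value_type = "string")),
  DV_TEXT = list(
    list(attribute = "value", suffix = "_keyword", kind = "keyword",
         value_type = "string"),
    list(attribute = "value", suffix = "_text", kind = "fulltext",
         value_type = "string")),
  DV_URI = list(list(attribute = "uri", suffix = "", kind = "generic",
                     value_type = "uri"))
)

#' Field mapping rows for a reference-model data type
#'
#' Returns the index fields generated for one attribute node of the given
#' data type: the attribute mapped, the field-name suffix, the field kind
#' (generic/keyword/fulltext) and the value type. DV_CODED_TEXT and
#' DV_TEXT string values produce both a keyword and a fulltext field.
#'
#' @param rm_type a reference-model data type (e.g. `"DV_QUANTITY"`).
#' @return data.frame with columns attribute, suffix, kind, value_type.
#' @export
map_data_type <- function(rm_type) {
  rows <- .DATA_TYPE_MAP[[rm_type]]
  if (is.null(rows)) stop("unsupported rm_type: ", rm_type, call. = FALSE)
  do.call(rbind, lapply(rows, function(r)
    data.frame(attribute = r$attribute, suffix = r$suffix, kind = r$kind,
               value_type = r$value_type, stringsAsFactors = FALSE)))
}

#' Sanitize an ontology name into a field-name component
#' @param name ontology name (may contain spaces/punctuation).
#' @return string with non-alphanumeric runs collapsed to `_`.
#' @export
sanitize_field_name <- function(name) {
  out <- gsub("[^A-Za-z0-9]+", "_", name)
  gsub("^_+|_+$", "", out)
}

#' Base field name for a template node
#'
#' Joins the archetype concept name, any cluster/slot ancestors, and the
#' node's own ontology name with `_` (recursively for multiple levels).
#' Dual-annotated string nodes additionally get `_keyword` / `_text`
#' suffixes, applied by the schema builder on top of this base name.
#'
#' @param node_name the node's ontology name.
#' @param context character vector of ancestor names, outermost first,
#'   beginning with the archetype concept name.
#' @return the base field name.
#' @examples
#' name_field("Body site", "problem_diagnosis") # "problem_diagnosis_Body_site"
#' @export
name_field <- function(node_name, context) {
  paste(c(vapply(context, sanitize_field_name, character(1)),
          sanitize_field_name(node_name)), collapse = "_")
}

.field_spec <- function(name, kind, value_type, source_path,
                        children = NULL, attribute = NULL) {
  structure(list(name = name, kind = kind, value_type = value_type,
                 source_path = source_path, children = children,
                 attribute = attribute),
            class = "field_spec")
}

#' Map a composition template to a document-index schema
#'
#' One template maps to exactly one index. Attribute nodes become leaf
#' fields per [map_data_type()] with names from the recursive naming
#' strategy; non-collection clusters/slots become object fields with
#' flattened children; collection clusters become nested fields keeping
#' sub-document structure. `id`, `patient_id` and `timestamp` fields are
#' injected. The timestamp source is the template's `timestamp_path` if
#' declared, else the first date/date-time node in document order.
#'
#' @param template a `template`.
#' @return an `index_schema`.
#' @export
map_template_to_schema <- function(template) {
  if (length(template$archetypes) == 0 ||
      all(vapply(template$archetypes,
                 function(a) length(a$root$children) == 0, logical(1))))
    stop("template has no entry attributes to map: ", template$template_id,
         call. = FALSE)
  seen <- character(0)
  claim <- function(name, path) {
    if (name %in% seen)
      stop("field name collision in schema: '", name, "' (from ", path, ")",
           call. = FALSE)
    seen <<- c(seen, name)
    name
  }
  first_time_path <- NULL
  leaf_fields <- function(node, context) {
    base <- name_field(node$name, context)
    rows <- .DATA_TYPE_MAP[[node$rm_type]]
    lapply(rows, function(r)
      .field_spec(claim(paste0(base, r$suffix), node$path), r$kind,
                  r$value_type, node$path, attribute = r$attribute))
  }
  build <- function(node, context) {
    if (node$rm_type %in% .RM_DATA_TYPES) {
      if (is.null(first_time_path) && node$rm_type %in% .RM_TEMPORAL)
        first_time_path <<- node$path
      return(leaf_fields(node, context))
    }
    # structural: CLUSTER / SLOT
    ctx2 <- c(context, node$name)
    children <- unlist(lapply(node$children, build, context = ctx2),
                       recursive = FALSE)
    if (isTRUE(node$is_collection)) {
      list(.field_spec(claim(name_field(node$name, context), node$path),
                       "nested", NA_character_, node$path,
                       children = children))
    } else {
      list(.field_spec(claim(name_field(node$name, context), node$path),
                       "object", NA_character_, node$path,
                       children = children))
    }
  }
  fields <- list(
    .field_spec(claim("id", "<injected>"), "keyword", "id", NA_character_),
    .field_spec(claim("patient_id", "<injected>"), "keyword", "id",
                NA_character_),
    .field_spec(claim("timestamp", "<injected>"), "generic", "date",
                NA_character_)
  )
  for (a in template$archetypes) {
    for (child in a$root$children) {
      fields <- c(fields, build(child, a$concept_name))
    }
  }
  structure(list(index_name = tolower(template$template_id),
                 template_id = template$template_id,
                 fields = fields,
                 id_field = "id",
                 timestamp_field = "timestamp",
                 timestamp_source = template$timestamp_path %||% first_time_path),
            class = "index_schema")
}

#' @export
print.index_schema <- function(x, ...) {
  cat("<index_schema> ", x$index_name, ": ",
      length(schema_flat_fields(x)), " fields\n", sep = "")
  invisible(x)
}

# Flat named list of every field spec (nested/object children included).
schema_flat_fields <- function(schema) {
  out <- list()
  rec <- function(fs) {
    for (f in fs) {
      out[[f$name]] <<- f
      if (!is.null(f$children)) rec(f$children)
    }
  }
  rec(schema$fields)
  out
}

# Map: template source path -> list of field specs derived from it.
schema_fields_by_path <- function(schema) {
  out <- list()
  for (f in schema_flat_fields(schema)) {
    if (!is.na(f$source_path))
      out[[f$source_path]] <- c(out[[f$source_path]], list(f))
  }
  out
}

.es_leaf_type <- function(f) {
  if (f$kind == "keyword") return("keyword")
  if (f$kind == "fulltext") return("text")
  switch(f$value_type,
         boolean = "boolean", integer = "integer", double = "double",
         date = "date", duration = "long", uri = "keyword", id = "keyword",
         string = "text",
         stop("unmapped value type: ", f$value_type, call. = FALSE))
}

.es_properties <- function(fields) {
  props <- list()
  for (f in fields) {
    props[[f$name]] <- if (f$kind %in% c("nested", "object")) {
      list(type = f$kind, properties = .es_properties(f$children))
    } else {
      list(type = .es_leaf_type(f))
    }
  }
  props
}

#' Emit an Elasticsearch 7.x mapping for a schema
#'
#' Serialises the schema as an ES `mappings` JSON object: generic fields
#' to their typed ES equivalents, keyword to `"keyword"`, fulltext to
#' `"text"`, structural fields to `"object"`/`"nested"` with nested
#' properties. Output is byte-stable for a fixed schema.
#'
#' @param schema an `index_schema`.
#' @param file optional path; when given the JSON is written there.
#' @return JSON string (invisibly when `file` is given).
#' @export
emit_es_mapping <- function(schema, file = NULL) {
  body <- list(mappings = list(properties = .es_properties(schema$fields)))
  json <- jsonlite::toJSON(body, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(json, file)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

# ---- entry flattening -------------------------------------------------

# schema derivation is pure in the template, so repeated flattening of
# entries against the same template reuses one schema
.schema_cache <- new.env(parent = emptyenv())

.schema_for <- function(template) {
  hit <- .schema_cache[[template$template_id]]
  if (!is.null(hit) && identical(hit$template, template)) return(hit$schema)
  schema <- map_template_to_schema(template)
  .schema_cache[[template$template_id]] <- list(template = template,
                                                schema = schema)
  schema
}

.flatten_leaf <- function(node, value, base, out, path) {
  fail <- function(msg) stop("flattening error at ", path, ": ", msg,
                             call. = FALSE)
  set <- function(suffix, v) { out[[paste0(base, suffix)]] <<- v }
  switch(node$rm_type,
    DV_QUANTITY = {
      if (is.list(value)) {
        if (!is.numeric(value$magnitude)) fail("quantity needs numeric magnitude")
        set("", value$magnitude)
        set("_units", value$units %||% node$units %||% "")
      } else {
        if (!is.numeric(value)) fail("expected numeric magnitude")
        set("", value)
        set("_units", node$units %||% "")
      }
    },
    DV_CODED_TEXT = {
      if (is.list(value)) { code <- value$code; label <- value$value }
      else { code <- value; label <- NULL }
      if (!is.character(code)) fail("expected a code string")
      if (is.null(label)) {
        for (dc in node$defining_codes %||% list()) {
          if (dc$code == code) { label <- dc$label; break }
        }
      }
      if (is.null(label)) fail(paste0("unknown code '", code, "'"))
      set("_keyword", label); set("_text", label); set("_code", code)
    },
    DV_TEXT = {
      if (!is.character(value)) fail("expected text")
      set("_keyword", value); set("_text", value)
    },
    DV_BOOLEAN = {
      if (!is.logical(value)) fail("expected logical")
      set("", value)
    },
    DV_COUNT = {
      if (!is.numeric(value) || value != round(value)) fail("expected integer")
      set("", as.integer(value))
    },
    DV_DATE = , DV_DATE_TIME = {
      if (!is.character(value)) fail("expected ISO-8601 timestamp string")
      parse_timestamp(value) # validates
      set("", value)
    },
    DV_DURATION = {
      if (!is.character(value)) fail("expected ISO-8601 duration string")
      set("", parse_duration(value))
    },
    DV_IDENTIFIER = , DV_URI = {
      if (!is.character(value)) fail("expected string")
      set("", value)
    },
    fail(paste0("unsupported rm_type ", node$rm_type))
  )
  out
}

#' Flatten a clinical entry into a document
#'
#' Converts one entry (a nested named list keyed by node ontology names,
#' mirroring the template structure) into a flat key-value document under
#' the schema's field names. Dual keyword/text fields receive the same
#' string under both names; collection clusters become lists of
#' sub-documents under the nested field name.
#'
#' @param template the `template` the entry conforms to.
#' @param entry nested named list of values keyed by ontology name. Leaf
#'   values may be atomic (main attribute) or named lists of attributes
#'   (e.g. `list(magnitude = 7.5, units = "kg")`).
#' @param patient_id patient identifier.
#' @param doc_id document identifier (unique within the index).
#' @param timestamp ISO-8601 timestamp for the document's time marker;
#'   when NULL it is read from the template's timestamp source node.
#' @return a `document_record`: list(index, id, patient_id, timestamp, fields).
#' @export
flatten_entry <- function(template, entry, patient_id, doc_id,
                          timestamp = NULL) {
  schema <- .schema_for(template)
  flatten_node <- function(node, data, context, out) {
    val <- data[[node$name]]
    if (is.null(val)) return(out)
    if (node$rm_type %in% .RM_DATA_TYPES) {
      return(.flatten_leaf(node, val, name_field(node$name, context), out,
                           node$path))
    }
    ctx2 <- c(context, node$name)
    if (isTRUE(node$is_collection)) {
      if (!is.list(val) || !is.null(names(val)))
        stop("flattening error at ", node$path,
             ": collection cluster expects an unnamed list of sub-entries",
             call. = FALSE)
      subs <- lapply(val, function(sub) {
        acc <- list()
        for (child in node$children) acc <- flatten_node(child, sub, ctx2, acc)
        acc
      })
      out[[name_field(node$name, context)]] <- subs
      return(out)
    }
    acc <- list()
    for (child in node$children) acc <- flatten_node(child, val, ctx2, acc)
    out[[name_field(node$name, context)]] <- acc
    out
  }
  fields <- list()
  for (a in template$archetypes) {
    for (child in a$root$children) {
      fields <- flatten_node(child, entry, a$concept_name, fields)
    }
  }
  if (is.null(timestamp)) {
    src <- schema$timestamp_source
    if (!is.null(src)) {
      by_path <- schema_fields_by_path(schema)
      f <- by_path[[src]]
      if (!is.null(f)) timestamp <- fields[[f[[1]]$name]]
    }
  }
  if (is.null(timestamp))
    stop("no timestamp for document ", doc_id,
         " and no timestamp source populated", call. = FALSE)
  structure(list(index = schema$index_name, id = doc_id,
                 patient_id = patient_id, timestamp = timestamp,
                 fields = fields),
            class = "document_record")
}

#' Validate a document against a schema
#'
#' Checks every populated field exists in the schema with a compatible
#' value type (numbers in numeric fields, strings in keyword/fulltext and
#' date fields, sub-document lists only under nested fields).
#'
#' @param schema an `index_schema`.
#' @param doc a `document_record`.
#' @return TRUE, or stops with a validation error.
#' @export
validate_document <- function(schema, doc) {
  flat <- schema_flat_fields(schema)
  check_value <- function(f, v, where) {
    ok <- switch(f$kind,
      keyword = , fulltext = is.character(v),
      generic = switch(f$value_type,
        boolean = is.logical(v),
        integer = , double = , duration = is.numeric(v),
        date = is.character(v) && !is.na(parse_timestamp(v)[1]),
        uri = , id = , string = is.character(v),
        FALSE),
      FALSE)
    if (!ok) stop("document field '", where, "' has incompatible value for ",
                  f$kind, "/", f$value_type, call. = FALSE)
  }
  check_fields <- function(fields, where_prefix) {
    for (nm in names(fields)) {
      f <- flat[[nm]]
      if (is.null(f))
        stop("document field '", nm, "' not in schema ", schema$index_name,
             call. = FALSE)
      v <- fields[[nm]]
      if (f$kind == "nested") {
        if (!is.list(v)) stop("nested field '", nm, "' must hold a list",
                              call. = FALSE)
        for (sub in v) check_fields(sub, nm)
      } else if (f$kind == "object") {
        check_fields(v, nm)
      } else {
        check_value(f, v, nm)
      }
    }
  }
  check_fields(doc$fields, "")
  for (nm in c("id", "patient_id", "timestamp")) {
    if (is.null(doc[[nm]])) stop("document missing ", nm, call. = FALSE)
  }
  TRUE
}
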