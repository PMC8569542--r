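# In-memory patient store: flattened documents grouped by index, one
# document per clinical entry (each carries patient_id), plus an
# injectable clock so current_date_time() is reproducible.

#' Create a patient store
#'
#' @param registry a `concept_registry`; index schemas are derived from
#'   its templates.
#' @param clock ISO-8601 timestamp used as "now" by
#'   `current_date_time()`; injectable for reproducibility.
#' @return a `patient_store`.
#' @export
patient_store <- function(registry, clock = "2021-01-01T00:00:00") {
  store <- new.env(parent = emptyenv())
  store$registry <- registry
  store$schemas <- list()
  for (t in registry$templates) {
    s <- map_template_to_schema(t)
    store$schemas[[s$index_name]] <- s
  }
  store$docs <- list()
  store$clock <- parse_timestamp(clock)
  store$bindings <- list()  # concept path -> binding info cache
  store$pid_cache <- list() # index -> patient -> docs
  class(store) <- "patient_store"
  store
}

#' @export
print.patient_store <- function(x, ...) {
  n_docs <- sum(vapply(x$docs, length, integer(1)))
  cat("<patient_store> ", length(store_patients(x)), " patients, ",
      n_docs, " documents across ", length(x$docs), " index(es)\n", sep = "")
  invisible(x)
}

#' Add a document to a store
#' @param store a `patient_store`.
#' @param doc a `document_record` (from [flatten_entry()]).
#' @return the store, invisibly.
#' @export
store_add_document <- function(store, doc) {
  schema <- store$schemas[[doc$index]]
  if (is.null(schema)) stop("unknown index: ", doc$index, call. = FALSE)
  store$docs[[doc$index]] <- c(store$docs[[doc$index]], list(doc))
  store$pid_cache[[doc$index]] <- NULL
  invisible(store)
}

#' Add a raw clinical entry (flatten + insert)
#' @param store a `patient_store`.
#' @param template_id the template the entry conforms to.
#' @param entry nested named list (see [flatten_entry()]).
#' @param patient_id,doc_id identifiers.
#' @param timestamp optional ISO-8601 time marker.
#' @return the store, invisibly.
#' @export
store_add_entry <- function(store, template_id, entry, patient_id, doc_id,
                            timestamp = NULL) {
  template <- store$registry$templates[[template_id]]
  if (is.null(template)) stop("unknown template: ", template_id, call. = FALSE)
  store_add_document(store,
                     flatten_entry(template, entry, patient_id, doc_id,
                                   timestamp))
}

#' All patient ids in a store
#' @param store a `patient_store`.
#' @return character vector, sorted.
#' @export
store_patients <- function(store) {
  ids <- unlist(lapply(store$docs, function(docs)
    vapply(docs, `[[`, character(1), "patient_id")))
  sort(unique(ids))
}

# documents of one patient in one index, in insertion order (grouping
# is cached per index and invalidated on insertion)
store_patient_docs <- function(store, index, patient_id) {
  cache <- store$pid_cache[[index]]
  if (is.null(cache)) {
    docs <- store$docs[[index]] %||% list()
    pids <- vapply(docs, `[[`, character(1), "patient_id")
    cache <- split(docs, factor(pids, levels = unique(pids)))
    store$pid_cache[[index]] <- cache
  }
  cache[[patient_id]] %||% list()
}

#' Write a store's documents as NDJSON
#'
#' One JSON object per line: index, id, patient_id, timestamp, fields.
#'
#' @param store a `patient_store`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
store_write_ndjson <- function(store, file) {
  con <- file(file, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (index in sort(names(store$docs))) {
    for (doc in store$docs[[index]]) {
      line <- jsonlite::toJSON(
        list(index = doc$index, id = doc$id, patient_id = doc$patient_id,
             timestamp = doc$timestamp, fields = doc$fields),
        auto_unbox = TRUE, digits = NA)
      writeLines(line, con)
    }
  }
  invisible(file)
}

#' Read documents from NDJSON into a store
#' @param store a `patient_store` (documents are appended).
#' @param file NDJSON path written by [store_write_ndjson()].
#' @return the store, invisibly.
#' @export
store_read_ndjson <- function(store, file) {
  for (line in readLines(file, encoding = "UTF-8")) {
    if (nchar(trimws(line)) == 0) next
    x <- jsonlite::parse_json(line)
    doc <- structure(list(index = x$index, id = x$id,
                          patient_id = x$patient_id,
                          timestamp = x$timestamp,
                          fields = .simplify_fields(x$fields)),
                     class = "document_record")
    store_add_document(store, doc)
  }
  invisible(store)
}

# jsonlite::parse_json keeps everything as lists; unwrap scalars but keep
# nested sub-document lists as lists.
.simplify_fields <- function(fields) {
  lapply(fields, function(v) {
    if (is.list(v) && is.null(names(v))) {
      lapply(v, .simplify_fields)       # nested sub-documents
    } else if (is.list(v) && !is.null(names(v))) {
      .simplify_fields(v)               # object sub-map
    } else {
      v
    }
  })
}

#' Write an Elasticsearch bulk-index file for a store
#'
#' Emits alternating action/document lines suitable for the `_bulk` API,
#' for loading the store into a live cluster.
#'
#' @param store a `patient_store`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
store_write_bulk <- function(store, file) {
  con <- file(file, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (index in sort(names(store$docs))) {
    for (doc in store$docs[[index]]) {
      action <- jsonlite::toJSON(
        list(index = list(`_index` = doc$index, `_id` = doc$id)),
        auto_unbox = TRUE)
      body <- jsonlite::toJSON(
        c(list(patient_id = doc$patient_id, timestamp = doc$timestamp),
          doc$fields),
        auto_unbox = TRUE, digits = NA)
      writeLines(c(action, body), con)
    }
  }
  invisible(file)
}
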