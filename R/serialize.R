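# Persistence: canonical JSON store file, one-way OBO 1.4 and Turtle
# export. The JSON schema is rebuilt field-by-field on load (never
# simplified), so save/load is the identity on stores.

SCHEMA_VERSION <- 1L

chr1 <- function(x) {
  if (is.null(x) || length(x) == 0L || is.null(x[[1L]])) return(NA_character_)
  as.character(x[[1L]])
}
chrv <- function(x) as.character(unlist(x, use.names = FALSE))

store_to_list <- function(store) {
  list(
    schema = SCHEMA_VERSION,
    next_num = store$next_num,
    roots = store$roots,
    terms = lapply(unname(store$terms), unclass),
    characters = lapply(unname(store$characters), function(ch) {
      ch <- unclass(ch)
      ch$name <- unclass(ch$name)
      ch$method <- unclass(ch$method)
      ch
    }),
    equivalences = store$equivalences,
    log = store$log,
    config = list(
      stopwords = store$config$stopwords,
      units = list(unit = store$config$units$unit,
                   allow_negative = store$config$units$allow_negative)
    )
  )
}

#' Save an ontology store to its canonical JSON file
#'
#' @param store A `pheno_store`.
#' @param path File path to write (UTF-8 JSON).
#' @return `path`, invisibly.
#' @seealso [load_store()], [export_obo()], [export_ttl()]
#' @export
save_store <- function(store, path) {
  stopifnot(inherits(store, "pheno_store"))
  jsonlite::write_json(store_to_list(store), path,
                       auto_unbox = FALSE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

rebuild_term <- function(x) {
  structure(list(
    id = chr1(x$id), label = chr1(x$label),
    verbal_definition = chr1(x$verbal_definition),
    sample_sentence = chr1(x$sample_sentence),
    taxon_example = chr1(x$taxon_example),
    parent_id = chr1(x$parent_id),
    status = chr1(x$status), creator = chr1(x$creator),
    created_at = chr1(x$created_at),
    # optional since schema 1; older files omit it
    annotation = if (is.null(x$annotation)) "" else chr1(x$annotation)
  ), class = "pheno_term")
}

rebuild_event <- function(ev) {
  list(time = chr1(ev$time), actor = chr1(ev$actor), kind = chr1(ev$kind),
       payload = lapply(ev$payload, chrv))
}

rebuild_character <- function(x) {
  structure(list(
    id = chr1(x$id),
    name = structure(list(
      quality = chr1(x$name$quality),
      preposition = chr1(x$name$preposition),
      structures = chrv(x$name$structures)
    ), class = "pheno_name"),
    method = structure(list(
      from = chr1(x$method$from), to = chr1(x$method$to),
      include = chrv(x$method$include), exclude = chrv(x$method$exclude),
      at = chr1(x$method$at)
    ), class = "pheno_method"),
    unit = chr1(x$unit),
    creators = chrv(x$creators),
    usage_count = as.integer(x$usage_count[[1L]]),
    history = lapply(x$history, rebuild_event),
    illustrations = if (is.null(x$illustrations)) character(0) else chrv(x$illustrations),
    status = chr1(x$status),
    structure_ids = chrv(x$structure_ids)
  ), class = "pheno_character")
}

#' Load an ontology store from its canonical JSON file
#'
#' Validates ids while loading: duplicate identifiers are an error.
#' Optional fields absent from files written by older minor schemas get
#' documented defaults (empty annotation, no illustrations).
#'
#' @param path File written by [save_store()].
#' @return A `pheno_store`.
#' @export
load_store <- function(path) {
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop_pheno(sprintf("malformed store file '%s': %s",
                                       path, conditionMessage(e)),
                               "pheno_parse_error")
                  })
  for (field in c("next_num", "roots", "terms", "characters")) {
    if (is.null(raw[[field]])) {
      stop_pheno(sprintf("malformed store file '%s': missing field '%s'",
                         path, field), "pheno_parse_error")
    }
  }
  st <- new.env(parent = emptyenv())
  class(st) <- "pheno_store"
  st$next_num <- as.integer(raw$next_num[[1L]])
  st$roots <- lapply(raw$roots, chr1)

  terms <- lapply(raw$terms, rebuild_term)
  chars <- lapply(raw$characters, rebuild_character)
  ids <- c(vapply(terms, `[[`, character(1), "id"),
           vapply(chars, `[[`, character(1), "id"))
  if (anyDuplicated(ids)) {
    stop_pheno(sprintf("malformed store file '%s': duplicate id '%s'",
                       path, ids[duplicated(ids)][[1L]]), "pheno_parse_error")
  }
  st$terms <- stats::setNames(terms, vapply(terms, `[[`, character(1), "id"))
  st$characters <- stats::setNames(chars, vapply(chars, `[[`, character(1), "id"))
  st$equivalences <- lapply(raw$equivalences, chrv)
  st$log <- lapply(raw$log, function(ev)
    list(time = chr1(ev$time), event = chr1(ev$event),
         payload = lapply(ev$payload, chrv)))
  st$config <- list(
    stopwords = chrv(raw$config$stopwords),
    units = data.frame(
      unit = chrv(raw$config$units$unit),
      allow_negative = as.logical(unlist(raw$config$units$allow_negative)),
      stringsAsFactors = FALSE
    )
  )
  st
}

# --- OBO 1.4 export (one-way) ---------------------------------------------

obo_escape <- function(x) gsub("\"", "\\\\\"", x)

#' Export a store to an OBO 1.4 flat file
#'
#' One-way export: terms and characters become `[Term]` stanzas with
#' id, name, def, is_a and equivalence annotations. There is no OBO
#' import; the JSON file is the canonical format.
#'
#' @inheritParams save_store
#' @return `path`, invisibly.
#' @export
export_obo <- function(store, path) {
  stopifnot(inherits(store, "pheno_store"))
  lines <- c("format-version: 1.4",
             sprintf("ontology: carex (exported %s)", "phenochar"), "")
  equiv_of <- function(id) {
    hits <- Filter(function(p) id %in% p, store$equivalences)
    setdiff(unlist(hits), id)
  }
  stanza <- function(id, name, def, parent, status, extra = character(0)) {
    s <- c("[Term]", paste0("id: ", id), paste0("name: ", name))
    if (nzchar(def)) s <- c(s, sprintf("def: \"%s\" []", obo_escape(def)))
    if (!is.na(parent)) s <- c(s, paste0("is_a: ", parent))
    for (eq in equiv_of(id)) s <- c(s, paste0("equivalent_to: ", eq))
    if (status == "deprecated") s <- c(s, "is_obsolete: true")
    c(s, extra, "")
  }
  for (t in store$terms[order(names(store$terms))]) {
    extra <- if (nzchar(t$annotation)) paste0("xref: ", sub("^[a-z_]+ ", "", t$annotation)) else character(0)
    lines <- c(lines, stanza(t$id, t$label, t$verbal_definition,
                             t$parent_id, t$status, extra))
  }
  for (ch in store$characters[order(names(store$characters))]) {
    lines <- c(lines, stanza(ch$id, format(ch$name), render_method(ch$method),
                             store$roots$quality, ch$status))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

ttl_escape <- function(x) gsub("\"", "\\\\\"", x)

#' Export a store to Turtle
#'
#' One-way RDF export: subclass axioms as `rdfs:subClassOf`,
#' equivalences as `owl:equivalentClass`, labels as `rdfs:label`.
#'
#' @inheritParams save_store
#' @return `path`, invisibly.
#' @export
export_ttl <- function(store, path) {
  stopifnot(inherits(store, "pheno_store"))
  iri <- function(id) paste0("carex:", sub("^CAREX:", "", id))
  lines <- c(
    "@prefix carex: <http://example.org/carex/> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .", ""
  )
  for (t in store$terms[order(names(store$terms))]) {
    lines <- c(lines, sprintf("%s a owl:Class ; rdfs:label \"%s\" .",
                              iri(t$id), ttl_escape(t$label)))
    if (!is.na(t$parent_id)) {
      lines <- c(lines, sprintf("%s rdfs:subClassOf %s .",
                                iri(t$id), iri(t$parent_id)))
    }
  }
  for (ch in store$characters[order(names(store$characters))]) {
    lines <- c(lines, sprintf("%s a owl:Class ; rdfs:label \"%s\" ; rdfs:subClassOf %s .",
                              iri(ch$id), ttl_escape(format(ch$name)),
                              iri(store$roots$quality)))
  }
  for (p in store$equivalences) {
    lines <- c(lines, sprintf("%s owl:equivalentClass %s .", iri(p[[1L]]), iri(p[[2L]])))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
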