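# Ontology store: terms, characters, subclass/equivalence axioms,
# permanent id assignment. Backed by an environment so that operations
# mutate the store in place and can still return the entity they touched.

#' Create an empty ontology store
#'
#' The store is seeded with three root classes: an anatomic-structure
#' root (annotated as equivalent to the external anatomical-entity
#' class), a perceived-quality root (annotated as a subclass of the
#' external quality class), and a "new additions" holding class under
#' which author-contributed terms receive their permanent identifiers
#' before an ontology engineer re-files them. The new-additions class is
#' itself a subclass of the anatomic-structure root, so new landmark
#' terms are simultaneously "under new additions" and reachable from the
#' structure root.
#'
#' @param stopwords Character vector used by the semantic check and
#'   search tokenization; defaults to [default_stopwords()].
#' @param units Unit vocabulary data frame as from [default_units()].
#' @return An object of class `pheno_store` (an environment).
#' @examples
#' st <- pheno_store()
#' store_roots(st)
#' @export
pheno_store <- function(stopwords = default_stopwords(), units = default_units()) {
  st <- new.env(parent = emptyenv())
  st$terms <- list()
  st$characters <- list()
  st$equivalences <- list()   # list of length-2 sorted character vectors
  st$next_num <- FIRST_FREE_NUM
  st$log <- list()
  st$config <- list(stopwords = stopwords, units = units)
  class(st) <- "pheno_store"

  seed_root <- function(num, label, parent_id, annotation) {
    id <- format_id(num)
    st$terms[[id]] <- structure(list(
      id = id, label = label, verbal_definition = "",
      sample_sentence = "", taxon_example = "",
      parent_id = parent_id, status = "active",
      creator = "system", created_at = "1970-01-01 00:00:00",
      annotation = annotation
    ), class = "pheno_term")
    id
  }
  root_s <- seed_root(ROOT_STRUCTURE_NUM, "anatomic structure", NA_character_,
                      paste("equivalent_to", ANCHOR_ANATOMICAL_ENTITY))
  root_q <- seed_root(ROOT_QUALITY_NUM, "perceived quality", NA_character_,
                      paste("subclass_of", ANCHOR_QUALITY))
  seed_root(ROOT_NEW_ADDITIONS_NUM, "new additions", root_s, "")
  st$roots <- list(structure = root_s, quality = root_q,
                   new_additions = format_id(ROOT_NEW_ADDITIONS_NUM))
  st
}

#' @export
print.pheno_store <- function(x, ...) {
  n_active <- sum(vapply(x$terms, function(t) t$status == "active", logical(1)))
  cat("<pheno_store>\n")
  cat(sprintf("  terms:      %d (%d active)\n", length(x$terms), n_active))
  cat(sprintf("  characters: %d\n", length(x$characters)))
  cat(sprintf("  equivalence axioms: %d\n", length(x$equivalences)))
  cat(sprintf("  next id:    %s\n", format_id(x$next_num)))
  invisible(x)
}

#' Root identifiers of a store
#' @param store A `pheno_store`.
#' @return Named list with `structure`, `quality` and `new_additions` ids.
#' @export
store_roots <- function(store) store$roots

next_id <- function(store) {
  id <- format_id(store$next_num)
  store$next_num <- store$next_num + 1L
  id
}

log_event <- function(store, event, payload = list(), time = now_stamp()) {
  store$log[[length(store$log) + 1L]] <-
    list(time = time, event = event, payload = payload)
  invisible(store)
}

all_ids <- function(store) c(names(store$terms), names(store$characters))

stop_pheno <- function(msg, class, ...) {
  stop(structure(class = c(class, "pheno_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

# --- terms ----------------------------------------------------------------

#' Register a new term in the ontology
#'
#' Adds an author-contributed term under the new-additions holding class
#' and assigns it a fresh permanent identifier. A term carries its label,
#' a verbal definition, a sample sentence and a taxon example. Duplicate
#' active labels (case-folded) are refused with a pointer to the existing
#' term, signalling that it should be reused instead.
#'
#' @param label Non-empty term label.
#' @param verbal_definition,sample_sentence,taxon_example Definition
#'   strings; may be empty.
#' @param creator Name of the contributing author.
#' @param store A `pheno_store`; modified in place.
#' @param time Timestamp string (override for reproducible fixtures).
#' @return The new `pheno_term`, invisibly the store is updated.
#' @export
add_term <- function(label, verbal_definition = "", sample_sentence = "",
                     taxon_example = "", creator = "unknown", store,
                     time = now_stamp()) {
  stopifnot(inherits(store, "pheno_store"))
  if (!is.character(label) || length(label) != 1L || !nzchar(trimws(label))) {
    stop_pheno("term label must be a non-empty string", "pheno_validation_error")
  }
  hit <- find_terms(label, store)
  if (nrow(hit) > 0L) {
    stop_pheno(sprintf("an active term with label '%s' already exists: %s (reuse it)",
                       label, hit$id[[1L]]),
               "pheno_duplicate_label", existing_id = hit$id[[1L]])
  }
  id <- next_id(store)
  term <- structure(list(
    id = id, label = fold_label(label),
    verbal_definition = verbal_definition,
    sample_sentence = sample_sentence,
    taxon_example = taxon_example,
    parent_id = store$roots$new_additions,
    status = "active", creator = creator, created_at = time,
    annotation = ""
  ), class = "pheno_term")
  store$terms[[id]] <- term
  log_event(store, "add_term", list(id = id, label = term$label), time)
  term
}

#' @export
print.pheno_term <- function(x, ...) {
  cat(sprintf("<pheno_term> %s '%s' (%s)\n", x$id, x$label, x$status))
  if (nzchar(x$verbal_definition)) cat("  def: ", x$verbal_definition, "\n", sep = "")
  cat("  parent: ", x$parent_id, "  creator: ", x$creator, "\n", sep = "")
  invisible(x)
}

#' Look up active terms by label
#'
#' Case-insensitive exact-label match among active terms, ordered by id.
#'
#' @param label_query Label to look up.
#' @inheritParams add_term
#' @return Data frame with columns `id`, `label`, `parent_id`, `creator`
#'   (zero rows when nothing matches).
#' @export
find_terms <- function(label_query, store) {
  stopifnot(inherits(store, "pheno_store"))
  q <- fold_label(label_query)
  keep <- Filter(function(t) t$status == "active" && t$label == q, store$terms)
  if (length(keep) > 0L) keep <- keep[order(names(keep))]
  data.frame(
    id = vapply(keep, `[[`, character(1), "id"),
    label = vapply(keep, `[[`, character(1), "label"),
    parent_id = vapply(keep, `[[`, character(1), "parent_id"),
    creator = vapply(keep, `[[`, character(1), "creator"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Retrieve a term by id (active or deprecated)
#' @param id Permanent identifier.
#' @inheritParams add_term
#' @return The `pheno_term`.
#' @export
get_term <- function(id, store) {
  t <- store$terms[[id]]
  if (is.null(t)) stop_pheno(sprintf("unknown term id '%s'", id), "pheno_unknown_id")
  t
}

#' Deprecate a term
#'
#' Marks a term as deprecated: it keeps its permanent id and all axioms
#' (for history) but is excluded from label lookup and can no longer be
#' used for new characters.
#'
#' @inheritParams get_term
#' @inheritParams add_term
#' @return The updated `pheno_term`.
#' @export
deprecate_term <- function(id, store, time = now_stamp()) {
  t <- get_term(id, store)
  if (t$status != "active") {
    stop_pheno(sprintf("term '%s' is already deprecated", id), "pheno_validation_error")
  }
  t$status <- "deprecated"
  store$terms[[id]] <- t
  log_event(store, "deprecate_term", list(id = id), time)
  t
}

# --- equivalence axioms ---------------------------------------------------

#' Record an equivalence axiom between two entities
#'
#' Equivalence is the OWL equivalent-classes construct, preferred over
#' synonym annotations because it is a formal semantic relation: an
#' enhanced character and its source denote the same measurement. The
#' pair is stored unordered and at most once.
#'
#' @param id_a,id_b Existing term or character ids; must differ.
#' @inheritParams add_term
#' @return The store, invisibly.
#' @export
add_equivalence <- function(id_a, id_b, store, time = now_stamp()) {
  stopifnot(inherits(store, "pheno_store"))
  if (identical(id_a, id_b)) {
    stop_pheno("cannot declare an entity equivalent to itself", "pheno_validation_error")
  }
  known <- all_ids(store)
  for (id in c(id_a, id_b)) {
    if (!id %in% known) stop_pheno(sprintf("unknown id '%s'", id), "pheno_unknown_id")
  }
  pair <- sort(c(id_a, id_b))
  dup <- any(vapply(store$equivalences, identical, logical(1), pair))
  if (!dup) store$equivalences[[length(store$equivalences) + 1L]] <- pair
  log_event(store, "add_equivalence", list(pair = pair), time)
  invisible(store)
}

#' Equivalence class of an entity
#'
#' Transitive-symmetric closure of the recorded equivalence axioms: the
#' set of ids connected to `id` through any chain of axioms, including
#' `id` itself.
#'
#' @inheritParams get_term
#' @inheritParams add_term
#' @return Sorted character vector of ids.
#' @export
equivalence_class <- function(id, store) {
  if (!id %in% all_ids(store)) {
    stop_pheno(sprintf("unknown id '%s'", id), "pheno_unknown_id")
  }
  members <- id
  repeat {
    grown <- members
    for (pair in store$equivalences) {
      if (any(pair %in% grown)) grown <- union(grown, pair)
    }
    if (length(grown) == length(members)) break
    members <- grown
  }
  unname(sort(members))
}

# --- hierarchy ------------------------------------------------------------

#' Parent chain of a term up to its root
#' @inheritParams get_term
#' @inheritParams add_term
#' @return Character vector of ids from the term to a root (inclusive).
#' @export
parent_chain <- function(id, store) {
  chain <- character(0)
  cur <- id
  while (!is.na(cur)) {
    if (cur %in% chain) stop_pheno("cycle detected in subclass graph", "pheno_cycle")
    chain <- c(chain, cur)
    t <- store$terms[[cur]]
    if (is.null(t)) stop_pheno(sprintf("unknown term id '%s'", cur), "pheno_unknown_id")
    cur <- t$parent_id
  }
  chain
}

#' Move a term under a new parent
#'
#' Curation hook for the ontology engineer: terms parked under the
#' new-additions class may later be re-filed as subclasses of other
#' classes. The move is refused if it would create a cycle or detach a
#' root. A provenance event is appended to the store log.
#'
#' @inheritParams get_term
#' @param new_parent_id Id of the new parent term.
#' @inheritParams add_term
#' @return The store, invisibly.
#' @export
reparent_term <- function(id, new_parent_id, store, time = now_stamp()) {
  t <- get_term(id, store)
  get_term(new_parent_id, store)
  if (is.na(t$parent_id)) {
    stop_pheno(sprintf("'%s' is a root class and cannot be reparented", id),
               "pheno_validation_error")
  }
  if (id %in% parent_chain(new_parent_id, store)) {
    stop_pheno("reparenting would create a cycle in the subclass graph", "pheno_cycle")
  }
  old <- t$parent_id
  t$parent_id <- new_parent_id
  store$terms[[id]] <- t
  log_event(store, "reparent_term",
            list(id = id, from = old, to = new_parent_id), time)
  invisible(store)
}
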