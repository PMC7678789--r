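# Character lifecycle: controlled name grammar, landmark method
# definitions, semantic check against the ontology, creation, reuse
# ("use this"), clone-and-enhance, usage counts and history.

# Tokenizer shared by the semantic check, search and the convergence
# metrics: lowercase, punctuation stripped, pure-number tokens dropped.
split_words <- function(text) {
  x <- tolower(text)
  x <- gsub("[[:punct:]]", " ", x)
  toks <- unlist(strsplit(x, "[[:space:]]+"), use.names = FALSE)
  toks <- toks[nzchar(toks)]
  toks[!grepl("^[0-9]+$", toks)]
}

# --- character names ------------------------------------------------------

#' Parse a character name against the of/between grammar
#'
#' Continuous-character names must follow the controlled pattern
#' `<quality> of <structure>` or `<quality> between <structure(s)>`:
#' "length of leaf" is accepted, "leaf length" is not. The "between"
#' form takes either one plural structure phrase ("distance between
#' pupils") or two phrases joined by "and" ("distance between tip and
#' base"). Input is normalized to lowercase single-spaced text.
#'
#' @param text Character name as typed.
#' @return A `pheno_name` with fields `quality`, `preposition` and
#'   `structures`; its [format()] method reproduces the canonical text.
#' @examples
#' parse_character_name("Length of  Leaf")
#' try(parse_character_name("leaf length"))
#' @export
parse_character_name <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    stop_pheno("character name must be a single string", "pheno_validation_error")
  }
  norm <- fold_label(text)
  toks <- strsplit(norm, " ", fixed = TRUE)[[1L]]
  toks <- toks[nzchar(toks)]
  pos <- which(toks %in% c("of", "between"))
  pos <- pos[pos > 1L & pos < length(toks)]
  if (length(toks) < 3L || length(pos) == 0L) {
    stop_pheno(sprintf(
      "'%s' does not follow the required pattern '<quality> of <structure>' or '<quality> between <structure(s)>' (e.g. 'length of leaf', not 'leaf length')",
      norm), "pheno_grammar_error")
  }
  p <- pos[[1L]]
  quality <- paste(toks[seq_len(p - 1L)], collapse = " ")
  prep <- toks[[p]]
  rest <- toks[seq.int(p + 1L, length(toks))]
  if (prep == "between") {
    andp <- which(rest == "and")
    andp <- andp[andp > 1L & andp < length(rest)]
    structures <- if (length(andp) > 0L) {
      a <- andp[[1L]]
      c(paste(rest[seq_len(a - 1L)], collapse = " "),
        paste(rest[seq.int(a + 1L, length(rest))], collapse = " "))
    } else {
      paste(rest, collapse = " ")
    }
  } else {
    structures <- paste(rest, collapse = " ")
  }
  structure(list(quality = quality, preposition = prep,
                 structures = structures), class = "pheno_name")
}

#' @export
format.pheno_name <- function(x, ...) {
  paste(x$quality, x$preposition, paste(x$structures, collapse = " and "))
}

#' @export
print.pheno_name <- function(x, ...) {
  cat("<pheno_name> ", format(x), "\n", sep = "")
  invisible(x)
}

# --- method definitions ---------------------------------------------------

#' Construct a landmark method definition
#'
#' The five-field landmark schema describing how a measurement is taken:
#' the landmark it starts `from`, the landmark it runs `to`, structures
#' to `include` or `exclude`, and the position `at` which it is taken.
#' All fields may be empty (an empty method is permitted for characters
#' defined by illustration only).
#'
#' @param from,to,at Landmark phrases (single strings, may be "").
#' @param include,exclude Character vectors of structure phrases.
#' @return A `pheno_method`.
#' @examples
#' pheno_method(from = "end of perigynium wings", to = "summit of perigynium",
#'              include = "perigynium beak teeth")
#' @export
pheno_method <- function(from = "", to = "", include = character(0),
                         exclude = character(0), at = "") {
  structure(list(
    from = as.character(from)[1L], to = as.character(to)[1L],
    include = as.character(include[nzchar(include)]),
    exclude = as.character(exclude[nzchar(exclude)]),
    at = as.character(at)[1L]
  ), class = "pheno_method")
}

method_is_empty <- function(m) {
  !nzchar(m$from) && !nzchar(m$to) && !nzchar(m$at) &&
    length(m$include) == 0L && length(m$exclude) == 0L
}

render_method <- function(m) {
  parts <- character(0)
  if (nzchar(m$from)) parts <- c(parts, paste0("From: ", m$from))
  if (nzchar(m$to)) parts <- c(parts, paste0("To: ", m$to))
  if (length(m$include)) parts <- c(parts, paste0("Include: ", paste(m$include, collapse = "; ")))
  if (length(m$exclude)) parts <- c(parts, paste0("Exclude: ", paste(m$exclude, collapse = "; ")))
  if (nzchar(m$at)) parts <- c(parts, paste0("At: ", m$at))
  paste(parts, collapse = " ")
}

#' @export
format.pheno_method <- function(x, ...) render_method(x)

#' @export
print.pheno_method <- function(x, ...) {
  cat("<pheno_method> ", if (method_is_empty(x)) "(empty)" else render_method(x),
      "\n", sep = "")
  invisible(x)
}

# --- semantic check -------------------------------------------------------

#' Check a method definition against the ontology
#'
#' Classifies every content word of the five method fields as `known`
#' (it is the label of an active ontology term), `new` (not in the
#' ontology) or `stopword`. A character may only be saved once no `new`
#' words remain; [register_new_terms()] resolves them.
#'
#' @param method A `pheno_method`.
#' @param store A `pheno_store`.
#' @return A `pheno_check`: per-field data frames of `(word, status)`,
#'   the sorted vector `new_words`, and the flag `all_known`.
#' @export
semantic_check <- function(method, store) {
  stopifnot(inherits(method, "pheno_method"), inherits(store, "pheno_store"))
  stops <- store$config$stopwords
  known_labels <- vapply(
    Filter(function(t) t$status == "active", store$terms),
    `[[`, character(1), "label")
  classify <- function(text) {
    words <- split_words(paste(text, collapse = " "))
    status <- ifelse(words %in% stops, "stopword",
                     ifelse(words %in% known_labels, "known", "new"))
    data.frame(word = words, status = status, stringsAsFactors = FALSE)
  }
  fields <- list(from = classify(method$from), to = classify(method$to),
                 include = classify(method$include),
                 exclude = classify(method$exclude), at = classify(method$at))
  new_words <- sort(unique(unlist(lapply(fields, function(f)
    f$word[f$status == "new"]), use.names = FALSE)))
  structure(list(fields = fields, new_words = new_words,
                 all_known = length(new_words) == 0L),
            class = "pheno_check")
}

#' @export
print.pheno_check <- function(x, ...) {
  cat("<pheno_check> all_known =", x$all_known, "\n")
  if (!x$all_known) {
    cat("  need info on new terms:", paste(x$new_words, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Register the new terms flagged by a semantic check
#'
#' Adds each `new` word of a [semantic_check()] report to the ontology
#' (under the new-additions class) with its verbal definition, sample
#' sentence and taxon example. The definitions must cover exactly the
#' report's new words; afterwards a re-check of the same method is
#' `all_known`.
#'
#' @param report A `pheno_check`.
#' @param definitions Named list, one entry per new word; each entry a
#'   list or character vector giving `verbal_definition`,
#'   `sample_sentence` and `taxon_example` (missing pieces default to "").
#' @param creator Contributing author.
#' @inheritParams semantic_check
#' @param time Timestamp override for reproducible fixtures.
#' @return List of the newly registered `pheno_term`s.
#' @export
register_new_terms <- function(report, definitions, creator, store,
                               time = now_stamp()) {
  stopifnot(inherits(report, "pheno_check"))
  given <- names(definitions)
  if (is.null(given)) given <- character(0)
  missing <- setdiff(report$new_words, given)
  extra <- setdiff(given, report$new_words)
  if (length(missing) || length(extra)) {
    stop_pheno(sprintf(
      "definitions must cover exactly the new words; missing: {%s}; extra: {%s}",
      paste(missing, collapse = ", "), paste(extra, collapse = ", ")),
      "pheno_validation_error")
  }
  lapply(report$new_words, function(w) {
    d <- definitions[[w]]
    pick <- function(i, key) {
      v <- if (!is.null(names(d)) && key %in% names(d)) d[[key]]
           else if (length(d) >= i) d[[i]] else ""
      as.character(v)[1L]
    }
    add_term(w, verbal_definition = pick(1L, "verbal_definition"),
             sample_sentence = pick(2L, "sample_sentence"),
             taxon_example = pick(3L, "taxon_example"),
             creator = creator, store = store, time = time)
  })
}

# --- character lifecycle --------------------------------------------------

history_event <- function(time, actor, kind, payload = list()) {
  list(time = time, actor = actor, kind = kind,
       payload = lapply(payload, as.character))
}

link_structures <- function(name, store) {
  ids <- character(0)
  for (phrase in name$structures) {
    hit <- find_terms(phrase, store)
    if (nrow(hit) == 0L) {
      words <- split_words(phrase)
      hit <- do.call(rbind, lapply(words, find_terms, store = store))
    }
    if (!is.null(hit) && nrow(hit) > 0L) ids <- c(ids, hit$id)
  }
  sort(unique(ids))
}

find_characters_by_name <- function(name_text, store, active_only = TRUE) {
  keep <- Filter(function(ch) {
    (!active_only || ch$status == "active") && format(ch$name) == name_text
  }, store$characters)
  if (length(keep) == 0L) return(keep)
  keep[order(names(keep))]
}

#' Save a new measurement character
#'
#' The defining contract of the recorder: a character must be fully
#' defined before any measurement can be recorded against it. The name
#' must parse under the of/between grammar, every content word of the
#' method must be known to the ontology (register new terms first), and
#' a unit must be selected. The saved character becomes a subclass of
#' the perceived-quality root, is linked to its structure term(s), and
#' starts with `usage_count = 1`.
#'
#' @param name_text Character name, e.g. `"length of leaf"`.
#' @param method A [pheno_method()]; may be empty only when at least one
#'   illustration reference is supplied.
#' @param unit Unit code from the store's unit vocabulary.
#' @param creator Author saving the character.
#' @param store A `pheno_store`; modified in place.
#' @param force Save even when an active character with the same
#'   canonical name exists (otherwise a reuse suggestion error is
#'   raised listing the matches with creators and usage counts).
#' @param illustrations Character vector of illustration file references.
#' @param time Timestamp override for reproducible fixtures.
#' @return The new `pheno_character`.
#' @export
create_character <- function(name_text, method = pheno_method(), unit, creator,
                             store, force = FALSE,
                             illustrations = character(0),
                             time = now_stamp()) {
  stopifnot(inherits(store, "pheno_store"))
  name <- if (inherits(name_text, "pheno_name")) name_text
          else parse_character_name(name_text)
  if (missing(unit) || is.null(unit) || !nzchar(unit)) {
    stop_pheno("save refused: a measurement unit must be selected before saving a character",
               "pheno_unit_error")
  }
  if (!unit %in% store$config$units$unit) {
    stop_pheno(sprintf("unknown unit '%s'; known units: %s", unit,
                       paste(store$config$units$unit, collapse = ", ")),
               "pheno_unit_error")
  }
  if (method_is_empty(method) && length(illustrations) == 0L) {
    stop_pheno("a character needs a method definition or at least one illustration",
               "pheno_validation_error")
  }
  report <- semantic_check(method, store)
  if (!report$all_known) {
    stop_pheno(sprintf("save refused: need info on new terms: %s",
                       paste(report$new_words, collapse = ", ")),
               "pheno_new_terms", report = report)
  }
  canonical <- format(name)
  dups <- find_characters_by_name(canonical, store)
  if (length(dups) > 0L && !force) {
    listing <- vapply(dups, function(ch) {
      sprintf("%s (creators: %s; used %d times)", ch$id,
              paste(ch$creators, collapse = ", "), ch$usage_count)
    }, character(1))
    stop_pheno(sprintf(
      "an active character named '%s' already exists — consider reusing it: %s",
      canonical, paste(listing, collapse = "; ")),
      "pheno_duplicate_name", matches = names(dups))
  }
  id <- next_id(store)
  ch <- structure(list(
    id = id, name = name, method = method, unit = unit,
    creators = creator, usage_count = 1L,
    history = list(history_event(time, creator, "created",
                                 list(name = canonical, unit = unit))),
    illustrations = as.character(illustrations),
    status = "active",
    structure_ids = link_structures(name, store)
  ), class = "pheno_character")
  store$characters[[id]] <- ch
  log_event(store, "create_character", list(id = id, name = canonical), time)
  ch
}

get_character <- function(id, store) {
  ch <- store$characters[[id]]
  if (is.null(ch)) {
    stop_pheno(sprintf("unknown character id '%s'", id), "pheno_unknown_id")
  }
  ch
}

#' Reuse an existing character verbatim
#'
#' Adopts a character as-is for a new measurement session: its usage
#' count is incremented by exactly one and a `used` event is appended to
#' its history. Definition, unit and creators are untouched. Deprecated
#' characters are refused.
#'
#' @param character_id Id of the character to reuse.
#' @param actor User reusing the character.
#' @inheritParams create_character
#' @return The updated `pheno_character`.
#' @export
use_this <- function(character_id, actor, store, time = now_stamp()) {
  ch <- get_character(character_id, store)
  if (ch$status != "active") {
    stop_pheno(sprintf("character '%s' is deprecated and cannot be reused",
                       character_id), "pheno_validation_error")
  }
  ch$usage_count <- ch$usage_count + 1L
  ch$history <- c(ch$history, list(history_event(time, actor, "used")))
  store$characters[[character_id]] <- ch
  log_event(store, "use_this", list(id = character_id, actor = actor), time)
  ch
}

#' Clone an existing character and enhance its definition
#'
#' Creates a new character from an existing one, typically with an
#' improved method definition. The clone is a new character with a fresh
#' permanent id and `usage_count = 1`, recorded as an OWL-style
#' equivalent class of its source (both are expected to denote the same
#' measurement), with creatorship shared between the source's creators
#' and the enhancing actor. The source is unchanged apart from a
#' cross-reference event in its history; its usage count does not move.
#'
#' @param source_id Id of the character to clone.
#' @param enhanced_method A [pheno_method()] replacing the source's
#'   method; `NULL` keeps the source method unchanged. Must pass the
#'   semantic check (register new terms first).
#' @param actor Enhancing user, appended to the creator list.
#' @param unit Unit for the clone; `NULL` inherits the source unit.
#' @inheritParams create_character
#' @return The new `pheno_character`.
#' @export
clone_and_enhance <- function(source_id, enhanced_method = NULL, actor, store,
                              unit = NULL, time = now_stamp()) {
  src <- get_character(source_id, store)
  method <- if (is.null(enhanced_method)) src$method else enhanced_method
  stopifnot(inherits(method, "pheno_method"))
  report <- semantic_check(method, store)
  if (!report$all_known) {
    stop_pheno(sprintf("enhanced method refused: need info on new terms: %s",
                       paste(report$new_words, collapse = ", ")),
               "pheno_new_terms", report = report)
  }
  new_unit <- if (is.null(unit)) src$unit else unit
  if (!new_unit %in% store$config$units$unit) {
    stop_pheno(sprintf("unknown unit '%s'", new_unit), "pheno_unit_error")
  }
  id <- next_id(store)
  history <- list(
    history_event(time, actor, "created", list(name = format(src$name))),
    history_event(time, actor, "cloned_from", list(source = source_id))
  )
  if (!identical(unclass(method), unclass(src$method))) {
    history <- c(history, list(history_event(time, actor, "enhanced")))
  }
  if (!identical(new_unit, src$unit)) {
    history <- c(history, list(history_event(time, actor, "unit_changed",
                                             list(from = src$unit, to = new_unit))))
  }
  clone <- structure(list(
    id = id, name = src$name, method = method, unit = new_unit,
    creators = unique(c(src$creators, actor)),
    usage_count = 1L, history = history,
    illustrations = src$illustrations, status = "active",
    structure_ids = src$structure_ids
  ), class = "pheno_character")
  store$characters[[id]] <- clone
  src$history <- c(src$history,
                   list(history_event(time, actor, "cloned_from",
                                      list(clone = id))))
  store$characters[[source_id]] <- src
  add_equivalence(source_id, id, store, time = time)
  log_event(store, "clone_and_enhance", list(source = source_id, clone = id), time)
  clone
}

#' Deprecate a character
#'
#' Deprecated characters keep their id and axioms but are excluded from
#' search and can no longer be reused or recorded against.
#'
#' @inheritParams use_this
#' @return The updated `pheno_character`.
#' @export
deprecate_character <- function(character_id, store, time = now_stamp()) {
  ch <- get_character(character_id, store)
  if (ch$status != "active") {
    stop_pheno(sprintf("character '%s' is already deprecated", character_id),
               "pheno_validation_error")
  }
  ch$status <- "deprecated"
  store$characters[[character_id]] <- ch
  log_event(store, "deprecate_character", list(id = character_id), time)
  ch
}

#' Full display record of a character
#'
#' Assembles everything the character page shows: the canonical name,
#' the method fields with per-word known-term marks, unit, creators,
#' usage count, history and illustration references.
#'
#' @inheritParams use_this
#' @return A `pheno_render` list.
#' @export
render_character <- function(character_id, store) {
  ch <- get_character(character_id, store)
  structure(list(
    id = ch$id,
    name = format(ch$name),
    method_text = render_method(ch$method),
    method_fields = semantic_check(ch$method, store)$fields,
    unit = ch$unit,
    creators = ch$creators,
    usage_count = ch$usage_count,
    status = ch$status,
    history = ch$history,
    illustrations = ch$illustrations
  ), class = "pheno_render")
}

#' @export
print.pheno_render <- function(x, ...) {
  cat("<character> ", x$name, " [", x$id, "]\n", sep = "")
  cat("  method:  ", if (nzchar(x$method_text)) x$method_text else "(illustration only)", "\n", sep = "")
  cat("  unit:    ", x$unit, "\n", sep = "")
  cat("  creators:", paste(x$creators, collapse = ", "), "\n")
  cat("  usage:   ", x$usage_count, "\n", sep = "")
  if (length(x$illustrations)) {
    cat("  illustrations:", paste(x$illustrations, collapse = ", "), "\n")
  }
  cat("  history: ", length(x$history), " event(s)\n", sep = "")
  invisible(x)
}

#' @export
print.pheno_character <- function(x, ...) {
  cat("<pheno_character> ", format(x$name), " [", x$id, "] ",
      "unit=", x$unit, " usage=", x$usage_count, " (", x$status, ")\n", sep = "")
  invisible(x)
}
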