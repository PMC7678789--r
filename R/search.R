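# Character search: token-containment matching over character names,
# ranked by usage count, with tooltip-style previews.

#' Search existing characters by name or phrase
#'
#' A character matches when every content token of the query (case
#' folded, stopwords dropped) occurs among the tokens of its canonical
#' name. Hits are ordered by usage count descending, then name
#' ascending, then id ascending, so the most-reused characters surface
#' first. Deprecated characters never match. An empty result signals the
#' caller to offer creating a new character.
#'
#' @param query Free-text query, e.g. `"length of inflorescence"`.
#' @param store A `pheno_store`.
#' @return Data frame with columns `character_id`, `name`, `creators`
#'   (comma-joined), `usage_count`, `preview`.
#' @export
search_characters <- function(query, store) {
  stopifnot(inherits(store, "pheno_store"))
  qtok <- setdiff(split_words(query), store$config$stopwords)
  hits <- Filter(function(ch) {
    if (ch$status != "active") return(FALSE)
    ntok <- setdiff(split_words(format(ch$name)), store$config$stopwords)
    all(qtok %in% ntok)
  }, store$characters)
  df <- data.frame(
    character_id = vapply(hits, `[[`, character(1), "id"),
    name = vapply(hits, function(ch) format(ch$name), character(1)),
    creators = vapply(hits, function(ch) paste(ch$creators, collapse = ", "),
                      character(1)),
    usage_count = vapply(hits, `[[`, integer(1), "usage_count"),
    preview = vapply(hits, function(ch) preview_of(ch), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  df[order(-df$usage_count, df$name, df$character_id), , drop = FALSE]
}

preview_of <- function(ch, width = 80L) {
  txt <- render_method(ch$method)
  out <- if (nzchar(txt)) txt
         else if (length(ch$illustrations)) paste0("[illustration] ", ch$illustrations[[1L]])
         else "(no definition)"
  if (nchar(out) > width) out <- paste0(substr(out, 1L, width - 1L), "…")
  out
}

#' Tooltip preview of a character's definition
#'
#' The verbal method text when present, else the first illustration
#' reference, else an explicit no-definition marker — what a mouse-over
#' tooltip would show when picking a character to reuse.
#'
#' @param character_id Id of an existing character.
#' @inheritParams search_characters
#' @return A single preview string.
#' @export
preview <- function(character_id, store) {
  preview_of(get_character(character_id, store), width = .Machine$integer.max)
}
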