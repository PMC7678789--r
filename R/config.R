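# Shared configuration: stopwords, unit vocabulary, id scheme.

#' Default stopword list
#'
#' Function words ignored when tokenizing character names and method
#' definitions for the semantic check, search matching and the
#' convergence metrics. The list is deliberately small: content words
#' (anatomical terms, qualities) must never be swallowed.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  c("of", "a", "an", "the", "to", "from", "at", "and", "or", "between")
}

#' Default measurement-unit vocabulary
#'
#' Seed vocabulary of unit codes a character may carry, with the sign
#' rule applied when values are recorded: length-like units and counts
#' must be non-negative, angles may be negative.
#'
#' @return Data frame with columns `unit` and `allow_negative`.
#' @export
default_units <- function() {
  data.frame(
    unit = c("mm", "cm", "m", "µm", "count", "ratio", "degree"),
    allow_negative = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

# --- permanent identifiers ------------------------------------------------

ID_PREFIX <- "CAREX:"
ID_WIDTH <- 7L

# Reserved low ids for the three seeded root classes.
ROOT_STRUCTURE_NUM <- 1L   # anatomic structure
ROOT_QUALITY_NUM <- 2L     # perceived quality
ROOT_NEW_ADDITIONS_NUM <- 3L
FIRST_FREE_NUM <- 10L

format_id <- function(n) {
  sprintf("%s%0*d", ID_PREFIX, ID_WIDTH, as.integer(n))
}

is_store_id <- function(x) {
  is.character(x) && length(x) == 1L &&
    grepl(paste0("^", ID_PREFIX, "[0-9]{", ID_WIDTH, "}$"), x)
}

# External semantic anchors, stored as annotation strings only.
ANCHOR_ANATOMICAL_ENTITY <- "UBERON:0001062"
ANCHOR_QUALITY <- "PATO:0000001"

# Fold a label for duplicate detection / lookup.
fold_label <- function(x) tolower(trimws(gsub("[[:space:]]+", " ", x)))

now_stamp <- function() format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC")
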