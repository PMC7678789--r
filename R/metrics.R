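# Evaluation metrics: definition convergence, Likert survey scoring,
# weighted influence strength, and error-rate accounting with
# wrong-definition / wrong-unit categories.

#' Round half away from zero
#'
#' Commercial rounding used for all printed percentages (87.5 rounds to
#' 88, 93.75 to 94), as opposed to R's banker's rounding.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Normalize definition text to content words
#'
#' Applies the convergence-analysis normalization: lowercase, strip
#' punctuation, drop pure-number tokens and stopwords. Order is
#' preserved and the operation is idempotent.
#'
#' @param text Character vector (joined before tokenizing).
#' @param stopwords Stopword list; defaults to [default_stopwords()].
#' @return Character vector of content words.
#' @examples
#' normalize_words("end of perigynium wings")   # no "of"
#' normalize_words("2 to 3 mm!")                # just "mm"
#' @export
normalize_words <- function(text, stopwords = default_stopwords()) {
  setdiff_keep_order <- function(x, drop) x[!x %in% drop]
  setdiff_keep_order(split_words(paste(text, collapse = " ")), stopwords)
}

DEFINITION_FIELDS <- c("from", "to", "include", "exclude", "at")

check_definition_records <- function(records) {
  needed <- c("session", DEFINITION_FIELDS)
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop_pheno(sprintf("definition records are missing column(s): %s",
                       paste(missing, collapse = ", ")),
               "pheno_validation_error")
  }
  records
}

#' Count unique content words in a session's definitions
#'
#' Size of the union of normalized words over the five landmark fields
#' of every definition record in the chosen session.
#'
#' @param records Data frame of definition records with columns
#'   `session`, `from`, `to`, `include`, `exclude`, `at` (plus any
#'   identifier columns).
#' @param session Session label to select (e.g. `"paper"` or
#'   `"machine"`); `NULL` uses all records.
#' @inheritParams normalize_words
#' @return Integer count.
#' @export
unique_word_count <- function(records, session = NULL,
                              stopwords = default_stopwords()) {
  records <- check_definition_records(records)
  if (!is.null(session)) records <- records[records$session == session, , drop = FALSE]
  words <- unlist(lapply(DEFINITION_FIELDS, function(f)
    normalize_words(records[[f]], stopwords)), use.names = FALSE)
  length(unique(words))
}

definition_keys <- function(records, stopwords, per_field = FALSE) {
  norm_field <- function(f) vapply(records[[f]], function(x)
    paste(normalize_words(x, stopwords), collapse = " "), character(1),
    USE.NAMES = FALSE)
  normed <- lapply(DEFINITION_FIELDS, norm_field)
  if (per_field) {
    keys <- unlist(Map(function(vals, f) paste0(f, "\r", vals),
                       normed, DEFINITION_FIELDS), use.names = FALSE)
    keys[!grepl("\r$", keys)]
  } else {
    do.call(paste, c(normed, sep = "\r"))
  }
}

#' Count unique definitions in a session
#'
#' A definition's identity is the 5-tuple of normalized field texts
#' (from, to, include, exclude, at): two records count as the same
#' definition when they agree word-for-word after normalization.
#' `per_field = TRUE` instead counts distinct non-empty normalized field
#' values across the five fields.
#'
#' @inheritParams unique_word_count
#' @param per_field Count per-field values rather than 5-field tuples.
#' @return Integer count.
#' @export
unique_definition_count <- function(records, session = NULL,
                                    stopwords = default_stopwords(),
                                    per_field = FALSE) {
  records <- check_definition_records(records)
  if (!is.null(session)) records <- records[records$session == session, , drop = FALSE]
  if (nrow(records) == 0L) return(0L)
  length(unique(definition_keys(records, stopwords, per_field)))
}

#' Percent reduction between two counts
#'
#' `(before - after) / before * 100`, rounded half away from zero — the
#' convergence statistic comparing unique word or definition counts
#' between independent and shared recording sessions.
#'
#' @param before,after Counts; `before` must be positive.
#' @return Integer percent.
#' @examples
#' reduction_percent(118, 89)  # 25
#' reduction_percent(122, 64)  # 48
#' @export
reduction_percent <- function(before, after) {
  if (!is.numeric(before) || before <= 0) {
    stop_pheno("'before' must be a positive count", "pheno_validation_error")
  }
  as.integer(round_half_away((before - after) / before * 100))
}

#' Score five-point Likert responses
#'
#' Values run 1 (strongly disagree) to 5 (strongly agree). Reports the
#' mean, the sample (n-1) standard deviation, and the agree percentage:
#' the share of responses scoring 4 or 5, as an integer percent.
#'
#' @param values Integer vector of responses in 1..5.
#' @return List with `mean`, `sd`, `agree_percent`, `n`.
#' @export
likert_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop_pheno("no responses to score", "pheno_validation_error")
  }
  if (any(!values %in% 1:5)) {
    stop_pheno("Likert responses must be integers in 1..5", "pheno_validation_error")
  }
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       agree_percent = as.integer(round_half_away(mean(values >= 4) * 100)),
       n = length(values))
}

#' Weighted influence strength
#'
#' Summarizes how strongly a factor influenced reuse decisions from the
#' counts of respondents choosing each level:
#' `3 x strong + 2 x some + 1 x weak + 0 x none`.
#'
#' @param strong,some,weak,none Non-negative response counts. The first
#'   argument may instead be a list/row with these four fields.
#' @return Numeric score.
#' @examples
#' influence_strength(15, 6, 2, 0)  # 59
#' @export
influence_strength <- function(strong, some = NULL, weak = NULL, none = NULL) {
  if (is.list(strong) || (is.numeric(strong) && length(strong) == 4L && is.null(some))) {
    c4 <- unlist(strong, use.names = FALSE)[1:4]
    strong <- c4[[1L]]; some <- c4[[2L]]; weak <- c4[[3L]]; none <- c4[[4L]]
  }
  counts <- c(strong, some, weak, none)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop_pheno("influence counts must be non-negative numbers", "pheno_validation_error")
  }
  sum(counts * c(3, 2, 1, 0))
}

#' Integer error-rate percent
#'
#' `wrong / total * 100`, rounded half away from zero.
#'
#' @param wrong,total Counts; `total` must be positive.
#' @return Integer percent.
#' @examples
#' error_rate(29, 52)  # 56
#' @export
error_rate <- function(wrong, total) {
  if (!is.numeric(total) || total <= 0) {
    stop_pheno("'total' must be a positive count", "pheno_validation_error")
  }
  as.integer(round_half_away(wrong / total * 100))
}

check_error_records <- function(records) {
  needed <- c("outcome", "categories")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop_pheno(sprintf("error records are missing column(s): %s",
                       paste(missing, collapse = ", ")),
               "pheno_validation_error")
  }
  bad <- records$outcome == "error" & !nzchar(records$categories)
  bad <- bad | (records$outcome == "correct" & nzchar(records$categories))
  if (any(bad)) {
    stop_pheno("outcome must be 'error' exactly when categories are non-empty",
               "pheno_validation_error")
  }
  records
}

#' Count error records, optionally discounting unit-only errors
#'
#' Error records carry a `categories` code: `"d"` for a wrong
#' definition, `"u"` for a wrong unit, `"du"` for both, empty for a
#' correct outcome. `aggregate_errors` counts error rows within an
#' optional filter; with `exclude_unit_only = TRUE`, rows whose only
#' problem is the unit (`"u"`) are discounted — the accounting used to
#' ask how many errors would remain once the unit-selection design flaw
#' is fixed.
#'
#' @param records Data frame with columns `outcome`
#'   (`correct`/`error`), `categories` (`""`, `"d"`, `"u"`, `"du"`),
#'   and optionally `participant`, `task`, `method`, `group`.
#' @param ... Named filters on columns, e.g. `task = "T2"`,
#'   `method = c("use_this", "clone_enhance")`.
#' @param exclude_unit_only Drop records whose categories are exactly
#'   `"u"`.
#' @return Integer count of error records.
#' @export
aggregate_errors <- function(records, ..., exclude_unit_only = FALSE) {
  records <- check_error_records(records)
  filters <- list(...)
  for (col in names(filters)) {
    if (!col %in% names(records)) {
      stop_pheno(sprintf("no column '%s' in error records", col),
                 "pheno_validation_error")
    }
    records <- records[records[[col]] %in% filters[[col]], , drop = FALSE]
  }
  errs <- records[records$outcome == "error", , drop = FALSE]
  if (exclude_unit_only) {
    norm <- vapply(strsplit(errs$categories, ""), function(x)
      paste(sort(x), collapse = ""), character(1))
    errs <- errs[norm != "u", , drop = FALSE]
  }
  nrow(errs)
}
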