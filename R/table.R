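# Measurement table: the spreadsheet surface. Values can only be
# recorded against characters that are saved and active in the store —
# the recorder's defining contract.

#' Create an empty measurement table
#'
#' A grid of specimens by characters holding unit-bearing numeric
#' values. Columns must be added with [add_column()] (which enforces
#' that the character is saved in the ontology) before any value can be
#' recorded. Every cell keeps per-entry provenance (actor, timestamp);
#' overwrites are allowed and the prior entries are retained as history.
#'
#' @return A `pheno_table`.
#' @export
pheno_table <- function() {
  structure(list(
    specimens = character(0),
    characters = character(0),
    entries = data.frame(specimen = character(0), character_id = character(0),
                         value = numeric(0), actor = character(0),
                         timestamp = character(0), stringsAsFactors = FALSE)
  ), class = "pheno_table")
}

#' Add a character column to a measurement table
#'
#' Refused unless the character is saved and active in the store: a
#' measurement may never be recorded against an undefined character.
#'
#' @param table A `pheno_table`.
#' @param character_id Id of a saved, active character.
#' @param store The `pheno_store` holding the character.
#' @return The updated table.
#' @export
add_column <- function(table, character_id, store) {
  stopifnot(inherits(table, "pheno_table"))
  ch <- tryCatch(get_character(character_id, store), pheno_error = function(e) {
    stop_pheno(sprintf(
      "cannot add column '%s': the character is not saved in the ontology — define and save it first",
      character_id), "pheno_unknown_id")
  })
  if (ch$status != "active") {
    stop_pheno(sprintf("cannot add column for deprecated character '%s'",
                       character_id), "pheno_validation_error")
  }
  if (character_id %in% table$characters) {
    stop_pheno(sprintf("column '%s' is already present", character_id),
               "pheno_validation_error")
  }
  table$characters <- c(table$characters, character_id)
  table
}

#' Record a measurement value
#'
#' Stores a numeric value for one specimen under one character column,
#' in the character's unit. Values must be finite numbers; units flagged
#' non-negative in the unit vocabulary (lengths, counts) reject negative
#' values. Overwriting keeps the previous entry in the provenance log.
#'
#' @inheritParams add_column
#' @param specimen Specimen id (opaque string).
#' @param value Numeric measurement in the character's unit.
#' @param actor Who recorded the value.
#' @param time Timestamp override.
#' @return The updated table.
#' @export
record_value <- function(table, specimen, character_id, value, store,
                         actor = "unknown", time = now_stamp()) {
  stopifnot(inherits(table, "pheno_table"))
  if (!character_id %in% table$characters) {
    stop_pheno(sprintf("no column '%s' in this table; add_column() it first",
                       character_id), "pheno_unknown_id")
  }
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop_pheno("measurement value must be a single finite number",
               "pheno_validation_error")
  }
  ch <- get_character(character_id, store)
  units <- store$config$units
  allow_neg <- units$allow_negative[match(ch$unit, units$unit)]
  if (isFALSE(allow_neg) && value < 0) {
    stop_pheno(sprintf("negative value %g is not valid for unit '%s'",
                       value, ch$unit), "pheno_validation_error")
  }
  if (!specimen %in% table$specimens) {
    table$specimens <- c(table$specimens, as.character(specimen))
  }
  table$entries <- rbind(table$entries, data.frame(
    specimen = as.character(specimen), character_id = character_id,
    value = as.numeric(value), actor = actor, timestamp = time,
    stringsAsFactors = FALSE))
  table
}

# Current value per (specimen, character): the last entry wins.
current_cells <- function(table) {
  e <- table$entries
  if (nrow(e) == 0L) return(e)
  key <- paste(e$specimen, e$character_id, sep = "\r")
  e[!duplicated(key, fromLast = TRUE), , drop = FALSE]
}

#' Table values as a wide data frame
#' @param table A `pheno_table`.
#' @return Data frame: one row per specimen, one column per character id.
#' @export
table_values <- function(table) {
  cells <- current_cells(table)
  out <- data.frame(specimen = table$specimens, stringsAsFactors = FALSE)
  for (cid in table$characters) {
    col <- rep(NA_real_, length(table$specimens))
    sub <- cells[cells$character_id == cid, , drop = FALSE]
    col[match(sub$specimen, table$specimens)] <- sub$value
    out[[cid]] <- col
  }
  out
}

#' @export
print.pheno_table <- function(x, ...) {
  cat(sprintf("<pheno_table> %d specimen(s) x %d character(s), %d entries\n",
              length(x$specimens), length(x$characters), nrow(x$entries)))
  if (length(x$specimens) && length(x$characters)) print(table_values(x))
  invisible(x)
}

#' Export a measurement table to CSV
#'
#' Wide layout: one row per specimen, one column per character id,
#' missing cells as empty fields (never 0). Long layout: one row per
#' current cell with unit and provenance
#' (`specimen, character_id, value, unit, actor, timestamp`).
#'
#' @inheritParams add_column
#' @param path Output file.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
export_table_csv <- function(table, path, store, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (layout == "wide") {
    utils::write.csv(table_values(table), path, row.names = FALSE, na = "")
  } else {
    cells <- current_cells(table)
    unit_of <- vapply(cells$character_id,
                      function(cid) get_character(cid, store)$unit, character(1))
    long <- data.frame(specimen = cells$specimen,
                       character_id = cells$character_id,
                       value = cells$value,
                       unit = unname(unit_of),
                       actor = cells$actor,
                       timestamp = cells$timestamp,
                       stringsAsFactors = FALSE)
    utils::write.csv(long, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Import a wide measurement-table CSV
#'
#' Every column header (other than `specimen`) must resolve to a saved
#' character in the store; unresolvable headers are an error naming the
#' offending columns. This re-asserts on import the invariant that no
#' cell exists without a character definition.
#'
#' @param path CSV written by [export_table_csv()] (wide layout).
#' @param store The `pheno_store` the column headers must resolve in.
#' @param actor Recorded as the importing actor for provenance.
#' @return A `pheno_table`.
#' @export
import_table_csv <- function(path, store, actor = "import") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"specimen" %in% names(df)) {
    stop_pheno("import needs a 'specimen' column", "pheno_parse_error")
  }
  cols <- setdiff(names(df), "specimen")
  bad <- cols[!vapply(cols, function(cid)
    !is.null(store$characters[[cid]]), logical(1))]
  if (length(bad)) {
    stop_pheno(sprintf(
      "column header(s) do not resolve to saved characters: %s",
      paste(bad, collapse = ", ")), "pheno_unknown_id")
  }
  tab <- pheno_table()
  for (cid in cols) tab <- add_column(tab, cid, store)
  for (i in seq_len(nrow(df))) {
    for (cid in cols) {
      v <- df[[cid]][[i]]
      if (!is.na(v) && (!is.character(v) || nzchar(v))) {
        tab <- record_value(tab, df$specimen[[i]], cid, as.numeric(v), store,
                            actor = actor)
      }
    }
  }
  tab$specimens <- as.character(df$specimen)
  tab
}
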