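# Seeded fixture generation: a Carex-like ontology with preloaded
# characters emulating the two study configurations, plus regenerated
# evaluation-input tables whose marginal counts match the published
# error and influence accounting.

FIXTURE_EPOCH <- as.POSIXct("2018-10-01 00:00:00", tz = "UTC")

fixture_clock <- function() {
  i <- 0L
  function() {
    i <<- i + 1L
    format(FIXTURE_EPOCH + i, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
}

SHARED_TERMS <- c(
  "perigynium", "beak", "wing", "wings", "inflorescence", "scale", "leaf",
  "culm", "spike", "achene", "stigma", "style", "teeth", "summit", "apex",
  "insertion", "lowest", "base", "tip", "end", "edge", "widest", "opposite",
  "body", "stem", "flower", "margin"
)

INDIVIDUAL_TERMS <- c(
  "leaf", "blade", "pupil", "pupils", "eye", "eyes", "apex", "base", "tip",
  "margin", "center", "left", "right", "midrib", "petiole"
)

use_n_times <- function(id, n, actor, store, clock) {
  for (i in seq_len(n)) use_this(id, actor, store, time = clock())
}

seed_shared_characters <- function(store, clock) {
  bf <- "Bruce Ford"; ym <- "Yin Ming"
  c1 <- create_character(
    "length of inflorescence",
    pheno_method(from = "insertion of lowest scale", to = "apex of inflorescence"),
    unit = "mm", creator = bf, store = store,
    illustrations = "inflorescence_length.png", time = clock())
  use_n_times(c1$id, 19L, "seed", store, clock)   # usage 20: the well-used preload

  c2 <- create_character(
    "length of inflorescence",
    pheno_method(from = "base of lowest spike", to = "tip of inflorescence"),
    unit = "mm", creator = ym, store = store, force = TRUE, time = clock())
  use_n_times(c2$id, 1L, "seed", store, clock)    # usage 2

  c3 <- create_character(
    "width of inflorescence",
    pheno_method(from = "edge of widest spike", to = "opposite edge of inflorescence"),
    unit = "cm",  # deliberate unit mismatch with the mm task
    creator = ym, store = store, time = clock())
  use_n_times(c3$id, 2L, "seed", store, clock)    # usage 3

  # Distractors: same name, illustration-only definitions.
  c4 <- create_character(
    "length of perigynium beak", pheno_method(),
    unit = "mm", creator = bf, store = store,
    illustrations = "perigynium_beak_a.png", time = clock())
  use_n_times(c4$id, 4L, "seed", store, clock)    # usage 5

  c5 <- create_character(
    "length of perigynium beak", pheno_method(),
    unit = "mm", creator = ym, store = store, force = TRUE,
    illustrations = c("perigynium_beak_b.png",
                      "perigynium_beak_b_style_stigma.png"),
    time = clock())
  use_n_times(c5$id, 1L, "seed", store, clock)    # usage 2

  create_character(
    "length of winged perigynium beak",
    pheno_method(from = "end of perigynium wings", to = "summit of perigynium",
                 include = "perigynium beak teeth"),
    unit = "mm", creator = bf, store = store, time = clock())  # usage 1
  invisible(store)
}

seed_individual_characters <- function(store, clock) {
  bf <- "Bruce Ford"; ym <- "Yin Ming"
  # Three illustration-only "length of leaf" entries: one matching the
  # task illustration and two non-matching ones.
  create_character("length of leaf", pheno_method(), unit = "mm", creator = bf,
                   store = store, illustrations = "leaf_length_match.png",
                   time = clock())
  create_character("length of leaf", pheno_method(), unit = "mm", creator = ym,
                   store = store, force = TRUE,
                   illustrations = "leaf_length_nonmatch_1.png", time = clock())
  create_character("length of leaf", pheno_method(), unit = "cm", creator = ym,
                   store = store, force = TRUE,
                   illustrations = "leaf_length_nonmatch_2.png", time = clock())
  invisible(store)
}

synth_label <- function(i, rng_words) {
  paste0(sample(rng_words$pre, 1L), sample(rng_words$suf, 1L), i)
}

#' Generate a seeded fixture store
#'
#' Builds an ontology store emulating the two study configurations. The
#' `shared` profile seeds Carex structure terms (perigynium, beak, wing,
#' inflorescence, scale, leaf, ...) and six preloaded characters varying
#' in usage count (one used 20 times vs. a few times for the others),
#' creator ("Bruce Ford" vs. the made-up "Yin Ming"), 0-2 illustration
#' references, and whether they match a task — including the deliberate
#' "length of perigynium beak" distractors (two illustration-only, one
#' text-defined as "From: end of perigynium wings To: summit of
#' perigynium Include: perigynium beak teeth"). The `individual` profile
#' seeds everyday-object terms and three illustration-only "length of
#' leaf" entries. The same `(seed, profile)` always yields a
#' byte-identical serialized store.
#'
#' @param profile `"shared"` or `"individual"`.
#' @param seed Integer seed driving any synthetic filler.
#' @param n_extra_terms,n_extra_characters Optional synthetic filler
#'   entities (Carex-like placeholder labels, no nomenclatural claims)
#'   for stress and property testing.
#' @return List with elements `store` (a `pheno_store`), `table` (an
#'   empty [pheno_table()] skeleton), `profile`, `seed`.
#' @export
make_fixture <- function(profile = c("shared", "individual"), seed = 1L,
                         n_extra_terms = 0L, n_extra_characters = 0L) {
  profile <- match.arg(profile)
  clock <- fixture_clock()
  store <- pheno_store()
  labels <- if (profile == "shared") SHARED_TERMS else INDIVIDUAL_TERMS
  for (lab in labels) {
    add_term(lab, verbal_definition = paste("seed structure term:", lab),
             creator = "seed", store = store, time = clock())
  }
  if (profile == "shared") seed_shared_characters(store, clock)
  else seed_individual_characters(store, clock)

  if (n_extra_terms > 0L || n_extra_characters > 0L) {
    withr_seed <- .Random.seed_exists()
    set.seed(seed)
    rng_words <- list(pre = c("peri", "achen", "stig", "ligul", "rhiz",
                              "glum", "carp", "lemm"),
                      suf = c("ium", "ella", "ula", "ina", "aria", "odes"))
    extra <- character(0)
    for (i in seq_len(n_extra_terms)) {
      lab <- synth_label(i, rng_words)
      add_term(lab, verbal_definition = "synthetic filler term",
               creator = "seed", store = store, time = clock())
      extra <- c(extra, lab)
    }
    pool <- c(extra, labels)
    qualities <- c("length", "width", "depth", "thickness", "diameter")
    for (i in seq_len(n_extra_characters)) {
      structure_lab <- sample(pool, 1L)
      nm <- paste(sample(qualities, 1L), "of", structure_lab)
      ch <- create_character(
        nm, pheno_method(from = paste("base of", structure_lab),
                         to = paste("apex of", structure_lab)),
        unit = sample(c("mm", "cm"), 1L), creator = "seed", store = store,
        force = TRUE, time = clock())
      use_n_times(ch$id, sample(0:3, 1L), "seed", store, clock)
    }
    if (!is.null(withr_seed)) assign(".Random.seed", withr_seed, envir = globalenv())
  }
  list(store = store, table = pheno_table(), profile = profile, seed = seed)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

# --- regenerated evaluation inputs ---------------------------------------

# Printed per-task machine-session error accounting, one row per cell:
# method x outcome x categories x count, for the nonexpert (NS, n=13)
# and expert (ES, n=19) groups.
machine_error_cells <- function() {
  cell <- function(group, task, method, outcome, categories, n) {
    data.frame(group = group, task = task, method = method,
               outcome = outcome, categories = categories, n = n,
               stringsAsFactors = FALSE)
  }
  rbind(
    cell("NS", "T1", "clone_enhance", "correct", "", 7),
    cell("NS", "T1", "create_new", "correct", "", 6),
    cell("NS", "T2", "use_this", "correct", "", 7),
    cell("NS", "T2", "clone_enhance", "correct", "", 2),
    cell("NS", "T2", "clone_enhance", "error", "d", 1),
    cell("NS", "T2", "create_new", "correct", "", 1),
    cell("NS", "T2", "create_new", "error", "d", 2),
    cell("NS", "T3", "use_this", "error", "u", 3),
    cell("NS", "T3", "clone_enhance", "correct", "", 3),
    cell("NS", "T3", "clone_enhance", "error", "d", 3),
    cell("NS", "T3", "clone_enhance", "error", "u", 1),
    cell("NS", "T3", "clone_enhance", "error", "du", 2),
    cell("NS", "T3", "create_new", "error", "d", 1),
    cell("NS", "T4", "use_this", "error", "d", 5),
    cell("NS", "T4", "clone_enhance", "error", "d", 2),
    cell("NS", "T4", "create_new", "correct", "", 3),
    cell("NS", "T4", "create_new", "error", "d", 2),
    cell("ES", "T1", "use_this", "error", "d", 2),
    cell("ES", "T1", "clone_enhance", "correct", "", 11),
    cell("ES", "T1", "create_new", "correct", "", 6),
    cell("ES", "T2", "use_this", "correct", "", 13),
    cell("ES", "T2", "clone_enhance", "correct", "", 4),
    cell("ES", "T2", "clone_enhance", "error", "d", 1),
    cell("ES", "T2", "create_new", "correct", "", 1),
    cell("ES", "T3", "use_this", "error", "u", 7),
    cell("ES", "T3", "clone_enhance", "correct", "", 6),
    cell("ES", "T3", "clone_enhance", "error", "u", 2),
    cell("ES", "T3", "create_new", "correct", "", 4),
    cell("ES", "T4", "use_this", "error", "d", 9),
    cell("ES", "T4", "clone_enhance", "correct", "", 2),
    cell("ES", "T4", "clone_enhance", "error", "d", 4),
    cell("ES", "T4", "create_new", "correct", "", 3),
    cell("ES", "T4", "create_new", "error", "d", 1)
  )
}

# Paper-session wrong-character counts per task (all definition errors),
# out of 13 NS and 19 ES participants per task.
paper_error_cells <- function() {
  data.frame(
    group = rep(c("NS", "ES"), each = 4),
    task = rep(c("T1", "T2", "T3", "T4"), 2),
    wrong = c(5, 7, 7, 10, 4, 5, 8, 8),
    total = rep(c(13, 19), each = 4),
    stringsAsFactors = FALSE
  )
}

influence_count_rows <- function() {
  data.frame(
    factor = c("meaningfulness_of_method_definition", "appropriateness_of_unit",
               "frequency_of_usage", "reputation_of_creator",
               "change_history_of_character", "others"),
    strong = c(15, 12, 8, 7, 0, 0),
    some = c(6, 6, 8, 7, 5, 3),
    weak = c(2, 3, 4, 1, 4, 3),
    none = c(0, 2, 3, 8, 14, 17),
    stringsAsFactors = FALSE
  )
}

expand_machine_errors <- function() {
  cells <- machine_error_cells()
  rows <- cells[rep(seq_len(nrow(cells)), cells$n), , drop = FALSE]
  rows$n <- NULL
  # deterministic participant assignment: cycle within group x task
  rows$participant <- NA_character_
  for (g in unique(rows$group)) {
    for (tk in unique(rows$task)) {
      idx <- which(rows$group == g & rows$task == tk)
      rows$participant[idx] <- sprintf("%s%02d", tolower(g), seq_along(idx))
    }
  }
  rownames(rows) <- NULL
  rows[, c("participant", "group", "task", "method", "outcome", "categories")]
}

expand_paper_errors <- function() {
  cells <- paper_error_cells()
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    r <- cells[i, ]
    data.frame(
      participant = sprintf("%s%02d", tolower(r$group), seq_len(r$total)),
      group = r$group, task = r$task,
      outcome = c(rep("error", r$wrong), rep("correct", r$total - r$wrong)),
      categories = c(rep("d", r$wrong), rep("", r$total - r$wrong)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

synth_definition_records <- function(seed) {
  set.seed(seed)
  n_participants <- 8L
  tasks <- c("T1", "T2", "T3", "T4")
  # Shared "converged" definitions per task (what reuse steers users to)
  canon <- list(
    T1 = c("base of culm", "apex of inflorescence", "", "", ""),
    T2 = c("insertion of lowest scale", "apex of inflorescence", "", "", ""),
    T3 = c("edge of widest spike", "opposite edge of inflorescence", "", "", ""),
    T4 = c("end of perigynium wings", "summit of perigynium",
           "perigynium beak teeth", "", "")
  )
  synonyms <- list(
    c("bottom", "base", "lower end", "very bottom"),
    c("top", "apex", "summit", "tip"),
    c("start", "beginning", "insertion", "origin"),
    c("whole", "entire", "complete", "full")
  )
  rows <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("p%02d", p)
    for (tk in tasks) {
      base <- canon[[tk]]
      # paper session: idiosyncratic wording around the canonical fields
      paper <- vapply(base, function(f) {
        if (!nzchar(f)) return("")
        paste(sample(synonyms[[sample(4L, 1L)]], 1L), f)
      }, character(1), USE.NAMES = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pid, task = tk, session = "paper",
        from = paper[1], to = paper[2], include = paper[3],
        exclude = paper[4], at = paper[5], stringsAsFactors = FALSE)
      # machine session: most users adopt the shared definition verbatim
      machine <- if (stats::runif(1) < 0.75) base else paper
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pid, task = tk, session = "machine",
        from = machine[1], to = machine[2], include = machine[3],
        exclude = machine[4], at = machine[5], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

synth_survey_responses <- function(seed) {
  set.seed(seed + 1L)
  qs <- c("skills_to_use", "easy_after_practice", "useful_for_explaining",
          "prefer_over_spreadsheet", "ce_quicker")
  probs <- list(c(.02, .05, .12, .40, .41), c(.02, .05, .12, .40, .41),
                c(.01, .02, .10, .45, .42), c(.02, .04, .14, .40, .40),
                c(.01, .02, .07, .35, .55))
  out <- do.call(rbind, Map(function(q, p) {
    data.frame(participant = sprintf("p%02d", 1:32), question = q,
               value = sample(1:5, 32, replace = TRUE, prob = p),
               stringsAsFactors = FALSE)
  }, qs, probs))
  rownames(out) <- NULL
  out[, c("participant", "question", "value")]
}

#' Regenerate the evaluation-module input tables
#'
#' The raw participant logs behind the published evaluation are not
#' available, so this generator emits synthetic record-level CSVs whose
#' marginal counts equal the published accounting: machine-session error
#' records reproducing every printed method-by-task cell for the
#' nonexpert (NS) and expert (ES) groups, paper-session error records
#' with the printed per-task wrong-character counts (29/52 NS, 25/76
#' ES), the influence-factor response counts, plus synthetic definition
#' records exhibiting paper-to-machine convergence and synthetic Likert
#' responses. Regeneration with the same seed is byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for the synthetic definition/survey tables.
#' @param profile Must be `"shared"`; the evaluation belongs to the
#'   shared configuration.
#' @return Named list of the file paths written: `machine_errors`,
#'   `paper_errors`, `influence_counts`, `definitions`,
#'   `survey_responses`.
#' @export
make_experiment_tables <- function(dir, seed = 1L, profile = "shared") {
  if (!identical(profile, "shared")) {
    stop_pheno("evaluation tables exist only for the shared profile",
               "pheno_validation_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    machine_errors = file.path(dir, "machine_errors.csv"),
    paper_errors = file.path(dir, "paper_errors.csv"),
    influence_counts = file.path(dir, "influence_counts.csv"),
    definitions = file.path(dir, "definitions.csv"),
    survey_responses = file.path(dir, "survey_responses.csv")
  )
  utils::write.csv(expand_machine_errors(), paths$machine_errors, row.names = FALSE)
  utils::write.csv(expand_paper_errors(), paths$paper_errors, row.names = FALSE)
  utils::write.csv(influence_count_rows(), paths$influence_counts, row.names = FALSE)
  utils::write.csv(synth_definition_records(seed), paths$definitions, row.names = FALSE)
  utils::write.csv(synth_survey_responses(seed), paths$survey_responses, row.names = FALSE)
  paths
}

#' Read an evaluation CSV written by [make_experiment_tables()]
#'
#' Thin reader that keeps empty category/field cells as `""` rather
#' than `NA`.
#'
#' @param path CSV file.
#' @return Data frame.
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in names(df)) {
    if (is.character(df[[col]])) df[[col]][is.na(df[[col]])] <- ""
    if (is.logical(df[[col]]) && all(is.na(df[[col]]))) df[[col]] <- ""
  }
  df
}
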