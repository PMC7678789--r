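test_that("the of/between grammar accepts quality-first names only", {
  n <- parse_character_name("length of leaf")
  expect_identical(n$quality, "length")
  expect_identical(n$preposition, "of")
  expect_identical(n$structures, "leaf")
  expect_error(parse_character_name("leaf length"), class = "pheno_grammar_error")

  n2 <- parse_character_name("distance between pupils")
  expect_identical(n2$preposition, "between")
  expect_identical(n2$structures, "pupils")
  n3 <- parse_character_name("distance between apex and base")
  expect_identical(n3$structures, c("apex", "base"))
  # normalization: case and runs of spaces
  expect_identical(format(parse_character_name("Length  OF   Leaf")), "length of leaf")
  expect_error(parse_character_name("of leaf"), class = "pheno_grammar_error")
  expect_error(parse_character_name("length of"), class = "pheno_grammar_error")
})

test_that("semantic check classifies words as known, new or stopword", {
  st <- tiny_store(c("perigynium"))
  m <- pheno_method(from = "end of perigynium wings")
  rep <- semantic_check(m, st)
  expect_false(rep$all_known)
  expect_identical(rep$new_words, c("end", "wings"))
  from <- rep$fields$from
  expect_identical(from$status[from$word == "of"], "stopword")
  expect_identical(from$status[from$word == "perigynium"], "known")

  expect_true(semantic_check(pheno_method(), st)$all_known)
  all_known <- semantic_check(pheno_method(from = "perigynium"), st)
  expect_true(all_known$all_known)
  # number tokens are not content words
  expect_true(semantic_check(pheno_method(at = "2 3"), st)$all_known)
})

test_that("registering the flagged terms makes a re-check all_known", {
  st <- tiny_store(c("perigynium"))
  m <- pheno_method(from = "end of perigynium wings")
  rep <- semantic_check(m, st)
  register_new_terms(rep, list(end = list(verbal_definition = "distal extremity"),
                               wings = list(verbal_definition = "lateral flanges")),
                     creator = "alice", store = st)
  expect_true(semantic_check(m, st)$all_known)
  # definitions must cover exactly the new words
  rep2 <- semantic_check(pheno_method(from = "perigynium"), st)
  expect_error(register_new_terms(rep2, list(stray = list()), "alice", st),
               class = "pheno_validation_error")
  expect_identical(register_new_terms(rep2, list(), "alice", st), list())
})

test_that("create_character enforces unit, known terms and duplicate policy", {
  st <- tiny_store(c("leaf", "apex", "base"))
  m <- pheno_method(from = "base of leaf", to = "apex of leaf")
  expect_error(create_character("length of leaf", m, unit = "", creator = "a", store = st),
               class = "pheno_unit_error")
  expect_error(
    create_character("length of leaf", pheno_method(from = "froopy bits"),
                     unit = "mm", creator = "a", store = st),
    class = "pheno_new_terms")

  ch <- create_character("length of leaf", m, unit = "mm", creator = "alice", store = st)
  expect_identical(ch$usage_count, 1L)
  expect_identical(ch$history[[1]]$kind, "created")
  expect_true(find_terms("leaf", st)$id %in% ch$structure_ids)

  err <- expect_error(
    create_character("length of leaf", m, unit = "mm", creator = "bob", store = st),
    class = "pheno_duplicate_name")
  expect_match(conditionMessage(err), "alice")
  forced <- create_character("length of leaf", m, unit = "mm", creator = "bob",
                             store = st, force = TRUE)
  expect_false(identical(forced$id, ch$id))

  # an empty method needs an illustration
  expect_error(create_character("width of leaf", pheno_method(), unit = "mm",
                                creator = "a", store = st),
               class = "pheno_validation_error")
  ill <- create_character("width of leaf", pheno_method(), unit = "mm",
                          creator = "a", store = st,
                          illustrations = "leaf_width.png")
  expect_identical(ill$illustrations, "leaf_width.png")
})

test_that("use_this increments usage by exactly one and appends a used event", {
  fx <- store_with_character()
  st <- fx$store; id <- fx$character$id
  before <- get_character(id, st)
  ch <- use_this(id, "bob", st)
  expect_identical(ch$usage_count, before$usage_count + 1L)
  expect_identical(tail(ch$history, 1)[[1]]$kind, "used")
  expect_identical(ch$unit, before$unit)
  expect_identical(ch$creators, before$creators)
  for (i in 1:5) use_this(id, "carol", st)
  expect_identical(get_character(id, st)$usage_count, before$usage_count + 6L)
  deprecate_character(id, st)
  expect_error(use_this(id, "bob", st), class = "pheno_validation_error")
  expect_error(use_this("CAREX:9999999", "bob", st), class = "pheno_unknown_id")
})

test_that("clone_and_enhance shares creatorship, links equivalence, leaves source intact", {
  fx <- store_with_character()
  st <- fx$store; src_id <- fx$character$id
  src_before <- get_character(src_id, st)
  clone <- clone_and_enhance(
    src_id, pheno_method(from = "base of leaf", to = "tip of leaf"),
    actor = "es03", store = st)
  expect_identical(clone$creators, c("alice", "es03"))
  expect_identical(clone$usage_count, 1L)
  expect_setequal(equivalence_class(src_id, st), c(src_id, clone$id))
  src_after <- get_character(src_id, st)
  expect_identical(src_after$method, src_before$method)
  expect_identical(src_after$unit, src_before$unit)
  expect_identical(src_after$usage_count, src_before$usage_count)
  expect_identical(tail(src_after$history, 1)[[1]]$kind, "cloned_from")
  expect_true(any(vapply(clone$history, function(e) e$kind == "enhanced", TRUE)))

  # identity-method clone: still a new id, still equivalent
  clone2 <- clone_and_enhance(src_id, NULL, "dana", st)
  expect_false(identical(clone2$id, src_id))
  # clone of a clone: three-member class
  clone3 <- clone_and_enhance(clone$id, NULL, "erin", st)
  expect_setequal(equivalence_class(src_id, st),
                  c(src_id, clone$id, clone2$id, clone3$id))
})

test_that("render assembles name, marked method text, usage and history", {
  st <- tiny_store(c("inflorescence", "scale", "apex", "insertion", "lowest"))
  ch <- create_character(
    "length of inflorescence",
    pheno_method(from = "insertion of lowest scale", to = "apex of inflorescence"),
    unit = "mm", creator = "Bruce Ford", store = st)
  r <- render_character(ch$id, st)
  expect_identical(r$method_text,
                   "From: insertion of lowest scale To: apex of inflorescence")
  expect_true(all(r$method_fields$from$status != "new"))
  expect_identical(r$illustrations, character(0))
  use_this(ch$id, "bob", st)
  expect_identical(render_character(ch$id, st)$usage_count, 2L)
  expect_error(render_character("CAREX:9999999", st), class = "pheno_unknown_id")
})

test_that("usage_count always equals 1 + used events; parse/render is a fixed point", {
  fx <- store_with_character()
  st <- fx$store
  set.seed(11)
  ids <- fx$character$id
  for (i in 1:40) {
    pick <- sample(ids, 1)
    if (stats::runif(1) < 0.7) use_this(pick, "u", st)
    else ids <- c(ids, clone_and_enhance(pick, NULL, paste0("u", i), st)$id)
  }
  for (id in ids) {
    ch <- get_character(id, st)
    used <- sum(vapply(ch$history, function(e) e$kind == "used", TRUE))
    expect_identical(ch$usage_count, 1L + used)
  }
  set.seed(12)
  for (i in 1:50) {
    nm <- random_name()
    parsed <- parse_character_name(nm)
    expect_identical(parse_character_name(format(parsed)), parsed)
  }
})
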