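test_that("new terms get fresh monotone ids under the new-additions class", {
  st <- pheno_store()
  t1 <- add_term("wing", creator = "alice", store = st)
  t2 <- add_term("beak", creator = "alice", store = st)
  expect_identical(t1$parent_id, store_roots(st)$new_additions)
  expect_identical(t1$status, "active")
  num <- function(id) as.integer(sub("^CAREX:", "", id))
  expect_gt(num(t2$id), num(t1$id))
  # new-additions is itself under the anatomic-structure root, so both
  # placement statements hold for a fresh term
  expect_identical(tail(parent_chain(t1$id, st), 1), store_roots(st)$structure)
})

test_that("duplicate active labels are refused with a pointer to the existing term", {
  st <- tiny_store()
  existing <- find_terms("perigynium", st)$id
  err <- expect_error(add_term("Perigynium", creator = "bob", store = st),
                      class = "pheno_duplicate_label")
  expect_match(conditionMessage(err), existing, fixed = TRUE)
  expect_error(add_term("   ", creator = "bob", store = st),
               class = "pheno_validation_error")
})

test_that("find_terms folds case, filters deprecated, and orders by id", {
  st <- tiny_store()
  expect_identical(nrow(find_terms("Perigynium", st)), 1L)
  expect_identical(nrow(find_terms("qwzx", st)), 0L)
  id <- find_terms("beak", st)$id
  deprecate_term(id, st)
  expect_identical(nrow(find_terms("beak", st)), 0L)
  expect_identical(get_term(id, st)$status, "deprecated")
  expect_error(deprecate_term(id, st), class = "pheno_validation_error")
  # id is never reassigned: a new term gets a strictly larger number
  relabelled <- add_term("beak", creator = "bob", store = st)
  expect_false(identical(relabelled$id, id))
})

test_that("equivalence classes are symmetric and transitively closed", {
  st <- tiny_store(c("a1", "a2", "a3", "a4"))
  ids <- vapply(c("a1", "a2", "a3", "a4"), function(l) find_terms(l, st)$id, "")
  add_equivalence(ids[1], ids[2], st)
  expect_identical(equivalence_class(ids[1], st), unname(sort(ids[1:2])))
  expect_identical(equivalence_class(ids[2], st), unname(sort(ids[1:2])))
  add_equivalence(ids[2], ids[3], st)
  expect_identical(equivalence_class(ids[1], st), unname(sort(ids[1:3])))
  expect_identical(equivalence_class(ids[4], st), unname(ids[4]))
  expect_error(add_equivalence(ids[1], ids[1], st), class = "pheno_validation_error")
  expect_error(add_equivalence(ids[1], "CAREX:9999999", st), class = "pheno_unknown_id")
  # recording the same pair twice keeps a single axiom
  n <- length(st$equivalences)
  add_equivalence(ids[2], ids[1], st)
  expect_identical(length(st$equivalences), n)
})

test_that("reparenting re-files a term but refuses cycles and root moves", {
  st <- tiny_store()
  wing <- add_term("wing", creator = "curator", store = st)
  peri <- find_terms("perigynium", st)$id
  reparent_term(wing$id, peri, st)
  chain <- parent_chain(wing$id, st)
  expect_identical(chain[2], peri)
  expect_identical(tail(chain, 1), store_roots(st)$structure)
  expect_error(reparent_term(store_roots(st)$structure, peri, st),
               class = "pheno_validation_error")
  # A under B then B under A must be refused
  a <- add_term("alpha", creator = "c", store = st)
  b <- add_term("beta", creator = "c", store = st)
  reparent_term(a$id, b$id, st)
  expect_error(reparent_term(b$id, a$id, st), class = "pheno_cycle")
})

test_that("save/load is the identity and rejects corrupt files", {
  fx <- store_with_character()
  st <- fx$store
  add_equivalence(fx$character$id, find_terms("leaf", st)$id, st)
  path <- withr::local_tempfile(fileext = ".json")
  save_store(st, path)
  st2 <- load_store(path)
  expect_equal(phenochar:::store_to_list(st), phenochar:::store_to_list(st2))
  expect_identical(st2$next_num, st$next_num)

  expect_error(load_store(withr::local_tempfile(fileext = ".json")),
               class = "pheno_parse_error")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", bad)
  expect_error(load_store(bad), class = "pheno_parse_error")

  # duplicate id in the file is rejected
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  raw$terms[[length(raw$terms) + 1L]] <- raw$terms[[1L]]
  dup <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, dup, auto_unbox = FALSE, na = "null", null = "null")
  expect_error(load_store(dup), class = "pheno_parse_error")
})

test_that("older files missing optional fields load with documented defaults", {
  fx <- store_with_character()
  path <- withr::local_tempfile(fileext = ".json")
  save_store(fx$store, path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  raw$terms <- lapply(raw$terms, function(t) { t$annotation <- NULL; t })
  raw$characters <- lapply(raw$characters, function(ch) { ch$illustrations <- NULL; ch })
  old <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, old, auto_unbox = FALSE, na = "null", null = "null")
  st2 <- load_store(old)
  expect_identical(st2$terms[[1]]$annotation, "")
  expect_identical(st2$characters[[1]]$illustrations, character(0))
})

test_that("OBO and Turtle exports carry stanzas, hierarchy and equivalence", {
  fx <- store_with_character()
  st <- fx$store
  clone <- clone_and_enhance(fx$character$id, NULL, "bob", st)
  obo <- withr::local_tempfile(fileext = ".obo")
  export_obo(st, obo)
  lines <- readLines(obo)
  expect_true(any(lines == "format-version: 1.4"))
  expect_true(any(lines == paste0("id: ", fx$character$id)))
  expect_true(any(grepl("^equivalent_to: ", lines)))
  expect_true(any(grepl("^is_a: ", lines)))
  ttl <- withr::local_tempfile(fileext = ".ttl")
  export_ttl(st, ttl)
  tl <- readLines(ttl)
  expect_true(any(grepl("owl:equivalentClass", tl)))
  expect_true(any(grepl("rdfs:subClassOf", tl)))
})
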