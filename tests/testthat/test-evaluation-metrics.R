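defs_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(participant = r[[1]], task = "T1", session = r[[2]],
               from = r[[3]], to = r[[4]], include = r[[5]],
               exclude = r[[6]], at = r[[7]], stringsAsFactors = FALSE)
  }))
}

test_that("normalize_words lowercases, strips numbers/punctuation/stopwords, idempotently", {
  expect_identical(normalize_words("end of perigynium wings"),
                   c("end", "perigynium", "wings"))
  expect_identical(normalize_words("2 to 3 mm!"), "mm")
  expect_identical(normalize_words(""), character(0))
  expect_identical(normalize_words("The APEX, of the Beak."), c("apex", "beak"))
  # order-preserving
  expect_identical(normalize_words("wings then beak then wings"),
                   c("wings", "then", "beak", "then", "wings"))
  set.seed(3)
  for (i in 1:200) {
    x <- random_text()
    once <- normalize_words(x)
    expect_identical(normalize_words(paste(once, collapse = " ")), once)
  }
})

test_that("unique word and definition counts match brute-force set oracles", {
  recs <- defs_df(
    list("p1", "paper", "base of leaf", "apex of leaf", "", "", ""),
    list("p2", "paper", "Base of the leaf!", "apex of leaf", "", "", ""),
    list("p3", "paper", "bottom of blade", "very tip", "", "", ""),
    list("p1", "machine", "base of leaf", "apex of leaf", "", "", ""),
    list("p2", "machine", "base of leaf", "apex of leaf", "", "", "")
  )
  # brute-force oracle: normalize every field by hand rules and union
  oracle_words <- function(session) {
    sub <- recs[recs$session == session, ]
    words <- unlist(lapply(c("from", "to", "include", "exclude", "at"),
                           function(f) normalize_words(sub[[f]])))
    length(unique(words))
  }
  expect_identical(unique_word_count(recs, "paper"), oracle_words("paper"))
  expect_identical(unique_word_count(recs, "machine"), 3L)  # base, leaf, apex
  expect_identical(unique_word_count(recs, "paper"), 7L)

  # records identical after normalization collapse to one definition
  expect_identical(unique_definition_count(recs, "machine"), 1L)
  # p1/p2 paper differ only in stopwords/punctuation -> same key
  expect_identical(unique_definition_count(recs, "paper"), 2L)
  # disjoint vocabularies: counts add
  a <- defs_df(list("p1", "s", "alpha beta", "", "", "", ""))
  b <- defs_df(list("p2", "s", "gamma delta", "", "", "", ""))
  both <- rbind(a, b)
  expect_identical(unique_word_count(both, "s"),
                   unique_word_count(a, "s") + unique_word_count(b, "s"))
  # per-field counting is offered behind a flag
  expect_identical(unique_definition_count(recs, "machine", per_field = TRUE), 2L)
})

test_that("reduction_percent rounds half away from zero and guards zero baselines", {
  expect_identical(reduction_percent(118, 89), 25L)
  expect_identical(reduction_percent(122, 64), 48L)
  expect_identical(reduction_percent(50, 50), 0L)
  expect_identical(reduction_percent(10, 0), 100L)
  expect_error(reduction_percent(0, 5), class = "pheno_validation_error")
})

test_that("likert_stats reports mean, sample sd and agree percentage", {
  s <- likert_stats(c(5, 5, 5, 5))
  expect_identical(s$mean, 5)
  expect_identical(s$sd, 0)
  expect_identical(s$agree_percent, 100L)

  s2 <- likert_stats(c(5, 5, 4, 3, 1))
  expect_equal(s2$mean, 3.6)
  expect_equal(s2$sd, sqrt(2.8))   # hand-computed n-1 variance
  expect_identical(s2$agree_percent, 60L)

  s3 <- likert_stats(3)
  expect_identical(s3$mean, 3)
  expect_identical(s3$agree_percent, 0L)
  expect_error(likert_stats(integer(0)), class = "pheno_validation_error")
  expect_error(likert_stats(c(2, 6)), class = "pheno_validation_error")
})

test_that("influence_strength is the 3/2/1/0 weighted sum and linear in counts", {
  expect_identical(influence_strength(15, 6, 2, 0), 59)
  expect_identical(influence_strength(0, 5, 4, 14), 14)
  expect_identical(influence_strength(0, 0, 0, 17), 0)
  # accepts a row/list form
  expect_identical(influence_strength(list(strong = 7, some = 7, weak = 1, none = 8)), 36)
  set.seed(5)
  for (i in 1:20) {
    a <- sample(0:20, 4); b <- sample(0:20, 4)
    expect_identical(influence_strength(a + b),
                     influence_strength(a) + influence_strength(b))
  }
  expect_error(influence_strength(-1, 0, 0, 0), class = "pheno_validation_error")
})

test_that("error_rate rounds half away from zero; complements sum to ~100", {
  expect_identical(error_rate(29, 52), 56L)
  expect_identical(error_rate(9, 21), 43L)
  expect_identical(error_rate(0, 10), 0L)
  expect_error(error_rate(1, 0), class = "pheno_validation_error")
  set.seed(6)
  for (i in 1:50) {
    t <- sample(1:200, 1); w <- sample(0:t, 1)
    expect_true((error_rate(w, t) + error_rate(t - w, t)) %in% 99:101)
  }
})

test_that("aggregate_errors filters, validates and discounts unit-only errors", {
  recs <- data.frame(
    participant = sprintf("p%d", 1:6),
    task = c("T1", "T1", "T2", "T2", "T3", "T3"),
    method = c("use_this", "create_new", "clone_enhance", "use_this",
               "clone_enhance", "create_new"),
    outcome = c("error", "correct", "error", "error", "error", "correct"),
    categories = c("u", "", "d", "du", "u", ""),
    stringsAsFactors = FALSE)
  expect_identical(aggregate_errors(recs), 4L)
  expect_identical(aggregate_errors(recs, exclude_unit_only = TRUE), 2L)  # du kept
  expect_identical(aggregate_errors(recs, task = "T2"), 2L)
  expect_identical(aggregate_errors(recs, method = "use_this"), 2L)
  expect_identical(aggregate_errors(recs[0, ]), 0L)
  bad <- recs; bad$categories[1] <- ""
  expect_error(aggregate_errors(bad), class = "pheno_validation_error")
})
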