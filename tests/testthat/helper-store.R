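# Small in-code fixtures shared across test files.

# Minimal store with a handful of anatomy terms.
tiny_store <- function(labels = c("perigynium", "beak", "leaf", "apex", "base")) {
  st <- pheno_store()
  for (lab in labels) add_term(lab, creator = "test", store = st)
  st
}

# A store with one saved character ready for reuse tests.
store_with_character <- function() {
  st <- tiny_store(c("leaf", "apex", "base", "tip"))
  ch <- create_character(
    "length of leaf",
    pheno_method(from = "base of leaf", to = "apex of leaf"),
    unit = "mm", creator = "alice", store = st)
  list(store = st, character = ch)
}

# Random accepted character names for grammar fixed-point checks.
random_name <- function() {
  qualities <- c("length", "width", "distance", "depth", "angle", "screen size")
  structures <- c("leaf", "perigynium beak", "lowest scale", "pupils",
                  "inflorescence", "culm base")
  if (stats::runif(1) < 0.5) {
    paste(sample(qualities, 1), "of", sample(structures, 1))
  } else if (stats::runif(1) < 0.5) {
    paste(sample(qualities, 1), "between", sample(structures, 1))
  } else {
    paste(sample(qualities, 1), "between", sample(structures, 1),
          "and", sample(structures, 1))
  }
}

# Random noisy text for normalization properties.
random_text <- function() {
  pool <- c("Perigynium", "BEAK", "2", "3.5", "mm!", "of", "the", "to",
            "apex,", "wing;", "scale", "(teeth)", "a", "42", "leaf.")
  paste(sample(pool, sample(1:12, 1), replace = TRUE), collapse = " ")
}
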