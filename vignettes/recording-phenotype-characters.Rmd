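---
title: "Recording continuous phenotype characters against a living ontology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recording continuous phenotype characters against a living ontology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenochar)
```

## The model

A narrative measurement such as "perigynium beak 2 to 3 mm" leaves the
essential information implicit: which quality is measured, and between
which anatomical landmarks. When such descriptions are ontologized
after publication, independent curators routinely produce different
formal translations of the same sentence. `phenochar` models the
alternative: semantics are captured *while recording*, and the
ontology grows under author control.

The data model has four layers.

**Terms.** An ontology entry with a permanent identifier
(`CAREX:` + seven digits), a label, a verbal definition, a sample
sentence, a taxon example, a parent class and an active/deprecated
status. Three classes are seeded: an *anatomic structure* root
(annotated equivalent to the external anatomical-entity class), a
*perceived quality* root (annotated as a subclass of the external
quality class) and a *new additions* holding class where
author-contributed terms land before an ontology engineer re-files
them. Identifiers are never reused; deprecation retains the id and all
axioms so that historical data stays resolvable.

**Characters.** A continuous character couples a name in the
controlled grammar `<quality> of|between <structure(s)>` with a
five-field landmark method (*from*, *to*, *include*, *exclude*, *at*),
a unit, an ordered creator list, a usage count and an append-only
history. The quality-first grammar is enforced ("length of leaf", not
"leaf length") because the noun-phrase-first form hides which token is
the quality. Characters sit under the perceived-quality root and are
linked to the structure terms their name mentions.

**Reuse semantics.** Adopting a character verbatim increments its
usage count by exactly one; the count is an evidence signal for which
definitions a community is converging on. Enhancing a character clones
it: the clone is a *new* character with a fresh id and usage 1,
recorded as an OWL `equivalentClass` of its source (both should denote
the same measurement) with creatorship shared between the source's
creators and the enhancing user. Equivalence is used instead of
synonym annotations because it is a formal construct usable in
reasoning. The source is untouched apart from a cross-reference event;
in particular its usage count does not move, since the clone — not the
source — is what the enhancing user adopted. Chains of enhancements
can drift semantically; the package records the provenance needed to
audit drift but makes no attempt to detect it.

**Measurements.** A table column can only reference a saved, active
character — this is the package's defining precondition, the thing
that distinguishes it from a spreadsheet. Cells are single finite
numbers in the character's unit with per-entry provenance; ranges and
qualifiers are out of scope (they belong to categorical-character
tooling).

## The semantic check

`semantic_check()` tokenizes each method field (lowercase, punctuation
stripped, pure-number tokens dropped) and classifies every token as a
stopword, a known active term label, or *new*. Saving is refused while
new words remain; `register_new_terms()` adds them (with definitions)
under the new-additions class, after which a re-check of the same
method is clean — an idempotence property the test suite enforces.

Matching is exact on case-folded single-word labels. Plural forms are
distinct labels ("wing" vs. "wings"): stemming would silently merge
anatomically distinct terms, so the vocabulary carries both where both
occur. The stopword list is deliberately small —
`r paste(default_stopwords(), collapse = ", ")` — configurable per
store and recorded in its serialization, because every additional
stopword risks swallowing a content word.

## Parameters that matter

- **Unit vocabulary** (`default_units()`): `mm, cm, m, µm, count,
  ratio, degree`. Saving without a unit is refused outright — the
  studied prototype showed unit omission and unit mismatch to be the
  dominant *design-caused* error class, and the redesign made unit
  confirmation mandatory. Length-like units and counts reject negative
  values; `degree` admits them.
- **Duplicate-name policy**: saving a character whose canonical name
  matches an active character is refused with a reuse suggestion
  listing the matches with creators and usage counts; `force = TRUE`
  overrides, since homonymous characters measured differently are
  legitimate (the preloaded "length of perigynium beak" variants are
  exactly that).
- **Search ranking**: token containment (every content token of the
  query must appear in the name), ordered by usage count descending,
  then name, then id. Usage-first ranking is a design choice: the UI
  this models shows usage prominently as the reuse signal. No fuzzy
  matching — a near-miss should be an explicit clone, not a silent hit.
- **Illustration-only characters**: a saved character needs a
  non-empty method *or* at least one illustration reference. Requiring
  a method always would make illustration-only definitions — which the
  studied material contains — unrepresentable; requiring neither would
  gut the semantic contract.

## Serialization

The canonical store file is a single pretty-printed UTF-8 JSON
document rebuilt field-by-field on load (no vector simplification), so
`load_store(save_store(s))` is the identity including counters, axioms
and logs — a property tested over seeded random stores. Files from
older minor schemas with missing optional fields load with documented
defaults (empty `annotation`, empty `illustrations`). OBO 1.4 and
Turtle are one-way exports for interoperability; there is no OBO
import and no description-logic reasoning.

## The fixture generator

`make_fixture()` rebuilds the studied configurations rather than
random data, because the interesting behaviors (ranking, distractors,
unit mismatch) are structural:

- The **shared** profile seeds 27 Carex structure/landmark terms and
  six preloaded characters: two "length of inflorescence" definitions
  (one by a recognizable expert, used 20 times, with matching text
  definition and unit; one by a made-up creator, used twice), a "width
  of inflorescence" whose unit deliberately mismatches a mm task, two
  illustration-only "length of perigynium beak" distractors (one with
  a second, misleading illustration) and a text-defined "length of
  winged perigynium beak" measured from the end of the perigynium
  wings to the summit of the perigynium, including the beak teeth.
  Usage counts are built honestly, by replaying `use_this()`, so the
  usage-equals-one-plus-used-events invariant holds in fixtures too.
- The **individual** profile seeds everyday-task terms and three
  illustration-only "length of leaf" entries (one matching).
- Optional synthetic filler terms/characters (clearly placeholder
  labels, no nomenclatural claims) support stress and property tests.

All fixture timestamps come from a fixed clock, so the same
`(seed, profile)` yields a byte-identical store file.

What the fixtures do **not** emulate: real participant behavior, task
timing, free-text variability of real users, or illustration content
(images are opaque string references). Tests passing on fixtures
therefore demonstrate the mechanics and arithmetic of the system, not
usability claims about human users.

## Evaluation metrics

`make_experiment_tables()` regenerates record-level CSVs whose
marginal counts equal the published evaluation accounting of the
studied prototype (the raw participant logs were never published):
machine-session error records reproducing every printed
method-by-task cell for the nonexpert (13 participants) and expert
(19 participants) groups, paper-session error records with the printed
per-task wrong-character counts, and the influence-factor response
counts. The printed nonexpert machine-session table enumerates 51
records rather than the 52 implied by 13 participants × 4 tasks; the
generator reproduces the printed cells as-is. Definition records and
Likert responses are synthetic (seeded) illustrations of convergence
and survey scoring; their unique-word counts are *not* calibrated to
the published 118/89/122/64 figures, because the exact stopword list
behind those counts is unrecoverable — only the derived percentages
are reproduced, from the published counts themselves.

Scoring rules, each chosen to match the published arithmetic exactly:

- `reduction_percent(before, after)` = round-half-away
  `((before − after)/before × 100)`; half-away rounding (not banker's)
  is required to reproduce printed values such as 87.5 → 88 and
  93.75 → 94, and is applied to every integer percentage the package
  prints.
- `likert_stats()` scores strongly-agree = 5 … strongly-disagree = 1,
  reports mean, *sample* (n−1) standard deviation (the conventional
  survey choice; the source material does not state its divisor) and
  the share of responses ≥ 4.
- `influence_strength()` = 3·strong + 2·some + 1·weak + 0·none, linear
  in its counts.
- `aggregate_errors()` counts error records under filters; with
  `exclude_unit_only = TRUE` it discounts records whose only category
  is the wrong unit (`"u"`), the accounting used to ask how many
  errors would survive the unit-confirmation redesign. Records with
  both categories (`"du"`) are *not* discounted.
- Definition identity for `unique_definition_count()` is the 5-field
  tuple of normalized texts. Whether the original analysis counted
  per-tuple or per-field is not stated; per-tuple is the default
  (a definition is the whole method) and per-field counting is
  available behind `per_field = TRUE`.

## Numerical and degenerate-input choices

- Ties in search order break by name then id, making search a pure
  function of `(query, store)`.
- `reduction_percent` and `error_rate` refuse zero baselines rather
  than returning NaN.
- Empty methods check clean (`all_known` is vacuously true); empty
  registration of an empty new-word set is a no-op.
- Measurement overwrites keep the prior entries; the current value is
  the latest entry. Missing cells export as empty CSV fields, never 0.
- Store mutation uses an environment-backed object (reference
  semantics): operations like `add_term()` both mutate the store and
  return the entity, matching how a persistent service behaves.
  Measurement tables, by contrast, are plain values returned from each
  operation.

## Problem sizes in the test suite

Property suites run on: 100 seeded fixture stores (id monotonicity and
JSON roundtrip), 20 random axiom graphs of 20 nodes with up to 25
equivalence axioms cross-checked against independent
connected-components computation, 10 random 30-step reuse/clone
sequences, 300 grammar fixed-point cases and 1000 normalization
idempotence cases. These sizes exercise every code path while keeping
the suite fast on a single CPU; the invariants are size-free, so
larger runs add confidence only marginally.

## Known limitations

- No description-logic reasoning, conflict detection, or remote
  ontology resolution; external anchors are annotation strings.
- Label matching is exact (case-folded); no stemming, no synonym
  expansion, no fuzzy search.
- Concept drift across clone-and-enhance chains is recorded but not
  detected or prevented.
- Specimen ids are opaque strings; there is no specimen metadata
  model.
- The CLI persists measurement tables as wide CSV, which drops
  per-entry provenance between invocations; programmatic use keeps it.
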