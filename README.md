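# phenochar

Ontology-aware recording of continuous phenotype characters.

## The problem

Published plant descriptions such as "perigynium beak 2 to 3 mm" are not
computable: nothing states which landmarks the measurement runs between,
so independent curators translating the same description into ontology
terms disagree with each other (and with the author). `phenochar`
attacks the problem at recording time instead of at curation time: a
continuous character must be *defined and saved in a phenotype
ontology* before any measurement can be recorded against it, and
authors extend the ontology themselves as they work.

The package targets biodiversity informaticians and taxonomists working
with measurement characters (the running examples are *Carex*
morphology), and implements:

- **An ontology store** seeded with an anatomic-structure root
  (annotated equivalent to `UBERON:0001062` *anatomical entity*), a
  perceived-quality root (subclass of `PATO:0000001` *quality*) and a
  *new additions* holding class. Author-contributed terms receive
  permanent `CAREX:`-style identifiers immediately, carry a verbal
  definition, sample sentence and taxon example, and can later be
  re-filed, deprecated or linked by OWL-style `equivalentClass` axioms
  by an ontology engineer. JSON is the canonical format; OBO 1.4 and
  Turtle are one-way exports.
- **A character lifecycle**: names must follow the controlled grammar
  `<quality> of|between <structure(s)>` ("length of leaf" is accepted,
  "leaf length" is not); methods are five landmark fields
  (from/to/include/exclude/at); a semantic check classifies every
  content word as known / new / stopword and new words must be
  registered before saving; saving requires a unit. Characters can be
  reused verbatim (`use_this()`, usage count +1) or cloned and enhanced
  (`clone_and_enhance()`: a new character, equivalent to its source,
  with shared creatorship).
- **Search** ranked by usage count, with tooltip previews (method text,
  else an illustration reference).
- **A measurement table** that only accepts columns backed by saved
  characters, with per-cell provenance and wide/long CSV interchange.
- **Evaluation metrics** for studies of such recorders: definition
  convergence (unique content words and unique normalized 5-field
  definitions, percent reduction), five-point Likert scoring (mean,
  sample SD, agree %), weighted influence strength
  (3·strong + 2·some + 1·weak + 0·none), and error accounting over
  wrong-definition (`d`) / wrong-unit (`u`) categories.
- **Seeded fixtures** emulating the studied configurations, and a
  CLI (`inst/scripts/phenochar`) over all of it.

## Worked example

```r
library(phenochar)

fx <- make_fixture("shared", seed = 1)   # Carex-like ontology, 6 preloaded characters
st <- fx$store

search_characters("length of inflorescence", st)
#>    character_id                    name   creators usage_count
#> 1 CAREX:0000037 length of inflorescence Bruce Ford          20
#> 2 CAREX:0000038 length of inflorescence   Yin Ming           2
#>                                                     preview
#> 1 From: insertion of lowest scale To: apex of inflorescence
#> 2       From: base of lowest spike To: tip of inflorescence
```

The best-established definition (used 20 times) surfaces first. Enhance
it, record three specimens, and round-trip the table:

```r
top <- search_characters("length of inflorescence", st)$character_id[1]
clone <- clone_and_enhance(
  top,
  pheno_method(from = "insertion of lowest scale",
               to = "apex of inflorescence", exclude = "stem"),
  actor = "es03", store = st)
clone$creators
#> [1] "Bruce Ford" "es03"
equivalence_class(top, st)
#> [1] "CAREX:0000037" "CAREX:0000043"

tab <- add_column(fx$table, clone$id, st)
tab <- record_value(tab, "S1", clone$id, 2.5, st, actor = "es03")
table_values(tab)
#>   specimen CAREX:0000043
#> 1       S1           2.5
```

The clone is a new character with a fresh permanent id, shares
creatorship with the original author, and is recorded as an OWL-style
equivalent class of its source; the measurement is stored in the
character's unit (mm) with provenance.

Evaluation metrics work on plain data frames:

```r
influence_strength(15, 6, 2, 0)   # 59  (3/2/1/0-weighted response counts)
reduction_percent(122, 64)        # 48  (percent fewer unique definitions)
error_rate(29, 52)                # 56  (integer percent, half away from zero)
```

## CLI

```sh
Rscript inst/scripts/phenochar init --store store.json --profile shared --seed 1
Rscript inst/scripts/phenochar search "length of inflorescence" --store store.json
Rscript inst/scripts/phenochar define --store store.json --name "length of ligule" \
    --from "base of ligule" --to "apex of ligule" --unit mm --creator you
Rscript inst/scripts/phenochar analyze errors --records machine_errors.csv --group NS
```

Exit codes: 0 success, 2 validation error, 3 I/O error.
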