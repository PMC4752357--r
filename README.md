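# muscleLogic

Anatomy-ontology reasoning and ontology-expanded literature search, built
around the mammalian feeding muscles.

Comparative anatomists define muscles by their attachments and
innervation: the styloglossus is *the* muscle innervated by the
hypoglossal nerve and attached to the stylohyal bone and the tongue.
`muscleLogic` makes that definition computable. It provides:

* **An ontology data model** — classes with labels, synonyms and xrefs;
  object properties (with transitivity and a property hierarchy); subclass
  axioms, general class inclusions (GCIs), and necessary-and-sufficient
  equivalence definitions — with a deterministic OBO-dialect flat-file
  reader/writer (`read_obo()` / `write_obo()`).
* **An EL reasoner** (`classify()`): axioms are normalized into the four
  EL normal forms (A ⊑ B, A₁ ⊓ A₂ ⊑ B, A ⊑ ∃r.B, ∃r.A ⊑ B) and saturated
  with completion rules to the least fixpoint of the subsumer sets S(·)
  and role-pair sets R(·), including role transitivity and the property
  hierarchy. Subsumption in this fragment is polynomial, every inference
  is recorded, and `explain()` returns a derivation that `replay_trace()`
  re-checks independently.
* **A DL query engine** (`answer()`): Protégé-style query strings such as
  `'muscle organ' and ('attached to' some 'mandible')` are parsed against
  labels *and synonyms* and answered from the saturation.
* **A pre-reasoned closure exporter** (`export_closure()`): materializes
  the full subclass closure and the closures along selected transitive
  properties (e.g. `part_of`) with asserted/inferred provenance flags, for
  databases that have no reasoner of their own.
* **A fixture ontology** (`build_fixture()`): the published subset of the
  feeding-muscle ontology — 50 classes, 100 axioms, all evidence-tagged in
  `fixture_manifest()` — including the trigeminal-innervation grouping and
  the innervation⇒branchial-arch GCIs.
* **Semantic text search** (`build_lexicon()`, `index_corpus()`,
  `search_corpus()`): Textpresso-style category search in which a query
  for a muscle category automatically matches every label and synonym of
  every class the reasoner classified under it, plus a seeded synthetic
  corpus generator (`generate_corpus()`) and a keyword-vs-semantic
  benchmark (`compare_engines()`).

## Worked example

```r
library(muscleLogic)

ont <- build_fixture()
ont
#> <ontology> feeding-muscle-fixture: 50 classes, 4 properties, 100 axioms (6 equivalence definitions)

sat <- classify(ont)
sat
#> <saturation> 50 classes, 158 subsumptions, 100 role pairs, 14 fresh names

res <- answer("'muscle organ' and ('attached to' some 'mandible')", ont, sat)
res
#> <query_result> 0 equivalents, 26 descendants (26 direct)
head(label_of(ont, res$descendants), 5)
#> [1] "Anterior digastric muscle"         "Buccinator muscle"
#> [3] "Depressor anguli oris muscle"      "Depressor labii inferioris muscle"
#> [5] "Eutherian genioglossus muscle"
```

The 26 descendants are the muscles *entailed* to attach to the mandible
(the 25 published ones plus the transversus mandibulae, whose attachment
the published conjunction list asserts — see the vignette for this
documented discrepancy). Synonyms resolve to the same class, so the same
query phrased with `'external pterygoid muscle'` instead of `'lateral
pterygoid muscle'` returns identical results.

Inference, with an auditable derivation — "epiphysis of digit" is
classified under "epiphysis of hand" purely from `part_of` transitivity
and the two compound definitions:

```r
tr <- explain(sat, resolve_label(ont, "epiphysis of digit"),
              resolve_label(ont, "epiphysis of hand"))
tr
#> derivation of MFMO:0000542 SubClassOf MFMO:0000543
#>    1. [init] S MFMO:0000542 MFMO:0000542  <=  (axiomatic)
#>    ...
#>    5. [R5  ] R BFO:0000050 MFMO:0000542 MFMO:0000540  <=  ...
#>    9. [R2  ] S MFMO:0000542 MFMO:0000543  <=  ...
replay_trace(tr, sat$normal_axioms, ont$properties)
#> [1] TRUE
```

Semantic versus keyword retrieval on a generated corpus:

```r
docs <- generate_corpus(
  corpus_spec(40, 20, 0.5, "Lateral pterygoid muscle", seed = 1), ont, sat)
idx <- index_corpus(docs, build_lexicon(ont, sat, "Lateral pterygoid muscle"))
compare_engines(idx, list(list(keywords = "mastication",
                               category = "lateral pterygoid muscle")))
#>                                         query     mode tp fp fn precision recall
#> 1 mastication + lateral pterygoid muscle  keyword 19  0 21         1  0.475
#> 2 mastication + lateral pterygoid muscle semantic 40  0  0         1  1.000
```

Keyword search only finds the documents that used the literal label;
semantic search also retrieves every synonym mention — recall 1.0 against
the generator's ground truth.

A thin command-line wrapper is installed under `exec/`:

```sh
muscle-logic fixture --out mfmo_subset.obo
muscle-logic query mfmo_subset.obo "'muscle organ' and ('attached to' some 'mandible')" --json
muscle-logic closure mfmo_subset.obo --props part_of --format tsv --out closure.tsv
```

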