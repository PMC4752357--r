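---
title: "Logic-based anatomy: reasoning and semantic search over the feeding muscles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logic-based anatomy: reasoning and semantic search over the feeding muscles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscleLogic)
```

## The problem

Comparative anatomists identify muscles by their attachments and
innervation: the anterior digastric and the geniohyoid both run from the
mandible to the hyoid, but one is supplied by a branch of the trigeminal
nerve and the other by the first cervical nerve.  When this knowledge is
written down only as free text, search engines cannot use it: a literal
query for "muscle innervated by the trigeminal nerve" will not retrieve a
study of the temporalis muscle, even though the temporalis *is* such a
muscle, and a query for the "lateral pterygoid muscle" will miss every
paper that calls it the "external pterygoid muscle".

`muscleLogic` implements the computational machinery that turns this
anatomical knowledge into something a machine can reason with:

1. an ontology data model with *logical definitions* of muscles
   (`ontology_model`: `ontology()`, `read_obo()`, `write_obo()`,
   `resolve_label()`);
2. a polynomial-time reasoner for the EL fragment of description logic
   (`classify()`, `explain()`);
3. a Protégé-style DL query engine (`parse_query()`, `answer()`);
4. a pre-reasoned closure exporter for databases without a reasoner
   (`export_closure()`, `write_closure()`);
5. a fixture ontology of the mammalian feeding muscles
   (`build_fixture()`, `fixture_manifest()`); and
6. a Textpresso-style semantic search over plain-text corpora, with a
   synthetic corpus generator for benchmarking (`build_lexicon()`,
   `index_corpus()`, `search_corpus()`, `generate_corpus()`,
   `compare_engines()`).

## Logical definitions

Every muscle class can carry a necessary-and-sufficient definition of the
form

```
innervated_by some <nerve>
attached_to  some <entity A>
attached_to  some <entity B>
```

For the styloglossus (MFMO:0000066) the definition is: innervated by the
hypoglossal nerve, attached to the stylohyal bone, attached to the
tongue.  Because the definition is sufficient as well as necessary, a
reasoner can *classify* muscles: any class entailed to satisfy the three
restrictions is a styloglossus.  The same mechanism builds the
comparative-anatomy groupings automatically — 'Trigeminal muscle' is
defined as `'muscle organ' and ('innervated by' some 'trigeminal
nerve')`, so every muscle asserted to have trigeminal innervation is
placed under it without any asserted `is_a` link.

Two *general class inclusions* (GCIs) encode the developmental rule that
innervation determines branchial-arch origin:

```
('innervated by' some 'trigeminal nerve') SubClassOf ('develops from' some 'branchial arch 1')
('innervated by' some 'facial nerve')     SubClassOf ('develops from' some 'branchial arch 2')
```

From these the reasoner infers, e.g., that the posterior digastric
muscle develops from the second arch, because it is innervated by the
facial nerve — no arch assertion exists anywhere in the ontology.

## The reasoner

The expression language is deliberately restricted to the EL fragment:
named classes, conjunction, and existential restriction (no negation,
disjunction, universal quantification or cardinality).  Everything the
anatomy use-cases need fits in this fragment, and within it subsumption
is decidable in polynomial time.

`normalize()` rewrites all axioms into four normal forms over named
classes (`A ⊑ B`, `A1 ⊓ A2 ⊑ B`, `A ⊑ ∃r.B`, `∃r.A ⊑ B`), introducing
deterministically numbered fresh names (`_:NF000001`, ...) for complex
sub-expressions; the rewriting is polarity-aware, so entailments over the
original classes are preserved exactly.  `saturate()` then computes the
least fixpoint of six completion rules over per-class subsumer sets
S(·) and per-property role-pair sets R(·): the four structural rules
matching the normal forms, a transitivity rule for properties flagged
transitive (`part_of`), and a property-hierarchy rule.  The fixpoint is
unique and independent of rule-application order; the worklist schedule
is purely a performance choice.  At most $n^2$ subsumptions and
$p \cdot n^2$ role pairs exist for $n$ names and $p$ properties and each
is processed once against indexed axioms, so saturation is polynomial in
classes × axioms.

Design choices worth recording:

* **⊤ is implicit, ⊥ absent.**  Every class has `owl:Thing` as a
  subsumer; there is no disjointness or negation, so inconsistency cannot
  arise and "unsatisfiable class" is not a concept the engine needs.
* **Cycles are equivalence groups.**  Mutually subsuming classes are
  reported as one equivalence group (standard DL semantics), never as an
  error.
* **Fresh names never leak.**  Reported subsumer sets, role pairs and
  query answers are restricted to the ontology's declared classes.
* **Every inference is auditable.**  Each addition records the rule and
  premises that produced it; `explain()` returns a well-founded
  derivation and `replay_trace()` re-checks it step by step against the
  rule schemata, independently of the engine's bookkeeping.

The test suite checks the engine against a deliberately naive
brute-force oracle (full passes over all axioms and classes until
stable, no indexing, no worklist) on hundreds of seeded random
ontologies, plus monotonicity (adding an axiom never removes an
entailment) and idempotence (classifying a materialized closure changes
nothing) property suites.

## DL queries and the published answer lists

`answer()` evaluates a query expression by adding a throwaway defined
class `Q ≡ <query>`, re-saturating, and reading off `Q`'s equivalents
and strict subsumees; the base saturation is never modified, so
answering is purely functional.  Equivalents are reported separately
from descendants (the Protégé convention), but the published competency
lists do not distinguish the two, so comparisons use their union.

The fixture reproduces three published competency-question answer sets:
muscles attached to the mandible (25 printed classes), derivatives of
branchial arch 1 (20 printed classes, including the defined grouping
class itself — answered *purely by inference* through the arch GCI), and
their conjunction (16 printed classes).

The published lists are internally inconsistent in two places: the
conjunction list contains the transversus mandibulae muscle (a
trigeminal muscle attached to the mandible) which the attachment list
omits, and the conjunction list omits the mylohyoid muscle although it
appears in both single-restriction lists.  The fixture encodes the
attachments so that the *logically consistent* sets are returned: the
transversus mandibulae carries its attachment axiom, hence the
attachment query answers with 26 classes (the 25 printed plus the
transversus) and the conjunction query with 17 (the 16 printed plus the
mylohyoid).  The acceptance tests assert these two one-class deltas
exactly rather than forcing either printed list; forcing both printed
lists simultaneously is logically impossible once "mandible" and
"mandible bone" name one class, which the published query strings
themselves require.

Two further interpretation choices: 'Trigeminal muscle' is treated as a
returned class (it satisfies the arch-1 query), and "Masseter muscle,
pars reflexa" / "Superficial masseter, pars reflexa" are one class with
the second string as synonym, as are the two zygomaticomandibularis
spellings.  Published groupings by innervation are encoded as full
equivalence definitions, not merely necessary axioms — equivalence is
required for automatic subsumption of the member muscles, which the
published class hierarchy displays.

Indented "parts" in the published lists (e.g. the deep masseter under
the masseter) are `part_of` the whole **and** carry their own attachment
and innervation axioms.  Attachment deliberately does *not* propagate
across `part_of`: no such propagation rule is stated in the source
material, and the printed answers are reproduced without one.

## The closure exporter

Databases without reasoning import a *pre-reasoned* ontology: every
entailed `is_a` pair and every entailed pair along selected transitive
properties (typically `part_of`) materialized, each flagged `asserted`
or `inferred`.  Reflexive pairs are included by default (common loader
convention) and flaggable off.  The property closures materialize *all*
entailed existential pairs, a superset of asserted-plus-chaining, since
pairs can also arise through subsumption into defined classes.
Selecting a non-transitive property is an explicit configuration error
because closure semantics presume chaining.  TSV and flat-ontology
outputs are deterministically sorted; the flat output is a fixpoint
(re-reading and re-exporting is byte-identical).

## Semantic search and the corpus generator

A *category* is the bag of phrases — labels and synonyms — of a class
and everything classified under it; `build_lexicon()` derives it from a
saturation, so the category for 'Trigeminal muscle' contains "temporalis
muscle" because the reasoner put the temporalis there.  Indexing splits
sentences with a deterministic rule (terminator + whitespace + capital
or digit), case-folds, keeps intra-word hyphens, and tags phrases by
longest match over token n-grams with no overlaps.  No stemming is
applied and no ML sentence splitter is used: synonyms must be explicit
in the ontology, and every behaviour must be bit-exactly reproducible.
Ranking is by match count with ties broken by document id — nothing in
the source use-cases specifies a ranking, so the simplest deterministic
one is used.  Both sentence and document scope are provided and each
test fixes its scope explicitly.

The corpus generator emulates the one feature of real abstracts that
matters for this comparison: relevant documents mention a category
member under a randomly chosen name (label, or synonym with probability
`synonym_probability`) embedded in template sentences together with a
topical keyword, while distractors contain the query's individual words
("muscle", "innervated", "trigeminal", "nerve", the topic word) in
non-matching arrangements and never contain a lexicon phrase (enforced
by a construction-time check).  It does **not** emulate real prose
variability: inflection, hedging, OCR noise, cross-sentence coreference,
or mentions via descriptions rather than names.  Passing tests
therefore demonstrate the *logical* superiority of ontology-expanded
retrieval — semantic recall 1.0 by construction, keyword recall equal to
the literal-phrase fraction, and semantic match sets containing keyword
match sets — not performance on real literature.  Generation is
seed-deterministic; the benchmark sizes used by the tests and the
acceptance script (tens of relevant documents, tens of distractors) were
chosen as the smallest corpora at which the binomial label/synonym split
is comfortably visible.

## Degenerate inputs and numerical choices

There are no floating-point tolerances anywhere: every computation is
exact set manipulation, and all comparisons in the tests are identity or
set equality.  Empty ontologies classify to `S(A) = {A, ⊤}`; empty
corpora index to empty postings and search returns an empty result, not
an error.  Duplicate labels (after case-folding, whitespace collapsing
and typographic-quote normalization) are rejected at load; ambiguous
synonyms are an error at resolution time, and ambiguous lexicon phrases
an error at lexicon build.  Conjunctions are flattened and kept in a
canonical sorted order so expression equality is structural; file
output sorts stanzas by CURIE and fixes tag order, making serialization
deterministic and write∘read the identity.

## Problem sizes

The property suites run on seeded random ontologies of up to 30 classes
and 60 axioms (200 instances against the brute-force oracle), random
DAGs of up to 50 nodes for closure checks, 100 random ontologies for
file round trips, and generated corpora of 40–180 documents.  These
sizes were chosen so the naive oracle — which is intentionally
quadratic-to-cubic — remains the bottleneck, keeping the whole suite in
the low minutes on one core while exercising every rule combination the
fragment admits.

## Limitations

* EL only: no negation, disjunction, universal restriction, cardinality,
  role chains (beyond transitivity), nominals or datatypes; queries are
  conjunctive.
* The flat-file dialect is an OBO subset with two documented extensions
  (`[gci]` stanzas, `equivalent_to:` tags); it does not parse OWL/RDF.
* The fixture covers only the published subset of the feeding-muscle
  ontology, not the full muscle catalogue.
* The search module is a model of Textpresso-style category search, not
  a client for any deployed site; PDF conversion and web UI are out of
  scope.
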