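trig_lexicon <- function() {
  build_lexicon(fixture_ont(), fixture_sat(), "Trigeminal muscle")
}

test_that("a category lexicon contains labels and synonyms of every subsumee", {
  lex <- trig_lexicon()
  expect_true("temporalis muscle" %in% names(lex))
  expect_true("masseter muscle" %in% names(lex))
  expect_true("external pterygoid muscle" %in% names(lex))  # synonym
  expect_identical(unname(unclass(lex)["external pterygoid muscle"]),
                   resolve_label(fixture_ont(), "Lateral pterygoid muscle"))
  # non-trigeminal muscles stay out
  expect_false("geniohyoid muscle" %in% names(lex))

  leaf <- build_lexicon(fixture_ont(), fixture_sat(),
                        "Lateral pterygoid muscle")
  expect_setequal(names(leaf), c("lateral pterygoid muscle",
                                 "external pterygoid muscle"))
  solo <- build_lexicon(fixture_ont(), fixture_sat(), "Mentalis muscle")
  expect_identical(names(solo), "mentalis muscle")
})

test_that("ambiguous phrases across classes abort the lexicon build", {
  cls <- list(ontology_class("EX:0000001", "root"),
              ontology_class("EX:0000002", "left child",
                             synonyms = "shared phrase"),
              ontology_class("EX:0000003", "right child",
                             synonyms = "shared phrase"))
  ont <- ontology(cls, list(), list(
    ax_subclass(ce_named("EX:0000002"), ce_named("EX:0000001")),
    ax_subclass(ce_named("EX:0000003"), ce_named("EX:0000001"))))
  expect_error(build_lexicon(ont, classify(ont), "root"),
               "ambiguous lexicon phrases.*shared phrase")
})

test_that("indexing tags synonym mentions with the class CURIE", {
  lex <- trig_lexicon()
  doc <- document("d1", "t",
                  "The external pterygoid was silent. The External Pterygoid Muscle fired during chewing.")
  idx <- index_corpus(list(doc), lex)
  expect_identical(unique(idx$tags$curie),
                   resolve_label(fixture_ont(), "Lateral pterygoid muscle"))
  expect_identical(nrow(idx$tags), 1L)  # first sentence lacks "muscle"
  none <- index_corpus(list(document("d2", "t", "Nothing anatomical here.")),
                       lex)
  expect_identical(nrow(none$tags), 0L)
})

test_that("longest match wins and spans re-extract to their phrases", {
  lex <- trig_lexicon()
  # "superficial masseter muscle" must not be tagged as "masseter muscle"
  doc <- document("d1", "t",
                  "Activity of the superficial masseter muscle preceded biting.")
  idx <- index_corpus(list(doc), lex)
  expect_identical(idx$tags$phrase, "superficial masseter muscle")
  span <- substr(idx$sentences$text[1], idx$tags$start, idx$tags$end)
  expect_identical(tolower(span), idx$tags$phrase)
})

test_that("every tag span in generated corpora matches its lexicon phrase", {
  ont <- fixture_ont()
  sat <- fixture_sat()
  lex <- trig_lexicon()
  docs <- generate_corpus(
    corpus_spec(120, 60, 0.5, "Trigeminal muscle", seed = 202), ont, sat)
  idx <- index_corpus(docs, lex)
  expect_gt(nrow(idx$tags), 0L)
  skey <- paste(idx$sentences$doc_id, idx$sentences$sentence)
  for (i in seq_len(nrow(idx$tags))) {
    row <- idx$tags[i, ]
    sent <- idx$sentences$text[skey == paste(row$doc_id, row$sentence)]
    span <- substr(sent, row$start, row$end)
    folded <- paste(tolower(strsplit(span, "[^[:alnum:]-]+")[[1]]),
                    collapse = " ")
    expect_identical(folded, row$phrase)
  }
})

test_that("semantic search finds subclass mentions that literal search misses", {
  ont <- fixture_ont()
  sat <- fixture_sat()
  lex <- trig_lexicon()
  hit <- document("herring", "Mastication and soft tissues",
                  "Dynamic strain near the temporalis muscle changed with mastication rate.")
  miss <- document("generic", "Surgical note",
                   "A muscle innervated by the trigeminal nerve may refer pain; mastication was not assessed in muscle tissue.")
  idx <- index_corpus(list(hit, miss), lex)
  sem <- search_corpus(idx, keywords = "mastication",
                       categories = "Trigeminal muscle",
                       mode = "semantic", scope = "document")
  expect_true("herring" %in% sem$doc_id)
  kw <- search_corpus(idx,
                      keywords = c("muscle innervated by the trigeminal nerve",
                                   "mastication"),
                      mode = "keyword", scope = "document")
  expect_false("herring" %in% kw$doc_id)
  expect_true("generic" %in% kw$doc_id)   # literal phrase, wrong document
})

test_that("searching an empty corpus or with an uncovered category behaves", {
  idx <- index_corpus(list(), trig_lexicon())
  res <- search_corpus(idx, keywords = "mastication", mode = "keyword")
  expect_identical(nrow(res), 0L)
  expect_error(search_corpus(idx, categories = "Geniohyoid muscle",
                             mode = "semantic"),
               "not covered")
  expect_error(search_corpus(idx), "at least one")
})

test_that("generated corpora are seed-deterministic with exact counts and labels", {
  ont <- fixture_ont()
  sat <- fixture_sat()
  spec <- corpus_spec(15, 10, 0.5, "Trigeminal muscle", seed = 33)
  d1 <- generate_corpus(spec, ont, sat)
  d2 <- generate_corpus(spec, ont, sat)
  expect_identical(d1, d2)
  expect_length(d1, 25L)
  rel <- d1[1:15]
  dis <- d1[16:25]
  expect_true(all(lengths(lapply(rel, `[[`, "truth_labels")) == 1L))
  expect_true(all(lengths(lapply(dis, `[[`, "truth_labels")) == 0L))
  # distractor-only corpora carry no truth labels at all
  d0 <- generate_corpus(corpus_spec(0, 5, 0, "Trigeminal muscle",
                                    seed = 1), ont, sat)
  expect_length(d0, 5L)
  expect_true(all(lengths(lapply(d0, `[[`, "truth_labels")) == 0L))
})

test_that("synonym mentions follow the requested probability; impossible requests error", {
  ont <- fixture_ont()
  sat <- fixture_sat()
  docs <- generate_corpus(
    corpus_spec(50, 0, 0.5, "Lateral pterygoid muscle", seed = 1),
    ont, sat)
  n_syn <- sum(vapply(docs, function(d) isTRUE(attr(d, "synonym_used")),
                      logical(1)))
  # Binomial(50, .5): central 99.9% mass
  expect_gt(n_syn, 10)
  expect_lt(n_syn, 40)
  expect_error(
    generate_corpus(corpus_spec(5, 0, 0.5, "Mentalis muscle", seed = 1),
                    ont, sat),
    "no class.*has synonyms")
})

test_that("JSON-lines corpora round-trip", {
  ont <- fixture_ont()
  sat <- fixture_sat()
  docs <- generate_corpus(corpus_spec(5, 5, 0.5, "Trigeminal muscle",
                                      seed = 9), ont, sat)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(docs, f)
  back <- read_corpus(f)
  expect_length(back, 10L)
  for (i in seq_along(docs)) {
    expect_identical(back[[i]]$doc_id, docs[[i]]$doc_id)
    expect_identical(back[[i]]$body, docs[[i]]$body)
    expect_identical(back[[i]]$truth_labels, docs[[i]]$truth_labels)
  }
})

test_that("semantic recall is total, keyword recall is the literal fraction, and matches nest", {
  ont <- fixture_ont()
  sat <- fixture_sat()
  spec <- corpus_spec(40, 20, 0.5, "Lateral pterygoid muscle",
                      topic_keyword = "mastication", seed = 77)
  docs <- generate_corpus(spec, ont, sat)
  lex <- build_lexicon(ont, sat, "Lateral pterygoid muscle")
  idx <- index_corpus(docs, lex)
  rep <- compare_engines(idx, list(
    list(keywords = "mastication", category = "lateral pterygoid muscle")))
  sem <- rep[rep$mode == "semantic", ]
  kw <- rep[rep$mode == "keyword", ]
  expect_identical(sem$recall, 1)
  literal_frac <- mean(vapply(docs[1:40], function(d) {
    identical(attr(d, "phrase_used"), "Lateral pterygoid muscle")
  }, logical(1)))
  expect_equal(kw$recall, literal_frac)
  # dominance: keyword matches are a subset of semantic matches
  kw_hits <- search_corpus(idx, keywords = "mastication",
                           categories = "lateral pterygoid muscle",
                           mode = "keyword", scope = "document")$doc_id
  sem_hits <- search_corpus(idx, keywords = "mastication",
                            categories = "lateral pterygoid muscle",
                            mode = "semantic", scope = "document")$doc_id
  expect_true(all(kw_hits %in% sem_hits))
})

test_that("all-synonym corpora give keyword recall 0 and semantic recall 1", {
  ont <- fixture_ont()
  sat <- fixture_sat()
  docs <- generate_corpus(
    corpus_spec(20, 10, 1, "Lateral pterygoid muscle", seed = 5),
    ont, sat)
  lex <- build_lexicon(ont, sat, "Lateral pterygoid muscle")
  idx <- index_corpus(docs, lex)
  rep <- compare_engines(idx, list(
    list(keywords = character(0), category = "lateral pterygoid muscle")))
  expect_identical(rep$recall[rep$mode == "semantic"], 1)
  expect_identical(rep$recall[rep$mode == "keyword"], 0)
})

test_that("querying a category by any of its phrases returns identical results", {
  ont <- fixture_ont()
  sat <- fixture_sat()
  docs <- generate_corpus(
    corpus_spec(20, 10, 0.5, "Lateral pterygoid muscle", seed = 11),
    ont, sat)
  idx <- index_corpus(docs, build_lexicon(ont, sat,
                                          "Lateral pterygoid muscle"))
  a <- search_corpus(idx, categories = "lateral pterygoid muscle",
                     mode = "semantic", scope = "document")
  b <- search_corpus(idx, categories = "external pterygoid muscle",
                     mode = "semantic", scope = "document")
  expect_identical(a, b)
})

test_that("sentence scope is stricter than document scope", {
  lex <- trig_lexicon()
  doc <- document("split", "t",
                  "The temporalis muscle was recorded. Mastication followed later.")
  idx <- index_corpus(list(doc), lex)
  sent <- search_corpus(idx, keywords = "mastication",
                        categories = "Trigeminal muscle",
                        mode = "semantic", scope = "sentence")
  docm <- search_corpus(idx, keywords = "mastication",
                        categories = "Trigeminal muscle",
                        mode = "semantic", scope = "document")
  expect_identical(nrow(sent), 0L)
  expect_identical(docm$doc_id, "split")
})

test_that("comparison without truth labels is a configuration error", {
  idx <- index_corpus(list(document("d", "t", "Plain body text.")),
                      trig_lexicon())
  expect_error(compare_engines(idx, list(list(keywords = "x",
                                              category = "Trigeminal muscle"))),
               "truth labels")
})
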