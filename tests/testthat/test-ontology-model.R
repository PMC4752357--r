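test_that("CURIE parsing and rendering round-trip", {
  cases <- c("MFMO:0000066", "RO:0002005", "BFO:0000050", "EX:1")
  parsed <- curie_parse(cases)
  expect_identical(curie(parsed$prefix, parsed$local_id), cases)
  expect_true(all(is_curie(cases)))
  expect_false(is_curie("not a curie"))
  expect_error(curie_parse("MFMO_0000066"), "not a CURIE")
  expect_identical(curie_from_purl(curie_to_purl("MFMO:0000066")),
                   "MFMO:0000066")
})

test_that("conjunctions canonicalize: flattened, sorted, deduplicated", {
  a <- ce_named("EX:0000001")
  b <- ce_named("EX:0000002")
  r <- ce_some("EP:0000001", ce_named("EX:0000003"))
  e1 <- ce_and(b, ce_and(r, a))
  e2 <- ce_and(a, b, r)
  expect_identical(e1, e2)
  expect_length(e1$conjuncts, 3L)
  expect_false(any(vapply(e1$conjuncts, inherits, logical(1), "ce_and")))
  # duplicate conjuncts collapse; single survivor is unwrapped
  expect_identical(ce_and(a, a), a)
})

test_that("class and synonym invariants are enforced at construction", {
  expect_error(ontology_class("EX:0000001", ""), "empty label")
  expect_error(ontology_class("EX:0000001", "m", synonyms = c("x", "x")),
               "duplicate synonyms")
  expect_error(ontology_class("EX:0000001", "m", synonyms = "M"),
               "own label")
})

test_that("ontology validation rejects dangling references and label clashes", {
  a <- ontology_class("EX:0000001", "alpha")
  b <- ontology_class("EX:0000002", "beta")
  expect_error(
    ontology(list(a), list(),
             list(ax_subclass(ce_named("EX:0000001"),
                              ce_named("EX:0000099")))),
    "undeclared classes.*EX:0000099")
  expect_error(
    ontology(list(a), list(),
             list(ax_subclass(ce_named("EX:0000001"),
                              ce_some("EP:0000001",
                                      ce_named("EX:0000001"))))),
    "undeclared properties")
  expect_error(
    ontology(list(a, ontology_class("EX:0000003", "Alpha")), list(),
             list()),
    "duplicate class labels")
  # mutating a valid container and re-validating catches the damage
  ont <- ontology(list(a, b), list(),
                  list(ax_subclass(ce_named("EX:0000001"),
                                   ce_named("EX:0000002"))))
  ont$classes[["EX:0000002"]] <- NULL
  expect_error(validate_ontology(ont), "undeclared classes")
})

test_that("property hierarchies must be acyclic", {
  p1 <- object_property("EP:0000001", "rel one",
                        parent_properties = "EP:0000002")
  p2 <- object_property("EP:0000002", "rel two",
                        parent_properties = "EP:0000001")
  expect_error(ontology(list(), list(p1, p2), list()), "cycle")
})

test_that("resolve_label matches CURIEs, labels and synonyms case-insensitively", {
  ont <- fixture_ont()
  lat <- resolve_label(ont, "Lateral pterygoid muscle")
  expect_identical(resolve_label(ont, "external pterygoid muscle"), lat)
  expect_identical(resolve_label(ont, "EXTERNAL  Pterygoid  Muscle"), lat)
  expect_identical(resolve_label(ont, lat), lat)
  expect_identical(resolve_label(ont, "mandible bone"),
                   resolve_label(ont, "mandible"))
  expect_error(resolve_label(ont, "no such muscle"), "unknown term")
})

test_that("an ambiguous synonym is reported with its candidates", {
  ont <- ontology(
    list(ontology_class("EX:0000001", "alpha", synonyms = "shared name"),
         ontology_class("EX:0000002", "beta", synonyms = "shared name")),
    list(), list())
  expect_error(resolve_label(ont, "shared name"),
               "ambiguous.*EX:0000001.*EX:0000002")
})

test_that("resolve_label is total over the fixture vocabulary and injective on labels", {
  ont <- fixture_ont()
  seen <- character(0)
  for (cl in ont$classes) {
    expect_identical(resolve_label(ont, cl$label), cl$id)
    expect_identical(resolve_label(ont, cl$id), cl$id)
    for (s in cl$synonyms) expect_identical(resolve_label(ont, s), cl$id)
    seen <- c(seen, cl$label)
  }
  expect_false(anyDuplicated(tolower(seen)) > 0)
})

test_that("property names resolve with space/underscore variants and synonyms", {
  ont <- fixture_ont()
  att <- resolve_property(ont, "attached to")
  expect_identical(resolve_property(ont, "attached_to"), att)
  expect_identical(resolve_property(ont, "attaches_to"), att)
  expect_error(resolve_property(ont, "glued to"), "unknown property")
})
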