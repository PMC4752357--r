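test_that("the query grammar parses names, existentials and conjunctions", {
  ont <- fixture_ont()
  q1 <- parse_query("'mandible'", ont)
  expect_identical(q1, ce_named(resolve_label(ont, "mandible")))

  q2 <- parse_query("'muscle organ' and ('attached to' some 'mandible')",
                    ont)
  expect_identical(q2$variant, "and")
  expect_length(q2$conjuncts, 2L)
  kinds <- sort(vapply(q2$conjuncts, `[[`, character(1), "variant"))
  expect_identical(kinds, c("named", "some"))

  q3 <- parse_query(paste(
    "'muscle organ' and ('innervated by' some 'trigeminal nerve')",
    "and ('attached_to' some 'mandible bone')"), ont)
  expect_length(q3$conjuncts, 3L)

  # typographic quotes, as they appear in print, are accepted
  q4 <- parse_query("‘muscle organ’ and (‘attached to’ some ‘mandible’)",
                    ont)
  expect_identical(q4, q2)
})

test_that("syntax and vocabulary errors are positioned and named", {
  ont <- fixture_ont()
  expect_error(parse_query("'muscle organ' and and 'mandible'", ont),
               "syntax error")
  expect_error(parse_query("('muscle organ'", ont), "expected '\\)'")
  expect_error(parse_query("'no such muscle'", ont), "unknown term")
})

test_that("the mandible-attachment query returns the attached muscles", {
  ont <- fixture_ont()
  res <- answer(query_mandible, ont, fixture_sat())
  expect_identical(res$equivalents, character(0))
  expected <- resolve_all(ont, c(published_mandible_muscles,
                                 "Transversus mandibulae muscle"))
  expect_identical(query_hits(res), expected)
})

test_that("the arch-1 query is answered purely by inference via the GCI", {
  ont <- fixture_ont()
  # no muscle carries a direct develops_from axiom
  direct_dev <- Filter(function(ax) {
    ax$variant == "subclass" && ax$sub$variant == "named" &&
      ax$sup$variant == "some" && ax$sup$property == "RO:0002202"
  }, ont$axioms)
  expect_length(direct_dev, 0L)
  res <- answer(query_arch1, ont, fixture_sat())
  expect_identical(query_hits(res),
                   resolve_all(ont, published_arch1_muscles))
  expect_true(resolve_label(ont, "Trigeminal muscle") %in% query_hits(res))
})

test_that("the conjunction query equals the set-algebra of its conjunct queries", {
  ont <- fixture_ont()
  sat <- fixture_sat()
  res_m <- query_hits(answer(query_mandible, ont, sat))
  res_a <- query_hits(answer(query_arch1, ont, sat))
  res_c <- query_hits(answer(query_trig_mandible, ont, sat))
  # brute-force oracle: intersect the single-restriction answers, minus
  # the grouping class itself (it lacks the attachment)
  expect_identical(res_c, sort(setdiff(intersect(res_m, res_a),
                                       resolve_label(ont, "Trigeminal muscle"))))
})

test_that("a class without subclasses answers with empty descendants", {
  ont <- fixture_ont()
  res <- answer("'Mentalis muscle'", ont, fixture_sat())
  expect_identical(res$descendants, character(0))
  expect_identical(res$equivalents,
                   resolve_label(ont, "Mentalis muscle"))
})

test_that("answering is pure: the base saturation is untouched and results repeat", {
  ont <- fixture_ont()
  sat <- classify(ont)
  before <- list(sat$subsumers, sat$role_pairs, sat$equivalence_groups)
  r1 <- answer(query_mandible, ont, sat)
  r2 <- answer(query_mandible, ont, sat)
  expect_identical(r1[c("equivalents", "descendants", "direct_children")],
                   r2[c("equivalents", "descendants", "direct_children")])
  expect_identical(list(sat$subsumers, sat$role_pairs,
                        sat$equivalence_groups), before)
})

test_that("a named-class query reproduces the classified strict subsumees", {
  ont <- fixture_ont()
  sat <- fixture_sat()
  for (label in c("muscle organ", "Masseter muscle", "Trigeminal muscle")) {
    id <- resolve_label(ont, label)
    res <- answer(sprintf("'%s'", label), ont, sat)
    strict <- names(sat$subsumers)[vapply(names(sat$subsumers),
      function(A) A != id && id %in% sat$subsumers[[A]] &&
        !(A %in% sat$subsumers[[id]]), logical(1))]
    expect_identical(res$descendants, sort(strict), info = label)
  }
})

test_that("conjunct order does not change the answer", {
  ont <- fixture_ont()
  sat <- fixture_sat()
  a <- answer(query_trig_mandible, ont, sat)
  b <- answer(paste(
    "('attached_to' some 'mandible bone') and",
    "('innervated by' some 'trigeminal nerve') and 'muscle organ'"),
    ont, sat)
  expect_identical(a[c("equivalents", "descendants")],
                   b[c("equivalents", "descendants")])
})

test_that("synonym pairs answer identically; distinct muscles do not", {
  ont <- fixture_ont()
  sat <- fixture_sat()
  expect_true(synonym_invariance_check("lateral pterygoid muscle",
                                       "external pterygoid muscle",
                                       ont, sat))
  expect_false(synonym_invariance_check("Masseter muscle",
                                        "Temporalis muscle", ont, sat))
  expect_error(synonym_invariance_check("no such", "mandible", ont, sat),
               "unknown term")
  # exhaustive sweep over every (label, synonym) pair in the fixture
  for (cl in ont$classes) {
    for (s in cl$synonyms) {
      expect_true(synonym_invariance_check(cl$label, s, ont, sat),
                  info = paste(cl$label, "~", s))
    }
  }
})
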