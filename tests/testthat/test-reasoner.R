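test_that("an axiom-free ontology saturates to S(A) = {A, top} and empty roles", {
  cls <- lapply(1:4, function(i)
    ontology_class(sprintf("EX:%07d", i), sprintf("class %d", i)))
  p <- object_property("EP:0000001", "rel", is_transitive = TRUE)
  ont <- ontology(cls, list(p), list())
  sat <- classify(ont)
  for (id in names(ont$classes)) {
    expect_identical(sat$subsumers[[id]], sort(c(id, "owl:Thing")))
  }
  expect_identical(nrow(sat$role_pairs[["EP:0000001"]]), 0L)
})

test_that("part_of chains classify compound structures: the epiphysis example", {
  ont <- fixture_ont()
  sat <- fixture_sat()
  eod <- resolve_label(ont, "epiphysis of digit")
  eoh <- resolve_label(ont, "epiphysis of hand")
  eop <- resolve_label(ont, "epiphysis of distal phalanx")
  expect_true(is_subsumed(sat, eod, eoh))
  expect_true(is_subsumed(sat, eop, eod))
  expect_true(is_subsumed(sat, eop, eoh))   # two-step chain
  expect_false(is_subsumed(sat, eoh, eod))  # no converse
})

test_that("innervation implies developmental origin through the GCIs", {
  ont <- fixture_ont()
  sat <- fixture_sat()
  dev <- sat$role_pairs[["RO:0002202"]]
  pd <- resolve_label(ont, "Posterior digastric muscle")
  arch2 <- resolve_label(ont, "branchial arch 2")
  expect_true(any(dev$sub == pd & dev$obj == arch2))
  # the taxon-specific subclass inherits the inference
  opd <- resolve_label(ont, "Orangutan posterior digastric muscle")
  expect_true(any(dev$sub == opd & dev$obj == arch2))
  # trigeminal-innervated muscles land on arch 1, not arch 2
  tmp <- resolve_label(ont, "Temporalis muscle")
  arch1 <- resolve_label(ont, "branchial arch 1")
  expect_true(any(dev$sub == tmp & dev$obj == arch1))
  expect_false(any(dev$sub == tmp & dev$obj == arch2))
})

test_that("muscles classify under the defined innervation grouping automatically", {
  ont <- fixture_ont()
  sat <- fixture_sat()
  tm <- resolve_label(ont, "Trigeminal muscle")
  expect_true(is_subsumed(sat, resolve_label(ont, "Anterior digastric muscle"), tm))
  expect_true(is_subsumed(sat, resolve_label(ont, "Masseter muscle"), tm))
  # same attachments, different nerve: the geniohyoid stays out
  expect_false(is_subsumed(sat, resolve_label(ont, "Geniohyoid muscle"), tm))
  expect_false(is_subsumed(sat, resolve_label(ont, "Posterior digastric muscle"), tm))
})

test_that("identical definitions produce one equivalence group", {
  cls <- list(
    ontology_class("EX:0000001", "defined one"),
    ontology_class("EX:0000002", "defined two"),
    ontology_class("EX:0000003", "filler"))
  p <- object_property("EP:0000001", "rel")
  def <- ce_some("EP:0000001", ce_named("EX:0000003"))
  ont <- ontology(cls, list(p),
                  list(ax_equivalent("EX:0000001", ce_and(def, ce_named("EX:0000003"))),
                       ax_equivalent("EX:0000002", ce_and(def, ce_named("EX:0000003")))))
  sat <- classify(ont)
  grp <- Filter(function(g) "EX:0000001" %in% g, sat$equivalence_groups)
  expect_length(grp, 1L)
  expect_identical(grp[[1]], c("EX:0000001", "EX:0000002"))
})

test_that("saturation equals the naive brute-force oracle on random ontologies", {
  for (seed in 1:60) {
    ont <- rand_ontology(seed, n_classes = sample(4:15, 1),
                         n_axioms = sample(5:30, 1),
                         n_props = sample(1:3, 1))
    nf <- normalize(ont)
    sat <- saturate(nf, ont$properties, names(ont$classes))
    oracle <- oracle_saturate(nf, ont$properties, names(ont$classes))
    expect_same_saturation(sat, oracle)
  }
})

test_that("adding an axiom never removes a subsumption (monotonicity)", {
  for (seed in 101:130) {
    ont <- rand_ontology(seed, n_classes = 8, n_axioms = 12)
    sat1 <- classify(ont)
    set.seed(seed + 5000)
    ids <- names(ont$classes)
    extra <- ax_subclass(ce_named(sample(ids, 1)), ce_named(sample(ids, 1)))
    ont2 <- ontology(unname(ont$classes), unname(ont$properties),
                     c(ont$axioms, list(extra)), name = ont$name)
    sat2 <- classify(ont2)
    for (id in ids) {
      expect_true(all(sat1$subsumers[[id]] %in% sat2$subsumers[[id]]),
                  info = paste("seed", seed, "class", id))
    }
  }
})

test_that("re-classifying a materialized closure changes nothing (idempotence)", {
  for (seed in c(7, 23, 77)) {
    ont <- rand_ontology(seed, n_classes = 10, n_axioms = 18)
    sat1 <- classify(ont)
    trans <- names(ont$properties)[vapply(ont$properties, `[[`,
                                          logical(1), "is_transitive")]
    pre <- export_closure(ont, trans)
    f <- withr::local_tempfile(fileext = ".obo")
    write_closure(pre, f, format = "obo", ont = ont)
    sat2 <- classify(read_obo(f))
    for (id in names(ont$classes)) {
      expect_identical(sat2$subsumers[[id]], sat1$subsumers[[id]],
                       info = paste("seed", seed, "class", id))
    }
  }
})

test_that("transitive role closure equals an independent graph closure", {
  skip_if_not_installed("igraph")
  for (seed in c(3, 14, 59)) {
    dag <- rand_dag_ontology(seed, n_nodes = 15)
    sat <- classify(dag$ontology)
    pairs <- sat$role_pairs[["EP:0000001"]]
    g <- igraph::make_empty_graph(n = length(dag$ids), directed = TRUE)
    g <- igraph::set_vertex_attr(g, "name", value = dag$ids)
    for (e in dag$edges) g <- igraph::add_edges(g, e)
    d <- igraph::distances(g, mode = "out")
    expected <- character(0)
    for (a in dag$ids) {
      for (b in dag$ids) {
        if (a != b && is.finite(d[a, b])) {
          expected <- c(expected, paste(a, b))
        }
      }
    }
    expect_setequal(paste(pairs$sub, pairs$obj), expected)
  }
})
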