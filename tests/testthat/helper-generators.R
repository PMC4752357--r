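# Seeded random-ontology generator for property-based tests.
#
# Produces valid ontologies in the EL fragment: named subclass axioms,
# existential (relationship) axioms, GCIs, and equivalence definitions
# whose right sides are conjunctions of named classes and existentials
# (occasionally with nested fillers, to exercise normalization and the
# equivalent_to file escape hatch).

rand_ontology <- function(seed, n_classes = 12, n_axioms = 20,
                          n_props = 3, p_transitive = 0.5,
                          nested = TRUE) {
  set.seed(seed)
  cls_ids <- sprintf("EX:%07d", seq_len(n_classes))
  classes <- lapply(seq_len(n_classes), function(i) {
    syns <- if (runif(1) < 0.3) sprintf("alt name %d", i) else character(0)
    ontology_class(cls_ids[i], sprintf("generated class %d", i),
                   synonyms = syns)
  })
  prop_ids <- sprintf("EP:%07d", seq_len(n_props))
  properties <- lapply(seq_len(n_props), function(i) {
    parents <- if (i > 1 && runif(1) < 0.3) prop_ids[sample.int(i - 1, 1)]
               else character(0)
    object_property(prop_ids[i], sprintf("generated relation %d", i),
                    is_transitive = runif(1) < p_transitive,
                    parent_properties = parents)
  })
  rand_named <- function() ce_named(sample(cls_ids, 1))
  rand_expr <- function(depth = 1) {
    roll <- runif(1)
    if (roll < 0.45 || depth > 2) {
      rand_named()
    } else if (roll < 0.75) {
      filler <- if (nested && runif(1) < 0.25) rand_expr(depth + 1)
                else rand_named()
      ce_some(sample(prop_ids, 1), filler)
    } else {
      ce_and(lapply(seq_len(sample(2:3, 1)),
                    function(i) rand_expr(depth + 1)))
    }
  }
  axioms <- lapply(seq_len(n_axioms), function(i) {
    roll <- runif(1)
    if (roll < 0.4) {
      ax_subclass(rand_named(), rand_named())
    } else if (roll < 0.6) {
      ax_subclass(rand_named(), ce_some(sample(prop_ids, 1), rand_named()))
    } else if (roll < 0.75) {
      # GCI
      ax_subclass(ce_some(sample(prop_ids, 1), rand_named()),
                  rand_expr())
    } else {
      ax_equivalent(sample(cls_ids, 1),
                    ce_and(lapply(seq_len(sample(2:3, 1)),
                                  function(i) rand_expr(2))))
    }
  })
  ontology(classes, properties, axioms,
           name = sprintf("random-%d", seed))
}

# random DAG as a part_of-only ontology (for closure tests)
rand_dag_ontology <- function(seed, n_nodes = 20, p_edge = 0.15) {
  set.seed(seed)
  ids <- sprintf("DG:%07d", seq_len(n_nodes))
  classes <- lapply(seq_len(n_nodes), function(i) {
    ontology_class(ids[i], sprintf("node %d", i))
  })
  part <- object_property("EP:0000001", "part of", is_transitive = TRUE)
  axioms <- list()
  edges <- list()
  for (i in seq_len(n_nodes)) {
    for (j in seq_len(n_nodes)) {
      if (i < j && runif(1) < p_edge) {   # i -> j respects a topological order
        axioms[[length(axioms) + 1L]] <-
          ax_subclass(ce_named(ids[i]), ce_some("EP:0000001",
                                                ce_named(ids[j])))
        edges[[length(edges) + 1L]] <- c(ids[i], ids[j])
      }
    }
  }
  list(ontology = ontology(classes, list(part), axioms,
                           name = sprintf("dag-%d", seed)),
       edges = edges, ids = ids)
}

fixture_ont <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_fixture()
    cache
  }
})

fixture_sat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- classify(fixture_ont())
    cache
  }
})
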