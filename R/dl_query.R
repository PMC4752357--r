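#' Parse a DL query string
#'
#' Thin wrapper over the shared expression grammar: parses a Protege-style
#' query such as `'muscle organ' and ('attached to' some 'mandible')`
#' against an ontology's labels and synonyms.
#'
#' @param text the query string.
#' @param ont an [ontology()].
#' @return a canonical `class_expression`.
#' @export
parse_query <- function(text, ont) parse_expression(text, ont)

#' Answer a DL query against a classified ontology
#'
#' Adds a throwaway defined class equivalent to the query expression,
#' extends the saturation, and reads off the named classes subsumed by the
#' query: `equivalents` (mutual subsumers), `descendants` (strictly
#' subsumed classes), and `direct_children` (descendants with no other
#' descendant between them and the query).  The base saturation is left
#' untouched; answering is purely functional.
#'
#' @param query a query string or a `class_expression` (see
#'   [parse_query()]).
#' @param ont the ontology the saturation was computed from.
#' @param sat the corresponding `saturation` from [classify()].  The
#'   argument is only consulted for its provenance check; the query is
#'   answered by re-saturating the augmented axiom set, which keeps `sat`
#'   immutable.
#' @return an object of class `query_result` with sorted CURIE vectors
#'   `equivalents`, `descendants`, `direct_children`.
#' @examples
#' ont <- build_fixture()
#' sat <- classify(ont)
#' res <- answer("'muscle organ' and ('attached to' some 'mandible')",
#'               ont, sat)
#' length(res$descendants)
#' @export
answer <- function(query, ont, sat) {
  stopifnot(inherits(ont, "ontology"), inherits(sat, "saturation"))
  if (is.character(query)) query <- parse_query(query, ont)
  stopifnot(is_class_expression(query))

  qid <- "_query:Q"
  nf <- normalize(ont)
  # normalize the query definition in an ontology-consistent way: reuse the
  # normalizer on a synthetic equivalence axiom, offsetting fresh names so
  # they cannot collide with the base normalization's.
  qnf <- normalize_query_definition(qid, query, ont,
                                    offset = max_fresh_index(nf))
  sat2 <- saturate(c(nf, qnf), ont$properties,
                   c(names(ont$classes), qid))

  originals <- names(ont$classes)
  eq <- originals[vapply(originals, function(A) {
    qid %in% sat2$subsumers[[A]] && A %in% sat2$subsumers[[qid]]
  }, logical(1))]
  desc <- setdiff(
    originals[vapply(originals, function(A) qid %in% sat2$subsumers[[A]],
                     logical(1))],
    eq)

  # direct children: descendants (collapsed to equivalence groups) with no
  # strictly intermediate descendant group
  direct <- desc[vapply(desc, function(A) {
    !any(vapply(desc, function(E) {
      E != A && E %in% sat2$subsumers[[A]] && !(A %in% sat2$subsumers[[E]])
    }, logical(1)))
  }, logical(1))]

  structure(list(query = query, equivalents = sort(eq),
                 descendants = sort(desc), direct_children = sort(direct)),
            class = "query_result")
}

max_fresh_index <- function(normal_axioms) {
  mx <- 0L
  for (ax in normal_axioms) {
    for (f in intersect(names(ax), c("A", "B", "A1", "A2"))) {
      if (is_fresh_name(ax[[f]])) {
        mx <- max(mx, as.integer(sub("^_:NF", "", ax[[f]])))
      }
    }
  }
  mx
}

# Normalize qid EquivalentTo expr with fresh-name counter offset so the
# produced fresh names are disjoint from the base ontology's normalization.
normalize_query_definition <- function(qid, expr, ont, offset) {
  tmp <- ont
  qcl <- ontology_class(curie("TMPQ", "0000001"), "query placeholder")
  # build by hand: run normalize() on a minimal ontology holding the query
  holder <- ontology(
    classes = c(unname(tmp$classes), list(qcl)),
    properties = unname(tmp$properties),
    axioms = list(ax_equivalent(qcl$id, expr)),
    name = "query"
  )
  qnf <- normalize(holder)
  rename <- function(x) {
    if (x == qcl$id) return(qid)
    if (is_fresh_name(x)) {
      n <- as.integer(sub("^_:NF", "", x))
      return(sprintf("_:NF%06d", n + offset))
    }
    x
  }
  lapply(qnf, function(ax) {
    for (f in intersect(names(ax), c("A", "B", "A1", "A2"))) {
      ax[[f]] <- rename(ax[[f]])
    }
    ax
  })
}

#' @export
print.query_result <- function(x, ...) {
  cat("<query_result> ", length(x$equivalents), " equivalents, ",
      length(x$descendants), " descendants (",
      length(x$direct_children), " direct)\n", sep = "")
  invisible(x)
}

#' All named classes answering a query
#' @param res a `query_result`.
#' @return sorted CURIEs: equivalents and descendants together (the form
#'   in which answer lists are usually published).
#' @export
query_hits <- function(res) {
  stopifnot(inherits(res, "query_result"))
  sort(c(res$equivalents, res$descendants))
}

#' Check that two names denote the same class
#'
#' True iff both strings resolve to the same class CURIE, in which case
#' any query phrased with either name returns identical results — the
#' behaviour an ontology-backed search shows for synonym pairs such as the
#' lateral vs. external pterygoid muscle, and that literal keyword engines
#' lack.
#'
#' @param label_a,label_b labels, synonyms or CURIE strings.
#' @param ont an [ontology()].
#' @param sat optional `saturation`; unused for the decision (synonymy is
#'   a vocabulary fact) but accepted so callers can pass their session
#'   state through.
#' @return TRUE or FALSE.
#' @export
synonym_invariance_check <- function(label_a, label_b, ont, sat = NULL) {
  identical(resolve_label(ont, label_a), resolve_label(ont, label_b))
}
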