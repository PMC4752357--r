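#' Structural equality of ontologies
#'
#' Two ontologies are structurally equal when they declare the same
#' classes (same labels, synonym sets, xref sets, definitions), the same
#' properties (same flags and parents), and the same set of axioms up to
#' the canonical expression form.  Axiom and synonym order is immaterial;
#' this is the notion of identity preserved by a write/read round trip.
#'
#' @param a,b ontologies.
#' @return TRUE or FALSE.
#' @export
ontology_equal <- function(a, b) {
  stopifnot(inherits(a, "ontology"), inherits(b, "ontology"))
  if (!setequal(names(a$classes), names(b$classes))) return(FALSE)
  if (!setequal(names(a$properties), names(b$properties))) return(FALSE)
  for (id in names(a$classes)) {
    ca <- a$classes[[id]]
    cb <- b$classes[[id]]
    if (!identical(ca$label, cb$label)) return(FALSE)
    if (!setequal(ca$synonyms, cb$synonyms)) return(FALSE)
    if (!setequal(ca$xrefs, cb$xrefs)) return(FALSE)
    if (!identical(ca$text_def, cb$text_def)) return(FALSE)
    if (!identical(ca$def_source, cb$def_source)) return(FALSE)
  }
  for (id in names(a$properties)) {
    pa <- a$properties[[id]]
    pb <- b$properties[[id]]
    if (!identical(pa$label, pb$label)) return(FALSE)
    if (!identical(pa$is_transitive, pb$is_transitive)) return(FALSE)
    if (!setequal(pa$parent_properties, pb$parent_properties)) return(FALSE)
    if (!setequal(pa$synonyms, pb$synonyms)) return(FALSE)
  }
  setequal(vapply(a$axioms, axiom_key, character(1)),
           vapply(b$axioms, axiom_key, character(1)))
}

axiom_key <- function(ax) {
  if (ax$variant == "subclass") {
    paste(ce_key(ax$sub), "SubClassOf", ce_key(ax$sup))
  } else {
    paste(ax$cls, "EquivalentTo", ce_key(ax$definition))
  }
}
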