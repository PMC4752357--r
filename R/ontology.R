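#' Ontology container
#'
#' An `ontology` holds named classes (with labels, synonyms, xrefs and
#' textual definitions), object properties (with transitivity flags and a
#' property hierarchy) and logical axioms.  Two axiom variants exist:
#'
#' * `ax_subclass(sub, sup)` — a subclass axiom; when `sub` is a complex
#'   expression this is a general class inclusion (GCI), e.g. "anything
#'   innervated by the trigeminal nerve develops from branchial arch 1".
#' * `ax_equivalent(id, definition)` — a necessary-and-sufficient
#'   definition of the named class `id`, e.g. the styloglossus as the muscle
#'   innervated by the hypoglossal nerve and attached to the stylohyal bone
#'   and the tongue.
#'
#' `ontology()` validates the container: every CURIE referenced by an axiom
#' must be declared, and class labels must be unique after case-folding.
#'
#' @param classes list of objects from [ontology_class()].
#' @param properties list of objects from [object_property()].
#' @param axioms list of axiom objects.
#' @param name optional ontology name written to the file header.
#' @return an object of class `ontology`.
#' @examples
#' ont <- ontology(
#'   classes = list(
#'     ontology_class("EX:0000001", "muscle organ"),
#'     ontology_class("EX:0000002", "masseter muscle")
#'   ),
#'   properties = list(),
#'   axioms = list(ax_subclass(ce_named("EX:0000002"), ce_named("EX:0000001")))
#' )
#' resolve_label(ont, "Masseter Muscle")
#' @name ontology
NULL

#' @rdname ontology
#' @param id CURIE of the class.
#' @param label primary human-readable name (non-empty).
#' @param synonyms character vector of alternative names (no duplicates,
#'   never equal to the label).
#' @param xrefs CURIEs of corresponding classes in other ontologies.
#' @param text_def optional textual definition.
#' @param def_source optional provenance of the definition.
#' @export
ontology_class <- function(id, label, synonyms = character(0),
                           xrefs = character(0), text_def = NULL,
                           def_source = NULL) {
  stopifnot(is_curie(id), is.character(label), length(label) == 1L)
  if (!nzchar(trimws(label))) {
    stop("class ", id, " has an empty label", call. = FALSE)
  }
  synonyms <- as.character(synonyms)
  if (anyDuplicated(fold_label(synonyms))) {
    stop("class ", id, " has duplicate synonyms", call. = FALSE)
  }
  if (fold_label(label) %in% fold_label(synonyms)) {
    stop("class ", id, " lists its own label as a synonym", call. = FALSE)
  }
  if (length(xrefs) && !all(is_curie(xrefs))) {
    stop("class ", id, " has malformed xrefs", call. = FALSE)
  }
  structure(list(id = id, label = label, synonyms = synonyms,
                 xrefs = as.character(xrefs), text_def = text_def,
                 def_source = def_source),
            class = "ontology_class")
}

#' @rdname ontology
#' @param is_transitive whether chains of the property entail direct pairs
#'   (`part_of` is the canonical transitive anatomical relation; attachment,
#'   innervation and developmental origin are not transitive).
#' @param parent_properties CURIEs of super-properties (acyclic hierarchy).
#' @export
object_property <- function(id, label, is_transitive = FALSE,
                            parent_properties = character(0),
                            synonyms = character(0)) {
  stopifnot(is_curie(id), is.character(label), length(label) == 1L,
            nzchar(trimws(label)), is.logical(is_transitive))
  structure(list(id = id, label = label,
                 is_transitive = isTRUE(is_transitive),
                 parent_properties = as.character(parent_properties),
                 synonyms = as.character(synonyms)),
            class = "object_property")
}

#' @rdname ontology
#' @param sub,sup class expressions.
#' @export
ax_subclass <- function(sub, sup) {
  stopifnot(is_class_expression(sub), is_class_expression(sup))
  structure(list(variant = "subclass", sub = ce_canonical(sub),
                 sup = ce_canonical(sup)),
            class = "ontology_axiom")
}

#' @rdname ontology
#' @param definition a class expression giving necessary-and-sufficient
#'   conditions for membership in class `id`.
#' @export
ax_equivalent <- function(id, definition) {
  stopifnot(is_curie(id), is_class_expression(definition))
  structure(list(variant = "equivalent", cls = id,
                 definition = ce_canonical(definition)),
            class = "ontology_axiom")
}

#' @export
print.ontology_axiom <- function(x, ...) {
  if (x$variant == "subclass") {
    cat(ce_key(x$sub), "SubClassOf", ce_key(x$sup), "\n")
  } else {
    cat(x$cls, "EquivalentTo", ce_key(x$definition), "\n")
  }
  invisible(x)
}

# Case-fold a label: lower case, collapse internal whitespace, normalize
# typographic quotes (the source literature mixes curly and straight quotes).
fold_label <- function(x) {
  x <- gsub("[‘’]", "'", x)
  x <- gsub("[“”]", "\"", x)
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

#' @rdname ontology
#' @export
ontology <- function(classes = list(), properties = list(), axioms = list(),
                     name = "ontology") {
  stopifnot(all(vapply(classes, inherits, logical(1), "ontology_class")),
            all(vapply(properties, inherits, logical(1), "object_property")),
            all(vapply(axioms, inherits, logical(1), "ontology_axiom")))
  class_ids <- vapply(classes, `[[`, character(1), "id")
  prop_ids <- vapply(properties, `[[`, character(1), "id")
  if (anyDuplicated(class_ids)) {
    stop("duplicate class ids: ",
         paste(unique(class_ids[duplicated(class_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(prop_ids)) {
    stop("duplicate property ids: ",
         paste(unique(prop_ids[duplicated(prop_ids)]), collapse = ", "),
         call. = FALSE)
  }
  names(classes) <- class_ids
  names(properties) <- prop_ids
  ont <- structure(list(classes = classes, properties = properties,
                        axioms = axioms, name = name),
                   class = "ontology")
  validate_ontology(ont)
  ont
}

#' Validate an ontology container
#'
#' Checks referential integrity (axioms and property hierarchies only
#' mention declared CURIEs), label uniqueness after case-folding, and
#' acyclicity of the property hierarchy.  Called by [ontology()]; exposed
#' for re-validation after manual surgery.
#'
#' @param ont an `ontology`.
#' @return the ontology, invisibly; errors describe the first violation.
#' @export
validate_ontology <- function(ont) {
  stopifnot(inherits(ont, "ontology"))
  class_ids <- names(ont$classes)
  prop_ids <- names(ont$properties)

  labels <- vapply(ont$classes, `[[`, character(1), "label")
  folded <- fold_label(labels)
  if (anyDuplicated(folded)) {
    dup <- labels[duplicated(folded) | duplicated(folded, fromLast = TRUE)]
    stop("duplicate class labels after case-folding: ",
         paste(unique(dup), collapse = "; "), call. = FALSE)
  }

  for (p in ont$properties) {
    missing <- setdiff(p$parent_properties, prop_ids)
    if (length(missing)) {
      stop("property ", p$id, " references undeclared parent properties: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  # acyclicity of the property hierarchy
  colour <- new.env(parent = emptyenv())
  visit <- function(pid, stack) {
    if (pid %in% stack) {
      stop("property hierarchy cycle involving ", pid, call. = FALSE)
    }
    for (parent in ont$properties[[pid]]$parent_properties) {
      visit(parent, c(stack, pid))
    }
  }
  for (pid in prop_ids) visit(pid, character(0))

  for (i in seq_along(ont$axioms)) {
    ax <- ont$axioms[[i]]
    exprs <- if (ax$variant == "subclass") list(ax$sub, ax$sup)
             else list(ce_named(ax$cls), ax$definition)
    cls <- unique(unlist(lapply(exprs, ce_classes)))
    props <- unique(unlist(lapply(exprs, ce_properties)))
    miss_c <- setdiff(cls, c(class_ids, TOP))
    miss_p <- setdiff(props, prop_ids)
    if (length(miss_c)) {
      stop("axiom ", i, " references undeclared classes: ",
           paste(miss_c, collapse = ", "), call. = FALSE)
    }
    if (length(miss_p)) {
      stop("axiom ", i, " references undeclared properties: ",
           paste(miss_p, collapse = ", "), call. = FALSE)
    }
  }
  invisible(ont)
}

#' @export
print.ontology <- function(x, ...) {
  n_eq <- sum(vapply(x$axioms, function(a) a$variant == "equivalent",
                     logical(1)))
  cat("<ontology> ", x$name, ": ", length(x$classes), " classes, ",
      length(x$properties), " properties, ", length(x$axioms),
      " axioms (", n_eq, " equivalence definitions)\n", sep = "")
  invisible(x)
}

#' Resolve a label, synonym or CURIE to a class id
#'
#' Matching is case-insensitive (whitespace collapsed, typographic quotes
#' normalized) and tried in order: CURIE, primary label, synonym.  Searching
#' for a muscle by any of its synonyms therefore lands on the same class —
#' the behaviour that distinguishes ontology-backed search from literal
#' keyword engines (e.g. 'external pterygoid muscle' resolves to the class
#' labelled 'lateral pterygoid muscle').
#'
#' @param ont an `ontology`.
#' @param text a label, synonym or CURIE string.
#' @return the CURIE of the unique matching class.
#' @export
resolve_label <- function(ont, text) {
  stopifnot(inherits(ont, "ontology"), is.character(text),
            length(text) == 1L)
  if (is_curie(text) && text %in% names(ont$classes)) return(text)
  key <- fold_label(text)
  labels <- fold_label(vapply(ont$classes, `[[`, character(1), "label"))
  hit <- names(ont$classes)[labels == key]
  if (length(hit) == 1L) return(hit)
  syn_hits <- character(0)
  for (cl in ont$classes) {
    if (key %in% fold_label(cl$synonyms)) syn_hits <- c(syn_hits, cl$id)
  }
  if (length(syn_hits) == 1L) return(syn_hits)
  if (length(syn_hits) > 1L) {
    stop("ambiguous synonym '", text, "': matches ",
         paste(syn_hits, collapse = ", "), call. = FALSE)
  }
  stop("unknown term: '", text, "'", call. = FALSE)
}

#' Resolve a property label or CURIE
#'
#' Space and underscore spellings are equivalent ("attached to" matches
#' "attached_to"); property synonyms (e.g. "attaches to") also match.
#'
#' @inheritParams resolve_label
#' @return the CURIE of the unique matching property.
#' @export
resolve_property <- function(ont, text) {
  stopifnot(inherits(ont, "ontology"), is.character(text),
            length(text) == 1L)
  if (is_curie(text) && text %in% names(ont$properties)) return(text)
  key <- gsub("_", " ", fold_label(text))
  for (p in ont$properties) {
    cands <- gsub("_", " ", fold_label(c(p$label, p$synonyms)))
    if (key %in% cands) return(p$id)
  }
  stop("unknown property: '", text, "'", call. = FALSE)
}

#' Primary label of a class id
#' @param ont an `ontology`.
#' @param id CURIE (vectorized).
#' @return character vector of labels (`NA` for undeclared ids).
#' @export
label_of <- function(ont, id) {
  vapply(id, function(x) {
    cl <- ont$classes[[x]]
    if (is.null(cl)) NA_character_ else cl$label
  }, character(1), USE.NAMES = FALSE)
}
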