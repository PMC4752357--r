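#' Export a pre-reasoned ontology
#'
#' Databases without a built-in reasoner consume ontologies with every
#' inferred relationship already materialized.  `export_closure()` runs
#' [classify()] and materializes (i) the full subclass closure over the
#' ontology's named classes and (ii), for each selected transitive
#' property (typically `part_of`), the closure of entailed existential
#' pairs `(A, B)` with `A SubClassOf property some B`.  Every pair carries
#' a provenance flag distinguishing asserted axioms from inferred ones.
#'
#' Property closures cover *all* entailed pairs, a superset of asserted
#' plus transitive chaining (pairs can also arise through subsumption into
#' defined classes).
#'
#' @param ont a validated [ontology()].
#' @param selected_properties CURIEs of transitive properties to
#'   materialize; selecting a non-transitive property is a configuration
#'   error since closure semantics presume chaining.
#' @param reflexive include the reflexive pairs `(A, A)` in the subclass
#'   closure (flagged `inferred`); on by default to match common
#'   pre-reasoned database loaders.
#' @return an object of class `prereasoned` with data.frames
#'   `subclass_closure` and one per property in `property_closures`, each
#'   with columns `sub`, `sup`/`obj`, `asserted` (logical).
#' @examples
#' ont <- build_fixture()
#' pre <- export_closure(ont, "BFO:0000050")
#' head(pre$subclass_closure)
#' @export
export_closure <- function(ont, selected_properties = character(0),
                           reflexive = TRUE) {
  stopifnot(inherits(ont, "ontology"))
  for (p in selected_properties) {
    prop <- ont$properties[[p]]
    if (is.null(prop)) {
      stop("selected property not declared: ", p, call. = FALSE)
    }
    if (!prop$is_transitive) {
      stop("selected property is not transitive: ", p,
           " ('", prop$label, "'); closure semantics differ for ",
           "non-transitive properties", call. = FALSE)
    }
  }
  sat <- classify(ont)
  originals <- names(ont$classes)

  asserted_sub <- character(0)
  asserted_rel <- list()
  for (ax in ont$axioms) {
    if (ax$variant == "subclass" && ax$sub$variant == "named" &&
        ax$sup$variant == "named") {
      asserted_sub <- c(asserted_sub, paste(ax$sub$class, ax$sup$class))
    }
    if (ax$variant == "subclass" && ax$sub$variant == "named" &&
        ax$sup$variant == "some" && ax$sup$filler$variant == "named") {
      r <- ax$sup$property
      asserted_rel[[r]] <- c(asserted_rel[[r]],
                             paste(ax$sub$class, ax$sup$filler$class))
    }
  }

  subs <- sups <- character(0)
  for (A in originals) {
    bs <- setdiff(sat$subsumers[[A]], TOP)
    if (!reflexive) bs <- setdiff(bs, A)
    subs <- c(subs, rep(A, length(bs)))
    sups <- c(sups, bs)
  }
  sc <- data.frame(sub = subs, sup = sups, stringsAsFactors = FALSE)
  sc$asserted <- paste(sc$sub, sc$sup) %in% asserted_sub
  sc <- sc[order(sc$sub, sc$sup), , drop = FALSE]
  rownames(sc) <- NULL

  pcs <- lapply(selected_properties, function(r) {
    df <- sat$role_pairs[[r]]
    df$asserted <- paste(df$sub, df$obj) %in% (asserted_rel[[r]] %||%
                                                 character(0))
    rownames(df) <- NULL
    df
  })
  names(pcs) <- selected_properties

  structure(list(subclass_closure = sc, property_closures = pcs,
                 ontology_name = ont$name,
                 selected_properties = selected_properties,
                 reflexive = reflexive),
            class = "prereasoned")
}

#' @export
print.prereasoned <- function(x, ...) {
  cat("<prereasoned> ", nrow(x$subclass_closure), " subclass pairs; ",
      paste(vapply(names(x$property_closures), function(r) {
        paste0(r, ": ", nrow(x$property_closures[[r]]), " pairs")
      }, character(1)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a pre-reasoned ontology to disk
#'
#' `format = "tsv"` writes sorted rows `sub`, `rel`, `sup`, `provenance`
#' (with `rel` either `is_a` or the property CURIE and `provenance`
#' `asserted`/`inferred`).  `format = "obo"` writes an ontology file with
#' every closure pair materialized as an `is_a`/`relationship` tag;
#' re-reading and re-exporting that file reproduces it byte-identically
#' (materialization is idempotent).
#'
#' @param pre a `prereasoned` object from [export_closure()].
#' @param path output file path.
#' @param format `"tsv"` or `"obo"`.
#' @param ont the source ontology; required for `format = "obo"` (labels,
#'   synonyms and property declarations are carried over).
#' @return `path`, invisibly.
#' @export
write_closure <- function(pre, path, format = c("tsv", "obo"), ont = NULL) {
  stopifnot(inherits(pre, "prereasoned"))
  format <- match.arg(format)
  if (format == "tsv") {
    sc <- pre$subclass_closure
    rows <- data.frame(sub = sc$sub,
                       rel = rep("is_a", nrow(sc)),
                       sup = sc$sup,
                       provenance = ifelse(sc$asserted, "asserted",
                                           "inferred"),
                       stringsAsFactors = FALSE)
    for (r in names(pre$property_closures)) {
      pc <- pre$property_closures[[r]]
      if (nrow(pc)) {
        rows <- rbind(rows, data.frame(
          sub = pc$sub, rel = r, sup = pc$obj,
          provenance = ifelse(pc$asserted, "asserted", "inferred"),
          stringsAsFactors = FALSE))
      }
    }
    rows <- rows[order(rows$sub, rows$rel, rows$sup), , drop = FALSE]
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c("sub\trel\tsup\tprovenance",
                 sprintf("%s\t%s\t%s\t%s", rows$sub, rows$rel, rows$sup,
                         rows$provenance)),
               con, useBytes = TRUE)
    return(invisible(path))
  }
  if (is.null(ont)) {
    stop("format = 'obo' needs the source ontology for declarations",
         call. = FALSE)
  }
  axioms <- list()
  sc <- pre$subclass_closure
  for (i in seq_len(nrow(sc))) {
    if (sc$sub[i] != sc$sup[i]) {  # reflexive pairs are implicit in OBO
      axioms[[length(axioms) + 1L]] <-
        ax_subclass(ce_named(sc$sub[i]), ce_named(sc$sup[i]))
    }
  }
  for (r in names(pre$property_closures)) {
    pc <- pre$property_closures[[r]]
    for (i in seq_len(nrow(pc))) {
      axioms[[length(axioms) + 1L]] <-
        ax_subclass(ce_named(pc$sub[i]), ce_some(r, ce_named(pc$obj[i])))
    }
  }
  flat <- ontology(unname(ont$classes), unname(ont$properties), axioms,
                   name = paste0(sub("-prereasoned$", "", ont$name),
                                 "-prereasoned"))
  write_obo(flat, path)
}
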