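#' Class expressions
#'
#' The EL fragment used throughout the package admits three expression
#' forms: a named class, an existential restriction
#' (`property some filler`), and a conjunction (`A and B and ...`).
#' Conjunctions are kept flattened (no conjunction directly inside a
#' conjunction) with conjuncts in a canonical sorted order, so structural
#' equality of expressions is plain `identical()` on the canonical form.
#'
#' @param id,property CURIE strings.
#' @param filler,... class expressions (for `ce_and()`, two or more).
#' @return an object of class `class_expression`.
#' @examples
#' ce_some("RO:0002005", ce_named("MFMO:0000301"))
#' ce_and(ce_named("MFMO:0000001"), ce_some("BFO:0000050", ce_named("MFMO:0000107")))
#' @name class_expression
NULL

#' @rdname class_expression
#' @export
ce_named <- function(id) {
  stopifnot(is_curie(id))
  structure(list(variant = "named", class = id),
            class = c("ce_named", "class_expression"))
}

#' @rdname class_expression
#' @export
ce_some <- function(property, filler) {
  stopifnot(is_curie(property), is_class_expression(filler))
  structure(list(variant = "some", property = property,
                 filler = ce_canonical(filler)),
            class = c("ce_some", "class_expression"))
}

#' @rdname class_expression
#' @export
ce_and <- function(...) {
  conjuncts <- list(...)
  if (length(conjuncts) == 1L && is.list(conjuncts[[1]]) &&
      !is_class_expression(conjuncts[[1]])) {
    conjuncts <- conjuncts[[1]]
  }
  stopifnot(all(vapply(conjuncts, is_class_expression, logical(1))))
  # flatten nested conjunctions, canonicalize children, sort, deduplicate
  flat <- list()
  for (c_ in conjuncts) {
    c_ <- ce_canonical(c_)
    if (inherits(c_, "ce_and")) flat <- c(flat, c_$conjuncts)
    else flat <- c(flat, list(c_))
  }
  keys <- vapply(flat, ce_key, character(1))
  flat <- flat[order(keys)]
  keys <- sort(keys)
  flat <- flat[!duplicated(keys)]
  if (length(flat) == 1L) return(flat[[1]])
  structure(list(variant = "and", conjuncts = flat),
            class = c("ce_and", "class_expression"))
}

#' @rdname class_expression
#' @param x any object.
#' @export
is_class_expression <- function(x) inherits(x, "class_expression")

#' Canonical form of a class expression
#'
#' Flattens and sorts conjunctions recursively; idempotent.
#' @param expr a class expression.
#' @return the canonicalized expression.
#' @export
ce_canonical <- function(expr) {
  stopifnot(is_class_expression(expr))
  switch(expr$variant,
    named = expr,
    some = ce_some(expr$property, expr$filler),
    and = ce_and(expr$conjuncts),
    stop("unknown expression variant: ", expr$variant)
  )
}

# Deterministic sort/equality key. Named classes sort before complex
# expressions of the same spelling because of the quoting.
ce_key <- function(expr) {
  switch(expr$variant,
    named = expr$class,
    some = paste0("(", expr$property, " some ", ce_key(expr$filler), ")"),
    and = paste0("(", paste(vapply(expr$conjuncts, ce_key, character(1)),
                            collapse = " and "), ")")
  )
}

#' Named classes and properties mentioned by an expression
#' @param expr a class expression.
#' @return character vector of CURIEs.
#' @export
ce_classes <- function(expr) {
  switch(expr$variant,
    named = expr$class,
    some = ce_classes(expr$filler),
    and = unique(unlist(lapply(expr$conjuncts, ce_classes)))
  )
}

#' @rdname ce_classes
#' @export
ce_properties <- function(expr) {
  switch(expr$variant,
    named = character(0),
    some = unique(c(expr$property, ce_properties(expr$filler))),
    and = unique(unlist(lapply(expr$conjuncts, ce_properties)))
  )
}

#' @export
print.class_expression <- function(x, ...) {
  cat("<class expression> ", ce_key(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.class_expression <- function(x, ...) ce_key(x)
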