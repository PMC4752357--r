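#' Normalize axioms into EL normal forms
#'
#' Classification rewrites every axiom into the four EL normal forms over
#' named classes only:
#'
#' * `NF1`: `A ⊑ B`
#' * `NF2`: `A1 ⊓ A2 ⊑ B`
#' * `NF3`: `A ⊑ ∃r.B`
#' * `NF4`: `∃r.A ⊑ B`
#'
#' Each equivalence definition `A ≡ D` is first split into `A ⊑ D`
#' and `D ⊑ A` (the definition is necessary *and* sufficient, which is
#' what lets a reasoner classify a muscle from its attachment and
#' innervation axioms).  Complex sub-expressions are then replaced by
#' deterministically numbered fresh names of the form `_:NF000001`;
#' conjunctions are binarized left-to-right over the canonical conjunct
#' order.  The rewriting is polarity-aware, so entailments over the
#' original named classes are preserved exactly.  Output order is
#' deterministic in the ontology's axiom order.
#'
#' A three-existential muscle definition such as the styloglossus yields
#' eight normal axioms: three NF3 (the necessary direction), three NF4
#' naming each existential, and two NF2 binarizing the conjunction back to
#' the defined class (the sufficient direction).
#'
#' @param ont a validated [ontology()].
#' @return a list of normal axioms, each a list with `form`
#'   (`"NF1"`..`"NF4"`) and named-class/property operands.
#' @examples
#' ont <- build_fixture()
#' nf <- normalize(ont)
#' table(vapply(nf, `[[`, character(1), "form"))
#' @export
normalize <- function(ont) {
  stopifnot(inherits(ont, "ontology"))
  st <- new.env(parent = emptyenv())
  st$out <- list()
  st$fresh_n <- 0L
  st$prop_ids <- names(ont$properties)

  emit <- function(ax) st$out[[length(st$out) + 1L]] <- ax
  fresh <- function() {
    st$fresh_n <- st$fresh_n + 1L
    sprintf("_:NF%06d", st$fresh_n)
  }
  check_prop <- function(r) {
    if (!(r %in% st$prop_ids)) {
      stop("expression references undeclared property: ", r, call. = FALSE)
    }
  }

  # norm(sub, sup): both canonical class expressions.
  norm <- function(sub, sup) {
    if (sup$variant == "and") {
      for (c_ in sup$conjuncts) norm(sub, c_)
      return(invisible())
    }
    if (sub$variant == "named") {
      if (sup$variant == "named") {
        emit(nf1(sub$class, sup$class))
      } else { # sup existential
        check_prop(sup$property)
        if (sup$filler$variant == "named") {
          emit(nf3(sub$class, sup$property, sup$filler$class))
        } else {
          f <- fresh()
          emit(nf3(sub$class, sup$property, f))
          norm(ce_named(f), sup$filler)
        }
      }
      return(invisible())
    }
    if (sub$variant == "some") {
      check_prop(sub$property)
      if (sup$variant == "named") {
        if (sub$filler$variant == "named") {
          emit(nf4(sub$property, sub$filler$class, sup$class))
        } else {
          f <- fresh()
          norm(sub$filler, ce_named(f))
          emit(nf4(sub$property, f, sup$class))
        }
      } else { # both complex: route through a fresh middle name
        m <- fresh()
        norm(sub, ce_named(m))
        norm(ce_named(m), sup)
      }
      return(invisible())
    }
    # sub is a conjunction
    if (sup$variant != "named") {
      m <- fresh()
      norm(sub, ce_named(m))
      norm(ce_named(m), sup)
      return(invisible())
    }
    ops <- character(0)
    for (c_ in sub$conjuncts) {
      if (c_$variant == "named") {
        ops <- c(ops, c_$class)
      } else {
        f <- fresh()
        norm(c_, ce_named(f))
        ops <- c(ops, f)
      }
    }
    # binarize left-to-right: (A1 n A2) -> G1, (G1 n A3) -> G2, ...
    acc <- ops[1]
    for (i in seq_along(ops)[-1]) {
      target <- if (i == length(ops)) sup$class else fresh()
      emit(nf2(acc, ops[i], target))
      acc <- target
    }
    invisible()
  }

  for (ax in ont$axioms) {
    if (ax$variant == "equivalent") {
      norm(ce_named(ax$cls), ax$definition)
      norm(ax$definition, ce_named(ax$cls))
    } else {
      norm(ax$sub, ax$sup)
    }
  }
  st$out
}

nf1 <- function(A, B) list(form = "NF1", A = A, B = B)
nf2 <- function(A1, A2, B) list(form = "NF2", A1 = A1, A2 = A2, B = B)
nf3 <- function(A, r, B) list(form = "NF3", A = A, r = r, B = B)
nf4 <- function(r, A, B) list(form = "NF4", r = r, A = A, B = B)

is_fresh_name <- function(x) startsWith(x, "_:NF")

normal_axiom_key <- function(ax) {
  switch(ax$form,
    NF1 = paste("NF1", ax$A, ax$B),
    NF2 = paste("NF2", ax$A1, ax$A2, ax$B),
    NF3 = paste("NF3", ax$A, ax$r, ax$B),
    NF4 = paste("NF4", ax$r, ax$A, ax$B)
  )
}
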