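#' Saturate normalized axioms with EL completion rules
#'
#' Computes the least fixpoint of the completion rules over the per-class
#' subsumer sets `S(.)` and per-property role-pair sets `R(.)`:
#'
#' * `R1`: `A' in S(A)` and `NF1(A',B)`  gives `B in S(A)`
#' * `R2`: `A1,A2 in S(A)` and `NF2(A1,A2,B)` gives `B in S(A)`
#' * `R3`: `A' in S(A)` and `NF3(A',r,B)` gives `(A,B) in R(r)`
#' * `R4`: `(A,B) in R(r)`, `B' in S(B)`, `NF4(r,B',C)` gives `C in S(A)`
#' * `R5`: `(A,B),(B,C) in R(r)`, `r` transitive, gives `(A,C) in R(r)`
#' * `R6`: `(A,B) in R(r)`, `r` sub-property of `s`, gives `(A,B) in R(s)`
#'
#' The fixpoint is independent of rule application order; a worklist keyed
#' by newly added subsumers/role pairs is used purely for speed.  Every
#' addition records the rule and premises that produced it, so any reported
#' subsumption can be explained and replayed ([explain()]).  Termination is
#' guaranteed: at most `n^2` subsumptions and `p*n^2` role pairs can ever be
#' added (`n` named classes incl. fresh names, `p` properties), and each
#' is processed once, so the worst case is polynomial in classes x axioms.
#'
#' @param normal_axioms list produced by [normalize()].
#' @param properties named list of [object_property()] objects.
#' @param original_classes character vector of the ontology's declared
#'   class CURIEs; fresh normalization names are filtered from reported
#'   subsumer sets and role pairs.
#' @return an object of class `saturation` with elements `subsumers`
#'   (named list, sorted CURIE vectors over original classes incl.
#'   `owl:Thing`), `role_pairs` (named list of two-column `sub`/`obj`
#'   data.frames per property), `equivalence_groups` (partition of the
#'   original classes by mutual subsumption) and `fresh_names`.
#' @seealso [classify()] for the one-call interface from an ontology.
#' @export
saturate <- function(normal_axioms, properties, original_classes) {
  prop_ids <- vapply(properties, `[[`, character(1), "id")
  names(properties) <- prop_ids
  transitive <- prop_ids[vapply(properties, `[[`, logical(1),
                                "is_transitive")]
  prop_supers <- property_super_closure(properties)

  # ---- axiom indices ------------------------------------------------------
  nf1_by_A <- new.env(parent = emptyenv())
  nf2_by_op <- new.env(parent = emptyenv())
  nf3_by_A <- new.env(parent = emptyenv())
  nf4_by_rB <- new.env(parent = emptyenv())
  push_idx <- function(env, key, val) {
    env[[key]] <- c(env[[key]], list(val))
  }
  mentioned <- character(0)
  for (ax in normal_axioms) {
    k <- normal_axiom_key(ax)
    switch(ax$form,
      NF1 = {
        push_idx(nf1_by_A, ax$A, list(B = ax$B, key = k))
        mentioned <- c(mentioned, ax$A, ax$B)
      },
      NF2 = {
        push_idx(nf2_by_op, ax$A1, list(other = ax$A2, B = ax$B, key = k))
        if (ax$A2 != ax$A1) {
          push_idx(nf2_by_op, ax$A2, list(other = ax$A1, B = ax$B, key = k))
        }
        mentioned <- c(mentioned, ax$A1, ax$A2, ax$B)
      },
      NF3 = {
        push_idx(nf3_by_A, ax$A, list(r = ax$r, B = ax$B, key = k))
        mentioned <- c(mentioned, ax$A, ax$B)
      },
      NF4 = {
        push_idx(nf4_by_rB, paste(ax$r, ax$A), list(C = ax$B, key = k))
        mentioned <- c(mentioned, ax$A, ax$B)
      }
    )
  }
  all_classes <- unique(c(original_classes, mentioned))
  all_classes <- setdiff(all_classes, TOP)
  fresh <- all_classes[is_fresh_name(all_classes)]

  # ---- state --------------------------------------------------------------
  S <- new.env(parent = emptyenv())       # A -> env of subsumers
  Rf <- new.env(parent = emptyenv())      # "r A" -> env of B ((A,B) in R(r))
  Rs <- new.env(parent = emptyenv())      # "r B" -> env of A
  deriv <- new.env(parent = emptyenv())   # fact key -> list(rule, premises)
  work <- list()

  sub_key <- function(A, B) paste("S", A, B)
  rel_key <- function(r, A, B) paste("R", r, A, B)

  add_sub <- function(A, B, rule, premises) {
    e <- S[[A]]
    if (is.null(e)) {
      e <- new.env(parent = emptyenv())
      S[[A]] <- e
    }
    if (!is.null(e[[B]])) return(invisible())
    e[[B]] <- TRUE
    deriv[[sub_key(A, B)]] <- list(rule = rule, premises = premises)
    work[[length(work) + 1L]] <<- c("S", A, B)
  }
  add_rel <- function(r, A, B, rule, premises) {
    kf <- paste(r, A)
    e <- Rf[[kf]]
    if (is.null(e)) {
      e <- new.env(parent = emptyenv())
      Rf[[kf]] <- e
    }
    if (!is.null(e[[B]])) return(invisible())
    e[[B]] <- TRUE
    ks <- paste(r, B)
    es <- Rs[[ks]]
    if (is.null(es)) {
      es <- new.env(parent = emptyenv())
      Rs[[ks]] <- es
    }
    es[[A]] <- TRUE
    deriv[[rel_key(r, A, B)]] <- list(rule = rule, premises = premises)
    work[[length(work) + 1L]] <<- c("R", r, A, B)
  }

  for (A in all_classes) {
    add_sub(A, A, "init", character(0))
    add_sub(A, TOP, "init", character(0))
  }

  # ---- fixpoint -----------------------------------------------------------
  head_i <- 1L
  while (head_i <= length(work)) {
    item <- work[[head_i]]
    head_i <- head_i + 1L
    if (item[1] == "S") {
      A <- item[2]
      Bn <- item[3]
      this_key <- sub_key(A, Bn)
      for (e in nf1_by_A[[Bn]] %||% list()) {            # R1
        add_sub(A, e$B, "R1", c(this_key, e$key))
      }
      sA <- S[[A]]
      for (e in nf2_by_op[[Bn]] %||% list()) {           # R2
        if (!is.null(sA[[e$other]])) {
          add_sub(A, e$B, "R2", c(this_key, sub_key(A, e$other), e$key))
        }
      }
      for (e in nf3_by_A[[Bn]] %||% list()) {            # R3
        add_rel(e$r, A, e$B, "R3", c(this_key, e$key))
      }
      # R4, triggered by a new subsumer of the filler side:
      # (Z,A) in R(r), Bn in S(A), NF4(r,Bn,C) => C in S(Z)
      for (r in prop_ids) {
        entries <- nf4_by_rB[[paste(r, Bn)]]
        if (is.null(entries)) next
        zs <- Rs[[paste(r, A)]]
        if (is.null(zs)) next
        for (Z in ls(zs)) {
          for (e in entries) {
            add_sub(Z, e$C, "R4", c(rel_key(r, Z, A), this_key, e$key))
          }
        }
      }
    } else {
      r <- item[2]
      A <- item[3]
      B <- item[4]
      this_key <- rel_key(r, A, B)
      # R4, triggered by a new role pair
      sB <- S[[B]]
      if (!is.null(sB)) {
        for (Bp in ls(sB)) {
          for (e in nf4_by_rB[[paste(r, Bp)]] %||% list()) {
            add_sub(A, e$C, "R4", c(this_key, sub_key(B, Bp), e$key))
          }
        }
      }
      if (r %in% transitive) {                           # R5
        succ <- Rf[[paste(r, B)]]
        if (!is.null(succ)) {
          for (C in ls(succ)) {
            add_rel(r, A, C, "R5", c(this_key, rel_key(r, B, C)))
          }
        }
        pred <- Rs[[paste(r, A)]]
        if (!is.null(pred)) {
          for (Z in ls(pred)) {
            add_rel(r, Z, B, "R5", c(rel_key(r, Z, A), this_key))
          }
        }
      }
      for (s in prop_supers[[r]] %||% character(0)) {    # R6
        add_rel(s, A, B, "R6", this_key)
      }
    }
  }

  # ---- reported views -----------------------------------------------------
  originals <- setdiff(original_classes, TOP)
  reported <- c(originals, TOP)
  subsumers <- lapply(originals, function(A) {
    e <- S[[A]]
    if (is.null(e)) sort(c(A, TOP)) else sort(intersect(ls(e), reported))
  })
  names(subsumers) <- originals

  role_pairs <- lapply(prop_ids, function(r) {
    subs <- character(0)
    objs <- character(0)
    for (A in originals) {
      e <- Rf[[paste(r, A)]]
      if (is.null(e)) next
      bs <- intersect(ls(e), originals)
      subs <- c(subs, rep(A, length(bs)))
      objs <- c(objs, bs)
    }
    df <- data.frame(sub = subs, obj = objs, stringsAsFactors = FALSE)
    df[order(df$sub, df$obj), , drop = FALSE]
  })
  names(role_pairs) <- prop_ids

  structure(list(
    subsumers = subsumers,
    role_pairs = role_pairs,
    equivalence_groups = equivalence_partition(subsumers),
    fresh_names = sort(fresh),
    properties = properties,
    normal_axioms = normal_axioms,
    derivations = deriv,
    internal = list(S = S, Rf = Rf, all_classes = all_classes)
  ), class = "saturation")
}

# strict super-properties of each property (reflexivity excluded)
property_super_closure <- function(properties) {
  ids <- names(properties)
  out <- list()
  for (r in ids) {
    seen <- character(0)
    queue <- properties[[r]]$parent_properties
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      if (p %in% seen) next
      seen <- c(seen, p)
      queue <- c(queue, properties[[p]]$parent_properties)
    }
    out[[r]] <- seen
  }
  out
}

equivalence_partition <- function(subsumers) {
  classes <- names(subsumers)
  done <- character(0)
  groups <- list()
  for (A in classes) {
    if (A %in% done) next
    grp <- classes[vapply(classes, function(B) {
      A %in% subsumers[[B]] && B %in% subsumers[[A]]
    }, logical(1))]
    groups[[length(groups) + 1L]] <- sort(grp)
    done <- c(done, grp)
  }
  groups
}

#' @export
print.saturation <- function(x, ...) {
  n_sub <- sum(lengths(x$subsumers))
  n_rel <- sum(vapply(x$role_pairs, nrow, integer(1)))
  cat("<saturation> ", length(x$subsumers), " classes, ", n_sub,
      " subsumptions, ", n_rel, " role pairs, ",
      length(x$fresh_names), " fresh names\n", sep = "")
  invisible(x)
}

#' Classify an ontology
#'
#' `normalize()` + `saturate()` + equivalence-group construction: computes
#' every entailed subsumption between the ontology's named classes.  This
#' is where logically defined muscles fall into place automatically — e.g.
#' a muscle asserted to be innervated by the trigeminal nerve is classified
#' under the defined class of trigeminal muscles without any asserted
#' `is_a` link.
#'
#' @param ont a validated [ontology()].
#' @return a `saturation` (see [saturate()]).
#' @examples
#' sat <- classify(build_fixture())
#' sat
#' @export
classify <- function(ont) {
  stopifnot(inherits(ont, "ontology"))
  saturate(normalize(ont), ont$properties, names(ont$classes))
}

#' Does the saturation entail a subsumption?
#'
#' @param sat a `saturation`.
#' @param sub,sup class CURIEs.
#' @return TRUE or FALSE.
#' @export
is_subsumed <- function(sat, sub, sup) {
  stopifnot(inherits(sat, "saturation"))
  subs <- sat$subsumers[[sub]]
  !is.null(subs) && sup %in% subs
}

#' Explain an entailed subsumption
#'
#' Walks the derivation recorded during saturation and returns one
#' well-founded derivation: a list of steps in dependency order, each with
#' its conclusion, the completion rule used, and its premises (earlier
#' conclusions and/or normal axioms).
#'
#' @param sat a `saturation`.
#' @param sub,sup class CURIEs with `sup` entailed as a subsumer of `sub`.
#' @return an object of class `derivation_trace`.
#' @examples
#' ont <- build_fixture()
#' sat <- classify(ont)
#' tr <- explain(sat, resolve_label(ont, "epiphysis of digit"),
#'               resolve_label(ont, "epiphysis of hand"))
#' print(tr)
#' @export
explain <- function(sat, sub, sup) {
  stopifnot(inherits(sat, "saturation"))
  goal <- paste("S", sub, sup)
  if (is.null(sat$derivations[[goal]])) {
    stop("not entailed: ", sub, " SubClassOf ", sup, call. = FALSE)
  }
  steps <- list()
  seen <- new.env(parent = emptyenv())
  visit <- function(key) {
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    d <- sat$derivations[[key]]
    if (is.null(d)) {
      stop("derivation record missing for ", key, call. = FALSE)
    }
    fact_premises <- d$premises[!startsWith(d$premises, "NF")]
    for (p in fact_premises) visit(p)
    steps[[length(steps) + 1L]] <<- list(conclusion = key, rule = d$rule,
                                         premises = d$premises)
  }
  visit(goal)
  structure(list(sub = sub, sup = sup, steps = steps),
            class = "derivation_trace")
}

#' @export
print.derivation_trace <- function(x, ...) {
  cat("derivation of", x$sub, "SubClassOf", x$sup, "\n")
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("  %2d. [%-4s] %s  <=  %s\n", i, s$rule, s$conclusion,
                if (length(s$premises)) paste(s$premises, collapse = "; ")
                else "(axiomatic)"))
  }
  invisible(x)
}

#' Replay a derivation trace
#'
#' Independently re-checks a trace: every premise must be an asserted
#' normal axiom or an earlier conclusion, and every step's conclusion must
#' follow from its premises by the step's completion rule.  Used to audit
#' the reasoner's soundness.
#'
#' @param trace a `derivation_trace`.
#' @param normal_axioms the normal axioms the saturation was built from.
#' @param properties the ontology's property list.
#' @return TRUE, or an error describing the first invalid step.
#' @export
replay_trace <- function(trace, normal_axioms, properties) {
  stopifnot(inherits(trace, "derivation_trace"))
  ax_keys <- vapply(normal_axioms, normal_axiom_key, character(1))
  prop_ids <- vapply(properties, `[[`, character(1), "id")
  names(properties) <- prop_ids
  supers <- property_super_closure(properties)
  derived <- character(0)
  ok_premise <- function(p) p %in% ax_keys || p %in% derived

  for (i in seq_along(trace$steps)) {
    s <- trace$steps[[i]]
    bad <- !vapply(s$premises, ok_premise, logical(1))
    if (any(bad)) {
      stop("step ", i, ": premise not derivable/asserted: ",
           paste(s$premises[bad], collapse = "; "), call. = FALSE)
    }
    con <- strsplit(s$conclusion, " ", fixed = TRUE)[[1]]
    pr <- lapply(s$premises, function(p) strsplit(p, " ", fixed = TRUE)[[1]])
    valid <- switch(s$rule,
      init = con[1] == "S" && (con[2] == con[3] || con[3] == TOP),
      R1 = length(pr) == 2 && con[1] == "S" &&
        pr[[1]][1] == "S" && pr[[1]][2] == con[2] &&
        pr[[2]][1] == "NF1" && pr[[2]][2] == pr[[1]][3] &&
        pr[[2]][3] == con[3],
      R2 = length(pr) == 3 && con[1] == "S" &&
        pr[[1]][1] == "S" && pr[[2]][1] == "S" &&
        pr[[1]][2] == con[2] && pr[[2]][2] == con[2] &&
        pr[[3]][1] == "NF2" && pr[[3]][4] == con[3] &&
        setequal(c(pr[[1]][3], pr[[2]][3]), c(pr[[3]][2], pr[[3]][3])),
      R3 = length(pr) == 2 && con[1] == "R" &&
        pr[[1]][1] == "S" && pr[[1]][2] == con[3] &&
        pr[[2]][1] == "NF3" && pr[[2]][2] == pr[[1]][3] &&
        pr[[2]][3] == con[2] && pr[[2]][4] == con[4],
      R4 = length(pr) == 3 && con[1] == "S" &&
        pr[[1]][1] == "R" && pr[[2]][1] == "S" && pr[[3]][1] == "NF4" &&
        pr[[1]][3] == con[2] &&            # (A,B) in R(r), conclusion on A
        pr[[2]][2] == pr[[1]][4] &&        # B' in S(B)
        pr[[3]][2] == pr[[1]][2] &&        # same property r
        pr[[3]][3] == pr[[2]][3] &&        # NF4 over B'
        pr[[3]][4] == con[3],
      R5 = length(pr) == 2 && con[1] == "R" &&
        pr[[1]][1] == "R" && pr[[2]][1] == "R" &&
        pr[[1]][2] == con[2] && pr[[2]][2] == con[2] &&
        isTRUE(properties[[con[2]]]$is_transitive) &&
        pr[[1]][3] == con[3] && pr[[1]][4] == pr[[2]][3] &&
        pr[[2]][4] == con[4],
      R6 = length(pr) == 1 && con[1] == "R" &&
        pr[[1]][1] == "R" && pr[[1]][3] == con[3] && pr[[1]][4] == con[4] &&
        con[2] %in% supers[[pr[[1]][2]]],
      FALSE
    )
    if (!isTRUE(valid)) {
      stop("step ", i, " (", s$rule, ") does not follow from its premises",
           call. = FALSE)
    }
    derived <- c(derived, s$conclusion)
  }
  if (!paste("S", trace$sub, trace$sup) %in% derived) {
    stop("trace does not conclude with the goal subsumption", call. = FALSE)
  }
  TRUE
}
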