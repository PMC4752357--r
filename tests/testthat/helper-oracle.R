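# Independent brute-force saturation oracle.
#
# Deliberately naive: repeated full passes over every class and every
# normal axiom until nothing changes, with plain character-vector sets and
# no indexing or worklist.  Shares nothing with the package's engine but
# the normal-form vocabulary, so agreement is a meaningful completeness /
# soundness check.

oracle_saturate <- function(normal_axioms, properties, original_classes) {
  prop_ids <- vapply(properties, `[[`, character(1), "id")
  names(properties) <- prop_ids
  TOPC <- "owl:Thing"

  mentioned <- character(0)
  for (ax in normal_axioms) {
    mentioned <- c(mentioned, unlist(ax[intersect(names(ax),
                                                  c("A", "B", "A1", "A2"))]))
  }
  all_cls <- setdiff(unique(c(original_classes, mentioned)), TOPC)

  S <- lapply(all_cls, function(A) c(A, TOPC))
  names(S) <- all_cls
  R <- lapply(prop_ids, function(r) character(0))  # "A B" strings
  names(R) <- prop_ids

  # reflexive-transitive super-property sets, computed by iteration
  supers <- lapply(prop_ids, function(r) r)
  names(supers) <- prop_ids
  repeat {
    grew <- FALSE
    for (r in prop_ids) {
      for (s in supers[[r]]) {
        add <- setdiff(properties[[s]]$parent_properties, supers[[r]])
        if (length(add)) {
          supers[[r]] <- c(supers[[r]], add)
          grew <- TRUE
        }
      }
    }
    if (!grew) break
  }

  repeat {
    changed <- FALSE
    for (A in all_cls) {
      for (ax in normal_axioms) {
        if (ax$form == "NF1" && ax$A %in% S[[A]] &&
            !(ax$B %in% S[[A]])) {
          S[[A]] <- c(S[[A]], ax$B)
          changed <- TRUE
        } else if (ax$form == "NF2" && ax$A1 %in% S[[A]] &&
                   ax$A2 %in% S[[A]] && !(ax$B %in% S[[A]])) {
          S[[A]] <- c(S[[A]], ax$B)
          changed <- TRUE
        } else if (ax$form == "NF3" && ax$A %in% S[[A]]) {
          pair <- paste(A, ax$B)
          if (!(pair %in% R[[ax$r]])) {
            R[[ax$r]] <- c(R[[ax$r]], pair)
            changed <- TRUE
          }
        }
      }
    }
    for (ax in normal_axioms) {
      if (ax$form != "NF4") next
      for (pair in R[[ax$r]]) {
        ab <- strsplit(pair, " ", fixed = TRUE)[[1]]
        if (ax$A %in% S[[ab[2]]] && !(ax$B %in% S[[ab[1]]])) {
          S[[ab[1]]] <- c(S[[ab[1]]], ax$B)
          changed <- TRUE
        }
      }
    }
    for (r in prop_ids) {
      if (properties[[r]]$is_transitive) {
        for (p1 in R[[r]]) {
          for (p2 in R[[r]]) {
            a <- strsplit(p1, " ", fixed = TRUE)[[1]]
            b <- strsplit(p2, " ", fixed = TRUE)[[1]]
            if (a[2] == b[1]) {
              pair <- paste(a[1], b[2])
              if (!(pair %in% R[[r]])) {
                R[[r]] <- c(R[[r]], pair)
                changed <- TRUE
              }
            }
          }
        }
      }
      for (s in setdiff(supers[[r]], r)) {
        add <- setdiff(R[[r]], R[[s]])
        if (length(add)) {
          R[[s]] <- c(R[[s]], add)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  originals <- setdiff(original_classes, TOPC)
  reported <- c(originals, TOPC)
  subsumers <- lapply(originals, function(A) sort(intersect(S[[A]], reported)))
  names(subsumers) <- originals
  role_pairs <- lapply(prop_ids, function(r) {
    keep <- vapply(R[[r]], function(pair) {
      ab <- strsplit(pair, " ", fixed = TRUE)[[1]]
      all(ab %in% originals)
    }, logical(1))
    sort(unname(R[[r]][keep]))
  })
  names(role_pairs) <- prop_ids
  list(subsumers = subsumers, role_pairs = role_pairs)
}

# package saturation reshaped for comparison with the oracle
reported_views <- function(sat) {
  list(
    subsumers = sat$subsumers[sort(names(sat$subsumers))],
    role_pairs = lapply(sat$role_pairs, function(df) {
      sort(paste(df$sub, df$obj))
    })
  )
}

expect_same_saturation <- function(sat, oracle) {
  rv <- reported_views(sat)
  expect_identical(rv$subsumers[sort(names(rv$subsumers))],
                   oracle$subsumers[sort(names(oracle$subsumers))])
  expect_identical(rv$role_pairs[sort(names(rv$role_pairs))],
                   oracle$role_pairs[sort(names(oracle$role_pairs))])
}
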