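#' Read and write the OBO-dialect exchange format
#'
#' The package's flat-file format is a UTF-8 OBO dialect: standard `[Term]`
#' stanzas (`id`, `name`, `def`, `synonym`, `xref`, `is_a`,
#' `relationship: <prop> <CURIE>`, `intersection_of`) and `[Typedef]`
#' stanzas (`id`, `name`, `synonym`, `is_transitive`, `is_a`), plus two
#' dialect extensions needed for the logic the standard stanzas cannot
#' carry:
#'
#' * `[gci]` stanzas with `sub:` / `sup:` expression strings hold general
#'   class inclusions such as "anything innervated by the trigeminal nerve
#'   develops from branchial arch 1";
#' * an `equivalent_to:` Term tag holds equivalence definitions that are
#'   not a plain conjunction of named classes and simple existentials
#'   (`intersection_of` lines may omit a named genus, since muscle
#'   definitions are often pure conjunctions of existentials).
#'
#' Expression strings use the DL-query grammar ([parse_expression()]).
#' Unknown Term/Typedef tags are preserved verbatim as opaque annotations.
#' `write_obo()` output is deterministic: stanzas sorted by CURIE, tags in
#' fixed order, so re-serializing a freshly read file is byte-identical.
#'
#' @param path file path.
#' @return `read_obo()` returns a validated [ontology()].
#' @examples
#' ont <- build_fixture()
#' f <- tempfile(fileext = ".obo")
#' write_obo(ont, f)
#' ont2 <- read_obo(f)
#' length(ont2$classes) == length(ont$classes)
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  stanzas <- split_stanzas(lines)

  header <- stanzas$header
  name <- "ontology"
  for (tl in header) {
    if (grepl("^ontology:", tl$text)) {
      name <- trimws(sub("^ontology:", "", tl$text))
    }
  }

  classes <- list()
  properties <- list()
  gci_raw <- list()
  eq_raw <- list()      # (id, expression string, line)
  isa_raw <- list()     # (id, target, line)
  rel_raw <- list()     # (id, prop, target, line)
  ix_raw <- list()      # (id, list of lines, line)

  for (st in stanzas$stanzas) {
    tags <- parse_stanza_tags(st)
    if (st$kind == "Term") {
      id <- required_tag(tags, "id", st)
      nm <- required_tag(tags, "name", st)
      syns <- vapply(tags$all[tags$keys == "synonym"],
                     function(t) parse_synonym(t), character(1))
      xr <- unlist(tags$all[tags$keys == "xref"])
      defv <- tags$all[tags$keys == "def"]
      text_def <- def_source <- NULL
      if (length(defv)) {
        d <- parse_def(defv[[1]], st)
        text_def <- d$text
        def_source <- d$source
      }
      known <- c("id", "name", "def", "synonym", "xref", "is_a",
                 "relationship", "intersection_of", "equivalent_to")
      cl <- ontology_class(id, nm, synonyms = syns,
                           xrefs = if (length(xr)) xr else character(0),
                           text_def = text_def, def_source = def_source)
      opaque <- unlist(st$lines[!(tags$keys %in% known)], use.names = FALSE)
      opaque <- setdiff(opaque, character(0))
      if (length(opaque)) attr(cl, "opaque") <- opaque
      classes[[length(classes) + 1L]] <- cl

      for (i in which(tags$keys == "is_a")) {
        isa_raw[[length(isa_raw) + 1L]] <-
          list(id = id, target = trimws(tags$all[[i]]), line = st$line_nos[i])
      }
      for (i in which(tags$keys == "relationship")) {
        parts <- strsplit(trimws(tags$all[[i]]), "[[:space:]]+")[[1]]
        if (length(parts) != 2L) {
          stop("malformed relationship tag at line ", st$line_nos[i],
               call. = FALSE)
        }
        rel_raw[[length(rel_raw) + 1L]] <-
          list(id = id, prop = parts[1], target = parts[2],
               line = st$line_nos[i])
      }
      ix <- which(tags$keys == "intersection_of")
      if (length(ix)) {
        ix_raw[[length(ix_raw) + 1L]] <-
          list(id = id, lines = tags$all[ix], line = st$line_nos[ix[1]])
      }
      for (i in which(tags$keys == "equivalent_to")) {
        eq_raw[[length(eq_raw) + 1L]] <-
          list(id = id, expr = trimws(tags$all[[i]]), line = st$line_nos[i])
      }
    } else if (st$kind == "Typedef") {
      id <- required_tag(tags, "id", st)
      nm <- required_tag(tags, "name", st)
      trans <- any(tags$keys == "is_transitive" &
                   trimws(unlist(tags$all)) == "true")
      parents <- trimws(unlist(tags$all[tags$keys == "is_a"]))
      syns <- vapply(tags$all[tags$keys == "synonym"],
                     function(t) parse_synonym(t), character(1))
      properties[[length(properties) + 1L]] <-
        object_property(id, nm, is_transitive = trans,
                        parent_properties = if (length(parents)) parents
                                            else character(0),
                        synonyms = syns)
    } else if (st$kind == "gci") {
      sub <- tags$all[tags$keys == "sub"]
      sup <- tags$all[tags$keys == "sup"]
      if (length(sub) != 1L || length(sup) != 1L) {
        stop("malformed [gci] stanza at line ", st$start,
             ": needs exactly one sub: and one sup:", call. = FALSE)
      }
      gci_raw[[length(gci_raw) + 1L]] <-
        list(sub = trimws(sub[[1]]), sup = trimws(sup[[1]]), line = st$start)
    } else {
      stop("malformed stanza [", st$kind, "] at line ", st$start,
           call. = FALSE)
    }
  }

  # Phase 2: resolve axioms against the declared vocabulary.
  shell <- ontology(classes, properties, list(), name = name)
  axioms <- list()
  for (r in isa_raw) {
    check_declared(shell, r$target, r$line)
    axioms[[length(axioms) + 1L]] <-
      ax_subclass(ce_named(r$id), ce_named(r$target))
  }
  for (r in rel_raw) {
    check_declared_prop(shell, r$prop, r$line)
    check_declared(shell, r$target, r$line)
    axioms[[length(axioms) + 1L]] <-
      ax_subclass(ce_named(r$id), ce_some(r$prop, ce_named(r$target)))
  }
  for (r in ix_raw) {
    conj <- lapply(r$lines, function(tl) {
      parts <- strsplit(trimws(tl), "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        check_declared(shell, parts[1], r$line)
        ce_named(parts[1])
      } else if (length(parts) == 2L) {
        check_declared_prop(shell, parts[1], r$line)
        check_declared(shell, parts[2], r$line)
        ce_some(parts[1], ce_named(parts[2]))
      } else {
        stop("malformed intersection_of tag at line ", r$line, call. = FALSE)
      }
    })
    if (length(conj) < 2L) {
      stop("intersection_of needs at least two conjuncts (line ", r$line,
           ")", call. = FALSE)
    }
    axioms[[length(axioms) + 1L]] <- ax_equivalent(r$id, ce_and(conj))
  }
  for (r in eq_raw) {
    expr <- with_line(r$line, parse_expression(r$expr, shell))
    axioms[[length(axioms) + 1L]] <- ax_equivalent(r$id, expr)
  }
  for (r in gci_raw) {
    sub <- with_line(r$line, parse_expression(r$sub, shell))
    sup <- with_line(r$line, parse_expression(r$sup, shell))
    axioms[[length(axioms) + 1L]] <- ax_subclass(sub, sup)
  }
  ontology(classes, properties, axioms, name = name)
}

check_declared <- function(ont, id, line) {
  if (!is_curie(id) || !(id %in% names(ont$classes))) {
    stop("undeclared class CURIE '", id, "' referenced at line ", line,
         call. = FALSE)
  }
}

check_declared_prop <- function(ont, id, line) {
  if (!is_curie(id) || !(id %in% names(ont$properties))) {
    stop("undeclared property CURIE '", id, "' referenced at line ", line,
         call. = FALSE)
  }
}

with_line <- function(line, expr) {
  tryCatch(expr, error = function(e) {
    stop(conditionMessage(e), " (line ", line, ")", call. = FALSE)
  })
}

split_stanzas <- function(lines) {
  header <- list()
  stanzas <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*(!.*)?$", ln)) next  # blank or comment
    m <- regmatches(ln, regexec("^\\[([^]]+)\\]\\s*$", ln))[[1]]
    if (length(m)) {
      if (!is.null(cur)) stanzas[[length(stanzas) + 1L]] <- cur
      cur <- list(kind = m[2], start = i, lines = list(),
                  line_nos = integer(0))
      next
    }
    if (!grepl("^[A-Za-z_][A-Za-z0-9_-]*:", ln)) {
      stop("malformed line ", i, ": '", ln, "'", call. = FALSE)
    }
    entry <- list(text = ln, line = i)
    if (is.null(cur)) {
      header[[length(header) + 1L]] <- entry
    } else {
      cur$lines[[length(cur$lines) + 1L]] <- ln
      cur$line_nos <- c(cur$line_nos, i)
    }
  }
  if (!is.null(cur)) stanzas[[length(stanzas) + 1L]] <- cur
  list(header = header, stanzas = stanzas)
}

parse_stanza_tags <- function(st) {
  keys <- character(length(st$lines))
  vals <- vector("list", length(st$lines))
  for (i in seq_along(st$lines)) {
    ln <- st$lines[[i]]
    colon <- regexpr(":", ln, fixed = TRUE)
    keys[i] <- substr(ln, 1L, colon - 1L)
    vals[[i]] <- trimws(substr(ln, colon + 1L, nchar(ln)))
  }
  list(keys = keys, all = vals)
}

required_tag <- function(tags, key, st) {
  v <- tags$all[tags$keys == key]
  if (length(v) != 1L) {
    stop("malformed [", st$kind, "] stanza at line ", st$start,
         ": needs exactly one '", key, "' tag", call. = FALSE)
  }
  trimws(v[[1]])
}

parse_synonym <- function(text) {
  m <- regmatches(text, regexec('^"((?:[^"\\\\]|\\\\.)*)"', text))[[1]]
  if (!length(m)) stop("malformed synonym tag: ", text, call. = FALSE)
  gsub('\\\\"', '"', m[2])
}

parse_def <- function(text, st) {
  m <- regmatches(text,
    regexec('^"((?:[^"\\\\]|\\\\.)*)"\\s*(?:\\[([^]]*)\\])?\\s*$', text))[[1]]
  if (!length(m)) {
    stop("malformed def tag at line ", st$start, ": ", text, call. = FALSE)
  }
  src <- if (nzchar(m[3])) m[3] else NULL
  list(text = gsub('\\\\"', '"', m[2]), source = src)
}

#' @rdname read_obo
#' @param ont a validated [ontology()].
#' @return `write_obo()` returns `path` invisibly.
#' @export
write_obo <- function(ont, path) {
  stopifnot(inherits(ont, "ontology"))
  validate_ontology(ont)
  out <- c("format-version: 1.2", paste0("ontology: ", ont$name))

  # Partition axioms by how the dialect expresses them.
  isa <- rel <- list()
  eqd <- list()
  gci <- list()
  for (ax in ont$axioms) {
    if (ax$variant == "equivalent") {
      eqd[[length(eqd) + 1L]] <- ax
    } else if (ax$sub$variant == "named" && ax$sup$variant == "named") {
      isa[[length(isa) + 1L]] <- ax
    } else if (ax$sub$variant == "named" && ax$sup$variant == "some" &&
               ax$sup$filler$variant == "named") {
      rel[[length(rel) + 1L]] <- ax
    } else {
      gci[[length(gci) + 1L]] <- ax
    }
  }
  isa_by <- split_by(isa, function(a) a$sub$class)
  rel_by <- split_by(rel, function(a) a$sub$class)
  eq_by <- split_by(eqd, function(a) a$cls)

  for (id in sort(names(ont$classes))) {
    cl <- ont$classes[[id]]
    out <- c(out, "", "[Term]", paste0("id: ", id),
             paste0("name: ", cl$label))
    if (!is.null(cl$text_def)) {
      src <- if (!is.null(cl$def_source)) cl$def_source else ""
      out <- c(out, paste0("def: \"", gsub('"', '\\\\"', cl$text_def),
                           "\" [", src, "]"))
    }
    for (s in sort(cl$synonyms)) {
      out <- c(out, paste0("synonym: \"", gsub('"', '\\\\"', s),
                           "\" EXACT []"))
    }
    for (x in sort(cl$xrefs)) out <- c(out, paste0("xref: ", x))
    sups <- sort(vapply(isa_by[[id]] %||% list(),
                        function(a) a$sup$class, character(1)))
    out <- c(out, paste0("is_a: ", sups, recycle0 = TRUE))
    rls <- rel_by[[id]] %||% list()
    rl_keys <- vapply(rls, function(a)
      paste(a$sup$property, a$sup$filler$class), character(1))
    out <- c(out, paste0("relationship: ", sort(rl_keys), recycle0 = TRUE))
    used_intersection <- FALSE  # one intersection_of group per stanza
    for (ax in eq_by[[id]] %||% list()) {
      lines <- if (used_intersection) NULL else
        intersection_lines(ax$definition)
      if (!is.null(lines)) {
        out <- c(out, paste0("intersection_of: ", lines))
        used_intersection <- TRUE
      } else {
        out <- c(out,
                 paste0("equivalent_to: ",
                        expression_to_string(ax$definition, ont)))
      }
    }
    op <- attr(cl, "opaque")
    if (!is.null(op)) out <- c(out, op)
  }

  for (id in sort(names(ont$properties))) {
    p <- ont$properties[[id]]
    out <- c(out, "", "[Typedef]", paste0("id: ", id),
             paste0("name: ", p$label))
    for (s in sort(p$synonyms)) {
      out <- c(out, paste0("synonym: \"", s, "\" EXACT []"))
    }
    if (p$is_transitive) out <- c(out, "is_transitive: true")
    out <- c(out, paste0("is_a: ", sort(p$parent_properties),
                         recycle0 = TRUE))
  }

  if (length(gci)) {
    strs <- lapply(gci, function(ax) {
      c(sub = expression_to_string(ax$sub, ont),
        sup = expression_to_string(ax$sup, ont))
    })
    ord <- order(vapply(strs, function(s) paste(s["sub"], s["sup"]),
                        character(1)))
    for (s in strs[ord]) {
      out <- c(out, "", "[gci]", paste0("sub: ", s[["sub"]]),
               paste0("sup: ", s[["sup"]]))
    }
  }

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, useBytes = TRUE)
  invisible(path)
}

# intersection_of lines for a definition expressible in standard OBO:
# a conjunction (>= 2 conjuncts) of named classes and simple existentials.
# Returns NULL when the definition needs the equivalent_to escape hatch.
intersection_lines <- function(def) {
  if (def$variant != "and") return(NULL)
  lines <- character(0)
  for (c_ in def$conjuncts) {
    if (c_$variant == "named") {
      lines <- c(lines, c_$class)
    } else if (c_$variant == "some" && c_$filler$variant == "named") {
      lines <- c(lines, paste(c_$property, c_$filler$class))
    } else {
      return(NULL)
    }
  }
  lines
}

split_by <- function(lst, key_fn) {
  if (!length(lst)) return(list())
  keys <- vapply(lst, key_fn, character(1))
  split(lst, keys)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
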