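#' Ontology-derived search lexicon
#'
#' A lexicon is a "category" in the Textpresso sense: the bag of phrases —
#' labels and synonyms — of a chosen class and all classes subsumed by it.
#' Because subsumption is computed by the reasoner, the category for
#' 'trigeminal muscle' automatically contains "temporalis muscle",
#' "masseter muscle" and every other phrase of a muscle *classified* under
#' it, which is exactly the expert knowledge keyword engines lack.
#'
#' @param ont an [ontology()].
#' @param sat the matching `saturation` from [classify()].
#' @param category label, synonym or CURIE of the category's root class.
#' @return an object of class `lexicon`: a named character vector mapping
#'   case-folded phrases to class CURIEs, ordered longest phrase first.
#' @examples
#' ont <- build_fixture()
#' sat <- classify(ont)
#' lex <- build_lexicon(ont, sat, "Trigeminal muscle")
#' "temporalis muscle" %in% names(lex)
#' @export
build_lexicon <- function(ont, sat, category) {
  stopifnot(inherits(ont, "ontology"), inherits(sat, "saturation"))
  root <- resolve_label(ont, category)
  members <- names(ont$classes)[vapply(names(ont$classes), function(A) {
    root %in% sat$subsumers[[A]]
  }, logical(1))]
  phrases <- character(0)
  targets <- character(0)
  for (id in members) {
    cl <- ont$classes[[id]]
    ph <- fold_phrase(c(cl$label, cl$synonyms))
    phrases <- c(phrases, ph)
    targets <- c(targets, rep(id, length(ph)))
  }
  dup <- phrases[duplicated(phrases)]
  collide <- unique(dup[vapply(dup, function(p) {
    length(unique(targets[phrases == p])) > 1L
  }, logical(1))])
  if (length(collide)) {
    stop("ambiguous lexicon phrases map to multiple classes: ",
         paste(collide, collapse = "; "), call. = FALSE)
  }
  keep <- !duplicated(phrases)
  lex <- targets[keep]
  names(lex) <- phrases[keep]
  lex <- lex[order(-nchar(names(lex)), names(lex))]
  members <- list(sort(members))
  names(members) <- root
  structure(lex, class = "lexicon", category = root, members = members)
}

# fold a phrase the same way document text is tokenized, so lexicon
# phrases and re-extracted spans compare bit-exactly
fold_phrase <- function(x) {
  vapply(x, function(p) paste(tokenize_text(p)$token, collapse = " "),
         character(1), USE.NAMES = FALSE)
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon> category ", attr(x, "category"), ": ", length(x),
      " phrases over ", length(unique(unclass(x))), " classes\n", sep = "")
  invisible(x)
}

#' Create a document
#'
#' @param doc_id unique identifier.
#' @param title document title.
#' @param body non-empty full text.
#' @param truth_labels for generated corpora: CURIEs of the classes the
#'   document genuinely mentions (ground truth for retrieval scoring).
#' @return an object of class `document`.
#' @export
document <- function(doc_id, title, body, truth_labels = character(0)) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id),
            is.character(body), length(body) == 1L, nzchar(body))
  structure(list(doc_id = doc_id, title = title, body = body,
                 truth_labels = as.character(truth_labels)),
            class = "document")
}

# Deterministic sentence splitting: terminator (.?!) + whitespace +
# capital letter or digit.  No ML splitter: reproducibility over
# linguistic perfection.
split_sentences <- function(text) {
  parts <- strsplit(text, "(?<=[.?!])\\s+(?=[A-Z0-9])", perl = TRUE)[[1]]
  parts[nzchar(trimws(parts))]
}

# Tokenize: case-fold, keep intra-word hyphens, drop other punctuation.
# Returns token plus character span into the input.
tokenize_text <- function(text) {
  m <- gregexpr("[[:alnum:]]+(?:-[[:alnum:]]+)*", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  toks <- regmatches(text, gregexpr("[[:alnum:]]+(?:-[[:alnum:]]+)*",
                                    text))[[1]]
  data.frame(token = tolower(toks), start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L,
             stringsAsFactors = FALSE)
}

#' Index a corpus for category-aware search
#'
#' Splits each document into sentences, tokenizes deterministically, and
#' tags phrase occurrences against one or more lexicons (merged; phrase
#' collisions across lexicons are a build error).  Tagging is case-folded
#' longest-match over token n-grams with no overlapping tags.
#'
#' @param documents list of [document()] objects.
#' @param lexicons a single `lexicon` or list of lexicons.
#' @return an object of class `corpus_index` with `sentences` (data.frame:
#'   `doc_id`, `sentence`, `text`) , `tokens`, and `tags` (postings:
#'   `doc_id`, `sentence`, `curie`, `phrase`, `start`, `end` character
#'   span into the sentence text).
#' @export
index_corpus <- function(documents, lexicons = list()) {
  stopifnot(is.list(documents))
  if (inherits(lexicons, "lexicon")) lexicons <- list(lexicons)
  lex <- merge_lexicons(lexicons)
  ids <- vapply(documents, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id: ", paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "), call. = FALSE)
  }

  sent_rows <- list()
  tag_rows <- list()
  tok_rows <- list()
  for (doc in documents) {
    sents <- split_sentences(doc$body)
    for (si in seq_along(sents)) {
      stext <- sents[si]
      toks <- tokenize_text(stext)
      sent_rows[[length(sent_rows) + 1L]] <-
        data.frame(doc_id = doc$doc_id, sentence = si, text = stext,
                   stringsAsFactors = FALSE)
      if (nrow(toks)) {
        tok_rows[[length(tok_rows) + 1L]] <-
          data.frame(doc_id = doc$doc_id, sentence = si,
                     position = seq_len(nrow(toks)), token = toks$token,
                     stringsAsFactors = FALSE)
      }
      for (tg in tag_sentence(toks, lex)) {
        tag_rows[[length(tag_rows) + 1L]] <-
          data.frame(doc_id = doc$doc_id, sentence = si,
                     curie = tg$curie, phrase = tg$phrase,
                     start = tg$start, end = tg$end,
                     stringsAsFactors = FALSE)
      }
    }
  }
  empty_tags <- data.frame(doc_id = character(0), sentence = integer(0),
                           curie = character(0), phrase = character(0),
                           start = integer(0), end = integer(0),
                           stringsAsFactors = FALSE)
  structure(list(
    sentences = if (length(sent_rows)) do.call(rbind, sent_rows) else
      data.frame(doc_id = character(0), sentence = integer(0),
                 text = character(0), stringsAsFactors = FALSE),
    tokens = if (length(tok_rows)) do.call(rbind, tok_rows) else
      data.frame(doc_id = character(0), sentence = integer(0),
                 position = integer(0), token = character(0),
                 stringsAsFactors = FALSE),
    tags = if (length(tag_rows)) do.call(rbind, tag_rows) else empty_tags,
    lexicon = lex,
    documents = documents
  ), class = "corpus_index")
}

merge_lexicons <- function(lexicons) {
  if (!length(lexicons)) {
    return(structure(character(0), class = "lexicon", category = NA))
  }
  phrases <- unlist(lapply(lexicons, names))
  targets <- unlist(lapply(lexicons, unclass))
  conflict <- unique(phrases[vapply(seq_along(phrases), function(i) {
    any(phrases == phrases[i] & targets != targets[i])
  }, logical(1))])
  if (length(conflict)) {
    stop("lexicons overlap on phrases with different classes: ",
         paste(conflict, collapse = "; "), call. = FALSE)
  }
  keep <- !duplicated(phrases)
  lex <- targets[keep]
  names(lex) <- phrases[keep]
  lex <- lex[order(-nchar(names(lex)), names(lex))]
  members <- do.call(c, lapply(lexicons, function(l) {
    attr(l, "members") %||% list()
  }))
  structure(lex, class = "lexicon",
            category = unname(vapply(lexicons, attr, character(1),
                                     "category")),
            members = members)
}

# longest-match, non-overlapping phrase tagging over the token sequence
tag_sentence <- function(toks, lex) {
  out <- list()
  if (!nrow(toks) || !length(lex)) return(out)
  lex_tokens <- strsplit(names(lex), " ", fixed = TRUE)
  maxlen <- max(lengths(lex_tokens))
  i <- 1L
  n <- nrow(toks)
  while (i <= n) {
    matched <- FALSE
    for (L in seq(min(maxlen, n - i + 1L), 1L)) {
      cand <- paste(toks$token[i:(i + L - 1L)], collapse = " ")
      hit <- match(cand, names(lex))
      if (!is.na(hit)) {
        out[[length(out) + 1L]] <- list(
          curie = unname(unclass(lex)[hit]), phrase = cand,
          start = toks$start[i], end = toks$end[i + L - 1L])
        i <- i + L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  out
}

#' @export
print.corpus_index <- function(x, ...) {
  cat("<corpus_index> ", length(x$documents), " documents, ",
      nrow(x$sentences), " sentences, ", nrow(x$tags),
      " category tags\n", sep = "")
  invisible(x)
}

#' Search an indexed corpus
#'
#' Two retrieval modes over the same index:
#'
#' * `mode = "keyword"` emulates a literal search engine: every query item
#'   (keywords *and* category roots, by their literal phrase) must occur
#'   verbatim as a token sequence.
#' * `mode = "semantic"` expands each category through the ontology: any
#'   lexicon phrase of the category — any label or synonym of any class
#'   classified under it — counts as a match.
#'
#' `scope = "sentence"` requires all query items to co-occur in one
#' sentence; `scope = "document"` anywhere in the document.  Results are
#' ranked by match count, ties broken by `doc_id`.
#'
#' @param index a `corpus_index`.
#' @param keywords character vector of literal keywords/phrases.
#' @param categories character vector of category phrases or CURIEs; in
#'   semantic mode each must be covered by the index's lexicon.
#' @param mode `"semantic"` or `"keyword"`.
#' @param scope `"sentence"` or `"document"`.
#' @return a data.frame of hits: `doc_id`, `matches` (match count),
#'   `matched_phrases` (semicolon-joined), sorted by rank.
#' @export
search_corpus <- function(index, keywords = character(0),
                          categories = character(0),
                          mode = c("semantic", "keyword"),
                          scope = c("sentence", "document")) {
  stopifnot(inherits(index, "corpus_index"))
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  if (!length(keywords) && !length(categories)) {
    stop("query needs at least one keyword or category", call. = FALSE)
  }

  lex <- index$lexicon
  cat_curies <- character(0)
  if (length(categories)) {
    cat_curies <- vapply(categories, function(ctg) {
      if (is_curie(ctg)) ctg
      else {
        hit <- match(fold_phrase(ctg), names(lex))
        if (is.na(hit)) {
          stop("category '", ctg, "' is not covered by the index lexicon",
               call. = FALSE)
        }
        unname(unclass(lex)[hit])
      }
    }, character(1))
    if (mode == "semantic") {
      missing <- setdiff(cat_curies, unclass(lex))
      if (length(missing)) {
        stop("category queried without its lexicon: ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
    }
  }

  # per (doc, sentence): which query items match, with which phrases
  items <- c(
    lapply(keywords, function(k) list(kind = "keyword", value = k)),
    lapply(seq_along(cat_curies), function(i) {
      list(kind = "category", value = cat_curies[i],
           literal = categories[i])
    })
  )
  sent_keys <- paste(index$sentences$doc_id, index$sentences$sentence)
  match_mat <- matrix(FALSE, nrow = nrow(index$sentences),
                      ncol = length(items))
  phrase_mat <- matrix("", nrow = nrow(index$sentences),
                       ncol = length(items))
  for (j in seq_along(items)) {
    it <- items[[j]]
    if (it$kind == "keyword" || mode == "keyword") {
      literal <- if (it$kind == "keyword") it$value else it$literal
      hit <- sentences_with_phrase(index, literal)
      match_mat[hit, j] <- TRUE
      phrase_mat[hit, j] <- fold_phrase(literal)
    } else {
      # semantic category item: expand to all phrases tagged to any class
      # subsumed into the category (the lexicon already is that set)
      tg <- index$tags[index$tags$curie %in% category_members(index, it$value), ,
                       drop = FALSE]
      if (nrow(tg)) {
        keys <- paste(tg$doc_id, tg$sentence)
        idx <- match(keys, sent_keys)
        for (k in seq_along(idx)) {
          match_mat[idx[k], j] <- TRUE
          phrase_mat[idx[k], j] <-
            if (nzchar(phrase_mat[idx[k], j])) {
              paste(phrase_mat[idx[k], j], tg$phrase[k], sep = ";")
            } else tg$phrase[k]
        }
      }
    }
  }

  doc_ids <- vapply(index$documents, `[[`, character(1), "doc_id")
  rows <- list()
  for (d in doc_ids) {
    in_doc <- index$sentences$doc_id == d
    if (!any(in_doc)) next
    if (scope == "sentence") {
      full <- in_doc & rowSums(match_mat) == length(items) &
        apply(match_mat, 1, all)
      n_match <- sum(full)
      if (n_match == 0L) next
      phrases <- unique(unlist(strsplit(phrase_mat[full, , drop = FALSE],
                                        ";", fixed = TRUE)))
    } else {
      per_item <- apply(match_mat[in_doc, , drop = FALSE], 2, any)
      if (!all(per_item)) next
      n_match <- sum(match_mat[in_doc, , drop = FALSE])
      phrases <- unique(unlist(strsplit(phrase_mat[in_doc, , drop = FALSE],
                                        ";", fixed = TRUE)))
    }
    phrases <- sort(phrases[nzchar(phrases)])
    rows[[length(rows) + 1L]] <-
      data.frame(doc_id = d, matches = n_match,
                 matched_phrases = paste(phrases, collapse = ";"),
                 stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(doc_id = character(0), matches = integer(0),
                      matched_phrases = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- res[order(-res$matches, res$doc_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# expansion set of a category CURIE inside an index: the classes the
# lexicon collected under that category root (recorded at build time); a
# non-root class used as a category expands to itself only, since the
# index carries no saturation of its own.
category_members <- function(index, root) {
  members <- attr(index$lexicon, "members")
  if (!is.null(members) && root %in% names(members)) {
    return(members[[root]])
  }
  root
}

# sentence rows (indices) containing the literal phrase as consecutive
# tokens
sentences_with_phrase <- function(index, phrase) {
  ptoks <- tokenize_text(phrase)$token
  if (!length(ptoks)) return(integer(0))
  hits <- integer(0)
  sk <- paste(index$tokens$doc_id, index$tokens$sentence)
  sent_keys <- paste(index$sentences$doc_id, index$sentences$sentence)
  for (i in seq_len(nrow(index$sentences))) {
    toks <- index$tokens$token[sk == sent_keys[i]]
    n <- length(toks) - length(ptoks) + 1L
    if (n < 1L) next
    for (s in seq_len(n)) {
      if (all(toks[s:(s + length(ptoks) - 1L)] == ptoks)) {
        hits <- c(hits, i)
        break
      }
    }
  }
  hits
}
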