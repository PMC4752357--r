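#' Specification for a synthetic benchmark corpus
#'
#' The generator emulates the abstracts an anatomy-literature corpus
#' contains: *relevant* documents mention a muscle from the target
#' category by a randomly chosen phrase (label, or a synonym with
#' probability `synonym_probability`) together with a topical keyword;
#' *distractor* documents contain the query's individual words ("muscle",
#' "innervated", "trigeminal", "nerve", the topic word) in non-matching
#' arrangements and never contain a lexicon phrase.  Ground-truth class
#' labels are attached to every document, so retrieval can be scored
#' exactly.
#'
#' @param n_relevant,n_distractor document counts (>= 0).
#' @param synonym_probability probability in `[0, 1]` that a relevant
#'   mention uses a synonym instead of the primary label.
#' @param target_category label, synonym or CURIE of the category whose
#'   members relevant documents mention.
#' @param topic_keyword a topical word included in every relevant
#'   document and echoed (in non-matching contexts) by distractors.
#' @param seed integer seed; equal seeds give byte-identical corpora.
#' @return an object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_relevant, n_distractor, synonym_probability = 0,
                        target_category, topic_keyword = "mastication",
                        seed = 1L) {
  stopifnot(n_relevant >= 0, n_distractor >= 0,
            synonym_probability >= 0, synonym_probability <= 1)
  structure(list(n_relevant = as.integer(n_relevant),
                 n_distractor = as.integer(n_distractor),
                 synonym_probability = synonym_probability,
                 target_category = target_category,
                 topic_keyword = topic_keyword,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

RELEVANT_TEMPLATES <- c(
  "Electromyographic activity of the %s was recorded during %s in awake animals.",
  "We measured in vivo strain in the %s while the animals performed %s.",
  "Motor unit recruitment in the %s varied systematically with %s rate.",
  "Fiber type composition of the %s reflects its role in %s.",
  "Stimulation of the %s altered jaw kinematics throughout %s."
)

DISTRACTOR_TEMPLATES <- c(
  "Trigeminal neuralgia is a disorder of the nerve that worsens during %s.",
  "The graft was attached to the mucosa near the mandible, sparing each muscle flap and nerve bundle.",
  "A muscle biopsy from the limb was compared with nerve conduction data unrelated to %s.",
  "Innervated skin grafts were attached over the mandible; no muscle tissue was sampled during %s.",
  "The nerve growth factor assay used smooth muscle cells, with %s cycles logged only as metadata."
)

#' Generate a synthetic corpus
#'
#' Seed-deterministic (the caller's RNG state is preserved).  Relevant
#' documents draw a member class of the target category uniformly, then a
#' phrase: a synonym of the class with probability
#' `spec$synonym_probability` (uniform over its synonyms), otherwise its
#' primary label.  Asking for synonym mentions of a category none of whose
#' members has a synonym is a spec error.  Each generated document carries
#' `truth_labels` (the mentioned class, or empty for distractors); the
#' phrase actually used is attached as attribute `phrase_used`.
#'
#' @param spec a [corpus_spec()].
#' @param ont an [ontology()].
#' @param sat the matching `saturation` (defines category membership).
#' @return a list of [document()] objects.
#' @examples
#' ont <- build_fixture()
#' sat <- classify(ont)
#' docs <- generate_corpus(
#'   corpus_spec(5, 5, 0.5, "Trigeminal muscle", seed = 42), ont, sat)
#' length(docs)
#' @export
generate_corpus <- function(spec, ont, sat) {
  stopifnot(inherits(spec, "corpus_spec"))
  lex <- build_lexicon(ont, sat, spec$target_category)
  members <- attr(lex, "members")[[1]]
  has_syn <- vapply(members, function(id) {
    length(ont$classes[[id]]$synonyms) > 0L
  }, logical(1))
  if (spec$synonym_probability > 0 && !any(has_syn)) {
    stop("synonym_probability > 0 but no class under '",
         spec$target_category, "' has synonyms", call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  docs <- vector("list", spec$n_relevant + spec$n_distractor)
  for (i in seq_len(spec$n_relevant)) {
    cls_id <- members[[sample.int(length(members), 1L)]]
    cl <- ont$classes[[cls_id]]
    use_syn <- length(cl$synonyms) > 0L &&
      stats::runif(1) < spec$synonym_probability
    phrase <- if (use_syn) {
      cl$synonyms[[sample.int(length(cl$synonyms), 1L)]]
    } else {
      cl$label
    }
    tmpl <- RELEVANT_TEMPLATES[[sample.int(length(RELEVANT_TEMPLATES), 1L)]]
    body <- paste(
      sprintf(tmpl, phrase, spec$topic_keyword),
      "Methods followed standard in vivo physiological protocols.")
    d <- document(sprintf("rel-%04d", i),
                  title = sprintf("Feeding physiology study %d", i),
                  body = body, truth_labels = cls_id)
    attr(d, "phrase_used") <- phrase
    attr(d, "synonym_used") <- use_syn
    docs[[i]] <- d
  }
  for (i in seq_len(spec$n_distractor)) {
    tmpl <- DISTRACTOR_TEMPLATES[[
      sample.int(length(DISTRACTOR_TEMPLATES), 1L)]]
    body <- if (grepl("%s", tmpl, fixed = TRUE)) {
      sprintf(tmpl, spec$topic_keyword)
    } else {
      tmpl
    }
    docs[[spec$n_relevant + i]] <-
      document(sprintf("dis-%04d", i),
               title = sprintf("Unrelated report %d", i), body = body)
  }

  # construction guard: distractors must contain no lexicon phrase
  for (d in docs[seq_len(spec$n_distractor) + spec$n_relevant]) {
    for (s in split_sentences(d$body)) {
      if (length(tag_sentence(tokenize_text(s), lex))) {
        stop("internal error: distractor template contains a lexicon phrase",
             call. = FALSE)
      }
    }
  }
  docs
}

#' Compare keyword and semantic retrieval on a truth-labelled corpus
#'
#' For each query, runs the same keyword+category formulation in both
#' modes of [search_corpus()] and scores the returned document sets
#' against the generator's ground truth (a document is relevant iff one of
#' its `truth_labels` belongs to the queried category).
#'
#' @param index a `corpus_index` over truth-labelled documents.
#' @param queries list of queries; each a list with elements `keywords`
#'   (character, possibly empty) and `category` (one category phrase or
#'   CURIE).
#' @param scope passed to [search_corpus()].
#' @return a data.frame with one row per query and mode: `query`, `mode`,
#'   `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
compare_engines <- function(index, queries, scope = "document") {
  stopifnot(inherits(index, "corpus_index"))
  truths <- lapply(index$documents, `[[`, "truth_labels")
  if (!any(lengths(truths) > 0L)) {
    stop("corpus has no truth labels; generate the corpus with ",
         "generate_corpus() or attach labels", call. = FALSE)
  }
  doc_ids <- vapply(index$documents, `[[`, character(1), "doc_id")
  rows <- list()
  for (q in queries) {
    root <- if (is_curie(q$category)) q$category else {
      hit <- match(fold_phrase(q$category), names(index$lexicon))
      if (is.na(hit)) {
        stop("category '", q$category, "' not covered by the index lexicon",
             call. = FALSE)
      }
      unname(unclass(index$lexicon)[hit])
    }
    members <- category_members(index, root)
    relevant <- doc_ids[vapply(truths, function(t) {
      any(t %in% members)
    }, logical(1))]
    for (mode in c("keyword", "semantic")) {
      res <- search_corpus(index, keywords = q$keywords %||% character(0),
                           categories = q$category, mode = mode,
                           scope = scope)
      got <- res$doc_id
      tp <- length(intersect(got, relevant))
      fp <- length(setdiff(got, relevant))
      fn <- length(setdiff(relevant, got))
      rows[[length(rows) + 1L]] <- data.frame(
        query = paste(c(q$keywords, q$category), collapse = " + "),
        mode = mode, tp = tp, fp = fp, fn = fn,
        precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
        recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read and write JSON-lines corpora
#'
#' One JSON object per line: `{"doc_id": ..., "title": ..., "body": ...,
#' "truth_labels": [...]}`.
#'
#' @param documents list of [document()] objects.
#' @param path file path.
#' @return `read_corpus()` returns a list of documents; `write_corpus()`
#'   returns `path` invisibly.
#' @export
write_corpus <- function(documents, path) {
  lines <- vapply(documents, function(d) {
    jsonlite::toJSON(list(doc_id = d$doc_id, title = d$title,
                          body = d$body,
                          truth_labels = as.list(d$truth_labels)),
                     auto_unbox = TRUE)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    document(x$doc_id, x$title %||% "", x$body,
             truth_labels = unlist(x$truth_labels) %||% character(0))
  })
}
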