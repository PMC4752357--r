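#' Compact URIs (CURIEs)
#'
#' Classes and properties are identified by CURIEs of the form
#' `PREFIX:NNNNNNN` (e.g. `MFMO:0000066`), the compact form of OBO PURLs
#' such as `http://purl.obolibrary.org/obo/MFMO_0000066`.  CURIEs are plain
#' character strings; comparison is string equality.
#'
#' @param x character vector of candidate CURIE strings.
#' @return `curie_parse()` returns a data.frame with columns `prefix` and
#'   `local_id`; `is_curie()` a logical vector; `curie()` the rendered string.
#' @examples
#' curie("MFMO", "0000066")
#' curie_parse("MFMO:0000066")
#' curie_from_purl("http://purl.obolibrary.org/obo/MFMO_0000066")
#' @name curie
NULL

CURIE_RE <- "^[A-Za-z_][A-Za-z0-9_.]*:[A-Za-z0-9_]+$"

#' @rdname curie
#' @param prefix namespace token.
#' @param local_id local identifier (zero-padded numeric string by OBO
#'   convention, but any token is accepted).
#' @export
curie <- function(prefix, local_id) {
  stopifnot(is.character(prefix), is.character(local_id))
  out <- paste0(prefix, ":", local_id)
  bad <- !grepl(CURIE_RE, out)
  if (any(bad)) {
    stop("invalid CURIE components: ", paste(out[bad], collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @rdname curie
#' @export
is_curie <- function(x) {
  is.character(x) & grepl(CURIE_RE, x)
}

#' @rdname curie
#' @export
curie_parse <- function(x) {
  bad <- !is_curie(x)
  if (any(bad)) {
    stop("not a CURIE: ", paste(x[bad], collapse = ", "), call. = FALSE)
  }
  pieces <- regmatches(x, regexpr(":", x, fixed = TRUE), invert = TRUE)
  data.frame(
    prefix = vapply(pieces, `[`, character(1), 1L),
    local_id = vapply(pieces, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

#' @rdname curie
#' @param purl an OBO PURL (`http://purl.obolibrary.org/obo/PREFIX_NNNNNNN`).
#' @export
curie_from_purl <- function(purl) {
  local <- sub("^https?://purl\\.obolibrary\\.org/obo/", "", purl)
  if (identical(local, purl) || !grepl("^[A-Za-z]+_[A-Za-z0-9]+$", local)) {
    stop("not an OBO PURL: ", purl, call. = FALSE)
  }
  sub("_", ":", local)
}

#' @rdname curie
#' @param id a CURIE string.
#' @export
curie_to_purl <- function(id) {
  p <- curie_parse(id)
  paste0("http://purl.obolibrary.org/obo/", p$prefix, "_", p$local_id)
}

# Implicit top concept; every class is subsumed by it.
TOP <- "owl:Thing"
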