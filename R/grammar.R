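#' Class-expression grammar
#'
#' One grammar serves both the DL query strings (Protege DL Query tab
#' syntax, e.g. `'muscle organ' and ('attached to' some 'mandible')`) and
#' the expression strings stored in the flat-file `[gci]` / `equivalent_to:`
#' tags, so file round trips and query parsing share a single code path.
#'
#' ```
#' expr    := primary ( "and" primary )*
#' primary := atom | atom "some" primary | "(" expr ")"
#' atom    := quoted name | CURIE
#' ```
#'
#' Quoted names accept straight and typographic single quotes and double
#' quotes.  An atom in property position (before `some`) is resolved
#' against property labels (space/underscore spellings equivalent); all
#' other atoms are resolved via [resolve_label()], so synonyms are valid
#' query vocabulary.
#'
#' @param text the expression string.
#' @param ont the ontology whose labels resolve the quoted names.
#' @return `parse_expression()` returns a canonical `class_expression`.
#' @examples
#' ont <- build_fixture()
#' parse_expression("'muscle organ' and ('attached to' some 'mandible')", ont)
#' @export
parse_expression <- function(text, ont) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- tokenize_expression(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- parse_expr(st, ont)
  if (st$pos <= nrow(st$toks)) {
    stop("syntax error at position ", st$toks$start[st$pos],
         ": unexpected '", st$toks$text[st$pos], "'", call. = FALSE)
  }
  ce_canonical(expr)
}

# Tokens: quoted names, CURIEs/bare words, parentheses.
tokenize_expression <- function(text) {
  text <- gsub("[‘’]", "'", text)
  text <- gsub("[“”]", "\"", text)
  pat <- "'[^']*'|\"[^\"]*\"|\\(|\\)|[^\\s()]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) stop("empty expression", call. = FALSE)
  raw <- regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
  starts <- as.integer(m)
  type <- character(length(raw))
  val <- raw
  for (i in seq_along(raw)) {
    t <- raw[i]
    if (t == "(") type[i] <- "lparen"
    else if (t == ")") type[i] <- "rparen"
    else if (grepl("^['\"]", t)) {
      type[i] <- "name"
      val[i] <- substr(t, 2L, nchar(t) - 1L)
    } else if (tolower(t) == "and") type[i] <- "and"
    else if (tolower(t) == "some") type[i] <- "some"
    else type[i] <- "name"  # bare CURIE or single-word name
  }
  data.frame(text = raw, type = type, value = val, start = starts,
             stringsAsFactors = FALSE)
}

peek <- function(st) if (st$pos <= nrow(st$toks)) st$toks$type[st$pos] else "eof"

advance <- function(st) {
  tok <- st$toks[st$pos, ]
  st$pos <- st$pos + 1L
  tok
}

parse_expr <- function(st, ont) {
  parts <- list(parse_primary(st, ont))
  while (peek(st) == "and") {
    advance(st)
    parts <- c(parts, list(parse_primary(st, ont)))
  }
  if (length(parts) == 1L) parts[[1]] else ce_and(parts)
}

parse_primary <- function(st, ont) {
  tp <- peek(st)
  if (tp == "lparen") {
    advance(st)
    inner <- parse_expr(st, ont)
    if (peek(st) != "rparen") {
      stop("syntax error: expected ')' at position ",
           if (st$pos <= nrow(st$toks)) st$toks$start[st$pos] else nchar_end(st),
           call. = FALSE)
    }
    advance(st)
    return(inner)
  }
  if (tp != "name") {
    stop("syntax error at position ",
         if (st$pos <= nrow(st$toks)) st$toks$start[st$pos] else nchar_end(st),
         ": expected a quoted name, CURIE or '('", call. = FALSE)
  }
  tok <- advance(st)
  if (peek(st) == "some") {
    advance(st)
    prop <- resolve_property(ont, tok$value)
    filler <- parse_primary(st, ont)
    return(ce_some(prop, filler))
  }
  ce_named(resolve_label(ont, tok$value))
}

nchar_end <- function(st) {
  n <- nrow(st$toks)
  st$toks$start[n] + nchar(st$toks$text[n])
}

#' Serialize a class expression to the grammar's string form
#'
#' Uses quoted primary labels so the output reads like the published query
#' strings; `parse_expression()` round-trips the result bit-exactly on the
#' canonical form.
#'
#' @param expr a class expression.
#' @param ont the ontology supplying labels.
#' @return a single string.
#' @export
expression_to_string <- function(expr, ont) {
  stopifnot(is_class_expression(expr))
  ser <- function(e, parenthesize) {
    switch(e$variant,
      named = quote_name(label_or_curie(ont, e$class)),
      some = {
        s <- paste(quote_name(property_label(ont, e$property)), "some",
                   ser(e$filler, TRUE))
        if (parenthesize) paste0("(", s, ")") else s
      },
      and = {
        s <- paste(vapply(e$conjuncts, ser, character(1), TRUE),
                   collapse = " and ")
        if (parenthesize) paste0("(", s, ")") else s
      }
    )
  }
  ser(ce_canonical(expr), FALSE)
}

quote_name <- function(x) paste0("'", x, "'")

label_or_curie <- function(ont, id) {
  cl <- ont$classes[[id]]
  if (is.null(cl)) id else cl$label
}

property_label <- function(ont, id) {
  p <- ont$properties[[id]]
  if (is.null(p)) id else p$label
}
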