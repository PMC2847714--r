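#' Build a parsing lexicon from loaded ontologies
#'
#' Every non-obsolete class contributes its name and EXACT synonyms, keyed by
#' normalized token sequences (lower case, hyphens and underscores as token
#' separators). Colliding keys are recorded, not dropped: one key may map to
#' several identifiers, and the ambiguity is surfaced downstream. Non-EXACT
#' synonym scopes are excluded from lexicon building.
#'
#' @param docs list of [obo_document()] objects.
#' @param roles character vector, one role per document: `"quality"` feeds
#'   the quality lexicon; `"gross-anatomy"`, `"cell"`, `"cell-component"`,
#'   `"process"` and `"chemical"` feed the bearer lexicon. The role
#'   `"go"` assigns `"cell-component"` or `"process"` per stanza from its
#'   OBO namespace.
#' @param grammar a [default_grammar()] configuration (normalization rules).
#' @return An object of class `xp_lexicon`.
#' @export
build_lexicon <- function(docs, roles, grammar = default_grammar()) {
  docs <- flatten_docs(docs)
  stopifnot(length(docs) == length(roles))
  quality <- list()
  bearer <- list()
  add_quality <- function(key, id) {
    quality[[key]] <<- unique(c(quality[[key]], id))
  }
  add_bearer <- function(key, id, role) {
    cur <- bearer[[key]]
    if (is.null(cur)) cur <- tibble(id = character(), role = character())
    if (!id %in% cur$id) {
      bearer[[key]] <<- bind_rows(cur, tibble(id = id, role = role))
    }
  }
  for (k in seq_along(docs)) {
    doc <- docs[[k]]
    role <- roles[k]
    for (st in doc$stanzas) {
      if (st$is_obsolete) next
      texts <- character()
      if (!is.na(st$name)) texts <- st$name
      exact <- map_chr(keep(st$synonyms, ~ .x$scope == "EXACT"), "text")
      texts <- unique(c(texts, exact))
      st_role <- role
      if (role == "go") {
        st_role <- if (identical(st$namespace, "biological_process")) {
          "process"
        } else {
          "cell-component"
        }
      }
      for (txt in texts) {
        key <- paste(normalize_tokens(txt, grammar), collapse = " ")
        if (!nzchar(key)) next
        if (role == "quality") add_quality(key, st$id)
        else add_bearer(key, st$id, st_role)
      }
    }
  }
  structure(list(quality = quality, bearer = bearer, grammar = grammar),
            class = "xp_lexicon")
}

#' @export
print.xp_lexicon <- function(x, ...) {
  cat(sprintf("<xp_lexicon: %d quality keys, %d bearer keys>\n",
              length(x$quality), length(x$bearer)))
  invisible(x)
}

#' Normalize a label into parsing tokens
#'
#' Case is folded to lower; hyphens and underscores act as token separators.
#'
#' @param x label text.
#' @param grammar a [default_grammar()] configuration.
#' @return Character vector of tokens.
#' @export
normalize_tokens <- function(x, grammar = default_grammar()) {
  x <- tolower(x)
  x <- gsub("[-_]", " ", x)
  x <- str_squish(x)
  if (!nzchar(x)) return(character())
  strsplit(x, " ", fixed = TRUE)[[1]]
}

# Singular fallback: irregular dictionary first, then trailing-"s" stripping.
singularize <- function(token, grammar) {
  irr <- grammar$irregular_plurals
  if (token %in% names(irr)) return(irr[[token]])
  if (nchar(token) > 3L && endsWith(token, "s") && !endsWith(token, "ss")) {
    return(substr(token, 1, nchar(token) - 1L))
  }
  token
}

# Token-sequence key variants tried at lookup (exact, then plural-normalized
# last token).
key_variants <- function(tokens, grammar) {
  out <- paste(tokens, collapse = " ")
  n <- length(tokens)
  sing <- singularize(tokens[n], grammar)
  if (!identical(sing, tokens[n])) {
    out <- c(out, paste(c(tokens[-n], sing), collapse = " "))
  }
  unique(out)
}

lexicon_quality_ids <- function(lexicon, text_or_tokens) {
  tokens <- if (length(text_or_tokens) <= 1L) {
    normalize_tokens(text_or_tokens, lexicon$grammar)
  } else {
    tolower(text_or_tokens)
  }
  if (!length(tokens)) return(character())
  unique(unlist(lexicon$quality[key_variants(tokens, lexicon$grammar)]))
}

lexicon_bearer_entries <- function(lexicon, tokens) {
  if (!length(tokens)) return(NULL)
  hits <- compact(lexicon$bearer[key_variants(tokens, lexicon$grammar)])
  if (!length(hits)) return(NULL)
  distinct(bind_rows(hits))
}

lexicon_bearer_ids <- function(lexicon, text) {
  tokens <- normalize_tokens(text, lexicon$grammar)
  hits <- lexicon_bearer_entries(lexicon, tokens)
  if (is.null(hits)) character() else unique(hits$id)
}
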