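#' Parse OBO flat-file text
#'
#' Reads the OBO 1.2 dialect used by phenotype cross-product files. Trailing
#' `! ...` comments are stripped everywhere (outside quoted strings) and play
#' no semantic role; unknown tags are retained verbatim as opaque lines on
#' their stanza; stanza order and identifiers are preserved. `[Typedef]`
#' stanzas are kept as raw blocks, with `is_transitive: true` declarations
#' collected into the document's transitive-relation set.
#'
#' @param text a single string (with embedded newlines) or a character vector
#'   of lines.
#' @return An [obo_document()].
#' @export
parse_obo <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  stripped <- vapply(lines, strip_obo_comment, character(1), USE.NAMES = FALSE)
  stripped <- sub("\\s+$", "", stripped)

  n <- length(stripped)
  idx <- seq_len(n)
  block_starts <- idx[grepl("^\\[", stripped)]
  header_end <- if (length(block_starts)) block_starts[1] - 1L else n

  header <- stripped[seq_len(header_end)]
  header <- header[nzchar(header)]
  ontology_id <- NA_character_
  m <- grepl("^ontology:", header)
  if (any(m)) ontology_id <- str_trim(sub("^ontology:", "", header[m][1]))

  stanzas <- list()
  typedefs <- list()
  first_line_of <- character()  # id -> line number of stanza start

  starts <- block_starts
  ends <- c(starts[-1] - 1L, n)
  for (k in seq_along(starts)) {
    kind <- stripped[starts[k]]
    body_idx <- seq(starts[k] + 1L, length.out = max(0L, ends[k] - starts[k]))
    body_idx <- body_idx[nzchar(stripped[body_idx])]
    body <- stripped[body_idx]
    if (kind == "[Term]") {
      st <- parse_term_block(body, body_idx)
      if (!is.null(stanzas[[st$id]])) {
        stop_phenoxp(
          sprintf("duplicate stanza id '%s' (lines %d and %d)",
                  st$id, as.integer(first_line_of[[st$id]]), starts[k]),
          "phenoxp_malformed_document"
        )
      }
      stanzas[[st$id]] <- st
      first_line_of[[st$id]] <- starts[k]
    } else {
      td <- parse_typedef_block(body)
      typedefs <- c(typedefs, list(td))
    }
  }
  obo_document(
    ontology_id = ontology_id, header = header,
    stanzas = unname(stanzas), typedefs = typedefs
  )
}

#' @param path path to an OBO file.
#' @rdname parse_obo
#' @export
read_obo <- function(path) {
  parse_obo(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

# Strip an unquoted, unescaped '!' comment from one line.
strip_obo_comment <- function(line) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  in_quote <- FALSE
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "\\") {
      i <- i + 2L
      next
    }
    if (ch == '"') in_quote <- !in_quote
    if (ch == "!" && !in_quote) {
      return(sub("\\s+$", "", substr(line, 1, i - 1L)))
    }
    i <- i + 1L
  }
  line
}

split_tag <- function(line) {
  pos <- regexpr(":", line, fixed = TRUE)
  if (pos < 0) return(NULL)
  list(
    tag = substr(line, 1, pos - 1L),
    value = str_trim(substr(line, pos + 1L, nchar(line)))
  )
}

parse_term_block <- function(body, body_lines) {
  id <- NA_character_
  name <- NA_character_
  namespace <- NA_character_
  synonyms <- list()
  is_a <- character()
  relationships <- list()
  intersection_of <- list()
  is_obsolete <- FALSE
  other <- character()
  for (line in body) {
    tv <- split_tag(line)
    if (is.null(tv)) {
      other <- c(other, line)
      next
    }
    switch(tv$tag,
      id = { id <- tv$value },
      name = { name <- tv$value },
      namespace = { namespace <- tv$value },
      synonym = {
        synonyms <- c(synonyms, list(parse_synonym(tv$value)))
      },
      is_a = { is_a <- c(is_a, first_token(tv$value)) },
      relationship = {
        parts <- strsplit(tv$value, "\\s+")[[1]]
        relationships <- c(relationships,
                           list(link_clause(parts[1], parts[2])))
      },
      intersection_of = {
        parts <- strsplit(tv$value, "\\s+")[[1]]
        cl <- if (length(parts) == 1L) {
          intersection_clause(parts[1])
        } else {
          intersection_clause(parts[2], relation = parts[1])
        }
        intersection_of <- c(intersection_of, list(cl))
      },
      is_obsolete = { is_obsolete <- tolower(tv$value) == "true" },
      { other <- c(other, line) }
    )
  }
  if (is.na(id)) {
    stop_phenoxp("term stanza without an id tag", "phenoxp_malformed_document")
  }
  term_stanza(
    id = id, name = name, namespace = namespace, synonyms = synonyms,
    is_a = is_a, relationships = relationships,
    intersection_of = intersection_of, is_obsolete = is_obsolete,
    other = other
  )
}

first_token <- function(x) strsplit(x, "\\s+")[[1]][1]

parse_synonym <- function(value) {
  m <- regmatches(value, regexec('^"((?:[^"\\\\]|\\\\.)*)"\\s*([A-Z_]*)', value))[[1]]
  if (length(m) < 2L) return(list(text = value, scope = "RELATED"))
  scope <- if (length(m) >= 3L && nzchar(m[3])) m[3] else "RELATED"
  list(text = gsub('\\\\(.)', "\\1", m[2]), scope = scope)
}

parse_typedef_block <- function(body) {
  id <- NA_character_
  is_transitive <- FALSE
  for (line in body) {
    tv <- split_tag(line)
    if (is.null(tv)) next
    if (tv$tag == "id") id <- tv$value
    if (tv$tag == "is_transitive") is_transitive <- tolower(tv$value) == "true"
  }
  list(id = id, is_transitive = is_transitive, lines = body)
}

with_comment <- function(value, id, labels) {
  if (!is.null(labels) && !is.na(labels[id] %||% NA)) {
    paste0(value, " ! ", labels[[id]])
  } else {
    value
  }
}

format_stanza <- function(st, labels = NULL) {
  out <- "[Term]"
  out <- c(out, paste0("id: ", with_comment(st$id, st$id, labels)))
  if (!is.na(st$name)) out <- c(out, paste0("name: ", st$name))
  if (!is.na(st$namespace)) out <- c(out, paste0("namespace: ", st$namespace))
  out <- c(out, st$other)
  for (syn in st$synonyms) {
    out <- c(out, sprintf('synonym: "%s" %s []',
                          gsub('"', '\\\\"', syn$text), syn$scope))
  }
  for (p in st$is_a) {
    out <- c(out, paste0("is_a: ", with_comment(p, p, labels)))
  }
  for (cl in st$intersection_of) {
    val <- if (is_genus(cl)) cl$filler else paste(cl$relation, cl$filler)
    out <- c(out, paste0("intersection_of: ",
                         with_comment(val, cl$filler, labels)))
  }
  for (rel in st$relationships) {
    out <- c(out, paste0("relationship: ", rel$relation, " ",
                         with_comment(rel$target, rel$target, labels)))
  }
  if (st$is_obsolete) out <- c(out, "is_obsolete: true")
  out
}

#' Write an ontology document as OBO flat-file text
#'
#' The output reparses to a structurally identical document. Stanza-internal
#' tags follow the OBO 1.2 canonical order (id, name, namespace, opaque tags,
#' synonym, is_a, intersection_of, relationship, is_obsolete). When a comment
#' dictionary is supplied, human-readable `! label` comments are regenerated
#' after identifiers; identifiers without an entry get no comment rather than
#' a guessed one.
#'
#' @param doc an [obo_document()].
#' @param labels optional named character vector (id -> label) used to emit
#'   trailing `! label` comments.
#' @param file optional path; when given the text is also written there.
#' @return The OBO text as a single string (invisibly when `file` is given).
#' @export
write_obo <- function(doc, labels = NULL, file = NULL) {
  blocks <- character()
  header <- doc$header
  if (!length(header)) {
    header <- c("format-version: 1.2",
                if (!is.na(doc$ontology_id)) paste0("ontology: ", doc$ontology_id))
  }
  blocks <- c(blocks, paste(header, collapse = "\n"))
  for (st in doc$stanzas) {
    blocks <- c(blocks, paste(format_stanza(st, labels), collapse = "\n"))
  }
  for (td in doc$typedefs) {
    blocks <- c(blocks, paste(c("[Typedef]", td$lines), collapse = "\n"))
  }
  text <- paste0(paste(blocks, collapse = "\n\n"), "\n")
  if (!is.null(file)) {
    writeLines(text, file, sep = "")
    return(invisible(text))
  }
  text
}
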