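#' Parse and write the EQ line syntax
#'
#' EQ definition files use one `TAG = value` line per element, with tags `E`,
#' `Q`, `E2`, `M` and `EW` (plus an optional `ID` tag binding the record to a
#' pre-composed class); records are separated by blank lines. Values may be
#' labels, CURIEs, or caret compositions like `dendrite^part_of(Purkinje_cell)`.
#' Labels are resolved to identifiers when a lexicon is supplied; otherwise
#' they are retained and flagged as unresolved for curation (see
#' `attr(x, "unresolved")`).
#'
#' @param lines character vector of lines for one record. For convenience,
#'   ` / ` separators inside a single string are also accepted.
#' @param lexicon optional [build_lexicon()] result used to resolve labels.
#' @return An [eq()] description; the bound class id, if any, is stored in
#'   `attr(x, "id")`.
#' @export
parse_eq_text <- function(lines, lexicon = NULL) {
  lines <- unlist(strsplit(lines, " / ", fixed = TRUE))
  lines <- lines[nzchar(str_trim(lines))]
  vals <- list()
  for (line in lines) {
    m <- regmatches(line, regexec("^\\s*(ID|EW|E2|E|Q|M)\\s*=\\s*(.*\\S)\\s*$", line))[[1]]
    if (length(m) < 3L) {
      stop_phenoxp(
        sprintf("cannot parse EQ line '%s' (expected 'TAG = value')", line),
        "phenoxp_syntax"
      )
    }
    vals[[m[2]]] <- m[3]
  }
  if (is.null(vals$E) || is.null(vals$Q)) {
    stop_phenoxp("incomplete EQ description: both E and Q lines are required",
                 "phenoxp_incomplete_description")
  }
  unresolved <- character()
  resolve_atom <- function(x, kind) {
    if (is_curie(x)) return(x)
    if (!is.null(lexicon)) {
      hit <- if (kind == "quality") {
        lexicon_quality_ids(lexicon, x)
      } else {
        lexicon_bearer_ids(lexicon, x)
      }
      if (length(hit) == 1L) return(hit)
    }
    unresolved <<- c(unresolved, x)
    x
  }
  resolve_expr <- function(x, kind) {
    if (is_named_expr(x)) return(xp_named(resolve_atom(x$id, kind)))
    xp_composed(resolve_atom(x$genus, kind), map(x$differentia, function(d) {
      list(relation = d$relation, filler = resolve_expr(d$filler, kind))
    }))
  }
  parse_value <- function(v, kind) {
    resolve_expr(parse_class_expression(v), kind)
  }
  out <- eq(
    entity = parse_value(vals$E, "bearer"),
    quality = resolve_atom(vals$Q, "quality"),
    entity2 = if (!is.null(vals$E2)) parse_value(vals$E2, "bearer"),
    modifier = if (!is.null(vals$M)) resolve_atom(vals$M, "quality"),
    entity_whole = if (!is.null(vals$EW)) parse_value(vals$EW, "bearer")
  )
  attr(out, "id") <- vals$ID
  attr(out, "unresolved") <- unique(unresolved)
  out
}

#' @param x an [eq()] description.
#' @rdname parse_eq_text
#' @export
write_eq_text <- function(x) {
  out <- character()
  id <- attr(x, "id")
  if (!is.null(id)) out <- c(out, paste0("ID = ", id))
  out <- c(out, paste0("E = ", format(x$entity)), paste0("Q = ", x$quality))
  if (!is.null(x$entity2)) out <- c(out, paste0("E2 = ", format(x$entity2)))
  if (!is.null(x$modifier)) out <- c(out, paste0("M = ", x$modifier))
  if (!is.null(x$entity_whole)) out <- c(out, paste0("EW = ", format(x$entity_whole)))
  out
}

#' Read and write EQ definition files
#'
#' @param path file path.
#' @param lexicon optional lexicon for label resolution.
#' @return `read_eq_file()` returns a tibble with columns `id` and `eq`
#'   (a list-column of [eq()] descriptions).
#' @export
read_eq_file <- function(path, lexicon = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\\s*#.*$", "", lines)
  breaks <- cumsum(!nzchar(str_trim(lines)))
  groups <- split(lines, breaks)
  eqs <- list()
  for (g in groups) {
    g <- g[nzchar(str_trim(g))]
    if (!length(g)) next
    eqs <- c(eqs, list(parse_eq_text(g, lexicon)))
  }
  tibble(
    id = map_chr(eqs, ~ attr(.x, "id") %||% NA_character_),
    eq = eqs
  )
}

#' @param defs a tibble with columns `id` and `eq`, or a list of [eq()]
#'   descriptions.
#' @rdname read_eq_file
#' @export
write_eq_file <- function(defs, path) {
  defs <- as_eq_table(defs)
  blocks <- map_chr(seq_len(nrow(defs)), function(i) {
    e <- defs$eq[[i]]
    if (!is.na(defs$id[i])) attr(e, "id") <- defs$id[i]
    paste(write_eq_text(e), collapse = "\n")
  })
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

as_eq_table <- function(defs) {
  if (is.data.frame(defs)) {
    stopifnot(all(c("id", "eq") %in% names(defs)))
    return(defs)
  }
  if (inherits(defs, "eq_description")) defs <- list(defs)
  tibble(
    id = map_chr(defs, ~ attr(.x, "id") %||% NA_character_),
    eq = defs
  )
}

#' Convert an EQ definition set to an OBO document of intersection stanzas
#'
#' Each definition becomes a `[Term]` stanza for its bound class id carrying
#' the genus-differentia `intersection_of` clauses; nested bearer expressions
#' are materialized as auxiliary stanzas.
#'
#' @param defs tibble with columns `id`, `eq` (see [read_eq_file()]).
#' @param vocab a [relation_vocabulary()].
#' @param ontology_id id for the resulting document.
#' @return An [obo_document()].
#' @export
as_xp_document <- function(defs, vocab = relation_vocabulary(),
                           ontology_id = "xp") {
  defs <- as_eq_table(defs)
  stanzas <- list()
  add <- function(st) {
    if (is.null(stanzas[[st$id]])) stanzas[[st$id]] <<- st
  }
  for (i in seq_len(nrow(defs))) {
    id <- defs$id[i]
    if (is.na(id)) {
      stop_phenoxp("EQ definition without a bound class id (ID tag)",
                   "phenoxp_incomplete_description")
    }
    tr <- eq_to_intersection(defs$eq[[i]], vocab)
    for (st in tr$aux) add(st)
    add(term_stanza(id = id, intersection_of = tr$clauses))
  }
  obo_document(
    ontology_id = ontology_id,
    header = c("format-version: 1.2", paste0("ontology: ", ontology_id)),
    stanzas = unname(stanzas)
  )
}
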