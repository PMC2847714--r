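#' Ontology document and term stanza constructors
#'
#' An `obo_document` is the in-memory form of an OBO 1.2 flat file restricted
#' to the tag subset used by cross-product (XP) definition work:
#' `format-version`, `ontology`, `id`, `name`, `namespace`, `synonym`, `is_a`,
#' `relationship`, `intersection_of` and `is_obsolete`. All other tags are
#' carried verbatim as opaque lines so that documents round-trip.
#'
#' @param ontology_id identifier of the ontology (the `ontology:` header tag).
#' @param header character vector of raw header tag-value lines (comments
#'   already stripped; `format-version`/`ontology` included).
#' @param stanzas list of [term_stanza()] objects; names are set to their ids.
#' @param typedefs list of parsed-lite `[Typedef]` blocks, each a list with
#'   elements `id`, `is_transitive` and `lines` (the raw tag-value lines).
#' @param source named character vector mapping stanza id to the ontology id
#'   of the document it came from (provenance after [merge_documents()]).
#' @return An object of class `obo_document`.
#' @export
obo_document <- function(ontology_id = NA_character_, header = character(),
                         stanzas = list(), typedefs = list(),
                         source = NULL) {
  ids <- map_chr(stanzas, "id")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop_phenoxp(
      sprintf("duplicate stanza id '%s' in document", dup),
      "phenoxp_malformed_document"
    )
  }
  names(stanzas) <- ids
  if (is.null(source)) {
    source <- stats::setNames(rep(ontology_id, length(ids)), ids)
  }
  transitive <- map_chr(keep(typedefs, ~ isTRUE(.x$is_transitive)), "id")
  structure(
    list(
      ontology_id = ontology_id,
      header = header,
      stanzas = stanzas,
      typedefs = typedefs,
      transitive_relations = unname(transitive),
      source = source
    ),
    class = "obo_document"
  )
}

#' @param id CURIE-style class identifier, e.g. `MP:0000017`.
#' @param name class label, or `NA` when the stanza carries no `name:` tag.
#' @param namespace optional OBO namespace.
#' @param synonyms list of `list(text =, scope =)` pairs.
#' @param is_a character vector of parent class identifiers.
#' @param relationships list of [link_clause()] objects.
#' @param intersection_of list of [intersection_clause()] objects; must be
#'   empty or have length at least two (a genus and one differentium).
#' @param is_obsolete logical; obsolete stanzas may not carry links or
#'   definitions.
#' @param other character vector of opaque tag-value lines kept verbatim.
#' @rdname obo_document
#' @export
term_stanza <- function(id, name = NA_character_, namespace = NA_character_,
                        synonyms = list(), is_a = character(),
                        relationships = list(), intersection_of = list(),
                        is_obsolete = FALSE, other = character()) {
  if (length(intersection_of) == 1L) {
    stop_phenoxp(
      sprintf(
        "stanza '%s' has exactly one intersection_of clause; a definition needs a genus and at least one differentium",
        id
      ),
      "phenoxp_definition_arity"
    )
  }
  n_genus <- sum(map_lgl(intersection_of, ~ is.na(.x$relation)))
  if (n_genus > 1L) {
    stop_phenoxp(
      sprintf("stanza '%s' has more than one genus intersection clause", id),
      "phenoxp_definition_arity"
    )
  }
  if (isTRUE(is_obsolete) &&
      (length(is_a) || length(relationships) || length(intersection_of))) {
    stop_phenoxp(
      sprintf("obsolete stanza '%s' carries links or a definition", id),
      "phenoxp_malformed_document"
    )
  }
  structure(
    list(
      id = id, name = name, namespace = namespace, synonyms = synonyms,
      is_a = is_a, relationships = relationships,
      intersection_of = intersection_of, is_obsolete = isTRUE(is_obsolete),
      other = other
    ),
    class = "term_stanza"
  )
}

#' @param relation relation identifier (e.g. `part_of`, `inheres_in`).
#' @param target target class identifier.
#' @rdname obo_document
#' @export
link_clause <- function(relation, target) {
  if (!nzchar(relation) || !nzchar(target)) {
    stop_phenoxp("link clause needs non-empty relation and target",
                 "phenoxp_malformed_document")
  }
  list(relation = relation, target = target)
}

#' @param filler class identifier filling the clause.
#' @rdname obo_document
#' @export
intersection_clause <- function(filler, relation = NA_character_) {
  if (!nzchar(filler)) {
    stop_phenoxp("intersection clause needs a non-empty filler",
                 "phenoxp_malformed_document")
  }
  list(relation = relation, filler = filler)
}

is_genus <- function(clause) is.na(clause$relation)

#' @export
print.obo_document <- function(x, ...) {
  cat(sprintf(
    "<obo_document '%s': %d term stanzas, %d typedefs>\n",
    x$ontology_id %||% NA, length(x$stanzas), length(x$typedefs)
  ))
  invisible(x)
}

#' @export
print.term_stanza <- function(x, ...) {
  cat(format_stanza(x), sep = "\n")
  invisible(x)
}

doc_labels <- function(doc) {
  stanzas <- doc$stanzas
  labs <- map_chr(stanzas, "name")
  labs[!is.na(labs)]
}

#' Collect id -> label maps from one or more documents
#'
#' @param ... `obo_document` objects (or lists of them).
#' @return A named character vector mapping identifiers to labels.
#' @export
collect_labels <- function(...) {
  docs <- flatten_docs(list(...))
  labs <- unlist(map(docs, doc_labels))
  labs[!duplicated(names(labs))]
}

flatten_docs <- function(x) {
  if (inherits(x, "obo_document")) return(list(x))
  out <- list()
  for (el in x) {
    if (inherits(el, "obo_document")) out <- c(out, list(el))
    else out <- c(out, flatten_docs(el))
  }
  out
}

stanza_equal <- function(a, b) {
  identical(unclass(a), unclass(b))
}

combine_stanzas <- function(a, b, sources) {
  conflict <- function(what) {
    stop_phenoxp(
      sprintf("merge conflict on '%s' (%s) between documents %s and %s",
              a$id, what, sources[1], sources[2]),
      "phenoxp_merge_conflict"
    )
  }
  name <- a$name
  if (!is.na(a$name) && !is.na(b$name) && a$name != b$name) conflict("name")
  if (is.na(name)) name <- b$name
  if (length(a$intersection_of) && length(b$intersection_of) &&
      !identical(a$intersection_of, b$intersection_of)) {
    conflict("intersection_of")
  }
  if (a$is_obsolete != b$is_obsolete) conflict("is_obsolete")
  namespace <- if (is.na(a$namespace)) b$namespace else a$namespace
  rels <- c(a$relationships, b$relationships)
  rels <- rels[!duplicated(map_chr(rels, ~ paste(.x$relation, .x$target)))]
  syns <- c(a$synonyms, b$synonyms)
  syns <- syns[!duplicated(map_chr(syns, ~ paste(.x$scope, .x$text)))]
  term_stanza(
    id = a$id, name = name, namespace = namespace, synonyms = syns,
    is_a = union(a$is_a, b$is_a), relationships = rels,
    intersection_of = if (length(a$intersection_of)) a$intersection_of else b$intersection_of,
    is_obsolete = a$is_obsolete,
    other = union(a$other, b$other)
  )
}

#' Merge ontology documents into a combined document
#'
#' Stanzas from all documents are pooled so that a reasoner can work over the
#' combined set (phenotype ontology, XP definitions, and the referenced
#' ontologies). Stanzas sharing an identifier are combined by union of their
#' links provided their names and definitions do not conflict; differing names
#' or differing `intersection_of` definitions raise a merge-conflict error
#' naming the id and both source documents. Transitive-relation declarations
#' are unioned and per-stanza provenance is recorded.
#'
#' @param docs list of [obo_document()] objects (a single document may also be
#'   passed bare).
#' @param ontology_id identifier to give the merged document.
#' @return An [obo_document()].
#' @export
merge_documents <- function(docs, ontology_id = "merged") {
  docs <- flatten_docs(docs)
  if (length(docs) == 1L) return(docs[[1]])
  stanzas <- list()
  source <- character()
  for (doc in docs) {
    for (st in doc$stanzas) {
      src <- doc$ontology_id %||% NA_character_
      if (is.null(stanzas[[st$id]])) {
        stanzas[[st$id]] <- st
        source[[st$id]] <- src
      } else {
        stanzas[[st$id]] <- combine_stanzas(
          stanzas[[st$id]], st, c(source[[st$id]], src)
        )
      }
    }
  }
  typedefs <- list()
  seen_td <- character()
  for (doc in docs) {
    for (td in doc$typedefs) {
      if (!is.na(td$id) && td$id %in% seen_td) next
      typedefs <- c(typedefs, list(td))
      seen_td <- c(seen_td, td$id)
    }
  }
  header <- unique(unlist(map(docs, "header")))
  header <- header[!grepl("^ontology:", header)]
  header <- c(header, paste0("ontology: ", ontology_id))
  obo_document(
    ontology_id = ontology_id,
    header = header,
    stanzas = unname(stanzas),
    typedefs = typedefs,
    source = source
  )
}

#' Report dangling references in a document
#'
#' XP files intentionally reference classes of external ontologies, so dangling
#' targets are permitted at parse time; this lint surfaces them.
#'
#' @param doc an [obo_document()].
#' @return A tibble with columns `stanza`, `via`, `target`.
#' @export
lint_dangling <- function(doc) {
  known <- names(doc$stanzas)
  rows <- list()
  for (st in doc$stanzas) {
    for (p in st$is_a) {
      if (!p %in% known) rows[[length(rows) + 1]] <- tibble(
        stanza = st$id, via = "is_a", target = p)
    }
    for (rel in st$relationships) {
      if (!rel$target %in% known) rows[[length(rows) + 1]] <- tibble(
        stanza = st$id, via = rel$relation, target = rel$target)
    }
    for (cl in st$intersection_of) {
      if (!cl$filler %in% known) rows[[length(rows) + 1]] <- tibble(
        stanza = st$id,
        via = if (is_genus(cl)) "intersection_of" else paste0("intersection_of:", cl$relation),
        target = cl$filler)
    }
  }
  if (!length(rows)) {
    return(tibble(stanza = character(), via = character(), target = character()))
  }
  bind_rows(rows)
}
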