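closure_edge_keys <- function(closure, status = NULL) {
  e <- closure$edges
  if (!is.null(status)) e <- e[e$status %in% status, ]
  edge_key(e$subject, e$relation, e$object)
}

#' Propose novel direct is_a links for curator review
#'
#' Returns inferred `is_a` edges whose subject and object both carry the
#' target ontology prefix, that are not asserted, not reflexive, and direct:
#' no distinct intermediate `Z` with `subject is_a Z is_a object` exists in
#' the closure. Each proposal carries its full provenance chain.
#'
#' @param closure a [compute_closure()] result.
#' @param target_prefix identifier prefix of the phenotype ontology (e.g.
#'   `"MP"`).
#' @return A tibble: `subject`, `object`, `subject_label`, `object_label`,
#'   `rule_chain`, sorted deterministically.
#' @export
infer_novel_links <- function(closure, target_prefix) {
  e <- closure$edges
  isa <- e[e$relation == "is_a", ]
  inf <- isa[isa$status == "inferred" &
               curie_prefix(isa$subject) == target_prefix &
               curie_prefix(isa$object) == target_prefix &
               isa$subject != isa$object, ]
  if (!nrow(inf)) {
    return(tibble(subject = character(), object = character(),
                  subject_label = character(), object_label = character(),
                  rule_chain = character()))
  }
  # direct: no distinct intermediate on an is_a path
  up <- split(isa$object, isa$subject)
  direct <- map_lgl(seq_len(nrow(inf)), function(i) {
    mids <- setdiff(up[[inf$subject[i]]] %||% character(),
                    c(inf$subject[i], inf$object[i]))
    !any(map_lgl(mids, ~ inf$object[i] %in% (up[[.x]] %||% character())))
  })
  inf <- inf[direct, ]
  lab <- function(id) {
    ifelse(is.na(closure$labels[id]), id, closure$labels[id])
  }
  out <- tibble(
    subject = inf$subject, object = inf$object,
    subject_label = unname(lab(inf$subject)),
    object_label = unname(lab(inf$object)),
    rule_chain = map_chr(seq_len(nrow(inf)), function(i) {
      provenance_chain(closure, inf$subject[i], "is_a", inf$object[i])
    })
  )
  arrange(out, .data$subject, .data$object)
}

#' Human-readable provenance chain for a closure edge
#'
#' Expands an inferred edge's premises recursively down to asserted edges and
#' definitions.
#'
#' @param closure a [compute_closure()] result.
#' @param subject,relation,object the edge.
#' @param max_depth recursion guard.
#' @return A single string.
#' @export
provenance_chain <- function(closure, subject, relation, object,
                             max_depth = 12L) {
  e <- closure$edges
  keys <- edge_key(e$subject, e$relation, e$object)
  idx <- stats::setNames(seq_len(nrow(e)), keys)
  render <- function(key, depth) {
    if (startsWith(key, "def:")) {
      return(paste0("definition(", sub("^def:", "", key), ")"))
    }
    if (startsWith(key, "reflexive:")) {
      return(paste0(sub("^reflexive:", "", key), " is_a itself"))
    }
    i <- idx[key]
    parts <- strsplit(key, "\t", fixed = TRUE)[[1]]
    shown <- paste(parts[1], parts[2], parts[3])
    if (is.na(i) || e$status[i] == "asserted" || depth >= max_depth) {
      return(shown)
    }
    prems <- strsplit(e$premises[i], ";", fixed = TRUE)[[1]]
    paste0(shown, " [", e$rule[i], ": ",
           paste(map_chr(prems, render, depth = depth + 1L), collapse = " & "),
           "]")
  }
  render(edge_key(subject, relation, object), 0L)
}

#' Query phenotype classes by the entity their quality inheres in
#'
#' Returns every class `X` for which `X inheres_in F` holds in the closure
#' for some `F` with `F is_a entity` (reflexive). Bridging axioms - plain
#' `is_a` links between classes of different anatomy ontologies - extend the
#' result across species, since composition with `is_a` folds `F is_a entity`
#' into a direct `inheres_in` edge.
#'
#' @param closure a [compute_closure()] result (computed over the phenotype
#'   and entity ontologies plus any bridging axioms).
#' @param entity class identifier to query.
#' @param prefix optional prefix filter for the returned phenotype classes.
#' @param include_parts also match `inheres_in_part_of` (see rule R6).
#' @return Sorted character vector of class identifiers.
#' @export
query_phenotypes_by_entity <- function(closure, entity, prefix = NULL,
                                       include_parts = FALSE) {
  if (!entity %in% c(closure$classes, closure$edges$object)) {
    stop_phenoxp(sprintf("unknown class '%s'", entity), "phenoxp_unknown_class")
  }
  rels <- closure$vocab$inheres_in
  if (include_parts) rels <- c(rels, closure$vocab$inheres_in_part_of)
  e <- closure$edges
  hits <- unique(e$subject[e$relation %in% rels & e$object == entity])
  if (!is.null(prefix)) hits <- hits[curie_prefix(hits) == prefix]
  sort(hits)
}

#' Rebuild an ontology document from a closure
#'
#' Every closure edge becomes an asserted link, so recomputing the closure of
#' the result adds nothing (idempotence). Definitions are carried over.
#'
#' @param closure a [compute_closure()] result.
#' @return An [obo_document()].
#' @export
closure_to_document <- function(closure) {
  e <- closure$edges
  ids <- unique(c(closure$classes, e$subject, e$object))
  stanzas <- map(ids, function(id) {
    mine <- e[e$subject == id, ]
    isa <- mine$object[mine$relation == "is_a"]
    rels <- mine[mine$relation != "is_a", ]
    term_stanza(
      id = id,
      name = if (!is.na(closure$labels[id] %||% NA)) closure$labels[[id]] else NA_character_,
      is_a = isa,
      relationships = map(seq_len(nrow(rels)),
                          ~ link_clause(rels$relation[.x], rels$object[.x])),
      intersection_of = closure$definitions[[id]] %||% list()
    )
  })
  obo_document(
    ontology_id = "closure",
    header = c("format-version: 1.2", "ontology: closure"),
    stanzas = stanzas
  )
}

#' Export a closure
#'
#' `write_closure_tsv()` writes every edge with status and rule chain;
#' `write_closure_obo()` writes an OBO rendering in which inferred links are
#' tagged with a trailing `! inferred (rule)` comment.
#'
#' @param closure a [compute_closure()] result.
#' @param path output file.
#' @param provenance optional character vector of comment lines prepended to
#'   the output (prefixed appropriately per format).
#' @return The path, invisibly.
#' @export
write_closure_tsv <- function(closure, path, provenance = NULL) {
  e <- closure$edges
  out <- tibble(
    subject = e$subject, relation = e$relation, object = e$object,
    status = e$status,
    rule_chain = map_chr(seq_len(nrow(e)), function(i) {
      if (e$status[i] == "asserted") return("")
      provenance_chain(closure, e$subject[i], e$relation[i], e$object[i])
    })
  )
  write_tsv_with_header(out, path, provenance)
  invisible(path)
}

#' @rdname write_closure_tsv
#' @export
write_closure_obo <- function(closure, path, provenance = NULL) {
  e <- closure$edges
  lines <- c("format-version: 1.2", "ontology: closure",
             paste0("remark: ", provenance %||% character()))
  ids <- sort(unique(c(e$subject, names(closure$definitions))))
  for (id in ids) {
    lines <- c(lines, "", "[Term]", paste0("id: ", id))
    nm <- closure$labels[id]
    if (!is.na(nm)) lines <- c(lines, paste0("name: ", unname(nm)))
    mine <- e[e$subject == id, ]
    mine <- arrange(mine, .data$relation, .data$object)
    for (i in seq_len(nrow(mine))) {
      tag <- if (mine$relation[i] == "is_a") {
        paste0("is_a: ", mine$object[i])
      } else {
        paste0("relationship: ", mine$relation[i], " ", mine$object[i])
      }
      if (mine$status[i] == "inferred") {
        tag <- paste0(tag, " ! inferred (", mine$rule[i], ")")
      }
      lines <- c(lines, tag)
    }
    for (cl in closure$definitions[[id]] %||% list()) {
      val <- if (is_genus(cl)) cl$filler else paste(cl$relation, cl$filler)
      lines <- c(lines, paste0("intersection_of: ", val))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
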