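#' Reasoner rule configuration
#'
#' The forward-chaining reasoner computes the least fixpoint of:
#'
#' * R1 - `is_a` transitivity (always on).
#' * R2 - closure of declared transitive relations (default `part_of`).
#' * R3 - composition with `is_a` on either side: `A r B, B is_a C => A r C`
#'   and `A is_a B, B r C => A r C`.
#' * R4 - necessary conditions of a genus-differentia definition:
#'   `X = G and {(ri, Fi)}` entails `X is_a G` and `X ri Fi`.
#' * R5 - sufficiency: any `Z` with `Z is_a G` and `Z ri Fi` for every
#'   differentium of `X` is entailed to be a subclass of `X`.
#' * R6 (optional, off by default) - part-to-whole quality propagation:
#'   `A inheres_in B => A inheres_in_part_of B` and
#'   `A inheres_in_part_of B, B part_of C => A inheres_in_part_of C`.
#'   The derived relation is deliberately distinct from plain `inheres_in`,
#'   because part-to-whole inheritance of qualities is not generally valid.
#'
#' @param transitive_relations relations closed under R2; `is_a` is always
#'   included.
#' @param composition_over_is_a enable R3.
#' @param quality_propagates_over_part_of enable R6.
#' @param emit_reflexive keep reflexive edges in the output (they are always
#'   used for R5 matching internally; curators never need `X is_a X`).
#' @return An object of class `rule_config`.
#' @export
rule_config <- function(transitive_relations = c("is_a", "part_of"),
                        composition_over_is_a = TRUE,
                        quality_propagates_over_part_of = FALSE,
                        emit_reflexive = FALSE) {
  structure(
    list(
      transitive_relations = union("is_a", transitive_relations),
      composition_over_is_a = isTRUE(composition_over_is_a),
      quality_propagates_over_part_of = isTRUE(quality_propagates_over_part_of),
      emit_reflexive = isTRUE(emit_reflexive)
    ),
    class = "rule_config"
  )
}

#' Materialize composed expressions so a document contains only named classes
#'
#' Every composed class expression in the supplied EQ definitions (at any
#' nesting depth) becomes a stanza with a deterministic `XP:` identifier and
#' its own intersection clauses; no further classes are ever created during
#' reasoning.
#'
#' @param doc a merged [obo_document()].
#' @param eqs optional EQ definition set (tibble with `id`, `eq`, see
#'   [read_eq_file()]), or an [obo_document()] of intersection stanzas.
#' @param vocab a [relation_vocabulary()].
#' @return An [obo_document()].
#' @export
materialize_expressions <- function(doc, eqs = NULL,
                                    vocab = relation_vocabulary()) {
  if (is.null(eqs)) return(doc)
  xp_doc <- if (inherits(eqs, "obo_document")) eqs else as_xp_document(eqs, vocab)
  merge_documents(list(doc, xp_doc), ontology_id = doc$ontology_id %||% "merged")
}

doc_asserted_edges <- function(doc) {
  rows <- list()
  for (st in doc$stanzas) {
    if (st$is_obsolete) next
    for (p in st$is_a) {
      rows[[length(rows) + 1]] <- c(st$id, "is_a", p)
    }
    for (rel in st$relationships) {
      rows[[length(rows) + 1]] <- c(st$id, rel$relation, rel$target)
    }
  }
  if (!length(rows)) {
    return(tibble(subject = character(), relation = character(),
                  object = character()))
  }
  m <- do.call(rbind, rows)
  distinct(tibble(subject = m[, 1], relation = m[, 2], object = m[, 3]))
}

doc_definitions <- function(doc) {
  defs <- list()
  for (st in doc$stanzas) {
    if (length(st$intersection_of)) defs[[st$id]] <- st$intersection_of
  }
  defs
}

# Kahn's algorithm over asserted is_a; on failure, report one cycle found by
# depth-first search.
check_isa_acyclic <- function(edges) {
  isa <- edges[edges$relation == "is_a" & edges$subject != edges$object, ]
  if (!nrow(isa)) return(invisible(TRUE))
  adj <- split(isa$object, isa$subject)
  indeg <- table(factor(isa$object, levels = unique(c(isa$subject, isa$object))))
  nodes <- names(indeg)
  indeg <- as.integer(indeg)
  names(indeg) <- nodes
  queue <- nodes[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    seen <- seen + 1L
    for (w in adj[[v]] %||% character()) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (seen < length(nodes)) {
    rem <- names(indeg)[indeg > 0L]
    cyc <- find_cycle(adj, rem)
    stop_phenoxp(
      paste0("asserted is_a cycle among distinct classes: ",
             paste(cyc, collapse = " -> ")),
      "phenoxp_cycle"
    )
  }
  invisible(TRUE)
}

find_cycle <- function(adj, nodes) {
  start <- nodes[1]
  path <- start
  cur <- start
  repeat {
    nxt <- intersect(adj[[cur]] %||% character(), nodes)[1]
    if (is.na(nxt)) return(path)
    if (nxt %in% path) {
      return(c(path[seq(match(nxt, path), length(path))], nxt))
    }
    path <- c(path, nxt)
    cur <- nxt
  }
}

new_edges <- function(subject, relation, object, rule, premises) {
  tibble(subject = subject, relation = relation, object = object,
         status = "inferred", rule = rule, premises = premises)
}

join_edges <- function(left, right, out_rule) {
  # (l.subject, l.relation, r.object) from pairs with l.object == r.subject
  if (!nrow(left) || !nrow(right)) return(NULL)
  j <- inner_join(
    transmute(left, subject, relation, mid = object,
              pk1 = edge_key(subject, relation, object)),
    transmute(right, mid = subject, object,
              pk2 = edge_key(subject, relation, object)),
    by = "mid", relationship = "many-to-many"
  )
  if (!nrow(j)) return(NULL)
  new_edges(j$subject, j$relation, j$object, out_rule,
            paste(j$pk1, j$pk2, sep = ";"))
}

derive_transitive <- function(delta, all, transitive) {
  out <- list()
  for (r in transitive) {
    d <- delta[delta$relation == r, ]
    a <- all[all$relation == r, ]
    rule <- if (r == "is_a") "R1" else "R2"
    out <- c(out, list(join_edges(d, a, rule), join_edges(a, d, rule)))
  }
  out
}

derive_composition <- function(delta, all) {
  isa_all <- all[all$relation == "is_a", ]
  isa_d <- delta[delta$relation == "is_a", ]
  rel_all <- all[all$relation != "is_a", ]
  rel_d <- delta[delta$relation != "is_a", ]
  # A r B, B is_a C => A r C
  comp1 <- list(join_edges(rel_d, isa_all, "R3"),
                join_edges(rel_all, isa_d, "R3"))
  # A is_a B, B r C => A r C (keep the r of the right edge)
  swap <- function(left, right) {
    if (!nrow(left) || !nrow(right)) return(NULL)
    j <- inner_join(
      transmute(left, subject, mid = object,
                pk1 = edge_key(subject, relation, object)),
      transmute(right, mid = subject, relation, object,
                pk2 = edge_key(subject, relation, object)),
      by = "mid", relationship = "many-to-many"
    )
    if (!nrow(j)) return(NULL)
    new_edges(j$subject, j$relation, j$object, "R3",
              paste(j$pk1, j$pk2, sep = ";"))
  }
  c(comp1, list(swap(isa_d, rel_all), swap(isa_all, rel_d)))
}

derive_quality_propagation <- function(delta, all, vocab) {
  ii <- vocab$inheres_in
  iipo <- vocab$inheres_in_part_of
  po <- vocab$part_of
  out <- list()
  d_ii <- delta[delta$relation == ii, ]
  if (nrow(d_ii)) {
    out <- c(out, list(new_edges(
      d_ii$subject, iipo, d_ii$object, "R6",
      edge_key(d_ii$subject, ii, d_ii$object)
    )))
  }
  d_iipo <- delta[delta$relation == iipo, ]
  a_iipo <- all[all$relation == iipo, ]
  d_po <- delta[delta$relation == po, ]
  a_po <- all[all$relation == po, ]
  propagate <- function(left, right) {
    if (!nrow(left) || !nrow(right)) return(NULL)
    j <- inner_join(
      transmute(left, subject, mid = object,
                pk1 = edge_key(subject, relation, object)),
      transmute(right, mid = subject, object,
                pk2 = edge_key(subject, relation, object)),
      by = "mid", relationship = "many-to-many"
    )
    if (!nrow(j)) return(NULL)
    new_edges(j$subject, iipo, j$object, "R6",
              paste(j$pk1, j$pk2, sep = ";"))
  }
  c(out, list(propagate(d_iipo, a_po), propagate(a_iipo, d_po)))
}

derive_sufficiency <- function(all, defs) {
  out <- list()
  isa <- all[all$relation == "is_a", ]
  for (x in names(defs)) {
    clauses <- defs[[x]]
    genus <- NULL
    diffs <- list()
    for (cl in clauses) {
      if (is_genus(cl)) genus <- cl$filler else diffs <- c(diffs, list(cl))
    }
    z <- NULL
    prem_genus <- NULL
    if (!is.null(genus)) {
      under <- isa$subject[isa$object == genus]
      z <- unique(c(under, genus))
    }
    for (d in diffs) {
      zi <- all$subject[all$relation == d$relation & all$object == d$filler]
      z <- if (is.null(z)) unique(zi) else intersect(z, zi)
      if (!length(z)) break
    }
    z <- setdiff(z, x)
    if (!length(z)) next
    prem <- map_chr(z, function(zz) {
      parts <- paste0("def:", x)
      if (!is.null(genus)) {
        parts <- c(parts, if (zz == genus) paste0("reflexive:", genus)
                   else edge_key(zz, "is_a", genus))
      }
      for (d in diffs) parts <- c(parts, edge_key(zz, d$relation, d$filler))
      paste(parts, collapse = ";")
    })
    out <- c(out, list(new_edges(z, "is_a", x, "R5", prem)))
  }
  out
}

#' Compute the deductive closure of an ontology document
#'
#' Forward-chains the rule set of [rule_config()] to its least fixpoint over
#' the asserted links and genus-differentia definitions of `doc` (which
#' should already be materialized: see [materialize_expressions()]).
#' Evaluation is semi-naive - transitivity and composition rules re-fire only
#' against the newest edge delta - and terminates because the edge universe
#' is finite. Reflexive edges are used for sufficiency matching but
#' suppressed in the output. A cycle among asserted `is_a` links between
#' distinct classes is an error.
#'
#' @param doc an [obo_document()] (merged and materialized).
#' @param config a [rule_config()].
#' @param vocab a [relation_vocabulary()].
#' @return An object of class `closure_graph` with fields `classes`, `edges`
#'   (tibble: subject, relation, object, status, rule, premises),
#'   `definitions`, `labels`, `config`, `vocab`.
#' @export
compute_closure <- function(doc, config = rule_config(),
                            vocab = relation_vocabulary()) {
  transitive <- union(config$transitive_relations, doc$transitive_relations)
  asserted <- doc_asserted_edges(doc)
  defs <- doc_definitions(doc)
  check_isa_acyclic(asserted)

  classes <- unique(c(
    names(doc$stanzas), asserted$subject, asserted$object,
    unlist(map(defs, ~ map_chr(.x, "filler")))
  ))

  asserted <- mutate(asserted, status = "asserted", rule = NA_character_,
                     premises = NA_character_)
  r4 <- list()
  for (x in names(defs)) {
    for (cl in defs[[x]]) {
      r4[[length(r4) + 1]] <- tibble(
        subject = x,
        relation = if (is_genus(cl)) "is_a" else cl$relation,
        object = cl$filler,
        status = "inferred", rule = "R4", premises = paste0("def:", x)
      )
    }
  }
  edges <- bind_rows(c(list(asserted), r4))
  edges <- edges[edges$subject != edges$object | edges$relation != "is_a", ]
  edges <- edges[!duplicated(edge_key(edges$subject, edges$relation, edges$object)), ]

  seen <- new.env(parent = emptyenv(), size = 4L * nrow(edges) + 16L)
  for (k in edge_key(edges$subject, edges$relation, edges$object)) {
    assign(k, TRUE, envir = seen)
  }

  delta <- edges
  repeat {
    batches <- c(
      derive_transitive(delta, edges, transitive),
      if (config$composition_over_is_a) derive_composition(delta, edges),
      if (config$quality_propagates_over_part_of)
        derive_quality_propagation(delta, edges, vocab),
      derive_sufficiency(edges, defs)
    )
    batches <- compact(batches)
    if (!length(batches)) break
    cand <- bind_rows(batches)
    cand <- cand[cand$subject != cand$object, ]
    if (!nrow(cand)) break
    keys <- edge_key(cand$subject, cand$relation, cand$object)
    keep_rows <- !duplicated(keys)
    cand <- cand[keep_rows, ]
    keys <- keys[keep_rows]
    fresh <- !vapply(keys, exists, logical(1), envir = seen, inherits = FALSE)
    cand <- cand[fresh, ]
    keys <- keys[fresh]
    if (!nrow(cand)) break
    for (k in keys) assign(k, TRUE, envir = seen)
    edges <- bind_rows(edges, cand)
    delta <- cand
  }

  edges <- arrange(edges, .data$relation, .data$subject, .data$object)
  structure(
    list(
      classes = sort(classes),
      edges = edges,
      definitions = defs,
      labels = collect_labels(doc),
      config = config,
      vocab = vocab
    ),
    class = "closure_graph"
  )
}

#' @export
print.closure_graph <- function(x, ...) {
  cat(sprintf(
    "<closure_graph: %d classes, %d edges (%d asserted, %d inferred), %d definitions>\n",
    length(x$classes), nrow(x$edges), sum(x$edges$status == "asserted"),
    sum(x$edges$status == "inferred"), length(x$definitions)))
  invisible(x)
}
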