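#' Recapitulate a phenotype ontology's is_a links from its logical definitions
#'
#' The validation experiment: every asserted `is_a` link of the phenotype
#' ontology is removed (the support ontologies are untouched), the deductive
#' closure is recomputed from the XP definitions plus the support ontologies,
#' and each original asserted edge is classified as recovered (re-inferred,
#' directly or indirectly) or missed. Newly inferred phenotype-internal
#' direct edges that were never asserted are reported as novel. Two recall
#' denominators are reported: `recall_all` uses every asserted link,
#' including links between classes that have no definition and so can never
#' be recovered; `recall_defined` restricts to links whose both endpoints
#' have definitions, isolating definition quality from coverage.
#'
#' @param phenotype_doc the phenotype [obo_document()].
#' @param xp_defs definition set: an [obo_document()] of intersection stanzas
#'   or a tibble with `id`, `eq` columns.
#' @param support_docs list of referenced ontology documents (quality,
#'   anatomy, cell, ...).
#' @param config a [rule_config()].
#' @param vocab a [relation_vocabulary()].
#' @return An object of class `recap_report`: tibbles `recovered`, `missed`,
#'   `novel`, the two recall fractions, and the underlying `closure`.
#' @export
recapitulate <- function(phenotype_doc, xp_defs, support_docs = list(),
                         config = rule_config(),
                         vocab = relation_vocabulary()) {
  if (!length(phenotype_doc$stanzas)) {
    stop_phenoxp("phenotype document has no classes; nothing to recapitulate",
                 "phenoxp_empty_report")
  }
  phen_ids <- names(phenotype_doc$stanzas)
  asserted <- doc_asserted_edges(phenotype_doc)
  asserted <- asserted[asserted$relation == "is_a" &
                         asserted$object %in% phen_ids, c("subject", "object")]

  stripped <- strip_isa(phenotype_doc, phen_ids)
  merged <- merge_documents(
    c(list(stripped), flatten_docs(support_docs)),
    ontology_id = "recap"
  )
  merged <- materialize_expressions(merged, xp_defs, vocab)
  closure <- compute_closure(merged, config, vocab)

  isa <- closure$edges[closure$edges$relation == "is_a", ]
  inferred_keys <- paste(isa$subject, isa$object)
  asserted_keys <- paste(asserted$subject, asserted$object)
  recovered <- asserted[asserted_keys %in% inferred_keys, ]
  missed <- asserted[!asserted_keys %in% inferred_keys, ]

  novel <- infer_novel_links(closure, unique(curie_prefix(phen_ids))[1])
  novel <- novel[!paste(novel$subject, novel$object) %in% asserted_keys, ]

  defined <- names(doc_definitions(materialize_expressions(
    obo_document("defs"), xp_defs, vocab)))
  both_defined <- asserted$subject %in% defined & asserted$object %in% defined
  n_def <- sum(both_defined)
  rec_def <- sum(both_defined & asserted_keys %in% inferred_keys)

  structure(
    list(
      recovered = as_tibble(recovered),
      missed = as_tibble(missed),
      novel = novel,
      recall_all = if (nrow(asserted)) nrow(recovered) / nrow(asserted) else 0,
      recall_defined = if (n_def) rec_def / n_def else 0,
      n_asserted = nrow(asserted),
      n_defined_links = n_def,
      closure = closure
    ),
    class = "recap_report"
  )
}

strip_isa <- function(doc, ids) {
  stanzas <- map(doc$stanzas, function(st) {
    st$is_a <- setdiff(st$is_a, ids)
    st
  })
  obo_document(
    ontology_id = doc$ontology_id, header = doc$header,
    stanzas = unname(stanzas), typedefs = doc$typedefs
  )
}

#' @export
print.recap_report <- function(x, ...) {
  cat("Recapitulation of asserted is_a links\n")
  cat(sprintf("  asserted:  %d\n", x$n_asserted))
  cat(sprintf("  recovered: %d (recall_all = %.3f)\n",
              nrow(x$recovered), x$recall_all))
  cat(sprintf("  missed:    %d\n", nrow(x$missed)))
  cat(sprintf("  novel:     %d proposed direct links\n", nrow(x$novel)))
  cat(sprintf("  recall over links between defined classes: %.3f (%d links)\n",
              x$recall_defined, x$n_defined_links))
  invisible(x)
}

#' Write a missing-link curation report
#'
#' Serializes the novel direct links proposed by the reasoner as a
#' tab-separated file for curator triage: subject and object with labels, the
#' rule chain down to asserted edges, and an initially `pending` verdict
#' column plus an empty note column. Verdicts follow the four observed triage
#' outcomes: accepted, rejected, partially-correct, pending.
#'
#' @param closure a [compute_closure()] result (or a [recapitulate()] report,
#'   whose novel set is then used).
#' @param target_prefix phenotype ontology prefix.
#' @param path output file.
#' @param provenance optional comment lines written as a `#` header.
#' @return The report tibble, invisibly.
#' @export
missing_link_report <- function(closure, target_prefix, path = NULL,
                                provenance = NULL) {
  novel <- if (inherits(closure, "recap_report")) {
    closure$novel
  } else {
    infer_novel_links(closure, target_prefix)
  }
  report <- tibble(
    subject_id = novel$subject,
    subject_label = novel$subject_label,
    object_id = novel$object,
    object_label = novel$object_label,
    rule_chain = novel$rule_chain,
    verdict = rep("pending", nrow(novel)),
    note = rep("", nrow(novel))
  )
  if (!is.null(path)) {
    write_tsv_with_header(report, path, provenance)
  }
  invisible(report)
}

#' Read back a triaged curation file
#'
#' @param path a file written by [missing_link_report()] (possibly with
#'   verdicts filled in by a curator).
#' @return A list with the `report` tibble and `verdicts`, a count per
#'   verdict category.
#' @export
read_curation_file <- function(path) {
  report <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                            col_types = readr::cols(.default = "c"))
  report$note[is.na(report$note)] <- ""
  verdicts <- count(report, .data$verdict, name = "n")
  list(report = report, verdicts = verdicts)
}

#' Consistency lint between a phenotype ontology and its reference ontologies
#'
#' Two kinds of cryptic inconsistency are surfaced:
#'
#' * `missing-path` - an asserted phenotype `is_a` link that cannot possibly
#'   be entailed because the supporting ontologies contain no connecting path
#'   between the two definitions' fillers (the classic case: 'asymmetric
#'   snout' under 'abnormal facial morphology' while the anatomy ontology has
#'   no link between 'snout' and 'face'). The finding names the filler pair
#'   whose connection is absent.
#' * `missing-counterpart` - a reference-ontology subsumption with no
#'   counterpart between correspondingly-defined phenotype classes (e.g.
#'   'pancreatic delta cell' under 'enteroendocrine cell' in the cell
#'   ontology while the two 'abnormal ... morphology' classes are unrelated).
#'   Only same-quality, same-qualifier definition pairs differing in the one
#'   entity filler are compared.
#'
#' The entailment check runs with part-to-whole quality propagation enabled,
#' so definitions phrased with `inheres_in_part_of` participate.
#'
#' @inheritParams recapitulate
#' @return A tibble of findings: `type`, `subject`, `object`,
#'   `filler_subject`, `filler_object`, `detail`.
#' @export
consistency_lint <- function(phenotype_doc, xp_defs, support_docs = list(),
                             config = rule_config(quality_propagates_over_part_of = TRUE),
                             vocab = relation_vocabulary()) {
  rec <- recapitulate(phenotype_doc, xp_defs, support_docs, config, vocab)
  defs <- doc_definitions(materialize_expressions(
    obo_document("defs"), xp_defs, vocab))
  support <- merge_documents(flatten_docs(support_docs), ontology_id = "support")
  sup_closure <- compute_closure(support, rule_config(), vocab)
  sup <- sup_closure$edges[sup_closure$edges$relation %in%
                            c("is_a", vocab$part_of), ]
  connected <- function(a, b) {
    if (a == b) return(TRUE)
    # reachability over is_a/part_of, both already transitively closed
    # individually; walk to cover mixed chains
    frontier <- a
    seen <- character()
    while (length(frontier)) {
      if (b %in% frontier) return(TRUE)
      seen <- c(seen, frontier)
      nxt <- unique(sup$object[sup$subject %in% frontier])
      frontier <- setdiff(nxt, seen)
    }
    FALSE
  }

  findings <- list()
  add <- function(type, subject, object, fa, fb, detail) {
    findings[[length(findings) + 1]] <<- tibble(
      type = type, subject = subject, object = object,
      filler_subject = fa, filler_object = fb, detail = detail)
  }

  entity_rels <- c(vocab$inheres_in, vocab$inheres_in_part_of, vocab$towards)
  clause_parts <- function(id) {
    cls <- defs[[id]]
    genus <- NULL
    diffs <- list()
    for (cl in cls %||% list()) {
      if (is_genus(cl)) genus <- cl$filler else diffs <- c(diffs, list(cl))
    }
    list(genus = genus, diffs = diffs)
  }

  # (a) asserted-but-unentailable links: find the unconnected filler pair
  for (i in seq_len(nrow(rec$missed))) {
    a <- rec$missed$subject[i]
    b <- rec$missed$object[i]
    if (is.null(defs[[a]]) || is.null(defs[[b]])) next
    pa <- clause_parts(a)
    pb <- clause_parts(b)
    if (!is.null(pa$genus) && !is.null(pb$genus) &&
        !connected(pa$genus, pb$genus)) {
      add("missing-path", a, b, pa$genus, pb$genus,
          "no is_a path between the quality genera")
      next
    }
    for (db in pb$diffs) {
      if (!db$relation %in% entity_rels) next
      cand <- keep(pa$diffs, ~ .x$relation %in% entity_rels)
      if (!length(cand)) next
      reachable <- map_lgl(cand, ~ connected(.x$filler, db$filler))
      if (!any(reachable)) {
        fa <- cand[[1]]$filler
        add("missing-path", a, b, fa, db$filler,
            sprintf("no is_a/part_of path from '%s' to '%s' in the support ontologies",
                    fa, db$filler))
      }
    }
  }

  # (b) reference subsumptions with no phenotype counterpart
  phen_ids <- names(phenotype_doc$stanzas)
  asserted <- doc_asserted_edges(phenotype_doc)
  asserted <- asserted[asserted$relation == "is_a", ]
  # asserted transitive reachability among phenotype classes
  phen_reach <- function(a, b) {
    frontier <- a
    seen <- character()
    while (length(frontier)) {
      if (b %in% frontier) return(TRUE)
      seen <- c(seen, frontier)
      nxt <- unique(asserted$object[asserted$subject %in% frontier])
      frontier <- setdiff(nxt, seen)
    }
    FALSE
  }
  defined <- intersect(phen_ids, names(defs))
  parts <- map(stats::setNames(defined, defined), clause_parts)
  for (a in defined) for (b in defined) {
    if (a == b) next
    pa <- parts[[a]]
    pb <- parts[[b]]
    if (!identical(pa$genus, pb$genus)) next
    da <- pa$diffs
    db <- pb$diffs
    if (length(da) != length(db)) next
    qa <- keep(da, ~ .x$relation == vocab$has_qualifier)
    qb <- keep(db, ~ .x$relation == vocab$has_qualifier)
    if (!identical(map_chr(qa, "filler"), map_chr(qb, "filler"))) next
    ea <- keep(da, ~ .x$relation %in% c(vocab$inheres_in, vocab$inheres_in_part_of))
    eb <- keep(db, ~ .x$relation %in% c(vocab$inheres_in, vocab$inheres_in_part_of))
    if (length(ea) != 1L || length(eb) != 1L) next
    if (ea[[1]]$relation != eb[[1]]$relation) next
    fa <- ea[[1]]$filler
    fb <- eb[[1]]$filler
    if (fa == fb) next
    isa_sup <- sup[sup$relation == "is_a", ]
    if (!any(isa_sup$subject == fa & isa_sup$object == fb)) next
    if (!phen_reach(a, b)) {
      add("missing-counterpart", a, b, fa, fb,
          sprintf("'%s' is_a '%s' in the reference ontology but the phenotype classes are unrelated",
                  fa, fb))
    }
  }

  if (!length(findings)) {
    return(tibble(type = character(), subject = character(),
                  object = character(), filler_subject = character(),
                  filler_object = character(), detail = character()))
  }
  bind_rows(findings)
}

#' Definition coverage statistics
#'
#' Counts non-obsolete classes, how many have a logical definition, the
#' percentage, and a breakdown of definitions by the entity-ontology prefixes
#' their fillers come from (a definition may touch several ontologies, so the
#' per-prefix counts can sum to more than the number of defined classes).
#'
#' @param phenotype_doc the phenotype [obo_document()].
#' @param xp_defs definition set ([obo_document()] or `id`/`eq` tibble).
#' @param quality_prefix prefix of the quality ontology, excluded from the
#'   entity breakdown.
#' @param vocab a [relation_vocabulary()].
#' @return An object of class `xp_coverage` with a one-row `summary` tibble
#'   (`ontology`, `total_classes`, `defined`, `pct`) and a `by_prefix`
#'   tibble (`prefix`, `n_definitions`).
#' @export
coverage_stats <- function(phenotype_doc, xp_defs, quality_prefix = "PATO",
                           vocab = relation_vocabulary()) {
  xp_doc <- materialize_expressions(obo_document("defs"), xp_defs, vocab)
  defs <- doc_definitions(xp_doc)
  live <- keep(phenotype_doc$stanzas, ~ !.x$is_obsolete)
  ids <- map_chr(live, "id")
  defined <- intersect(ids, names(defs))

  expand_prefixes <- function(id) {
    cls <- defs[[id]]
    out <- character()
    for (cl in cls) {
      if (is_genus(cl)) next
      if (cl$relation == vocab$has_qualifier) next
      out <- c(out, filler_prefixes(cl$filler, defs))
    }
    unique(out)
  }
  filler_prefixes <- function(id, defs) {
    if (grepl("^XP:", id) && !is.null(defs[[id]])) {
      cls <- defs[[id]]
      return(unlist(map(cls, function(cl) {
        if (is_genus(cl)) curie_prefix(cl$filler)
        else filler_prefixes(cl$filler, defs)
      })))
    }
    curie_prefix(id)
  }

  n_def <- length(defined)
  prefixes <- unlist(map(defined, expand_prefixes))
  prefixes <- prefixes[prefixes != quality_prefix]
  by_prefix <- if (length(prefixes)) {
    arrange(count(tibble(prefix = prefixes), .data$prefix,
                  name = "n_definitions"),
            desc(.data$n_definitions), .data$prefix)
  } else {
    tibble(prefix = character(), n_definitions = integer())
  }
  structure(
    list(
      summary = tibble(
        ontology = phenotype_doc$ontology_id %||% NA_character_,
        total_classes = length(ids),
        defined = n_def,
        pct = if (length(ids)) 100 * n_def / length(ids) else 0
      ),
      by_prefix = by_prefix
    ),
    class = "xp_coverage"
  )
}

#' @export
print.xp_coverage <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Coverage for '%s': %d / %d classes defined (%.1f%%)\n",
              s$ontology, s$defined, s$total_classes, s$pct))
  if (nrow(x$by_prefix)) {
    for (i in seq_len(nrow(x$by_prefix))) {
      cat(sprintf("  %-12s %d\n", x$by_prefix$prefix[i],
                  x$by_prefix$n_definitions[i]))
    }
  }
  invisible(x)
}

#' Write a recapitulation summary
#'
#' Human-readable text plus a machine-readable key-value block.
#'
#' @param report a [recapitulate()] report.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_recap_summary <- function(report, path) {
  lines <- c(
    "Recapitulation of asserted is_a links",
    sprintf("  asserted links:  %d", report$n_asserted),
    sprintf("  recovered:       %d", nrow(report$recovered)),
    sprintf("  missed:          %d", nrow(report$missed)),
    sprintf("  novel proposals: %d", nrow(report$novel)),
    "",
    "[summary]",
    sprintf("n_asserted=%d", report$n_asserted),
    sprintf("n_recovered=%d", nrow(report$recovered)),
    sprintf("n_missed=%d", nrow(report$missed)),
    sprintf("n_novel=%d", nrow(report$novel)),
    sprintf("recall_all=%.6f", report$recall_all),
    sprintf("recall_defined=%.6f", report$recall_defined)
  )
  writeLines(lines, path)
  invisible(path)
}
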