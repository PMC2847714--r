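#' Parameters for the random ontology-suite generator
#'
#' The generator emulates the recapitulation study design at desk scale: a
#' quality ontology and an entity ontology (rooted random DAGs), a phenotype
#' ontology whose classes carry genus-differentia definitions over sampled
#' (quality, entity) pairs, an asserted is_a graph consisting of the entailed
#' links minus a withheld set plus extra links that no definition supports,
#' and a ground-truth manifest that makes expected recall and expected novel
#' links exact by construction.
#'
#' @param seed integer seed; identical parameters give byte-identical output.
#' @param n_quality,n_entity,n_phenotype class counts per ontology.
#' @param extra_parent_prob probability that a DAG node gets a second parent.
#' @param defined_fraction fraction of phenotype classes given a logical
#'   definition (default mirrors a well-curated cross-product set).
#' @param withheld_links number of entailed direct links withheld from the
#'   asserted graph (the expected novel set).
#' @param unsupported_links number of asserted links that no definition
#'   entails (the expected missed set).
#' @param nesting_prob probability that a definition's bearer is a nested
#'   `component^part_of(structure)` expression.
#' @param modifier_prob probability that a definition carries an 'abnormal'
#'   modifier.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(seed = 101L, n_quality = 12L, n_entity = 25L,
                             n_phenotype = 40L, extra_parent_prob = 0.15,
                             defined_fraction = 0.73, withheld_links = 5L,
                             unsupported_links = 10L, nesting_prob = 0.1,
                             modifier_prob = 0.25) {
  structure(
    list(seed = as.integer(seed), n_quality = as.integer(n_quality),
         n_entity = as.integer(n_entity),
         n_phenotype = as.integer(n_phenotype),
         extra_parent_prob = extra_parent_prob,
         defined_fraction = defined_fraction,
         withheld_links = as.integer(withheld_links),
         unsupported_links = as.integer(unsupported_links),
         nesting_prob = nesting_prob, modifier_prob = modifier_prob),
    class = "generator_params"
  )
}

random_dag <- function(n, extra_parent_prob) {
  parents <- vector("list", n)
  for (i in seq_len(n)[-1]) {
    p <- sample.int(i - 1L, 1L)
    parents[[i]] <- p
    if (i > 2L && stats::runif(1) < extra_parent_prob) {
      q <- sample.int(i - 1L, 1L)
      if (q != p) parents[[i]] <- c(p, q)
    }
  }
  parents
}

dag_ancestors <- function(parents) {
  n <- length(parents)
  anc <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- parents[[i]]
    anc[[i]] <- sort(unique(c(ps, unlist(anc[ps]))))
  }
  anc
}

dag_document <- function(ontology_id, prefix, stem, parents, seed) {
  n <- length(parents)
  ids <- sprintf("%s:%07d", prefix, seq_len(n))
  stanzas <- map(seq_len(n), function(i) {
    term_stanza(
      id = ids[i],
      name = if (i == 1L) paste0(stem, " root") else paste0(stem, i),
      is_a = ids[parents[[i]] %||% integer()]
    )
  })
  obo_document(
    ontology_id = ontology_id,
    header = c("format-version: 1.2",
               paste0("ontology: ", ontology_id),
               paste0("remark: phenoxp-generator seed=", seed)),
    stanzas = stanzas
  )
}

#' Generate a random ontology suite with known entailments
#'
#' Builds the documents described in [generator_params()]. Entailed phenotype
#' subsumptions are computed with the independent naive-saturation oracle
#' ([naive_closure()]), not the production reasoner, so generator and
#' reasoner cannot share a bug. Withheld links are sampled from the entailed
#' direct links; unsupported extra links are sampled only between classes
#' whose definitions do not entail them (keeping the asserted graph acyclic),
#' guaranteeing they count as missed during recapitulation. To keep the
#' withheld-link experiment well posed at any seed, the generator first mints
#' a few guaranteed child/parent definition pairs (child quality and entity
#' strictly under the parent's) before filling in random definitions.
#'
#' @param params a [generator_params()] list.
#' @param vocab a [relation_vocabulary()].
#' @return A list of class `xp_suite`: `documents` (quality, entity,
#'   phenotype), `xp_defs` (tibble `id`, `eq`), and `ground_truth` with
#'   tibbles `entailed`, `direct`, `withheld`, `unsupported`, `asserted` and
#'   the expected `recall_all`, `recall_defined`.
#' @export
generate_suite <- function(params = generator_params(),
                           vocab = relation_vocabulary()) {
  p <- params
  n_guaranteed <- if (p$withheld_links > 0L) p$withheld_links + 3L else 0L
  n_defined <- max(round(p$defined_fraction * p$n_phenotype),
                   2L * n_guaranteed)
  if (n_defined > p$n_phenotype) {
    stop_phenoxp(
      "infeasible generator parameters: not enough phenotype classes for the requested withheld links",
      "phenoxp_generation"
    )
  }
  with_seed(p$seed, {
    q_parents <- random_dag(p$n_quality, p$extra_parent_prob)
    e_parents <- random_dag(p$n_entity, p$extra_parent_prob)
    q_anc <- dag_ancestors(q_parents)
    e_anc <- dag_ancestors(e_parents)
    q_ids <- sprintf("GQ:%07d", seq_len(p$n_quality))
    e_ids <- sprintf("GE:%07d", seq_len(p$n_entity))
    p_ids <- sprintf("GP:%07d", seq_len(p$n_phenotype))

    quality_doc <- dag_document("gen-quality", "GQ", "quality", q_parents,
                                p$seed)
    entity_doc <- dag_document("gen-entity", "GE", "entity", e_parents,
                               p$seed)

    seen_def <- character()
    def_key <- function(e, q, m = NULL) {
      paste(format(canonicalize_expr(e)), q, m %||% "none")
    }
    defs <- list()  # phenotype index -> eq or NULL
    slot <- 1L

    sample_with_ancestor <- function(anc) {
      cand <- which(lengths(anc) > 0L)
      i <- cand[sample.int(length(cand), 1L)]
      a <- anc[[i]]
      list(child = i, parent = a[sample.int(length(a), 1L)])
    }

    # guaranteed child/parent definition pairs
    for (k in seq_len(n_guaranteed)) {
      for (try in 1:50) {
        ep <- sample_with_ancestor(e_anc)
        qi_child <- sample.int(p$n_quality, 1L)
        q_choices <- c(qi_child, q_anc[[qi_child]])
        qi_parent <- q_choices[sample.int(length(q_choices), 1L)]
        e_child <- xp_named(e_ids[ep$child])
        e_par <- xp_named(e_ids[ep$parent])
        k1 <- def_key(e_child, q_ids[qi_child])
        k2 <- def_key(e_par, q_ids[qi_parent])
        if (k1 != k2 && !k1 %in% seen_def && !k2 %in% seen_def) {
          defs[[slot]] <- eq(e_child, q_ids[qi_child])
          defs[[slot + 1L]] <- eq(e_par, q_ids[qi_parent])
          seen_def <- c(seen_def, k1, k2)
          slot <- slot + 2L
          break
        }
      }
    }

    # random definitions for the remaining defined classes
    while (slot <= n_defined) {
      placed <- FALSE
      for (try in 1:50) {
        qi <- sample.int(p$n_quality, 1L)
        if (stats::runif(1) < p$nesting_prob && p$n_entity >= 2L) {
          pair <- sample.int(p$n_entity, 2L)
          ent <- xp_composed(e_ids[pair[1]], list(
            list(relation = vocab$part_of, filler = xp_named(e_ids[pair[2]]))
          ))
        } else {
          ent <- xp_named(e_ids[sample.int(p$n_entity, 1L)])
        }
        modifier <- if (stats::runif(1) < p$modifier_prob) "GQ:abnormal"
        kk <- def_key(ent, q_ids[qi], modifier)
        if (!kk %in% seen_def) {
          defs[[slot]] <- eq(ent, q_ids[qi], modifier = modifier)
          seen_def <- c(seen_def, kk)
          placed <- TRUE
          break
        }
      }
      if (!placed) break
      slot <- slot + 1L
    }
    n_defined <- slot - 1L

    # phenotype document without is_a links (added below from ground truth)
    labels <- map_chr(seq_len(p$n_phenotype), function(i) {
      if (i <= n_defined && is_named_expr(defs[[i]]$entity) &&
          is.null(defs[[i]]$modifier)) {
        qi <- match(defs[[i]]$quality, q_ids)
        ei <- match(defs[[i]]$entity$id, e_ids)
        nm <- paste(
          if (qi == 1L) "quality root" else paste0("quality", qi),
          if (ei == 1L) "entity root" else paste0("entity", ei)
        )
        nm
      } else {
        paste0("phenotype", i)
      }
    })
    # the quality ontology also carries the modifier class used by defs
    quality_doc$stanzas[["GQ:abnormal"]] <-
      term_stanza("GQ:abnormal", "abnormal modifier", is_a = q_ids[1])
    quality_doc$source[["GQ:abnormal"]] <- quality_doc$ontology_id

    def_tbl <- tibble(
      id = p_ids[seq_len(n_defined)],
      eq = defs[seq_len(n_defined)]
    )

    bare_phenotype <- obo_document(
      ontology_id = "gen-phenotype",
      header = c("format-version: 1.2", "ontology: gen-phenotype",
                 paste0("remark: phenoxp-generator seed=", p$seed)),
      stanzas = map(seq_len(p$n_phenotype), function(i) {
        term_stanza(id = p_ids[i], name = labels[i])
      })
    )

    # ground-truth entailments via the naive oracle
    merged <- materialize_expressions(
      merge_documents(list(quality_doc, entity_doc, bare_phenotype)),
      def_tbl, vocab
    )
    oracle <- naive_closure(merged, rule_config(), vocab)
    isa <- oracle[oracle$relation == "is_a" &
                    startsWith(oracle$subject, "GP:") &
                    startsWith(oracle$object, "GP:") &
                    oracle$subject != oracle$object, ]
    entailed <- tibble(subject = isa$subject, object = isa$object)
    ekeys <- paste(entailed$subject, entailed$object)
    up <- split(entailed$object, entailed$subject)
    is_direct <- map_lgl(seq_len(nrow(entailed)), function(i) {
      mids <- setdiff(up[[entailed$subject[i]]],
                      c(entailed$subject[i], entailed$object[i]))
      !any(map_lgl(mids,
                   ~ entailed$object[i] %in% (up[[.x]] %||% character())))
    })
    direct <- entailed[is_direct, ]
    if (nrow(direct) < p$withheld_links) {
      stop_phenoxp(
        sprintf(
          "infeasible generator parameters: only %d direct entailed links for %d withheld",
          nrow(direct), p$withheld_links),
        "phenoxp_generation"
      )
    }
    withheld <- direct[sort(sample.int(nrow(direct), p$withheld_links)), ]
    wkeys <- paste(withheld$subject, withheld$object)
    asserted <- entailed[!ekeys %in% wkeys, ]

    # unsupported extra links: never entailed, acyclicity preserved
    reach <- function(edges, a, b) {
      frontier <- a
      seen <- character()
      while (length(frontier)) {
        if (b %in% frontier) return(TRUE)
        seen <- c(seen, frontier)
        nxt <- unique(edges$object[edges$subject %in% frontier])
        frontier <- setdiff(nxt, seen)
      }
      FALSE
    }
    unsupported <- tibble(subject = character(), object = character())
    tries <- 0L
    while (nrow(unsupported) < p$unsupported_links && tries < 500L) {
      tries <- tries + 1L
      ab <- sample.int(p$n_phenotype, 2L)
      a <- p_ids[ab[1]]
      b <- p_ids[ab[2]]
      if (paste(a, b) %in%
            c(ekeys, paste(unsupported$subject, unsupported$object))) next
      # keep the union of entailed and asserted edges acyclic, so no
      # derived equivalence can arise between wrong assertions and
      # entailments
      cur <- bind_rows(entailed, unsupported)
      if (reach(cur, b, a)) next
      unsupported <- bind_rows(unsupported, tibble(subject = a, object = b))
    }
    if (nrow(unsupported) < p$unsupported_links) {
      stop_phenoxp(
        "infeasible generator parameters: could not place the requested unsupported links",
        "phenoxp_generation"
      )
    }

    all_asserted <- arrange(bind_rows(asserted, unsupported),
                            .data$subject, .data$object)
    phen_stanzas <- map(seq_len(p$n_phenotype), function(i) {
      term_stanza(
        id = p_ids[i], name = labels[i],
        is_a = sort(all_asserted$object[all_asserted$subject == p_ids[i]])
      )
    })
    phenotype_doc <- obo_document(
      ontology_id = "gen-phenotype",
      header = bare_phenotype$header,
      stanzas = phen_stanzas
    )

    n_ass <- nrow(all_asserted)
    akeys <- paste(all_asserted$subject, all_asserted$object)
    defined_ids <- def_tbl$id
    both_def <- all_asserted$subject %in% defined_ids &
      all_asserted$object %in% defined_ids
    recovered_keys <- akeys %in% ekeys

    structure(
      list(
        documents = list(quality = quality_doc, entity = entity_doc,
                         phenotype = phenotype_doc),
        xp_defs = def_tbl,
        ground_truth = list(
          entailed = entailed, direct = direct, withheld = withheld,
          unsupported = unsupported, asserted = all_asserted,
          recall_all = if (n_ass) sum(recovered_keys) / n_ass else 0,
          recall_defined = if (sum(both_def)) {
            sum(recovered_keys & both_def) / sum(both_def)
          } else 0
        ),
        params = p
      ),
      class = "xp_suite"
    )
  })
}

#' @export
print.xp_suite <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf(
    "<xp_suite seed=%d: %d quality, %d entity, %d phenotype classes; %d defined; %d asserted links (%d withheld, %d unsupported)>\n",
    x$params$seed, x$params$n_quality, x$params$n_entity,
    x$params$n_phenotype, nrow(x$xp_defs), nrow(gt$asserted),
    nrow(gt$withheld), nrow(gt$unsupported)))
  invisible(x)
}

#' Write a generated suite to a directory
#'
#' Emits the three OBO documents, the EQ definition file, and a ground-truth
#' manifest in YAML.
#'
#' @param suite a [generate_suite()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_suite <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_obo(suite$documents$quality, file = file.path(dir, "quality.obo"))
  write_obo(suite$documents$entity, file = file.path(dir, "entity.obo"))
  write_obo(suite$documents$phenotype, file = file.path(dir, "phenotype.obo"))
  write_eq_file(suite$xp_defs, file.path(dir, "definitions.eq"))
  gt <- suite$ground_truth
  pair_list <- function(tb) {
    map(seq_len(nrow(tb)), ~ list(subject = tb$subject[.x],
                                  object = tb$object[.x]))
  }
  yaml::write_yaml(
    list(
      seed = suite$params$seed,
      recall_all = gt$recall_all,
      recall_defined = gt$recall_defined,
      entailed = pair_list(gt$entailed),
      withheld = pair_list(gt$withheld),
      unsupported = pair_list(gt$unsupported)
    ),
    file.path(dir, "ground_truth.yaml")
  )
  invisible(dir)
}
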