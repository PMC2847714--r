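#' Default Obol-style grammar configuration
#'
#' The production set is data rather than code, so per-ontology grammars can
#' mimic the terminological conventions of different phenotype ontologies
#' without code changes. Six productions ship as the default grammar (in
#' priority order):
#'
#' * `quality_bearer` - `quality bearer` ("big ears")
#' * `quality_of_bearer` - `quality "of" bearer` ("decreased diameter of femur")
#' * `abnormal_morphology` - `"abnormal" bearer "morphology"`
#' * `abnormal_bearer` - `"abnormal(ity) [of]" bearer` (quality-root + abnormal
#'   modifier, the "Abnormality of vision" pattern)
#' * `compound_bearer` - bearer resolution by splitting into an anatomical or
#'   cell structure followed by a cell-component head, yielding a nested
#'   `component^part_of(structure)` bearer ("Purkinje cell dendrite")
#' * `absent_bearer` - `"absent" bearer`: a lacking-all-parts-of-type
#'   description with E2 set to the bearer and E left unresolved for curation
#'   (the whole that lacks the part is anatomical knowledge, not label
#'   syntax)
#'
#' Bearer matching is longest-match and right-anchored (English phenotype
#' labels are head-final); all maximal parses are returned and ambiguity is
#' surfaced, never silently resolved.
#'
#' @return A list of class `xp_grammar`.
#' @export
default_grammar <- function() {
  structure(
    list(
      productions = c("quality_bearer", "quality_of_bearer",
                      "abnormal_morphology", "abnormal_bearer",
                      "compound_bearer", "absent_bearer"),
      role_priority = c("gross-anatomy", "cell", "cell-component",
                        "process", "chemical"),
      irregular_plurals = c(
        teeth = "tooth", feet = "foot", ganglia = "ganglion",
        vertebrae = "vertebra", testes = "testis", ossicles = "ossicle",
        vibrissae = "vibrissa", viscera = "viscus"
      ),
      abnormal_tokens = c("abnormal", "abnormality"),
      of_token = "of",
      morphology_label = "morphology",
      absent_token = "absent",
      quality_root_label = "quality",
      quality_root_id = "PATO:0000001",
      abnormal_label = "abnormal",
      absence_quality_label = "lacking all parts of type",
      absence_quality_id = "PATO:0002000",
      unresolved_id = "_UNRESOLVED_"
    ),
    class = "xp_grammar"
  )
}

#' Read a grammar configuration file
#'
#' A YAML file with any subset of the [default_grammar()] fields; unspecified
#' fields keep their defaults. See
#' `system.file("extdata", "default_grammar.yaml", package = "phenoxp")`.
#'
#' @param path YAML file path.
#' @return An `xp_grammar` configuration.
#' @export
read_grammar <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- default_grammar()
  for (nm in names(cfg)) {
    val <- cfg[[nm]]
    if (nm == "irregular_plurals" && is.list(val)) val <- unlist(val)
    g[[nm]] <- val
  }
  g
}

# Resolve a bearer token span to candidate class expressions.
# Returns a tibble: expr (list-col), role, via.
resolve_bearer <- function(tokens, lexicon, vocab, grammar,
                           allow_compound = TRUE) {
  out <- list()
  whole <- lexicon_bearer_entries(lexicon, tokens)
  if (!is.null(whole)) {
    for (i in seq_len(nrow(whole))) {
      out[[length(out) + 1]] <- list(
        expr = xp_named(whole$id[i]), role = whole$role[i], via = "whole")
    }
  }
  if (allow_compound && length(tokens) >= 2L) {
    for (split_at in seq_len(length(tokens) - 1L)) {
      struct <- lexicon_bearer_entries(lexicon, tokens[seq_len(split_at)])
      comp <- lexicon_bearer_entries(lexicon, tokens[(split_at + 1L):length(tokens)])
      if (is.null(struct) || is.null(comp)) next
      struct <- filter(struct, .data$role %in% c("gross-anatomy", "cell"))
      comp <- filter(comp, .data$role == "cell-component")
      if (!nrow(struct) || !nrow(comp)) next
      for (i in seq_len(nrow(comp))) {
        for (j in seq_len(nrow(struct))) {
          out[[length(out) + 1]] <- list(
            expr = xp_composed(comp$id[i], list(
              list(relation = vocab$part_of, filler = xp_named(struct$id[j]))
            )),
            role = comp$role[i], via = "compound"
          )
        }
      }
    }
  }
  out
}

#' Decompose a phenotype class label into candidate EQ descriptions
#'
#' Applies the grammar's productions over the normalized tokens of `label`.
#' All maximal parses are returned, ranked by (fewest unmatched tokens,
#' longest bearer span, bearer role priority, production priority); when more
#' than one distinct parse exists `is_ambiguous` is set and every parse is
#' present. Failure is an empty candidate list - such labels (clinical terms
#' like "situs inversus") go to the manual curation queue.
#'
#' @param label phenotype class label.
#' @param lexicon an [build_lexicon()] lexicon.
#' @param vocab a [relation_vocabulary()].
#' @param grammar a [default_grammar()] configuration.
#' @return An object of class `xp_parse_result`: a list with `label`,
#'   `candidates` (each a list with `eq`, `rule`, `bearer_span`, `role`),
#'   `unmatched_tokens` and `is_ambiguous`.
#' @export
parse_label <- function(label, lexicon, vocab = relation_vocabulary(),
                        grammar = default_grammar()) {
  stopifnot(nzchar(label))
  tokens <- normalize_tokens(label, grammar)
  n <- length(tokens)
  cands <- list()
  add <- function(eq, rule, bearer_span, role, prod_idx) {
    cands[[length(cands) + 1]] <<- list(
      eq = eq, rule = rule, bearer_span = bearer_span, role = role,
      prod_idx = prod_idx)
  }
  lookup_q1 <- function(key) {
    ids <- lexicon_quality_ids(lexicon, normalize_tokens(key, grammar))
    if (length(ids) == 1L) ids else NA_character_
  }

  for (prod_idx in seq_along(grammar$productions)) {
    prod <- grammar$productions[prod_idx]
    if (prod == "quality_bearer" && n >= 2L) {
      for (j in 2:n) {
        q_ids <- lexicon_quality_ids(lexicon, tokens[seq_len(j - 1L)])
        if (!length(q_ids)) next
        bearers <- resolve_bearer(tokens[j:n], lexicon, vocab, grammar)
        for (q in q_ids) for (b in bearers) {
          add(eq(entity = b$expr, quality = q), prod, n - j + 1L, b$role, prod_idx)
        }
      }
    } else if (prod == "quality_of_bearer" && n >= 3L) {
      ofs <- which(tokens == grammar$of_token)
      for (k in ofs[ofs > 1 & ofs < n]) {
        q_ids <- lexicon_quality_ids(lexicon, tokens[seq_len(k - 1L)])
        if (!length(q_ids)) next
        bearers <- resolve_bearer(tokens[(k + 1L):n], lexicon, vocab, grammar)
        for (q in q_ids) for (b in bearers) {
          add(eq(entity = b$expr, quality = q), prod, n - k, b$role, prod_idx)
        }
      }
    } else if (prod == "abnormal_morphology" && n >= 3L &&
               tokens[1] %in% grammar$abnormal_tokens &&
               tokens[n] == grammar$morphology_label) {
      q <- lookup_q1(grammar$morphology_label)
      m <- lookup_q1(grammar$abnormal_label)
      if (!is.na(q) && !is.na(m)) {
        bearers <- resolve_bearer(tokens[2:(n - 1L)], lexicon, vocab, grammar)
        for (b in bearers) {
          add(eq(entity = b$expr, quality = q, modifier = m),
              prod, n - 2L, b$role, prod_idx)
        }
      }
    } else if (prod == "abnormal_bearer" && n >= 2L &&
               tokens[1] %in% grammar$abnormal_tokens) {
      rest <- tokens[-1]
      if (length(rest) > 1L && rest[1] == grammar$of_token) rest <- rest[-1]
      m <- lookup_q1(grammar$abnormal_label)
      q <- lexicon_quality_ids(lexicon, normalize_tokens(grammar$quality_root_label, grammar))
      q <- if (length(q) == 1L) q else grammar$quality_root_id
      if (!is.na(m) && length(rest)) {
        bearers <- resolve_bearer(rest, lexicon, vocab, grammar)
        for (b in bearers) {
          add(eq(entity = b$expr, quality = q, modifier = m),
              prod, length(rest), b$role, prod_idx)
        }
      }
    } else if (prod == "absent_bearer" && n >= 2L &&
               tokens[1] == grammar$absent_token) {
      q <- lexicon_quality_ids(lexicon, normalize_tokens(grammar$absence_quality_label, grammar))
      q <- if (length(q) == 1L) q else grammar$absence_quality_id
      bearers <- resolve_bearer(tokens[2:n], lexicon, vocab, grammar)
      for (b in bearers) {
        e <- eq(entity = grammar$unresolved_id, quality = q, entity2 = b$expr)
        attr(e, "needs_curation") <- TRUE
        add(e, prod, n - 1L, b$role, prod_idx)
      }
    }
    # compound_bearer acts inside resolve_bearer(), not as a standalone rule
  }

  if (length(cands)) {
    keys <- map_chr(cands, function(cd) {
      paste(format(canonicalize_expr(cd$eq$entity)), cd$eq$quality,
            cd$eq$modifier %||% "",
            if (is.null(cd$eq$entity2)) "" else format(canonicalize_expr(cd$eq$entity2)))
    })
    role_rank <- match(map_chr(cands, "role"), grammar$role_priority)
    role_rank[is.na(role_rank)] <- length(grammar$role_priority) + 1L
    ord <- order(-map_int(cands, "bearer_span"), role_rank,
                 map_int(cands, "prod_idx"), keys, method = "radix")
    cands <- cands[ord]
    keys <- keys[ord]
    cands <- cands[!duplicated(keys)]
  }
  structure(
    list(
      label = label,
      candidates = cands,
      unmatched_tokens = if (length(cands)) character() else tokens,
      is_ambiguous = length(cands) > 1L
    ),
    class = "xp_parse_result"
  )
}

#' @export
print.xp_parse_result <- function(x, ...) {
  cat(sprintf("<parse of '%s': %d candidate(s)%s>\n", x$label,
              length(x$candidates),
              if (x$is_ambiguous) ", ambiguous" else ""))
  for (cd in x$candidates) {
    cat("  [", cd$rule, "] ", paste(write_eq_text(cd$eq), collapse = " / "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
as_tibble.xp_parse_result <- function(x, ...) {
  if (!length(x$candidates)) {
    return(tibble(label = character(), rule = character(), eq = list()))
  }
  tibble(
    label = x$label,
    rule = map_chr(x$candidates, "rule"),
    eq = map(x$candidates, "eq")
  )
}

#' Batch-parse an ontology's labels into XP stanzas and a curation queue
#'
#' Labels with exactly one candidate parse become intersection stanzas;
#' ambiguous or unparseable labels are routed to a curation queue reporting
#' the candidates and unmatched tokens. The coverage fraction is the share of
#' non-obsolete classes that received a definition.
#'
#' @param ontology the phenotype [obo_document()] whose class labels to parse.
#' @param lexicon an [build_lexicon()] lexicon.
#' @param vocab a [relation_vocabulary()].
#' @param grammar a [default_grammar()] configuration.
#' @return A list of class `xp_batch`: `document` (XP stanzas as an
#'   [obo_document()]), `queue` (tibble: `id`, `label`, `n_candidates`,
#'   `candidates`, `unmatched`), `coverage`, `n_classes`, `n_accepted`.
#' @export
batch_parse <- function(ontology, lexicon, vocab = relation_vocabulary(),
                        grammar = default_grammar()) {
  stanzas <- list()
  queue <- list()
  n_classes <- 0L
  n_accepted <- 0L
  add_stanza <- function(st) {
    if (is.null(stanzas[[st$id]])) stanzas[[st$id]] <<- st
  }
  for (st in ontology$stanzas) {
    if (st$is_obsolete || is.na(st$name)) next
    n_classes <- n_classes + 1L
    res <- parse_label(st$name, lexicon, vocab, grammar)
    usable <- keep(res$candidates, ~ !isTRUE(attr(.x$eq, "needs_curation")))
    if (length(res$candidates) == 1L && length(usable) == 1L) {
      n_accepted <- n_accepted + 1L
      tr <- eq_to_intersection(usable[[1]]$eq, vocab)
      for (aux in tr$aux) add_stanza(aux)
      add_stanza(term_stanza(id = st$id, intersection_of = tr$clauses))
    } else {
      queue[[length(queue) + 1]] <- tibble(
        id = st$id, label = st$name,
        n_candidates = length(res$candidates),
        candidates = paste(
          map_chr(res$candidates,
                  ~ paste(write_eq_text(.x$eq), collapse = " / ")),
          collapse = " | "),
        unmatched = paste(res$unmatched_tokens, collapse = " ")
      )
    }
  }
  queue <- if (length(queue)) bind_rows(queue) else tibble(
    id = character(), label = character(), n_candidates = integer(),
    candidates = character(), unmatched = character())
  structure(
    list(
      document = obo_document(
        ontology_id = paste0(ontology$ontology_id %||% "xp", "-xp"),
        header = c("format-version: 1.2"),
        stanzas = unname(stanzas)
      ),
      queue = queue,
      coverage = if (n_classes) n_accepted / n_classes else 0,
      n_classes = n_classes,
      n_accepted = n_accepted
    ),
    class = "xp_batch"
  )
}

#' @export
print.xp_batch <- function(x, ...) {
  cat(sprintf(
    "<xp_batch: %d/%d classes defined (coverage %.2f), %d queued for curation>\n",
    x$n_accepted, x$n_classes, x$coverage, nrow(x$queue)))
  invisible(x)
}

#' Write a curation queue as tab-separated values
#'
#' @param batch an [batch_parse()] result.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_curation_queue <- function(batch, path) {
  readr::write_tsv(batch$queue, path)
  invisible(path)
}
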