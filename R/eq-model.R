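#' Relation vocabulary for EQ translation
#'
#' The EQ model relates a quality to its bearer with `inheres_in`, to the
#' dependent entity of a relational quality with `towards`, and to a modifier
#' class (such as PATO 'abnormal') with `has_qualifier`; `part_of` builds
#' nested bearer expressions and `has_part` appears in the cardinality
#' rendering of absence. The exact identifiers are configuration, since OBO
#' files differ in whether relations carry CURIEs.
#'
#' @param inheres_in,towards,has_qualifier,part_of,has_part relation
#'   identifiers; all must be distinct.
#' @param inheres_in_part_of relation produced by part-to-whole quality
#'   propagation (reasoner rule R6); kept distinct from plain `inheres_in`.
#' @return An object of class `relation_vocabulary`.
#' @export
relation_vocabulary <- function(inheres_in = "inheres_in",
                                towards = "towards",
                                has_qualifier = "has_qualifier",
                                part_of = "part_of",
                                has_part = "has_part",
                                inheres_in_part_of = "inheres_in_part_of") {
  core <- c(inheres_in, towards, has_qualifier, part_of, has_part)
  if (anyDuplicated(core)) {
    stop_phenoxp("relation vocabulary identifiers must be distinct",
                 "phenoxp_malformed_vocabulary")
  }
  structure(
    list(inheres_in = inheres_in, towards = towards,
         has_qualifier = has_qualifier, part_of = part_of,
         has_part = has_part, inheres_in_part_of = inheres_in_part_of),
    class = "relation_vocabulary"
  )
}

#' EQ phenotype descriptions
#'
#' An EQ description decomposes a phenotype into an entity (E, the bearer), a
#' quality (Q), an optional second entity (E2) for relational qualities, an
#' optional modifier (M, typically 'abnormal'), and an optional entity whole
#' (EW) - surface syntax stating that the bearer is part of a larger
#' structure, sugar for one level of `part_of` nesting.
#'
#' @param entity bearer: a class identifier, caret expression text, or
#'   `xp_expr`.
#' @param quality quality class identifier (or unresolved label).
#' @param entity2 optional second entity for relational qualities.
#' @param modifier optional modifier class identifier.
#' @param entity_whole optional whole; requires `entity` to be a named class.
#' @return An object of class `eq_description`.
#' @export
eq <- function(entity, quality, entity2 = NULL, modifier = NULL,
               entity_whole = NULL) {
  stopifnot(is.character(quality), length(quality) == 1L)
  entity <- as_xp_expr(entity)
  if (!is.null(entity2)) entity2 <- as_xp_expr(entity2)
  if (!is.null(entity_whole)) entity_whole <- as_xp_expr(entity_whole)
  structure(
    list(entity = entity, quality = quality, entity2 = entity2,
         modifier = modifier, entity_whole = entity_whole),
    class = "eq_description"
  )
}

#' @export
print.eq_description <- function(x, ...) {
  cat(paste(write_eq_text(x), collapse = "\n"), "\n", sep = "")
  invisible(x)
}

eq_equal <- function(a, b) {
  identical(format(canonicalize_expr(a$entity)), format(canonicalize_expr(b$entity))) &&
    identical(a$quality, b$quality) &&
    identical(a$modifier, b$modifier) &&
    identical(
      if (is.null(a$entity2)) NULL else format(canonicalize_expr(a$entity2)),
      if (is.null(b$entity2)) NULL else format(canonicalize_expr(b$entity2))
    )
}

#' Fold the EW tag into a nested bearer expression (and back)
#'
#' `E = dendrite, EW = Purkinje cell` is equivalent to
#' `E = dendrite^part_of(Purkinje cell)`; the nested form is the canonical
#' one. `denormalize_entity_whole()` recovers the EW surface form when the
#' entity is a one-level `part_of` composition.
#'
#' @param x an [eq()] description with EW set.
#' @param vocab a [relation_vocabulary()].
#' @return An [eq()] description.
#' @export
normalize_entity_whole <- function(x, vocab = relation_vocabulary()) {
  if (is.null(x$entity_whole)) return(x)
  if (!is_named_expr(x$entity)) {
    stop_phenoxp(
      "EW is set while the entity is already a composed expression; fold one in at a time",
      "phenoxp_ambiguous_composition"
    )
  }
  eq(
    entity = xp_composed(x$entity$id, list(
      list(relation = vocab$part_of, filler = x$entity_whole)
    )),
    quality = x$quality, entity2 = x$entity2, modifier = x$modifier
  )
}

#' @rdname normalize_entity_whole
#' @export
denormalize_entity_whole <- function(x, vocab = relation_vocabulary()) {
  e <- x$entity
  if (is_named_expr(e) || length(e$differentia) != 1L ||
      e$differentia[[1]]$relation != vocab$part_of) {
    return(x)
  }
  eq(
    entity = e$genus, quality = x$quality, entity2 = x$entity2,
    modifier = x$modifier, entity_whole = e$differentia[[1]]$filler
  )
}

#' Materialize a composed expression as auxiliary stanzas
#'
#' @param x an `xp_expr`.
#' @return A list with the expression's identifier (`id`) and any auxiliary
#'   [term_stanza()] objects (`stanzas`) needed to name nested compositions.
#' @export
materialize_expression <- function(x) {
  if (is_named_expr(x)) return(list(id = x$id, stanzas = list()))
  x <- canonicalize_expr(x)
  aux <- list()
  clauses <- list(intersection_clause(x$genus))
  for (d in x$differentia) {
    sub <- materialize_expression(d$filler)
    aux <- c(aux, sub$stanzas)
    clauses <- c(clauses, list(intersection_clause(sub$id, relation = d$relation)))
  }
  id <- expression_id(x)
  st <- term_stanza(id = id, name = format(x), intersection_of = clauses)
  list(id = id, stanzas = c(aux, list(st)))
}

#' Translate an EQ description to genus-differentia intersection clauses
#'
#' The translation is row-for-row: the genus clause is Q; `inheres_in E` is
#' always present; `towards E2` is added iff E2 is present; `has_qualifier M`
#' is added iff M is present. A set EW tag is folded into the bearer first.
#' Composed bearers are materialized as auxiliary stanzas with deterministic
#' identifiers.
#'
#' @param x an [eq()] description.
#' @param vocab a [relation_vocabulary()].
#' @return A list with `clauses` (list of [intersection_clause()]) and `aux`
#'   (auxiliary [term_stanza()] objects for nested expressions).
#' @export
eq_to_intersection <- function(x, vocab = relation_vocabulary()) {
  x <- normalize_entity_whole(x, vocab)
  aux <- list()
  ent <- materialize_expression(x$entity)
  aux <- c(aux, ent$stanzas)
  clauses <- list(
    intersection_clause(x$quality),
    intersection_clause(ent$id, relation = vocab$inheres_in)
  )
  if (!is.null(x$entity2)) {
    e2 <- materialize_expression(x$entity2)
    aux <- c(aux, e2$stanzas)
    clauses <- c(clauses, list(intersection_clause(e2$id, relation = vocab$towards)))
  }
  if (!is.null(x$modifier)) {
    clauses <- c(clauses,
                 list(intersection_clause(x$modifier, relation = vocab$has_qualifier)))
  }
  list(clauses = clauses, aux = aux)
}

# Reconstruct an expression from a (possibly materialized) identifier.
resolve_filler_expr <- function(id, context) {
  if (!is.null(context) && grepl("^XP:", id)) {
    for (doc in context) {
      st <- doc$stanzas[[id]]
      if (!is.null(st) && length(st$intersection_of)) {
        genus <- NULL
        diffs <- list()
        for (cl in st$intersection_of) {
          if (is_genus(cl)) genus <- cl$filler
          else diffs <- c(diffs, list(list(
            relation = cl$relation,
            filler = resolve_filler_expr(cl$filler, context)
          )))
        }
        return(xp_composed(genus, diffs))
      }
    }
  }
  xp_named(id)
}

context_docs <- function(context) {
  if (is.null(context)) return(NULL)
  flatten_docs(context)
}

# is `id` a descendant (or equal) of `root` over is_a links in `docs`?
isa_descendant <- function(id, root, docs) {
  seen <- character()
  frontier <- id
  while (length(frontier)) {
    if (root %in% frontier) return(TRUE)
    seen <- c(seen, frontier)
    parents <- character()
    for (doc in docs) {
      for (f in frontier) {
        st <- doc$stanzas[[f]]
        if (!is.null(st)) parents <- c(parents, st$is_a)
      }
    }
    frontier <- setdiff(unique(parents), seen)
  }
  FALSE
}

#' Recover an EQ description from intersection clauses
#'
#' Inverse of [eq_to_intersection()]. Requires exactly one genus clause and
#' exactly one `inheres_in` differentium, at most one `towards` and at most
#' one `has_qualifier`; any other differentium relation is an unsupported
#' pattern. With `strict_quality = TRUE` and a context holding the quality
#' ontology, the genus must be a descendant of the quality root.
#'
#' @param clauses list of [intersection_clause()] objects.
#' @param context optional `obo_document`(s) used to expand materialized
#'   `XP:` fillers and to check quality ancestry.
#' @param vocab a [relation_vocabulary()].
#' @param strict_quality enforce that the genus is a quality.
#' @param quality_root root of the quality ontology for the strict check.
#' @return An [eq()] description.
#' @export
intersection_to_eq <- function(clauses, context = NULL,
                               vocab = relation_vocabulary(),
                               strict_quality = FALSE,
                               quality_root = "PATO:0000001") {
  context <- context_docs(context)
  genus <- NULL
  entity <- NULL
  entity2 <- NULL
  modifier <- NULL
  for (cl in clauses) {
    if (is_genus(cl)) {
      if (!is.null(genus)) {
        stop_phenoxp("more than one genus clause; not an EQ definition",
                     "phenoxp_not_eq")
      }
      genus <- cl$filler
    } else if (cl$relation == vocab$inheres_in) {
      if (!is.null(entity)) {
        stop_phenoxp("more than one inheres_in differentium; not an EQ definition",
                     "phenoxp_not_eq")
      }
      entity <- resolve_filler_expr(cl$filler, context)
    } else if (cl$relation == vocab$towards) {
      if (!is.null(entity2)) {
        stop_phenoxp("more than one towards differentium; not an EQ definition",
                     "phenoxp_not_eq")
      }
      entity2 <- resolve_filler_expr(cl$filler, context)
    } else if (cl$relation == vocab$has_qualifier) {
      if (!is.null(modifier)) {
        stop_phenoxp("more than one has_qualifier differentium; not an EQ definition",
                     "phenoxp_not_eq")
      }
      modifier <- cl$filler
    } else {
      stop_phenoxp(
        sprintf("unsupported differentium relation '%s' in definition", cl$relation),
        "phenoxp_unsupported_pattern"
      )
    }
  }
  if (is.null(genus)) {
    stop_phenoxp("no genus clause; not an EQ definition", "phenoxp_not_eq")
  }
  if (is.null(entity)) {
    stop_phenoxp("missing inheres_in differentium; not an EQ definition",
                 "phenoxp_not_eq")
  }
  if (strict_quality && !is.null(context) &&
      !isa_descendant(genus, quality_root, context)) {
    stop_phenoxp(
      sprintf("genus '%s' is not a descendant of the quality root '%s'",
              genus, quality_root),
      "phenoxp_genus_not_quality"
    )
  }
  eq(entity = entity, quality = genus, entity2 = entity2, modifier = modifier)
}

default_absence_qualities <- function() {
  list(
    lacking = c("PATO:0002000", "lacking all parts of type"),
    fewer = c("PATO:0002001", "has fewer parts of type"),
    extra = c("PATO:0002002", "has extra parts of type")
  )
}

#' Translate an absence phenotype
#'
#' Absence is modelled with a relational quality on the entity missing the
#' part: `E = abdomen, Q = lacking all parts of type, E2 = spleen`. The
#' relational mode emits the standard towards-pattern intersection clauses.
#' The cardinality mode renders the explicit OWL form
#' `Abdomen that has_part exactly 0 spleen` - available only for the
#' lacking-all-parts quality, since a relative increase or decrease in number
#' has no cardinality form; note the explicit form can create inconsistencies
#' with the anatomy ontology and is therefore not the default.
#'
#' @param x an [eq()] description whose quality is a number-of-parts
#'   relational quality and which has E2 set.
#' @param mode `"relational"` or `"cardinality"`.
#' @param vocab a [relation_vocabulary()].
#' @param labels optional id -> label map used for the cardinality rendering.
#' @param absence_qualities named list of recognized number-of-parts
#'   qualities (ids and labels).
#' @return Intersection clauses (relational mode) or a Manchester-syntax
#'   string (cardinality mode).
#' @export
translate_absence <- function(x, mode = c("relational", "cardinality"),
                              vocab = relation_vocabulary(), labels = NULL,
                              absence_qualities = default_absence_qualities()) {
  mode <- match.arg(mode)
  kind <- NA_character_
  for (k in names(absence_qualities)) {
    if (x$quality %in% absence_qualities[[k]]) kind <- k
  }
  if (is.na(kind)) {
    stop_phenoxp(
      sprintf("quality '%s' is not a recognized number-of-parts relational quality",
              x$quality),
      "phenoxp_unsupported_pattern"
    )
  }
  if (is.null(x$entity2)) {
    stop_phenoxp("absence translation requires E2 (the missing part)",
                 "phenoxp_incomplete_description")
  }
  if (mode == "relational") {
    return(eq_to_intersection(x, vocab)$clauses)
  }
  if (kind != "lacking") {
    stop_phenoxp(
      "relative counts (fewer/extra parts) have no cardinality form",
      "phenoxp_unsupported_cardinality"
    )
  }
  lab <- function(id) {
    if (!is.null(labels) && !is.na(labels[id] %||% NA)) labels[[id]] else id
  }
  paste0(
    cap_first(lab(expression_id(x$entity))), " that ", vocab$has_part,
    " exactly 0 ", lab(expression_id(x$entity2))
  )
}

manchester_expr <- function(x, lab, vocab, parenthesize = FALSE) {
  if (is_named_expr(x)) return(lab(x$id))
  x <- canonicalize_expr(x)
  body <- paste0(
    lab(x$genus), " that ",
    paste(map_chr(x$differentia, function(d) {
      paste0(d$relation, " some ", manchester_expr(d$filler, lab, vocab, TRUE))
    }), collapse = " and ")
  )
  if (parenthesize) paste0("(", body, ")") else body
}

#' Render an EQ description in OWL Manchester syntax
#'
#' Produces `Q that inheres_in some E`, extended with `and towards some E2`
#' and `and has_qualifier some M` when present; composed bearers are
#' parenthesized. Identifiers without a supplied label fall back to the CURIE.
#'
#' @param x an [eq()] description.
#' @param labels optional named character vector (id -> label).
#' @param vocab a [relation_vocabulary()].
#' @return A single string.
#' @export
write_manchester <- function(x, labels = NULL, vocab = relation_vocabulary()) {
  x <- normalize_entity_whole(x, vocab)
  lab <- function(id) {
    if (!is.null(labels) && !is.na(labels[id] %||% NA)) labels[[id]] else id
  }
  out <- paste0(
    lab(x$quality), " that ", vocab$inheres_in, " some ",
    manchester_expr(x$entity, lab, vocab, parenthesize = !is_named_expr(x$entity))
  )
  if (!is.null(x$entity2)) {
    out <- paste0(out, " and ", vocab$towards, " some ",
                  manchester_expr(x$entity2, lab, vocab,
                                  parenthesize = !is_named_expr(x$entity2)))
  }
  if (!is.null(x$modifier)) {
    out <- paste0(out, " and ", vocab$has_qualifier, " some ", lab(x$modifier))
  }
  out
}
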