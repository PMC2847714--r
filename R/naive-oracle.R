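#' Naive saturation closure (independent oracle)
#'
#' A deliberately simple reference implementation of the same rule semantics
#' as [compute_closure()]: every rule is re-applied to every edge pair until
#' nothing new is derived, with no delta bookkeeping and no provenance. It is
#' kept free of code shared with the production reasoner so the two can check
#' each other; the synthetic-suite generator also uses it to compute
#' ground-truth entailments.
#'
#' @param doc an [obo_document()] (merged and materialized).
#' @param config a [rule_config()].
#' @param vocab a [relation_vocabulary()].
#' @return A tibble with columns `subject`, `relation`, `object`, `status`.
#' @export
naive_closure <- function(doc, config = rule_config(),
                          vocab = relation_vocabulary()) {
  transitive <- union(config$transitive_relations, doc$transitive_relations)
  defs <- doc_definitions(doc)

  es <- character(); er <- character(); eo <- character()
  for (st in doc$stanzas) {
    if (st$is_obsolete) next
    for (p in st$is_a) { es <- c(es, st$id); er <- c(er, "is_a"); eo <- c(eo, p) }
    for (rel in st$relationships) {
      es <- c(es, st$id); er <- c(er, rel$relation); eo <- c(eo, rel$target)
    }
  }
  n_asserted_input <- length(es)
  for (x in names(defs)) {
    for (cl in defs[[x]]) {
      es <- c(es, x)
      er <- c(er, if (is.na(cl$relation)) "is_a" else cl$relation)
      eo <- c(eo, cl$filler)
    }
  }
  status <- c(rep("asserted", n_asserted_input),
              rep("inferred", length(es) - n_asserted_input))
  df <- data.frame(s = es, r = er, o = eo, status = status,
                   stringsAsFactors = FALSE)
  df <- df[!(df$s == df$o & df$r == "is_a"), ]
  df <- df[!duplicated(paste(df$s, df$r, df$o)), ]

  repeat {
    cand <- list()
    # transitivity over every pair of edges
    for (rel in transitive) {
      a <- df[df$r == rel, ]
      if (nrow(a)) {
        m <- merge(a[, c("s", "o")], a[, c("s", "o")],
                   by.x = "o", by.y = "s")
        if (nrow(m)) cand[[length(cand) + 1]] <-
          data.frame(s = m$s, r = rel, o = m$o.y)
      }
    }
    if (config$composition_over_is_a) {
      isa <- df[df$r == "is_a", ]
      oth <- df[df$r != "is_a", ]
      if (nrow(isa) && nrow(oth)) {
        m1 <- merge(oth, isa[, c("s", "o")], by.x = "o", by.y = "s")
        if (nrow(m1)) cand[[length(cand) + 1]] <-
          data.frame(s = m1$s, r = m1$r, o = m1$o.y)
        m2 <- merge(isa[, c("s", "o")], oth, by.x = "o", by.y = "s")
        if (nrow(m2)) cand[[length(cand) + 1]] <-
          data.frame(s = m2$s, r = m2$r, o = m2$o.y)
      }
    }
    if (config$quality_propagates_over_part_of) {
      ii <- df[df$r == vocab$inheres_in, ]
      if (nrow(ii)) cand[[length(cand) + 1]] <-
        data.frame(s = ii$s, r = vocab$inheres_in_part_of, o = ii$o)
      iipo <- df[df$r == vocab$inheres_in_part_of, ]
      po <- df[df$r == vocab$part_of, ]
      if (nrow(iipo) && nrow(po)) {
        m <- merge(iipo[, c("s", "o")], po[, c("s", "o")],
                   by.x = "o", by.y = "s")
        if (nrow(m)) cand[[length(cand) + 1]] <-
          data.frame(s = m$s, r = vocab$inheres_in_part_of, o = m$o.y)
      }
    }
    # sufficiency: scan every class against every definition
    subjects <- unique(c(df$s, df$o, names(defs)))
    for (x in names(defs)) {
      genus <- NULL
      diffs <- list()
      for (cl in defs[[x]]) {
        if (is.na(cl$relation)) genus <- cl$filler
        else diffs <- c(diffs, list(cl))
      }
      for (z in subjects) {
        if (z == x) next
        ok <- TRUE
        if (!is.null(genus) && z != genus) {
          ok <- any(df$s == z & df$r == "is_a" & df$o == genus)
        }
        if (ok) for (d in diffs) {
          if (!any(df$s == z & df$r == d$relation & df$o == d$filler)) {
            ok <- FALSE
            break
          }
        }
        if (ok) cand[[length(cand) + 1]] <-
          data.frame(s = z, r = "is_a", o = x)
      }
    }
    if (!length(cand)) break
    cd <- do.call(rbind, cand)
    cd <- cd[cd$s != cd$o, ]
    cd <- cd[!duplicated(paste(cd$s, cd$r, cd$o)), ]
    cd <- cd[!(paste(cd$s, cd$r, cd$o) %in% paste(df$s, df$r, df$o)), ]
    if (!nrow(cd)) break
    cd$status <- "inferred"
    df <- rbind(df, cd)
  }

  out <- tibble(subject = df$s, relation = df$r, object = df$o,
                status = df$status)
  arrange(out, .data$relation, .data$subject, .data$object)
}
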