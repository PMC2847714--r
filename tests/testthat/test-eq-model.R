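test_that("the femur-shape pair translates to the printed intersection", {
  tr <- eq_to_intersection(eq("MA:0001359", "PATO:0000052"))
  expect_length(tr$clauses, 2)
  expect_true(is.na(tr$clauses[[1]]$relation))
  expect_equal(tr$clauses[[1]]$filler, "PATO:0000052")
  expect_equal(tr$clauses[[2]]$relation, "inheres_in")
  expect_equal(tr$clauses[[2]]$filler, "MA:0001359")
  expect_length(tr$aux, 0)
})

test_that("relational quality with modifier yields all four clauses in order", {
  tr <- eq_to_intersection(eq("MA:0000141", "PATO:0000033",
                              entity2 = "CHEBI:18248",
                              modifier = "PATO:0000460"))
  rels <- purrr::map_chr(tr$clauses,
                         ~ if (is.na(.x$relation)) "genus" else .x$relation)
  expect_equal(rels, c("genus", "inheres_in", "towards", "has_qualifier"))
})

test_that("translation is a bijection on randomly generated descriptions", {
  ids <- function(prefix, n) sprintf("%s:%07d", prefix, seq_len(n))
  qs <- ids("QQ", 8); es <- ids("EE", 10)
  withr::with_seed(42, {
    for (i in 1:60) {
      entity <- if (runif(1) < 0.3) {
        xp_composed(sample(es, 1), list(list(
          relation = "part_of", filler = xp_named(sample(es, 1)))))
      } else {
        xp_named(sample(es, 1))
      }
      x <- eq(
        entity = entity, quality = sample(qs, 1),
        entity2 = if (runif(1) < 0.3) sample(es, 1),
        modifier = if (runif(1) < 0.3) sample(qs, 1)
      )
      tr <- eq_to_intersection(x)
      ctx <- if (length(tr$aux)) {
        list(obo_document("aux", stanzas = tr$aux,
                          header = "format-version: 1.2"))
      }
      back <- intersection_to_eq(tr$clauses, context = ctx)
      expect_true(phenoxp:::eq_equal(back, x))
    }
  })
})

test_that("all sixteen example mapping rows round-trip exactly", {
  rows <- eq_example_rows()
  expect_equal(nrow(rows), 16)
  for (i in seq_len(nrow(rows))) {
    tr <- eq_to_intersection(rows$eq[[i]])
    ctx <- if (length(tr$aux)) {
      list(obo_document("aux", stanzas = tr$aux,
                        header = "format-version: 1.2"))
    }
    back <- intersection_to_eq(tr$clauses, context = ctx)
    expect_true(phenoxp:::eq_equal(back, rows$eq[[i]]),
                info = rows$label[i])
  }
})

test_that("non-EQ clause patterns raise the specific errors", {
  ii <- function(x) intersection_clause(x, "inheres_in")
  expect_error(
    intersection_to_eq(list(intersection_clause("Q:1"), ii("E:1"), ii("E:2"))),
    class = "phenoxp_not_eq")
  expect_error(
    intersection_to_eq(list(intersection_clause("Q:1"),
                            intersection_clause("E:1", "develops_from"))),
    class = "phenoxp_unsupported_pattern")
  expect_error(
    intersection_to_eq(list(intersection_clause("Q:1"),
                            intersection_clause("E:1", "towards"))),
    class = "phenoxp_not_eq")
})

test_that("strict mode rejects a genus that is not a quality", {
  fx <- build_paper_fixture()
  clauses <- list(intersection_clause("MA:0001359"),
                  intersection_clause("MA:0000236", "inheres_in"))
  expect_error(
    intersection_to_eq(clauses, context = list(fx$mini_pato, fx$mini_ma),
                       strict_quality = TRUE),
    class = "phenoxp_genus_not_quality")
  ok <- intersection_to_eq(
    list(intersection_clause("PATO:0000586"),
         intersection_clause("MA:0000236", "inheres_in")),
    context = list(fx$mini_pato), strict_quality = TRUE)
  expect_equal(ok$quality, "PATO:0000586")
})

test_that("EW folds into a part_of nesting and unfolds back", {
  x <- eq("GO:0030425", "PATO:0000051", modifier = "PATO:0000460",
          entity_whole = "CL:0000121")
  n <- normalize_entity_whole(x)
  expect_null(n$entity_whole)
  expect_equal(format(n$entity), "GO:0030425^part_of(CL:0000121)")
  d <- denormalize_entity_whole(n)
  expect_equal(d$entity$id, "GO:0030425")
  expect_equal(d$entity_whole$id, "CL:0000121")
  composed <- eq("A:1^part_of(B:1)", "Q:1", entity_whole = "C:1")
  expect_error(normalize_entity_whole(composed),
               class = "phenoxp_ambiguous_composition")
})

test_that("Manchester rendering matches the worked examples", {
  fx <- build_paper_fixture()
  expect_equal(
    write_manchester(eq("MA:0001359", "PATO:0000052"), labels = fx$labels),
    "shape that inheres_in some femur")
  expect_equal(
    write_manchester(eq("GO:0030425^part_of(CL:0000121)", "PATO:0000051",
                        modifier = "PATO:0000460"), labels = fx$labels),
    "morphology that inheres_in some (dendrite that part_of some Purkinje cell) and has_qualifier some abnormal")
  # unlabelled ids fall back to the CURIE
  expect_equal(write_manchester(eq("E:1", "Q:1")),
               "Q:1 that inheres_in some E:1")
})

test_that("Manchester text has exactly one inheres_in and bounded optionals", {
  withr::with_seed(7, {
    for (i in 1:25) {
      x <- eq(
        entity = sprintf("E:%d", sample(9, 1)),
        quality = sprintf("Q:%d", sample(9, 1)),
        entity2 = if (runif(1) < 0.5) sprintf("E:%d", sample(9, 1)),
        modifier = if (runif(1) < 0.5) sprintf("Q:%d", sample(9, 1))
      )
      txt <- write_manchester(x)
      count <- function(p) lengths(regmatches(txt, gregexpr(p, txt, fixed = TRUE)))
      expect_equal(count("inheres_in some"), 1)
      expect_lte(count("towards some"), 1)
      expect_lte(count("has_qualifier some"), 1)
    }
  })
})

test_that("rendering is invariant under differentia reordering", {
  a <- xp_composed("G:1", list(
    list(relation = "part_of", filler = xp_named("B:1")),
    list(relation = "develops_from", filler = xp_named("A:1"))
  ))
  b <- xp_composed("G:1", list(
    list(relation = "develops_from", filler = xp_named("A:1")),
    list(relation = "part_of", filler = xp_named("B:1"))
  ))
  expect_equal(write_manchester(eq(a, "Q:1")), write_manchester(eq(b, "Q:1")))
  expect_equal(expression_id(a), expression_id(b))
})

test_that("absence translates in both modes with the documented restriction", {
  fx <- build_paper_fixture()
  absent_spleen <- eq("MA:0000029", "PATO:0002000", entity2 = "MA:0000141")
  rel <- translate_absence(absent_spleen, "relational")
  rels <- purrr::map_chr(rel,
                         ~ if (is.na(.x$relation)) "genus" else .x$relation)
  expect_equal(rels, c("genus", "inheres_in", "towards"))
  expect_equal(
    translate_absence(absent_spleen, "cardinality", labels = fx$labels),
    "Abdomen that has_part exactly 0 spleen")
  fewer <- eq("MA:0000184", "PATO:0002001", entity2 = "CL:0000540")
  expect_error(translate_absence(fewer, "cardinality"),
               class = "phenoxp_unsupported_cardinality")
  not_absence <- eq("MA:0000029", "PATO:0000052", entity2 = "MA:0000141")
  expect_error(translate_absence(not_absence, "relational"),
               class = "phenoxp_unsupported_pattern")
})

test_that("EQ line syntax parses, resolves labels, and round-trips", {
  fx <- build_paper_fixture()
  lex <- fixture_lexicon(fx)
  hypo <- parse_eq_text(c("E = urine", "Q = decreased concentration of",
                          "E2 = calcium"), lex)
  expect_equal(hypo$entity$id, "MA:0002504")
  expect_equal(hypo$quality, "PATO:0001162")
  expect_equal(hypo$entity2$id, "CHEBI:29108")
  expect_length(attr(hypo, "unresolved"), 0)

  # unresolved labels are retained and flagged when no lexicon is given
  raw <- parse_eq_text(c("E = urine", "Q = decreased concentration of",
                         "E2 = calcium"))
  expect_setequal(attr(raw, "unresolved"),
                  c("urine", "decreased concentration of", "calcium"))

  nested <- parse_eq_text("E = dendrite^part_of(Purkinje_cell) / Q = morphology", lex)
  expect_equal(format(nested$entity), "GO:0030425^part_of(CL:0000121)")

  expect_error(parse_eq_text("Q = shape"),
               class = "phenoxp_incomplete_description")
  err <- expect_error(parse_eq_text("E = a^part_of(b / Q = shape"),
                      class = "phenoxp_syntax")
  expect_match(conditionMessage(err), "offset")

  for (x in list(hypo, nested)) {
    expect_true(phenoxp:::eq_equal(parse_eq_text(write_eq_text(x)), x))
  }
})

test_that("EQ files round-trip through disk including bound ids", {
  fx <- build_paper_fixture()
  defs <- eq_example_rows()[1:4, ]
  path <- withr::local_tempfile(fileext = ".eq")
  write_eq_file(defs, path)
  back <- read_eq_file(path)
  expect_equal(back$id, defs$id)
  for (i in seq_len(nrow(defs))) {
    expect_true(phenoxp:::eq_equal(back$eq[[i]], defs$eq[[i]]))
  }
})

test_that("materialization of nested bearers is deterministic", {
  x <- xp_composed("GO:0030425", list(
    list(relation = "part_of", filler = xp_named("CL:0000121"))))
  m1 <- materialize_expression(x)
  m2 <- materialize_expression(x)
  expect_identical(m1$id, m2$id)
  expect_match(m1$id, "^XP:")
  expect_identical(m1$stanzas, m2$stanzas)
})
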