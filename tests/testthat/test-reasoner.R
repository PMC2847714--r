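chain_doc <- function() {
  obo_document("chain", header = "format-version: 1.2", stanzas = list(
    term_stanza("X:1", name = "a", is_a = "X:2"),
    term_stanza("X:2", name = "b", is_a = "X:3"),
    term_stanza("X:3", name = "c")
  ))
}

test_that("is_a transitivity closes a simple chain", {
  cl <- compute_closure(chain_doc())
  keys <- edge_set(cl$edges, with_status = FALSE)
  expect_true("X:1 is_a X:3" %in% keys)
  inferred <- cl$edges[cl$edges$status == "inferred", ]
  expect_equal(nrow(inferred), 1)
  expect_equal(inferred$rule, "R1")
})

test_that("declared transitive relations close and compose with is_a", {
  doc <- parse_obo(c(
    "format-version: 1.2",
    "[Term]", "id: A:1", "relationship: part_of A:2",
    "[Term]", "id: A:2", "relationship: part_of A:3",
    "[Term]", "id: A:3", "is_a: A:4",
    "[Term]", "id: A:4",
    "[Typedef]", "id: part_of", "is_transitive: true"
  ))
  keys <- edge_set(compute_closure(doc)$edges, with_status = FALSE)
  expect_true("A:1 part_of A:3" %in% keys)  # R2
  expect_true("A:1 part_of A:4" %in% keys)  # R2 + R3
})

test_that("definitions unfold (R4) and classify (R5), giving the degeneration inference", {
  fx <- build_paper_fixture()
  cl <- compute_closure(fixture_merged(fx))
  keys <- edge_set(cl$edges, with_status = FALSE)
  # R4: necessary conditions of 'Purkinje cell degeneration'
  expect_true("MP:9000012 is_a PATO:0000639" %in% keys)
  expect_true("MP:9000012 inheres_in CL:0000121" %in% keys)
  # R5 via the cell-ontology hierarchy
  expect_true("MP:9000012 is_a MP:9000011" %in% keys)
  expect_true("MP:9000012 is_a MP:9000010" %in% keys)
  expect_true("MP:9000013 is_a MP:9000011" %in% keys)
  # the subcellular sibling is not subsumed by the cellular classes
  expect_false("MP:9000014 is_a MP:9000011" %in% keys)
})

test_that("materialization creates nested stanzas once, deterministically", {
  fx <- build_paper_fixture()
  defs <- tibble::tibble(
    id = "MP:0008572",
    eq = list(eq("GO:0030425^part_of(CL:0000121)", "PATO:0000051",
                 modifier = "PATO:0000460"))
  )
  m1 <- materialize_expressions(fx$mini_go, defs)
  m2 <- materialize_expressions(fx$mini_go, defs)
  expect_identical(names(m1$stanzas), names(m2$stanzas))
  xp_ids <- grep("^XP:", names(m1$stanzas), value = TRUE)
  expect_length(xp_ids, 1)
  st <- m1$stanzas[[xp_ids]]
  expect_equal(st$intersection_of[[1]]$filler, "GO:0030425")
  expect_equal(st$intersection_of[[2]]$relation, "part_of")
  expect_equal(st$intersection_of[[2]]$filler, "CL:0000121")
  # no composed expressions: document unchanged
  expect_identical(materialize_expressions(fx$mini_go), fx$mini_go)
})

test_that("production closure equals the naive oracle on seeded documents", {
  for (seed in 1:25) {
    suite <- generate_suite(small_suite_params(seed))
    doc <- suite_doc(suite)
    prod <- compute_closure(doc)$edges
    oracle <- naive_closure(doc)
    expect_identical(edge_set(prod), edge_set(oracle), info = paste("seed", seed))
  }
})

test_that("closure is idempotent and monotone", {
  fx <- build_paper_fixture()
  cl <- compute_closure(fixture_merged(fx))
  again <- compute_closure(closure_to_document(cl))
  expect_identical(edge_set(cl$edges, with_status = FALSE),
                   edge_set(again$edges, with_status = FALSE))
  # monotonicity: closure contains every asserted edge, and adding an
  # assertion never removes an entailment
  asserted <- phenoxp:::doc_asserted_edges(fixture_merged(fx))
  keys <- edge_set(cl$edges, with_status = FALSE)
  expect_true(all(paste(asserted$subject, asserted$relation,
                        asserted$object) %in% keys))
  extra <- fixture_merged(fx)
  extra$stanzas[["MP:0002812"]]$is_a <-
    c(extra$stanzas[["MP:0002812"]]$is_a, "MP:9000010")
  bigger <- compute_closure(extra)
  expect_true(all(keys %in% edge_set(bigger$edges, with_status = FALSE)))
})

test_that("the final edge set is independent of input order", {
  suite <- generate_suite(small_suite_params(3))
  doc <- suite_doc(suite)
  ref <- edge_set(compute_closure(doc)$edges)
  withr::with_seed(11, {
    for (i in 1:20) {
      shuffled <- doc
      shuffled$stanzas <- shuffled$stanzas[sample(length(shuffled$stanzas))]
      expect_identical(edge_set(compute_closure(shuffled)$edges), ref)
    }
  })
})

test_that("asserted is_a cycles are rejected with the cycle listed", {
  doc <- obo_document("cyc", header = "format-version: 1.2", stanzas = list(
    term_stanza("X:1", is_a = "X:2"),
    term_stanza("X:2", is_a = "X:3"),
    term_stanza("X:3", is_a = "X:1")
  ))
  err <- expect_error(compute_closure(doc), class = "phenoxp_cycle")
  expect_match(conditionMessage(err), "X:")
})

test_that("quality propagation is off by default and emits a distinct relation", {
  doc <- parse_obo(c(
    "format-version: 1.2",
    "[Term]", "id: Q:1",
    "[Term]", "id: P:1", "relationship: inheres_in E:1",
    "[Term]", "id: E:1", "relationship: part_of E:2",
    "[Term]", "id: E:2",
    "[Typedef]", "id: part_of", "is_transitive: true"
  ))
  off <- compute_closure(doc)
  expect_false(any(off$edges$relation == "inheres_in_part_of"))
  on <- compute_closure(doc, rule_config(quality_propagates_over_part_of = TRUE))
  keys <- edge_set(on$edges, with_status = FALSE)
  expect_true("P:1 inheres_in_part_of E:2" %in% keys)
  # plain inheres_in is never propagated to the whole
  expect_false("P:1 inheres_in E:2" %in% keys)
})

test_that("novel direct links: exactly the withheld degeneration link, with provenance", {
  fx <- build_paper_fixture(withhold_fig2_link = TRUE)
  cl <- compute_closure(fixture_merged(fx))
  novel <- infer_novel_links(cl, "MP")
  expect_equal(nrow(novel), 1)
  expect_equal(novel$subject, "MP:9000012")
  expect_equal(novel$object, "MP:9000011")
  expect_match(novel$rule_chain, "R5")
  expect_match(novel$rule_chain, "CL:0000121 is_a CL:0000117")
  # with the link asserted there is nothing novel left
  full <- compute_closure(fixture_merged(build_paper_fixture()))
  expect_equal(nrow(infer_novel_links(full, "MP")), 0)
})

test_that("novel links match a brute-force definition of directness", {
  suite <- generate_suite(generator_params(seed = 21))
  rec <- recapitulate(suite$documents$phenotype, suite$xp_defs,
                      suite$documents[c("quality", "entity")])
  e <- rec$closure$edges
  isa <- e[e$relation == "is_a", ]
  keys <- paste(isa$subject, isa$object)
  brute_direct <- function(s, o) {
    mids <- setdiff(unique(isa$object[isa$subject == s]), c(s, o))
    !any(paste(mids, o) %in% keys)
  }
  asserted <- phenoxp:::doc_asserted_edges(suite$documents$phenotype)
  expected <- isa[isa$status == "inferred" &
                    startsWith(isa$subject, "GP:") &
                    startsWith(isa$object, "GP:"), ]
  expected <- expected[
    purrr::map_lgl(seq_len(nrow(expected)),
                   ~ brute_direct(expected$subject[.x], expected$object[.x])) &
      !paste(expected$subject, expected$object) %in%
        paste(asserted$subject, asserted$object), ]
  expect_identical(pair_set(rec$novel), pair_set(expected))
})

test_that("entity queries honor the is_a hierarchy and bridge files", {
  fx <- build_paper_fixture()
  cl <- compute_closure(fixture_merged(fx, bridge = TRUE))
  # species-specific query
  expect_true("MP:9000012" %in% query_phenotypes_by_entity(cl, "CL:0000121"))
  # query on the generic neuron catches all cellular degeneration classes
  neuron_hits <- query_phenotypes_by_entity(cl, "CL:0000540", prefix = "MP")
  expect_true(all(c("MP:9000011", "MP:9000012", "MP:9000013") %in% neuron_hits))
  # cross-species query through the bridge; the asserted subclass
  # 'abnormal tooth development' inherits the bearer condition
  expect_setequal(query_phenotypes_by_entity(cl, "UBERON:0001091",
                                             prefix = "MP"),
                  c("MP:9000040", "MP:9000041"))
  # an entity no definition mentions
  expect_length(query_phenotypes_by_entity(cl, "CHEBI:29108"), 0)
  expect_error(query_phenotypes_by_entity(cl, "NOPE:1"),
               class = "phenoxp_unknown_class")
  # scan oracle: subjects of inheres_in edges to any descendant-or-self
  e <- cl$edges
  isa <- e[e$relation == "is_a", ]
  under <- c("CL:0000540", isa$subject[isa$object == "CL:0000540"])
  scan <- sort(unique(e$subject[e$relation == "inheres_in" &
                                  e$object %in% under]))
  scan <- scan[startsWith(scan, "MP:")]
  expect_identical(neuron_hits, scan)
})

test_that("closure exports are readable and tag inferred links", {
  fx <- build_paper_fixture()
  cl <- compute_closure(fixture_merged(fx))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_closure_tsv(cl, tsv, provenance = "test run")
  back <- readr::read_tsv(tsv, comment = "#", show_col_types = FALSE)
  expect_identical(sort(unique(back$status)), c("asserted", "inferred"))
  obo <- withr::local_tempfile(fileext = ".obo")
  write_closure_obo(cl, obo)
  lines <- readLines(obo)
  expect_true(any(grepl("! inferred \\(R", lines)))
  # the export still parses as OBO (comments are stripped)
  expect_silent(parse_obo(lines))
})
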