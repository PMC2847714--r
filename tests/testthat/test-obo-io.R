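test_that("parsing the printed big-ears stanza strips comments and keeps semantics", {
  text <- c(
    "format-version: 1.2",
    "ontology: mp-xp",
    "",
    "[Term]",
    "id: MP:0000017 ! big ears",
    "intersection_of: PATO:0000586 ! increased size",
    "intersection_of: inheres_in MA:0000236 ! ear"
  )
  doc <- parse_obo(text)
  expect_equal(doc$ontology_id, "mp-xp")
  expect_length(doc$stanzas, 1)
  st <- doc$stanzas[["MP:0000017"]]
  expect_true(is.na(st$name))
  expect_length(st$intersection_of, 2)
  genus <- st$intersection_of[[1]]
  diff <- st$intersection_of[[2]]
  expect_true(is.na(genus$relation))
  expect_equal(genus$filler, "PATO:0000586")
  expect_equal(diff$relation, "inheres_in")
  expect_equal(diff$filler, "MA:0000236")

  # comment insensitivity: same document without comments parses identically
  no_comments <- sub("\\s*!.*$", "", text)
  expect_identical(parse_obo(no_comments)$stanzas, doc$stanzas)
})

test_that("an empty document parses to a header-only structure", {
  doc <- parse_obo(c("format-version: 1.2", "ontology: empty"))
  expect_length(doc$stanzas, 0)
  expect_equal(doc$ontology_id, "empty")
})

test_that("unknown tags are opaque passthrough and synonyms keep scopes", {
  text <- c(
    "format-version: 1.2",
    "[Term]",
    "id: XX:0000001",
    "name: widget",
    'def: "some definition" [PMID:1]',
    'synonym: "gadget" EXACT []',
    'synonym: "thing ! not a comment" RELATED []',
    "xref: EXT:1"
  )
  doc <- parse_obo(text)
  st <- doc$stanzas[[1]]
  expect_equal(st$other, c('def: "some definition" [PMID:1]', "xref: EXT:1"))
  expect_equal(st$synonyms[[1]], list(text = "gadget", scope = "EXACT"))
  expect_equal(st$synonyms[[2]]$scope, "RELATED")
  expect_equal(st$synonyms[[2]]$text, "thing ! not a comment")
  # opaque lines survive a round trip
  expect_identical(parse_obo(write_obo(doc))$stanzas, doc$stanzas)
})

test_that("malformed documents are rejected with informative errors", {
  dup <- c("[Term]", "id: A:1", "name: x", "", "[Term]", "id: A:1", "name: y")
  err <- expect_error(parse_obo(dup), class = "phenoxp_malformed_document")
  expect_match(conditionMessage(err), "lines 1 and 5")

  one_clause <- c("[Term]", "id: A:1", "intersection_of: B:1")
  err2 <- expect_error(parse_obo(one_clause), class = "phenoxp_definition_arity")
  expect_match(conditionMessage(err2), "A:1")

  obsolete_with_links <- c("[Term]", "id: A:1", "is_a: A:2",
                           "is_obsolete: true")
  expect_error(parse_obo(obsolete_with_links),
               class = "phenoxp_malformed_document")
})

test_that("typedef transitivity declarations are collected", {
  doc <- parse_obo(c(
    "format-version: 1.2",
    "[Term]", "id: A:1",
    "[Typedef]", "id: part_of", "is_transitive: true",
    "[Typedef]", "id: develops_from"
  ))
  expect_equal(doc$transitive_relations, "part_of")
  round <- parse_obo(write_obo(doc))
  expect_equal(round$transitive_relations, "part_of")
  expect_length(round$typedefs, 2)
})

test_that("write/parse round trip is idempotent over generated documents", {
  for (seed in 1:6) {
    suite <- generate_suite(small_suite_params(seed))
    for (doc in suite$documents) {
      once <- parse_obo(write_obo(doc))
      twice <- parse_obo(write_obo(once))
      expect_identical(unname(doc$stanzas), unname(once$stanzas))
      expect_identical(once$stanzas, twice$stanzas)
      expect_identical(once$header, twice$header)
    }
  }
})

test_that("labels dictionary regenerates trailing comments; unknown ids get none", {
  fx <- build_paper_fixture()
  st <- fx$xp_defs$stanzas[["MP:0000017"]]
  lines <- strsplit(write_obo(
    obo_document("x", stanzas = list(st),
                 header = c("format-version: 1.2", "ontology: x")),
    labels = fx$labels
  ), "\n")[[1]]
  expect_true("id: MP:0000017 ! big ears" %in% lines)
  expect_true("intersection_of: inheres_in MA:0000236 ! ear" %in% lines)
  # an id absent from the dictionary is written without a guessed comment
  st2 <- term_stanza("ZZ:0000001", is_a = "ZZ:0000002")
  lines2 <- strsplit(write_obo(
    obo_document("y", stanzas = list(st2),
                 header = "format-version: 1.2"), labels = fx$labels
  ), "\n")[[1]]
  expect_true("is_a: ZZ:0000002" %in% lines2)
})

test_that("merge unions stanzas, records provenance, and is order-insensitive", {
  fx <- build_paper_fixture()
  single <- merge_documents(list(fx$mini_cl))
  expect_identical(single, fx$mini_cl)

  ab <- merge_documents(list(fx$mini_mp, fx$mini_pato, fx$mini_cl))
  ba <- merge_documents(list(fx$mini_cl, fx$mini_pato, fx$mini_mp))
  expect_identical(ab$stanzas[sort(names(ab$stanzas))],
                   ba$stanzas[sort(names(ba$stanzas))])
  expect_equal(unname(ab$source[["CL:0000121"]]), "mini-cl")

  # same id with compatible content (bridge style) is unioned
  merged <- merge_documents(list(fx$mini_ma, fx$mini_bridge))
  expect_setequal(merged$stanzas[["MA:0000348"]]$is_a,
                  c("MA:0000001", "UBERON:0001091"))
})

test_that("conflicting duplicate ids abort the merge naming both sources", {
  a <- obo_document("src-a", stanzas = list(term_stanza("X:1", name = "left")),
                    header = "format-version: 1.2")
  b <- obo_document("src-b", stanzas = list(term_stanza("X:1", name = "right")),
                    header = "format-version: 1.2")
  err <- expect_error(merge_documents(list(a, b)),
                      class = "phenoxp_merge_conflict")
  expect_match(conditionMessage(err), "X:1")
  expect_match(conditionMessage(err), "src-a")
  expect_match(conditionMessage(err), "src-b")
})

test_that("dangling references are permitted and surfaced by the lint", {
  doc <- obo_document("x", stanzas = list(
    term_stanza("X:1", name = "a", is_a = "Y:9")
  ), header = "format-version: 1.2")
  lint <- lint_dangling(doc)
  expect_equal(nrow(lint), 1)
  expect_equal(lint$target, "Y:9")
  expect_equal(nrow(lint_dangling(build_paper_fixture()$mini_cl)), 0)
})
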