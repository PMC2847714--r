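# Shared helpers for the test suite. Fixtures are built in code; nothing is
# read from disk except files the tests themselves write to tempdir().

edge_set <- function(edges, with_status = TRUE) {
  if (with_status) {
    sort(paste(edges$subject, edges$relation, edges$object, edges$status))
  } else {
    sort(paste(edges$subject, edges$relation, edges$object))
  }
}

pair_set <- function(tb) sort(paste(tb$subject, tb$object))

fixture_merged <- function(fx, bridge = FALSE) {
  docs <- list(fx$mini_mp, fx$mini_pato, fx$mini_cl, fx$mini_ma,
               fx$mini_go, fx$mini_chebi, fx$xp_defs)
  if (bridge) docs <- c(docs, list(fx$mini_bridge))
  merge_documents(docs)
}

small_suite_params <- function(seed) {
  generator_params(seed = seed, n_quality = 6, n_entity = 12,
                   n_phenotype = 15, withheld_links = 2,
                   unsupported_links = 3)
}

suite_doc <- function(suite) {
  materialize_expressions(merge_documents(suite$documents), suite$xp_defs)
}

# A tiny two-ontology pair with a deliberate label collision on "ear".
collision_lexicon <- function() {
  mk <- function(oid, id, name) {
    obo_document(oid, stanzas = list(term_stanza(id = id, name = name)),
                 header = c("format-version: 1.2", paste0("ontology: ", oid)))
  }
  build_lexicon(
    list(mk("a", "AA:0000001", "ear"), mk("b", "BB:0000001", "ear"),
         build_mini_pato_for_tests()),
    roles = c("gross-anatomy", "cell", "quality")
  )
}

build_mini_pato_for_tests <- function() {
  build_paper_fixture()$mini_pato
}
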