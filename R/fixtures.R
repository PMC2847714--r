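# Hand-built mini-ontologies reproducing the classic worked examples:
# the 'big ears' stanza, the Purkinje-cell degeneration inference, the
# equivalence-mapping example rows, the snout/face missing-path anecdote and
# the pancreatic delta cell counterpart anecdote. Identifiers printed in the
# source material are kept verbatim; classes whose real identifiers are not
# printed carry synthetic private ids (MP:9xxxxxx and friends).

ts <- function(id, name = NA_character_, is_a = character(),
               ns = NA_character_, syn = list(), rel = list(), xp = list(),
               obsolete = FALSE) {
  term_stanza(
    id = id, name = name, namespace = ns,
    synonyms = map(syn, ~ list(text = .x, scope = "EXACT")),
    is_a = is_a, relationships = rel, intersection_of = xp,
    is_obsolete = obsolete
  )
}

mini_doc <- function(ontology_id, stanzas, typedefs = list()) {
  obo_document(
    ontology_id = ontology_id,
    header = c("format-version: 1.2", paste0("ontology: ", ontology_id)),
    stanzas = stanzas, typedefs = typedefs
  )
}

part_of_typedef <- function() {
  list(list(id = "part_of", is_transitive = TRUE,
            lines = c("id: part_of", "is_transitive: true")))
}

build_mini_pato <- function() {
  mini_doc("mini-pato", list(
    ts("PATO:0000001", "quality", ns = "quality"),
    ts("PATO:0000051", "morphology", "PATO:0000001", ns = "quality"),
    ts("PATO:0000141", "structure", "PATO:0000051", ns = "quality"),
    ts("PATO:0000639", "degenerate", "PATO:0000141", ns = "quality"),
    ts("PATO:0000052", "shape", "PATO:0000051", ns = "quality"),
    ts("PATO:0000616", "asymmetric", "PATO:0000052", ns = "quality"),
    ts("PATO:0000117", "size", "PATO:0000001", ns = "quality"),
    ts("PATO:0000586", "increased size", "PATO:0000117", ns = "quality",
       syn = list("big", "large", "enlarged")),
    ts("PATO:0001715", "decreased diameter", "PATO:0000117", ns = "quality"),
    ts("PATO:0001499", "spherical", "PATO:0000052", ns = "quality"),
    ts("PATO:0000625", "inverted", "PATO:0000001", ns = "quality"),
    ts("PATO:0000502", "delayed", "PATO:0000001", ns = "quality"),
    ts("PATO:0000936", "truncated", "PATO:0000052", ns = "quality"),
    ts("PATO:0000645", "hypoplastic", "PATO:0000117", ns = "quality"),
    ts("PATO:0000599", "decreased width", "PATO:0000117", ns = "quality"),
    ts("PATO:0000585", "shrunken", "PATO:0000117", ns = "quality"),
    ts("PATO:0001323", "area", "PATO:0000117", ns = "quality"),
    ts("PATO:0000085", "sensitivity", "PATO:0000001", ns = "quality"),
    ts("PATO:0000033", "concentration of", "PATO:0000001", ns = "quality"),
    ts("PATO:0001162", "decreased concentration of", "PATO:0000033",
       ns = "quality"),
    ts("PATO:0001555", "has number of", "PATO:0000001", ns = "quality"),
    ts("PATO:0002000", "lacking all parts of type", "PATO:0001555",
       ns = "quality"),
    ts("PATO:0002001", "has fewer parts of type", "PATO:0001555",
       ns = "quality"),
    ts("PATO:0002002", "has extra parts of type", "PATO:0001555",
       ns = "quality"),
    ts("PATO:0000460", "abnormal", "PATO:0000001", ns = "quality")
  ))
}

build_mini_cl <- function() {
  mini_doc("mini-cl", list(
    ts("CL:0000000", "cell"),
    ts("CL:0002319", "neural cell", "CL:0000000"),
    ts("CL:0000540", "neuron", "CL:0002319"),
    ts("CL:0000117", "CNS neuron", "CL:0000540"),
    ts("CL:0000121", "Purkinje cell", "CL:0000117"),
    ts("CL:0000100", "motor neuron", "CL:0000540"),
    ts("CL:0000232", "erythrocyte", "CL:0000000"),
    ts("CL:0000164", "enteroendocrine cell", "CL:0000000"),
    ts("CL:0000173", "pancreatic delta cell", "CL:0000164")
  ))
}

build_mini_ma <- function(snout_part_of_face = TRUE) {
  snout_rel <- if (snout_part_of_face) {
    list(link_clause("part_of", "MA:0002446"))
  } else {
    list()
  }
  mini_doc("mini-ma", list(
    ts("MA:0000001", "mouse anatomical structure"),
    ts("MA:0000236", "ear", "MA:0000001"),
    ts("MA:0001359", "femur", "MA:0000001"),
    ts("MA:0000029", "abdomen", "MA:0000001"),
    ts("MA:0000141", "spleen", "MA:0000001",
       rel = list(link_clause("part_of", "MA:0000029"))),
    ts("MA:0002445", "snout", "MA:0000001", rel = snout_rel),
    ts("MA:0002446", "face", "MA:0000001"),
    ts("MA:0002504", "urine", "MA:0000001"),
    ts("MA:0000019", "visceral organ system", "MA:0000001"),
    ts("MA:0000184", "basal ganglia", "MA:0000001"),
    ts("MA:0000348", "tooth", "MA:0000001")
  ), typedefs = part_of_typedef())
}

build_mini_go <- function() {
  mini_doc("mini-go", list(
    ts("GO:0030425", "dendrite", ns = "cellular_component"),
    ts("GO:0030424", "axon", ns = "cellular_component"),
    ts("GO:0042476", "odontogenesis", ns = "biological_process",
       syn = list("tooth development")),
    ts("GO:0001822", "kidney development", ns = "biological_process"),
    ts("GO:0007601", "visual perception", ns = "biological_process")
  ))
}

build_mini_chebi <- function() {
  mini_doc("mini-chebi", list(
    ts("CHEBI:29108", "calcium"),
    ts("CHEBI:18248", "iron"),
    ts("CHEBI:22676", "auxin")
  ))
}

build_mini_mp <- function(withhold_fig2_link = FALSE) {
  pcd_parents <- if (withhold_fig2_link) character() else "MP:9000011"
  mini_doc("mini-mp", list(
    ts("MP:0000001", "mammalian phenotype"),
    ts("MP:0000017", "big ears", "MP:0000001"),
    ts("MP:9000010", "neurodegeneration", "MP:0000001"),
    ts("MP:9000011", "neuron degeneration", "MP:9000010"),
    ts("MP:9000012", "Purkinje cell degeneration", pcd_parents),
    ts("MP:9000013", "motor neuron degeneration", "MP:9000011"),
    ts("MP:9000014", "axon degeneration", "MP:9000010"),
    ts("MP:9000040", "abnormal tooth morphology", "MP:0000001"),
    ts("MP:9000041", "abnormal tooth development", "MP:9000040"),
    ts("MP:0008152", "decreased diameter of femur", "MP:0000001"),
    ts("MP:0002812", "spherocytosis", "MP:0000001"),
    ts("MP:0008739", "abnormal spleen iron level", "MP:0000001"),
    ts("MP:0002766", "situs inversus", "MP:0000001"),
    ts("MP:0000528", "delayed kidney development", "MP:0000001"),
    ts("MP:0003242", "loss of basal ganglion neurons", "MP:0000001"),
    ts("MP:0008572", "abnormal Purkinje cell dendrite morphology",
       "MP:0000001")
  ))
}

fixture_xp_defs <- function(vocab = relation_vocabulary()) {
  g <- function(q) intersection_clause(q)
  ii <- function(e) intersection_clause(e, vocab$inheres_in)
  tw <- function(e) intersection_clause(e, vocab$towards)
  hq <- function(m) intersection_clause(m, vocab$has_qualifier)
  dendrite_pc <- materialize_expression(
    xp_composed("GO:0030425",
                list(list(relation = vocab$part_of,
                          filler = xp_named("CL:0000121"))))
  )
  stanzas <- c(dendrite_pc$stanzas, list(
    ts("MP:0000017", xp = list(g("PATO:0000586"), ii("MA:0000236"))),
    ts("MP:9000010", xp = list(g("PATO:0000639"), ii("CL:0002319"))),
    ts("MP:9000011", xp = list(g("PATO:0000639"), ii("CL:0000540"))),
    ts("MP:9000012", xp = list(g("PATO:0000639"), ii("CL:0000121"))),
    ts("MP:9000013", xp = list(g("PATO:0000639"), ii("CL:0000100"))),
    ts("MP:9000014", xp = list(g("PATO:0000639"), ii("GO:0030424"))),
    ts("MP:9000040", xp = list(g("PATO:0000051"), ii("MA:0000348"),
                               hq("PATO:0000460"))),
    ts("MP:9000041", xp = list(g("PATO:0000001"), ii("GO:0042476"),
                               hq("PATO:0000460"))),
    ts("MP:0008152", xp = list(g("PATO:0001715"), ii("MA:0001359"))),
    ts("MP:0002812", xp = list(g("PATO:0001499"), ii("CL:0000232"))),
    ts("MP:0008739", xp = list(g("PATO:0000033"), ii("MA:0000141"),
                               tw("CHEBI:18248"), hq("PATO:0000460"))),
    ts("MP:0002766", xp = list(g("PATO:0000625"), ii("MA:0000019"))),
    ts("MP:0000528", xp = list(g("PATO:0000502"), ii("GO:0001822"))),
    ts("MP:0003242", xp = list(g("PATO:0002001"), ii("MA:0000184"),
                               tw("CL:0000540"))),
    ts("MP:0008572", xp = list(g("PATO:0000051"), ii(dendrite_pc$id),
                               hq("PATO:0000460")))
  ))
  mini_doc("mini-mp-xp", stanzas)
}

# The 'asymmetric snout' / 'abnormal facial morphology' anecdote, isolated:
# the asserted phenotype link is only recoverable once the anatomy ontology
# links snout to face. The parent class is defined with inheres_in_part_of,
# the standard shape of "abnormal X morphology" cross-product definitions.
build_snout_case <- function(with_part_of = TRUE,
                             vocab = relation_vocabulary()) {
  mp <- mini_doc("snout-mp", list(
    ts("MP:0000001", "mammalian phenotype"),
    ts("MP:9000021", "abnormal face morphology", "MP:0000001"),
    ts("MP:9000020", "abnormal snout morphology", "MP:9000021")
  ))
  defs <- mini_doc("snout-xp", list(
    ts("MP:9000020", xp = list(
      intersection_clause("PATO:0000051"),
      intersection_clause("MA:0002445", vocab$inheres_in),
      intersection_clause("PATO:0000460", vocab$has_qualifier))),
    ts("MP:9000021", xp = list(
      intersection_clause("PATO:0000051"),
      intersection_clause("MA:0002446", vocab$inheres_in_part_of),
      intersection_clause("PATO:0000460", vocab$has_qualifier)))
  ))
  list(
    phenotype = mp, xp_defs = defs,
    support = list(build_mini_pato(), build_mini_ma(with_part_of))
  )
}

# The pancreatic delta cell anecdote: the cell ontology subsumption has no
# counterpart between the two correspondingly-defined phenotype classes.
build_delta_case <- function(vocab = relation_vocabulary()) {
  mp <- mini_doc("delta-mp", list(
    ts("MP:0000001", "mammalian phenotype"),
    ts("MP:9000030", "abnormal pancreatic delta cell morphology",
       "MP:0000001"),
    ts("MP:9000031", "abnormal enteroendocrine cell morphology",
       "MP:0000001")
  ))
  defs <- mini_doc("delta-xp", list(
    ts("MP:9000030", xp = list(
      intersection_clause("PATO:0000051"),
      intersection_clause("CL:0000173", vocab$inheres_in),
      intersection_clause("PATO:0000460", vocab$has_qualifier))),
    ts("MP:9000031", xp = list(
      intersection_clause("PATO:0000051"),
      intersection_clause("CL:0000164", vocab$inheres_in),
      intersection_clause("PATO:0000460", vocab$has_qualifier)))
  ))
  list(phenotype = mp, xp_defs = defs,
       support = list(build_mini_pato(), build_mini_cl()))
}

#' Build the worked-example fixture suite
#'
#' Hand-built mini-ontologies that reproduce, end to end, the classic worked
#' examples: the 'big ears' intersection stanza, the Purkinje-cell
#' degeneration inference over the cell ontology hierarchy, the
#' equivalence-mapping example rows, absence and relational-quality
#' phenotypes, the cross-species tooth bridge, and the snout/face and
#' pancreatic delta cell consistency anecdotes.
#'
#' @param withhold_fig2_link drop the asserted 'Purkinje cell degeneration'
#'   is_a 'neuron degeneration' link, the configuration in which the
#'   reasoner proposes it back as a novel link.
#' @param snout_part_of_face include the snout part_of face link in the
#'   anatomy ontology (its absence is the missing-path lint case).
#' @param vocab a [relation_vocabulary()].
#' @return A list of class `paper_fixture` with mini ontologies (`mini_pato`,
#'   `mini_cl`, `mini_ma`, `mini_go`, `mini_chebi`, `mini_mp`,
#'   `mini_bridge`), the definition document `xp_defs`, the example-row
#'   table `eq_examples`, the isolated `snout_case`/`delta_case` fixtures,
#'   and a combined label map `labels`.
#' @export
build_paper_fixture <- function(withhold_fig2_link = FALSE,
                                snout_part_of_face = TRUE,
                                vocab = relation_vocabulary()) {
  mini_pato <- build_mini_pato()
  mini_cl <- build_mini_cl()
  mini_ma <- build_mini_ma(snout_part_of_face)
  mini_go <- build_mini_go()
  mini_chebi <- build_mini_chebi()
  mini_mp <- build_mini_mp(withhold_fig2_link)
  mini_bridge <- mini_doc("mini-bridge", list(
    ts("UBERON:0001091", "tooth"),
    ts("MA:0000348", is_a = "UBERON:0001091")
  ))
  fixture <- list(
    mini_pato = mini_pato, mini_cl = mini_cl, mini_ma = mini_ma,
    mini_go = mini_go, mini_chebi = mini_chebi, mini_mp = mini_mp,
    mini_bridge = mini_bridge,
    xp_defs = fixture_xp_defs(vocab),
    eq_examples = eq_example_rows(),
    snout_case = build_snout_case(snout_part_of_face, vocab),
    delta_case = build_delta_case(vocab),
    labels = collect_labels(mini_pato, mini_cl, mini_ma, mini_go,
                            mini_chebi, mini_mp, mini_bridge)
  )
  structure(fixture, class = "paper_fixture")
}

#' Equivalence-mapping example rows
#'
#' The sixteen example mappings from pre-composed phenotype classes to EQ
#' descriptions across the mouse, human, worm and plant phenotype
#' ontologies, with identifiers as printed.
#'
#' @return A tibble: `id`, `label`, `eq` (list-column of [eq()]).
#' @export
eq_example_rows <- function() {
  rows <- list(
    list("MP:0008152", "Decreased diameter of femur",
         eq("MA:0001359", "PATO:0001715")),
    list("MP:0002812", "Spherocytosis", eq("CL:0000232", "PATO:0001499")),
    list("MP:0008739", "Abnormal spleen iron level",
         eq("MA:0000141", "PATO:0000033", entity2 = "CHEBI:18248",
            modifier = "PATO:0000460")),
    list("MP:0002766", "Situs inversus", eq("MA:0000019", "PATO:0000625")),
    list("MP:0000528", "Delayed kidney development",
         eq("GO:0001822", "PATO:0000502")),
    list("MP:0004714", "Truncated notochord", eq("EMAP:4109", "PATO:0000936")),
    list("MP:0000938", "Motor neuron degeneration",
         eq("CL:0000100", "PATO:0000639")),
    list("MP:0005405", "Axon degeneration", eq("GO:0030424", "PATO:0000639")),
    list("MP:0003242", "Loss of basal ganglion neurons",
         eq("MA:0000184", "PATO:0002001", entity2 = "CL:0000540")),
    list("MP:0008572", "Abnormal Purkinje cell dendrite morphology",
         eq("GO:0030425^part_of(CL:0000121)", "PATO:0000051",
            modifier = "PATO:0000460")),
    list("HP:0000013", "Hypoplastic uterus", eq("FMA:17558", "PATO:0000645")),
    list("HP:0000504", "Abnormality of vision",
         eq("GO:0007601", "PATO:0000001", modifier = "PATO:0000460")),
    list("HP:0003275", "Narrow pelvis", eq("FMA:9578", "PATO:0000599")),
    list("WBPhenotype:0000086", "Shruken intestine",
         eq("WBbt:0005772", "PATO:0000585")),
    list("TO:0000540", "Leaf area", eq("PO:0009025", "PATO:0001323")),
    list("TO:000163", "Auxin sensitivity",
         eq("PO:0000003", "PATO:0000085", entity2 = "CHEBI:22676"))
  )
  tibble(
    id = map_chr(rows, 1),
    label = map_chr(rows, 2),
    eq = map(rows, 3)
  )
}

#' Lexicon over the fixture's reference ontologies
#'
#' @param fixture a [build_paper_fixture()] result.
#' @param grammar a [default_grammar()] configuration.
#' @return An `xp_lexicon`.
#' @export
fixture_lexicon <- function(fixture, grammar = default_grammar()) {
  build_lexicon(
    list(fixture$mini_pato, fixture$mini_ma, fixture$mini_cl,
         fixture$mini_go, fixture$mini_chebi),
    roles = c("quality", "gross-anatomy", "cell", "go", "chemical"),
    grammar = grammar
  )
}
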