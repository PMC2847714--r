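# phenoxp

Logical definitions for phenotype ontologies via entity–quality
cross-products.

## The problem

Model-organism and clinical databases describe phenotypes with two
incompatible conventions. Pre-composed ontologies such as the Mammalian
Phenotype ontology (MP) or the Human Phenotype ontology (HP) mint a named
class per phenotype ("big ears", "Purkinje cell degeneration") and arrange
them in an `is_a` hierarchy. Post-composed annotation (ZFIN, FlyBase)
assembles descriptions at curation time from an **entity** (E) in an anatomy,
cell, process or chemical ontology and a **quality** (Q) from the PATO
quality ontology — the *EQ model*, optionally extended with a second entity
(E2) for relational qualities, a modifier (M, usually `abnormal`), and an
entity whole (EW) for bearers that are parts of larger structures.

The two conventions meet through *logical definitions*: an equivalence
between a pre-composed class and an EQ description, encoded as a
genus–differentia class intersection,

```
'big ears'  ≡  'increased size' ⊓ inheres_in some 'ear'
```

or in OBO flat-file syntax:

```
[Term]
id: MP:0000017 ! big ears
intersection_of: PATO:0000586 ! increased size
intersection_of: inheres_in MA:0000236 ! ear
```

Collections of such equivalences are *cross-product* (XP) files, e.g.
MP-XP-CL for MP classes defined over the cell ontology. Once classes carry
definitions, a reasoner can re-derive the phenotype hierarchy from the
reference ontologies — recovering asserted `is_a` links (validating the
definitions), proposing missing ones for curator review, and exposing
inconsistencies between ontologies that ought to agree.

## What the package does

* **obo_io** — read/write the OBO 1.2 dialect used by XP files
  (`parse_obo()`, `write_obo()`, `merge_documents()`), with faithful
  round-trips and regenerated `! label` comments.
* **eq_model** — `eq()` descriptions, translation to/from intersection
  clauses (`eq_to_intersection()`, `intersection_to_eq()`), EW
  normalization, absence phenotypes in relational and cardinality form
  (`translate_absence()`), and OWL Manchester rendering
  (`write_manchester()`).
* **label_grammar** — Obol-style decomposition of class labels into
  candidate EQ definitions over lexicons built from loaded ontologies
  (`build_lexicon()`, `parse_label()`, `batch_parse()`), with all ambiguity
  surfaced into a curation queue.
* **reasoner** — a forward-chaining fixpoint reasoner
  (`compute_closure()`) implementing `is_a`/transitive-relation closure,
  composition with `is_a`, definition unfolding and sufficiency, and
  optional part-to-whole quality propagation; plus `infer_novel_links()`
  and `query_phenotypes_by_entity()` (cross-species via bridging axioms).
  An independent naive-saturation oracle (`naive_closure()`) cross-checks
  it edge for edge.
* **validation** — `recapitulate()` (delete the phenotype ontology's
  `is_a` links, re-derive them, report recall), `missing_link_report()`
  for curator triage, `consistency_lint()` for missing-path and
  missing-counterpart findings, and `coverage_stats()`.
* **fixtures** — `build_paper_fixture()` (hand-built mini-ontologies for
  the classic worked examples) and `generate_suite()` (seeded random
  ontology suites whose entailed, withheld and unsupported links are known
  by construction).

Results are tibbles or carry `tidy()`/`glance()`/`autoplot()` methods. A
command-line entry point lives at `inst/scripts/phenoxp.R` (subcommands
`translate`, `parse-labels`, `reason`, `suggest-links`, `recapitulate`,
`lint`, `coverage`, `query`, `fixture`).

## Worked example

```r
library(phenoxp)

fx  <- build_paper_fixture()
lex <- fixture_lexicon(fx)

# decompose a label into an EQ definition
parse_label("big ears", lex)
#> <parse of 'big ears': 1 candidate(s)>
#>   [quality_bearer] E = MA:0000236 / Q = PATO:0000586

# the reasoner proposes the withheld degeneration link back
fxw <- build_paper_fixture(withhold_fig2_link = TRUE)
cl  <- compute_closure(merge_documents(list(
  fxw$mini_mp, fxw$mini_pato, fxw$mini_cl, fxw$mini_ma,
  fxw$mini_go, fxw$mini_chebi, fxw$xp_defs)))
infer_novel_links(cl, "MP")[, 1:4]
#> # A tibble: 1 × 4
#>   subject    object     subject_label              object_label
#> 1 MP:9000012 MP:9000011 Purkinje cell degeneration neuron degeneration

# recapitulation on a generated suite with known ground truth
suite <- generate_suite(generator_params(seed = 42))
recapitulate(suite$documents$phenotype, suite$xp_defs,
             suite$documents[c("quality", "entity")])
#> Recapitulation of asserted is_a links
#>   asserted:  80
#>   recovered: 70 (recall_all = 0.875)
#>   missed:    10
#>   novel:     5 proposed direct links
#>   recall over links between defined classes: 0.946 (74 links)
```

The proposed link is 'Purkinje cell degeneration' `is_a` 'neuron
degeneration', inferred from the definitions and the cell ontology's
`is_a` chain (Purkinje cell → CNS neuron → neuron). In the recapitulation,
`recall_all` is measured over every asserted link — including the ten
deliberately unsupported ones the generator planted, which are correctly
missed — while the five withheld entailed links come back as novel
proposals; both match the generator's ground truth exactly.

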