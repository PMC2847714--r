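---
title: "Logical definitions for phenotype ontologies: model, reasoner and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logical definitions for phenotype ontologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoxp)
```

## The model

A pre-composed phenotype class is given a *logical definition* as an
entity–quality (EQ) class intersection. The description has up to five
elements:

* **E** — the bearer entity, a class from an anatomy (MA, FMA), cell (CL),
  cell-component or process (GO) or chemical (CHEBI) ontology. E may be a
  *composed* expression, `genus^relation(filler)` in caret syntax: the
  bearer of "abnormal Purkinje cell dendrite morphology" is
  `dendrite^part_of(Purkinje cell)`, a class that no ontology pre-composes.
* **Q** — the quality, a PATO class; always present.
* **E2** — a second entity for *relational* qualities ("concentration of
  calcium", "lacking all parts of type spleen").
* **M** — a modifier class, in practice PATO `abnormal`. We deliberately
  model abnormality only through a `has_qualifier` differentium, never as a
  boolean flag; what constitutes "normal" is out of scope.
* **EW** — the *entity whole*, surface syntax asserting that the bearer is
  part of a larger structure. EW is sugar: `normalize_entity_whole()`
  rewrites `E = dendrite, EW = Purkinje cell` into the nested composition,
  which is the canonical internal form. One canonical form keeps equality,
  hashing and reasoning simple; `denormalize_entity_whole()` recovers the
  surface form for tabular presentation.

The translation to intersection clauses is fixed: genus = Q, one
`inheres_in E` differentium, `towards E2` iff E2 is present, `has_qualifier
M` iff M is present. `intersection_to_eq()` is its exact inverse, and the
bijection is property-tested over randomly generated descriptions. The
Manchester rendering is write-only — `Q that inheres_in some E [and towards
some E2] [and has_qualifier some M]` — and we never parse Manchester text.

Composed expressions are materialized before reasoning: each distinct
composition becomes a stanza whose identifier is `XP:` plus a content hash
of the canonicalized caret form. Differentia are sorted by (relation,
rendered filler) before hashing, so two expressions are equal iff their
canonical renderings are identical and repeated materialization is stable
across runs and machines.

### Absence

Absence is phrased with relational number-of-parts qualities on the entity
that *lacks* the part (`E = abdomen, Q = lacking all parts of type,
E2 = spleen`), because a missing spleen cannot bear a quality. The explicit
cardinality rendering (`Abdomen that has_part exactly 0 spleen`) is
available behind a mode flag, only for the lacking-all-parts quality —
relative counts have no cardinality form — and it is deliberately **inert in
the reasoner**: no rule consumes `has_part exactly 0`, since making it
bite requires non-monotonic machinery that is out of scope, and naive use
can contradict the anatomy ontology. The relational form is therefore the
default.

## The label grammar

Lexicons are built from the names and EXACT synonyms of every non-obsolete
class in the loaded ontologies, keyed by normalized token sequences (lower
case, hyphens and underscores as separators). Non-EXACT synonyms are
excluded: broad or related synonyms produce wrong equivalences, and the
productions are specified over labels and exact synonyms only. Collisions
are kept — one key may map to several classes — and any resulting ambiguity
is surfaced, never resolved silently.

Six productions ship as defaults, applied over the token sequence with all
maximal parses returned: `quality bearer`, `quality "of" bearer`,
`"abnormal" bearer "morphology"`, `"abnormal(ity) [of]" bearer` (quality
root plus abnormal modifier), compound-bearer splitting (an anatomical or
cell structure followed by a cell-component head becomes
`component^part_of(structure)`), and `"absent" bearer`. The production set,
role priorities and irregular-plural table live in a YAML grammar file
(`inst/extdata/default_grammar.yaml`), because different phenotype
ontologies follow different terminological conventions and should be
parseable by configuration rather than code changes.

Heuristics worth stating explicitly:

* Bearer matching is longest-match and right-anchored, because English
  phenotype labels are head-final. This is a documented heuristic, not a
  claim about grammar.
* Plural handling is an irregular dictionary plus trailing-"s" stripping
  tried as a fallback key variant ("ears" → "ear").
* The absence production leaves E unresolved (`_UNRESOLVED_`, flagged
  `needs_curation`): the whole that lacks the part ("abdomen" for an absent
  spleen) is anatomical knowledge, not label syntax, so guessing it would
  be wrong by construction.
* Ranking is (fewest unmatched tokens, longest bearer span, role priority
  gross-anatomy > cell > cell-component > process > chemical, production
  order), with a lexicographic tie-break for determinism.

`batch_parse()` accepts only unambiguous single-candidate parses into the
XP document; everything else — no parse (clinical eponyms such as "situs
inversus"), multiple parses, unresolved absence bearers — goes to a
curation queue with the candidates and unmatched tokens listed.

## The reasoner

`compute_closure()` computes the least fixpoint of a small monotone rule
set over the merged, materialized documents: R1 `is_a` transitivity; R2
closure of declared transitive relations (default `part_of`, plus any
`is_transitive` Typedef declarations); R3 composition of any relation with
`is_a` on either side; R4 definition necessary conditions; R5 definition
sufficiency. Termination is guaranteed because the edge universe is
bounded by |classes|² × |relations|. Evaluation is semi-naive —
transitivity and composition re-fire only against the newest delta, while
R5 is re-evaluated per iteration (definitions are few, candidate sets are
computed by joins) — and every inferred edge records its rule and premise
edges, so curator-facing reports can show full provenance chains down to
asserted links.

Design choices where the design was genuinely open:

* **Part-to-whole quality propagation (R6)** is off by default, and when
  enabled derives the *distinct* relation `inheres_in_part_of`
  (`inheres_in` composed with reflexive-transitive `part_of`), never plain
  `inheres_in`: a quality of a dendrite is not a quality of the cell. This
  mirrors how real "abnormal X morphology" cross-products are written —
  their definitions use `inheres_in_part_of` so that phenotypes of parts
  classify under phenotypes of wholes only when the ontology says so. The
  snout/face recapitulation and `consistency_lint()` run with R6 enabled
  for exactly this reason.
* **Reflexivity**: `Z = genus` is accepted when matching R5, but reflexive
  edges are suppressed in every output; curators never see `X is_a X`.
* **Cycles**: a cycle among *asserted* `is_a` links is a hard input error,
  reported with the cycle listed. Derived mutual subsumption is allowed —
  two classes given the same definition are legitimately equivalent, and
  wrong asserted links can combine with definitions to entail
  equivalences; reporting beats refusing here.
* **Other relations** (`develops_from`, ...) get no special semantics: they
  participate only through R3 and any declared transitivity.
* **Segmentation**: the CLI's `reason --segment` reasons over the phenotype
  document paired with each support ontology in turn, the classic strategy
  for memory-bound reasoners; results can be incomplete for definitions
  spanning several ontologies, and the output says so.

The production reasoner is anchored to an independent oracle:
`naive_closure()` re-applies every rule to every edge pair until nothing
changes, with no delta bookkeeping, no indexes and no shared derivation
code. Tests compare the two edge-for-edge on hundreds of seeded random
documents, and the suite generator computes its ground truth with the
oracle, so generator and production reasoner cannot share a bug.

## Validation procedures

`recapitulate()` removes every asserted `is_a` link of the phenotype
ontology (support ontologies untouched), recomputes the closure from the
definitions, and classifies each original edge as recovered (entailed,
directly or indirectly — we count reconstructable links, not graph
isomorphism) or missed; inferred phenotype-internal *direct* edges never
asserted are reported as novel proposals. Two recall denominators are
reported: `recall_all` over every asserted link — including links between
undefined classes that can never be recovered — and `recall_defined` over
links whose both endpoints have definitions. The first measures the
combination of coverage and definition quality, the second isolates
definition quality; conflating them makes recapitulation numbers hard to
interpret.

Novel links are *direct*: an inferred `subject is_a object` is suppressed
when a distinct intermediate `Z` with `subject is_a Z is_a object` exists
in the closure, so curators see a minimal proposal set. Curation reports
are TSV with labels, provenance chains and a verdict column whose values
follow the four observed triage outcomes (accepted, rejected,
partially-correct, pending); `read_curation_file()` recovers verdict
counts from a triaged file.

`consistency_lint()` surfaces two failure shapes seen when ontologies that
ought to agree do not: *missing-path* (an asserted phenotype link whose
definitions' fillers have no connecting `is_a`/`part_of` path in the
support ontologies — resolved by adding, say, `snout part_of face` to the
anatomy ontology) and *missing-counterpart* (a reference-ontology
subsumption, like pancreatic delta cell under enteroendocrine cell, with
no corresponding link between the equivalently-shaped phenotype classes).
Type (b) compares only same-genus, same-qualifier definition pairs
differing in the one entity filler; broader diffing produces noise.

## The synthetic suite generator

`generate_suite()` emulates the recapitulation study design at desk scale:
rooted random DAGs for the quality and entity ontologies (each non-root
class gets one tree parent and, with probability 0.15, a second);
phenotype classes of which a fraction carry definitions over sampled
(Q, E[, M]) tuples, with nested `component^part_of(structure)` bearers at
probability 0.1; an asserted `is_a` graph equal to the entailed set minus
a withheld sample of direct entailed links, plus extra links no definition
supports. Ground truth (entailed, withheld, unsupported, expected recall)
is computed by the naive oracle before any assertion exists, so expected
recall and the expected novel set are exact, with no tolerance.

Default conditions: 12 quality classes, 25 entity classes, 40 phenotype
classes, 73% of phenotype classes defined (the coverage a well-curated
cross-product set reaches), 5 withheld links, 10 unsupported links. Two
structural guarantees keep the experiment well posed at any seed: the
generator first mints `withheld + 3` child/parent definition pairs (child
quality and entity at or below the parent's) so enough direct entailed
links exist to withhold, and unsupported links are sampled acyclically
against the *union* of entailed and asserted edges, so a wrong assertion
can never combine with an entailment into a derived equivalence.
Definitions are de-duplicated on canonical form for the same reason.

What the generator does **not** emulate: the class-count ratios, depth
distributions and label vocabulary of real MP/MA/CL releases, multiple
entity ontologies per suite, and curation noise in definitions. Passing
tests on generated suites therefore demonstrate the correctness of the
machinery — translation, reasoning, bookkeeping — under known ground
truth, not the recall one would measure on real ontologies, which depends
on curation coverage and reference-ontology completeness. The classic
headline counts from full 2009-era MP/HP releases are in that second
category: they require those exact versioned downloads and are not
reproducible at desk scale, which is why validation here is worked
examples plus construction oracles.

Problem sizes in the shipped tests and acceptance script (200 oracle
comparisons at ≤ 40 classes, 10–20 recapitulation suites at default size,
500 synthesized labels, ~100 round-trip documents) were chosen to exercise
every rule interaction several times over while keeping a full run in the
low minutes on a single core.

## Numerical and formatting choices

* Deterministic ordering everywhere user-visible: closure edges sorted by
  (relation, subject, object), novel links by (subject, object), parse
  candidates by the ranking key with a lexicographic tie-break. Identical
  inputs give byte-identical outputs.
* `XP:` identifiers use the first ten hex digits of a stable string hash
  of the canonical caret form.
* OBO writing follows canonical tag order (id, name, namespace, opaque
  tags, synonym, is_a, intersection_of, relationship, is_obsolete);
  trailing `! label` comments are regenerated from a supplied id→label
  dictionary and omitted — never guessed — when the referenced ontology is
  not loaded.
* The cardinality rendering capitalizes the sentence-initial entity label,
  matching the conventional presentation of such axioms.
* Seeds: every stochastic routine takes an explicit integer seed and
  restores the caller's RNG state; generated files record the seed in a
  header remark.

## Known limitations

* No OWL-DL semantics: no negation, disjointness or cardinality
  *reasoning* (cardinality is render-only), and no equivalence-class
  machinery beyond mutual-subsumption reporting.
* `intersection_to_eq()` handles the EQ pattern only; definitions using
  other differentium relations (e.g. `inheres_in_part_of` aggregates) are
  reasoned over but reported as unsupported patterns by the EQ inverter.
* The grammar ships with the six default productions; labels outside them
  (clinical eponyms, coordination, measurements) are routed to curation by
  design rather than guessed.
* Bridging axioms are plain subclass links; no attempt is made to verify
  them against the bridged ontologies.
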