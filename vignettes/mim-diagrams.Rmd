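---
title: "Molecular interaction maps: the model, the MIMML dialect, and rule-based validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular interaction maps: the model, the MIMML dialect, and rule-based validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimml)
```

## The notation

Molecular Interaction Maps (MIMs) depict cellular signaling networks the
way electrical engineers draw circuits: each molecular species appears
once, and everything that happens to it — binding, modification,
conversion, regulation — is a typed line attached to its glyph. The
notation's value for data exchange comes from being *closed*: there are
exactly eight entity glyph kinds, twelve interaction types in three
categories, and a fixed repertoire of arrowhead marks. A diagram that
uses only these, wired according to the syntax rules, is machine-checkable.

The eight entity kinds:

* **simple physical entity (SPE)** — a molecule (protein, DNA, RNA, small
  molecule) not in complex; a labeled rounded rectangle, normally drawn
  once per diagram so all of its interactions are traceable to one place.
* **entity feature** — a named region of an SPE (domain, motif, site),
  linked to its parent.
* **modifier** — a borderless label for small molecules (phosphate,
  methyl, ubiquitin) that may appear many times; routing every phosphate
  to a single glyph would be prohibitive.
* **conceptual entity** — a rectangle for things without clear physical
  structure (ionizing radiation, a phenotype).
* **source/sink** — the empty-set symbol: an unspecified source or
  degradation product.
* **explicit complex** — a filled dot *on a binding line* denoting the
  bound product. Because the dot is itself connectable, chains of dots
  encode binding order: in the trimer example, C binds the A:B dot, so C
  must dissociate before A and B can.
* **implicit complex** — an enclosure of entities asserting association
  without binding order.
* **restricted copy** — a dot acting as a copy of an SPE, existing solely
  so homo-oligomerization can be drawn without duplicating the SPE.

The twelve interaction types: eight *reactions* (non-covalent reversible
binding, covalent irreversible binding, covalent modification,
stoichiometric conversion, production without loss, template reaction,
cleavage, state combination), three *contingencies* (stimulation,
necessary stimulation, inhibition), and *catalysis*. Contingencies and
catalysis do not connect two entities: they run from a controller entity
to an **anchor** on another interaction's line — that is how "protein X
inhibits the binding of Y and Z" is drawn. Color never carries meaning.

## The in-memory model

`mim_diagram()` plus the `add_*` authoring functions build a diagram as a
plain R list with named entity and interaction records. Authoring
enforces the referential invariants (unique identifiers, resolvable
references, kind-specific attributes) eagerly, so programs constructing
diagrams fail fast. The reader deliberately does *not*: a MIMML file with
a dangling `visRef` or an unknown arrowhead token parses fine and the
problems surface as validation findings, because a validator that crashes
on invalid input cannot report on it.

Orientation is a modeling subtlety worth spelling out. For symmetric
types (the two bindings and state combination) either terminus may be
considered the start; `termini()` therefore canonicalizes the pair by
lexicographic order of the referent identifiers (a deterministic,
content-independent tie-break). For every other type, the terminus
*without* an arrowhead is the start, regardless of storage order — so a
conversion stored product-first is not an error, and the arrowhead-usage
check compares terminal marks as an unordered pair.

## The MIMML dialect

The exchange format is a small XML dialect: a `Diagram` root holding
`EntityGlyph`, `InteractionGlyph` (with `Point`, `Anchor`, `Branch`
children) and a trailing `MimBio` metadata section with Dublin-Core-style
diagram terms (`dc-title`, `dc-creator`, `dc-identifier`),
`CrossReference` records and `Annotation` records (a comment plus an
optional `PublicationXref`). The published schema for the notation is not
reproducible from the main description of the format, so the dialect here
is fixed by this package and documented by its writer: UTF-8, LF
endings, two-space indent, elements sorted by identifier, numbers at up
to nine significant digits. Fixing a byte-exact normal form is what makes
the golden-file tests meaningful and gives the round-trip contract teeth:
`write(read(write(x)))` is byte-identical to `write(x)`, and reading back
any written diagram yields a semantically equal model
(`semantic_equal()`, coordinate tolerance 1e-9).

Strict parsing requires the MIMML namespace and rejects unknown elements
and attributes; lenient parsing accepts un-namespaced input and drops
unknown constructs with a warning. Everything accepted strictly is
accepted leniently with the same result.

## Two-level validation

Level 1 checks the structural grammar: identifier uniqueness, reference
resolution, closed-vocabulary tokens, the two-point minimum for lines,
and kind-specific attribute usage. Level 2 is the syntax-rule engine
covering the notation's five rule families: label formats, arrowhead
usage, on-line symbol placement, connection rules, and (folded into the
same pass) restricted-copy and branch usage. Level 2 runs only when
level 1 found no duplicate or dangling identifiers — a rule engine over
unresolvable references would produce nonsense. All problems are
findings, never exceptions; findings are reported exhaustively and sorted
by (context, rule) so reports are deterministic and invariant to storage
order.

Reports render to an SVRL subset (`fired-rule` per rule evaluated,
`failed-assert` per finding with an XPath location, a message, and named
`diagnostic-reference` entries such as `vis-id` and `inter-vis-id`) and
to JSON. The SVRL grammar ships with the package
(`inst/extdata/svrl-subset.xsd`) and every emitted location path resolves
to exactly one element of the serialized document.

### The connection rule table

The complete connection tables of the notation's full specification are
not restated in its published summary, so this package fixes the table as
data (`connection_rule_table()`), anchored to the statements that are
published: bindings connect physical things (SPEs, features, conceptual
entities, complexes, and — only for homodimers — restricted copies);
covalent modification runs from a modifier to the modified entity;
conversions connect anything physical including source/sink; explicit
complexes may sit only on covalent modification, the two bindings, and
state combination; contingencies end on anchors of reactions or other
contingencies; catalysis ends on anchors of reactions only (a catalyst
accelerates a reaction). Any future reconciliation with the full tables
means editing rows, never the engine.

Three points the published description leaves open were decided here:

* **Cleavage** is treated as directed from the cleaved entity to the
  released moiety, and its product side additionally admits *modifier*
  entities. The motivating example — cleavage of phosphate from the
  kinase CaMK — releases a small molecule that the notation draws as a
  modifier; without this row entry the canonical example could not
  validate.
* **State combination** is treated as a symmetric reaction (it appears in
  the explicit-complex host list alongside the bindings).
* **Contingencies carry no on-line symbols**, and the intramolecular mark
  is legal only on a reaction whose two termini resolve, through their
  parent references, to the same SPE.
* **Branching** is restricted to the producing reaction types
  (stoichiometric conversion, production without loss, template reaction,
  cleavage); bindings and contingencies may not fan out.

## The synthetic-data generator

`generate_valid_diagram()` is correct by construction: entities are laid
out first (SPE-dominated kind frequencies: 0.5 SPE, 0.15 feature, 0.1
modifier, 0.1 conceptual, 0.15 others), then interactions are sampled
only from feasible rows of the rule table, then metadata is attached.
Explicit complexes decorate eligible lines with probability `p_complex`
(default 0.3); homodimers, intramolecular bindings and branched
conversions appear as reaction variants so the full taxonomy is
exercised. Rather than tuning category probabilities until all three
interaction categories are *probably* present, the generator
deterministically seeds one reaction, one contingency and one catalysis
whenever at least three interactions are requested — coverage holds with
probability 1 and the remaining draws stay free. Randomness comes from
R's default Mersenne-Twister stream via `set.seed()`, whose sequence is
fixed across platforms for a given R version; the caller's RNG state is
saved and restored.

What the generator emulates is the *syntactic* variety of MIM diagrams —
every glyph kind, every interaction category, metadata, decoration. What
it does not emulate is biology: labels are synthetic tokens, topology is
random rather than pathway-like, and coordinates are grid layout. Passing
round-trip and soundness tests on generator output therefore demonstrates
the format and engine are consistent, not that real curated maps are
handled gracefully in all their messiness; the worked examples
(`worked_example()`) cover the characteristic hand-drawn constructions
for that reason.

`mutate_to_violate()` inverts the generator's guarantee: one element is
edited or added so that exactly the requested rule family fires. A rule
can be infeasible on a given diagram (no homodimer to corrupt, no
disallowed host line for an explicit complex); that is an error by
contract, and measured precision is over feasible mutations.

## Numerical and degenerate-input choices

* Coordinates are real user units, origin top-left, y downward (the
  common vector-graphics convention; the notation is silent).
* Coordinate comparison tolerance in `semantic_equal()`: 1e-9, matching
  the writer's nine significant digits.
* Anchor and explicit-complex positions live in [0, 1] along the line.
* The empty diagram is valid, validates clean, and renders to a bare
  canvas; an interaction needs at least two points; geometry is required
  exactly for the kinds that are not line-attached dots.
* Modifier labels are capped at 16 characters (small-molecule tokens),
  feature labels must differ from their parent's, and symbol-only kinds
  (explicit complex, restricted copy, source/sink) are the only ones
  allowed empty labels.

## Problem sizes

The shipped test suite validates 1000 seeded diagrams for soundness,
round-trips 200, swap-tests 200 for symmetric-orientation invariance, and
measures mutation precision over 100 seeds times the twelve-rule
catalogue; the whole suite runs in well under a minute on one CPU. The
`scripts/acceptance.R` report recomputes the same quantities at the same
sizes from scratch.

## Limitations

Transport interactions are outside the formal notation (their semantics
are ambiguous without localization states) and are not modeled. Layout
rules are not validated — only syntax. The renderer draws stored points
verbatim, with placeholder geometries for the rarer line-end marks
(production, template, state-combination, catalysis) whose canonical
visual forms are fixed only in the full glyph reference. Shorthand
glyphs, polymerase/helicase/primase symbols, and combinatorial
interpretation semantics are out of scope.
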