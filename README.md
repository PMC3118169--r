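# mimml

Molecular Interaction Map (MIM) diagrams in R: a typed glyph/arc data
model, the MIMML XML exchange format with a lossless round-trip, and a
two-level Schematron-style validator with SVRL and JSON reports.

## The problem

MIM notation draws cellular signaling networks like circuit diagrams:
each molecular species is a glyph drawn once, and everything that happens
to it — binding, covalent modification, conversion, regulation — is a
typed line. The notation is closed (8 entity kinds, 12 interaction types
in 3 categories, a fixed arrowhead repertoire) and comes with syntax
rules saying what may connect to the start, the end, and the line itself
of each interaction type. That closedness is what makes diagrams
machine-checkable and exchangeable between tools — but only if there is a
concrete format, a data model, and a validator. This package provides all
three for R users: curators who want their maps checked, tool authors who
need to read and write pathway diagrams, and developers who need a
corpus of valid and precisely-invalid test diagrams.

The validator works at two levels. Level 1 checks the structural
grammar: identifier uniqueness, reference resolution, closed-vocabulary
tokens, attribute usage. Level 2 is a rule engine over the notation's
five syntax-rule families — label formats, arrowhead usage, placement of
on-line symbols (the explicit-complex dot and the intramolecular mark),
and connection rules driven by a per-type table
(`connection_rule_table()`). For example, an explicit complex may sit
only on covalent-modification, non-covalent-reversible-binding,
covalent-irreversible-binding and state-combination lines; a stimulation
must end on an anchor of another interaction, never directly on an
entity; a restricted copy may only bind its own parent. Findings are
reported exhaustively (never thrown), sorted deterministically, and
rendered as SVRL (`fired-rule` / `failed-assert` with XPath locations and
named diagnostics) or JSON.

## A worked example

The CaMK builder encodes the intramolecular regulation of
Ca2+/calmodulin-dependent protein kinase: the CaMK protein with its
kinase and regulation domains as entity features, calmodulin binding the
regulation domain, an intramolecular binding between the two domains, and
phosphorylation of substrates catalyzed by the kinase domain.

```r
library(mimml)
d <- worked_example("camk")
print(d)
#> MIM diagram: 640 x 420 user units
#>   entities:     7  (entity-feature: 2, explicit-complex: 1, modifier: 1, simple-physical-entity: 3)
#>   interactions: 4  (catalysis: 1, reaction: 3)
#>   metadata:     0 cross-references, 1 annotations
validate_all(d)
#> MIM validation report for 'example-camk'
#>   level 1 (structure):   0 finding(s)
#>   level 2 (syntax rules): 0 finding(s)
```

Seven entities: the three proteins (CaMK, calmodulin, Substrates), the
two CaMK domains, the phosphate modifier, and the explicit-complex dot on
the calmodulin binding. Re-attaching that dot to an illegal host line is
caught by the rule engine:

```r
bad <- mutate_to_violate(d, "ONLINE-EXPLICIT-COMPLEX", seed = 1)
validate_all(bad)
#> MIM validation report for 'example-camk'
#>   level 1 (structure):   0 finding(s)
#>   level 2 (syntax rules): 1 finding(s)
#>   [ONLINE-EXPLICIT-COMPLEX] cplxCaM: explicit complex may not sit on a catalysis line
```

`write_mimml()` / `read_mimml()` serialize to the MIMML dialect in a
byte-stable normal form, `render_svg()` draws the glyph vocabulary, and
`generate_valid_diagram(generator_config(seed = ...))` produces seeded
diagrams that always validate clean. A command-line wrapper lives at
`inst/exec/mimml` with `validate`, `roundtrip`, `generate`, `example` and
`make-fixtures` subcommands.

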