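Package: mimml
Title: Molecular Interaction Map Diagrams, the MIMML Exchange Format, and
    Rule-Based Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An implementation of the Molecular Interaction Map (MIM)
    notation for bioregulatory network diagrams. Provides an in-memory
    glyph/arc data model with authoring operations that enforce
    referential invariants, a reader and deterministic writer for the
    MIMML XML exchange dialect with a lossless semantic round-trip,
    a two-level validation engine (structural grammar checks plus a
    Schematron-style syntax-rule engine) that reports findings in an
    SVRL-subset XML and in JSON, seeded generation of valid diagrams and
    targeted invalid mutants for testing, builders for a set of worked
    example diagrams, a minimal SVG renderer for the MIM glyph
    vocabulary, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
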