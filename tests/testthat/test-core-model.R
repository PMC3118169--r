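test_that("diagram construction enforces positive dimensions", {
  d <- mim_diagram(800, 600)
  expect_s3_class(d, "mim_diagram")
  expect_length(d$entities, 0)
  expect_length(d$interactions, 0)
  expect_s3_class(mim_diagram(1, 1), "mim_diagram")
  expect_error(mim_diagram(0, 600), class = "mim_argument_error")
  expect_error(mim_diagram(800, -1), class = "mim_argument_error")
})

test_that("the glyph vocabularies are closed with the notation's counts", {
  expect_length(mim_entity_kinds(), 8)
  expect_length(mim_interaction_types(), 12)
  expect_length(mim_arrowhead_tokens(), 12)
  expect_setequal(mim_interaction_categories(),
                  c("reaction", "contingency", "catalysis"))
  expect_error(mim_interaction_category("teleportation"))
  expect_error(mim_arrowhead_signature("teleportation"))
  expect_error(add_entity(mim_diagram(), "flying-saucer"),
               class = "mim_model_error")
  expect_error(
    add_interaction(binding_pair(), "teleportation",
                    mim_points("cleavage", "A", "B")),
    class = "mim_model_error")
})

test_that("entity kind invariants are enforced at construction", {
  d <- mim_diagram(400, 300)
  d <- add_entity(d, "simple-physical-entity", "CaMK",
                  geometry = geo_at(100, 50))
  camk <- last_id(d)
  expect_length(d$entities, 1)
  d <- add_entity(d, "entity-feature", "kinase domain", parentRef = camk,
                  geometry = geo_at(100, 100))
  expect_equal(d$entities[[last_id(d)]]$parentRef, camk)

  # feature without parent, feature with non-SPE parent, dangling parent
  expect_error(add_entity(d, "entity-feature", "x", geometry = geo_at(1, 1)),
               class = "mim_model_error")
  expect_error(add_entity(d, "entity-feature", "x", parentRef = last_id(d),
                          geometry = geo_at(1, 1)),
               class = "mim_model_error")
  expect_error(add_entity(d, "restricted-copy", parentRef = "ghost"),
               class = "mim_reference_error")

  # implicit complex: non-empty members, no source-sink members
  d <- add_entity(d, "source-sink", geometry = geo_at(300, 50, 20, 20))
  sink <- last_id(d)
  expect_error(add_entity(d, "implicit-complex", "c"),
               class = "mim_model_error")
  expect_error(add_entity(d, "implicit-complex", "c", memberRefs = sink),
               class = "mim_model_error")
  d <- add_entity(d, "implicit-complex", "c", memberRefs = camk,
                  geometry = geo_at(200, 200, 100, 60))

  # explicit complex needs a hosting line
  expect_error(add_entity(d, "explicit-complex"),
               class = "mim_model_error")
  expect_error(add_entity(d, "explicit-complex", lineRef = camk,
                          linePosition = 0.5),
               class = "mim_model_error")

  # duplicate identifiers are conflicts
  expect_error(add_entity(d, "simple-physical-entity", "again", id = camk,
                          geometry = geo_at(9, 9)),
               class = "mim_conflict_error")
})

test_that("interactions require two referenced termini", {
  d <- binding_pair()
  expect_length(d$interactions, 1)
  expect_error(
    add_interaction(d, "non-covalent-reversible-binding",
                    list(mim_point(0, 0, "barbed", "A"))),
    class = "mim_model_error")
  expect_error(
    add_interaction(d, "non-covalent-reversible-binding",
                    mim_points("non-covalent-reversible-binding",
                               "A", "nope")),
    class = "mim_reference_error")
})

test_that("resolve finds entities, interactions, anchors and metadata", {
  d <- binding_pair()
  d <- add_anchor(d, "bindAB", 0.4, id = "bindAB.site")
  d <- add_cross_reference(d, "UniProt", "P12345", id = "x1")
  expect_equal(resolve(d, "A")$kind, "simple-physical-entity")
  expect_equal(resolve(d, "bindAB")$type, "non-covalent-reversible-binding")
  hit <- resolve(d, "bindAB.site")
  expect_equal(hit$anchor$position, 0.4)
  expect_equal(hit$interaction$id, "bindAB")
  expect_equal(resolve(d, "x1")$db, "UniProt")
  expect_error(resolve(d, "nope"), class = "mim_lookup_error")
})

test_that("termini canonicalizes symmetric types and orients directed ones", {
  # stored B -> A, symmetric: canonical order is lexicographic
  d <- mim_diagram(300, 100)
  d <- add_entity(d, "simple-physical-entity", "B", id = "B",
                  geometry = geo_at(10, 10))
  d <- add_entity(d, "simple-physical-entity", "A", id = "A",
                  geometry = geo_at(200, 10))
  d <- add_interaction(d, "non-covalent-reversible-binding",
                       mim_points("non-covalent-reversible-binding",
                                  "B", "A"), id = "i")
  tm <- termini(d$interactions[["i"]])
  expect_equal(tm$startRef, "A")
  expect_equal(tm$endRef, "B")
  expect_true(tm$canonical)

  # covalent modification: modifier on the arrowhead-free end
  d2 <- diagram_with_type("covalent-modification")
  tm2 <- termini(d2$interactions[["target"]])
  expect_equal(tm2$startRef, "P")
  expect_equal(tm2$endRef, "A")

  # directed stored reversed: arrowheads decide the start
  d3 <- mim_diagram(300, 100)
  d3 <- add_entity(d3, "simple-physical-entity", "A", id = "A",
                   geometry = geo_at(10, 10))
  d3 <- add_entity(d3, "simple-physical-entity", "B", id = "B",
                   geometry = geo_at(200, 10))
  d3 <- add_interaction(
    d3, "stoichiometric-conversion",
    list(mim_point(0, 0, "filled-triangle", "B"),
         mim_point(10, 0, "none", "A")), id = "i")
  tm3 <- termini(d3$interactions[["i"]])
  expect_equal(tm3$startRef, "A")
  expect_equal(tm3$endRef, "B")
})

test_that("termini is idempotent", {
  for (type in c("non-covalent-reversible-binding",
                 "stoichiometric-conversion", "covalent-modification")) {
    d <- diagram_with_type(type)
    i <- d$interactions[["target"]]
    expect_identical(termini(i), termini(i))
  }
})

test_that("effective_targets lists trunk end plus branch ends in order", {
  d <- worked_example("conversion-branch")
  expect_equal(effective_targets(d$interactions[["convABC"]]), c("B", "C"))
  b <- binding_pair()
  expect_equal(effective_targets(b$interactions[["bindAB"]]), "B")
})

test_that("random add sequences keep identifiers unique and references closed", {
  set.seed(42)
  for (trial in 1:10) {
    d <- mim_diagram(600, 600)
    for (k in 1:20) {
      op <- sample(c("spe", "feature", "bind"), 1)
      spes <- names(d$entities)[vapply(d$entities, function(e)
        e$kind == "simple-physical-entity", TRUE)]
      if (op == "spe" || !length(spes)) {
        d <- add_entity(d, "simple-physical-entity", paste0("S", k),
                        geometry = geo_at(k * 10, 50))
      } else if (op == "feature") {
        d <- add_entity(d, "entity-feature", paste0("F", k),
                        parentRef = sample(spes, 1),
                        geometry = geo_at(k * 10, 100))
      } else if (length(spes) >= 2) {
        ab <- sample(spes, 2)
        d <- add_interaction(d, "non-covalent-reversible-binding",
                             mim_points("non-covalent-reversible-binding",
                                        ab[1], ab[2]))
      }
    }
    ids <- c(names(d$entities), names(d$interactions))
    expect_false(any(duplicated(ids)))
    # referential closure: every held reference resolves
    for (e in d$entities)
      for (ref in c(e$parentRef, e$memberRefs, e$lineRef, e$metadataRefs))
        expect_no_error(resolve(d, ref))
    for (i in d$interactions) {
      expect_no_error(resolve(d, i$points[[1]]$visRef))
      expect_no_error(resolve(d, i$points[[length(i$points)]]$visRef))
    }
  }
})
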