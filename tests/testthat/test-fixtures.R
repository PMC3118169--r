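test_that("generator configuration rejects impossible requests", {
  expect_error(generator_config(p_complex = 1.2),
               class = "mim_argument_error")
  expect_error(generator_config(n_entities = 0),
               class = "mim_argument_error")
  expect_error(
    generate_valid_diagram(generator_config(seed = 1, n_entities = 1,
                                            n_interactions = 3)),
    class = "mim_argument_error")
})

test_that("generation is deterministic in the seed", {
  cfg <- generator_config(seed = 7, n_entities = 12, n_interactions = 15)
  a <- generate_valid_diagram(cfg)
  b <- generate_valid_diagram(cfg)
  expect_true(semantic_equal(a, b))
  expect_identical(write_mimml(a), write_mimml(b))
  c_ <- generate_valid_diagram(generator_config(seed = 8, n_entities = 12,
                                                n_interactions = 15))
  expect_false(identical(write_mimml(a), write_mimml(c_)))
})

test_that("entity-only generation yields the requested count, clean", {
  d <- generate_valid_diagram(generator_config(seed = 1, n_entities = 5,
                                               n_interactions = 0))
  expect_length(d$entities, 5)
  expect_length(d$interactions, 0)
  expect_equal(n_findings(validate_all(d)), 0)
})

test_that("rich configurations cover all three interaction categories", {
  for (s in 1:25) {
    d <- generate_valid_diagram(generator_config(
      seed = s, n_entities = 12, n_interactions = 10))
    cats <- unique(mim_interaction_category(
      vapply(d$interactions, `[[`, "", "type")))
    expect_setequal(cats, c("reaction", "contingency", "catalysis"))
  }
})

test_that("generator output validates clean across seeds", {
  for (s in 1:100) {
    d <- generate_valid_diagram(generator_config(
      seed = s, n_entities = 12, n_interactions = 10))
    expect_equal(n_findings(validate_all(d)), 0, info = paste("seed", s))
  }
})

test_that("mutations are minimal, targeted, and error when infeasible", {
  d <- generate_valid_diagram(generator_config(seed = 3, n_entities = 12,
                                               n_interactions = 10))
  for (rule in mutation_catalogue()) {
    m <- tryCatch(mutate_to_violate(d, rule, seed = 5),
                  mim_infeasible_error = function(e) NULL)
    if (is.null(m)) next
    expect_true(rule %in% rules_in(validate_all(m)), info = rule)
  }
  expect_error(mutate_to_violate(mim_diagram(5, 5), "CONNECT-END", 0),
               class = "mim_infeasible_error")
  expect_error(mutate_to_violate(d, "NOT-A-RULE", 0),
               class = "mim_argument_error")
})

test_that("worked examples validate clean and read back from their goldens", {
  for (nm in worked_example_names()) {
    d <- worked_example(nm)
    expect_equal(n_findings(validate_all(d)), 0, info = nm)
  }
  expect_error(worked_example("nope"), class = "mim_lookup_error")
})

test_that("the trimer encodes binding order through its explicit complexes", {
  d <- worked_example("trimer")
  bindings <- Filter(function(i)
    i$type == "non-covalent-reversible-binding", d$interactions)
  expect_length(bindings, 2)
  complexes <- Filter(function(e) e$kind == "explicit-complex", d$entities)
  expect_length(complexes, 2)
  # the trimer-forming binding attaches to the dimer's complex node, not to
  # A or B directly, so C must dissociate before A and B can
  second <- d$interactions[["bindABC"]]
  refs <- c(second$points[[1]]$visRef,
            second$points[[length(second$points)]]$visRef)
  expect_true("cplxAB" %in% refs)
  expect_equal(d$entities[["cplxAB"]]$lineRef, "bindAB")
})

test_that("the phosphorylation example carries its complex on the line", {
  d <- worked_example("phospho")
  mod <- d$interactions[["phosA"]]
  expect_equal(mod$type, "covalent-modification")
  expect_equal(termini(mod)$startRef, "P")
  expect_equal(d$entities[["P"]]$kind, "modifier")
  expect_equal(d$entities[["phosA_cplx"]]$lineRef, "phosA")
})

test_that("the branched conversion produces two targets", {
  d <- worked_example("conversion-branch")
  expect_length(d$interactions, 1)
  expect_equal(effective_targets(d$interactions[["convABC"]]), c("B", "C"))
})

test_that("the cleavage example carries title, identifier and a citation", {
  d <- worked_example("cleavage")
  expect_equal(d$entities[["CaMK"]]$kind, "simple-physical-entity")
  expect_equal(d$entities[["P"]]$kind, "modifier")
  expect_equal(d$interactions[["cleavP"]]$type, "cleavage")
  expect_true(all(c("title", "identifier") %in%
                    names(d$metadata$diagramTerms)))
  expect_length(d$metadata$crossReferences, 1)
})

test_that("the CaMK example matches its published structure", {
  d <- worked_example("camk")
  features <- Filter(function(e)
    e$kind == "entity-feature" && identical(e$parentRef, "CaMK"), d$entities)
  expect_length(features, 2)
  expect_setequal(vapply(features, `[[`, "", "label"),
                  c("kinase domain", "regulation domain"))
  expect_true("Substrates" %in% vapply(d$entities, `[[`, "", "label"))
  expect_true(any(vapply(d$interactions, `[[`, TRUE, "intramolecular")))
  mods <- Filter(function(i) i$type == "covalent-modification",
                 d$interactions)
  expect_true(any(vapply(mods, function(i)
    termini(i)$endRef == "Substrates", TRUE)))
})
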