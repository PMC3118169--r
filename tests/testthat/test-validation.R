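test_that("structural validation reports token, id and reference problems", {
  # writer output of a generator diagram is structurally clean
  d <- generate_valid_diagram(generator_config(seed = 5))
  expect_length(validate_structure(write_mimml(d)), 0)

  # a wild arrowhead token
  bad <- mutate_to_violate(d, "STRUCT-ENUM-TOKEN", seed = 1)
  expect_true("STRUCT-ENUM-TOKEN" %in%
                vapply(validate_structure(bad), `[[`, "", "rule"))

  # duplicate identifiers
  dup <- mutate_to_violate(d, "STRUCT-ID-UNIQUE", seed = 1)
  fs <- validate_structure(dup)
  hit <- fs[vapply(fs, function(f) f$rule == "STRUCT-ID-UNIQUE", TRUE)]
  expect_length(hit, 1)
  expect_match(hit[[1]]$message, "2 elements")

  # dangling reference
  dang <- mutate_to_violate(d, "STRUCT-REF-RESOLVES", seed = 1)
  expect_true("STRUCT-REF-RESOLVES" %in%
                vapply(validate_structure(dang), `[[`, "", "rule"))
})

test_that("level 2 is suppressed while references are broken", {
  d <- generate_valid_diagram(generator_config(seed = 5))
  rep_clean <- validate_all(d)
  expect_length(rep_clean$level1, 0)
  expect_length(rep_clean$level2, 0)
  expect_setequal(rep_clean$checkedRules, mim_rule_ids())

  rep_bad <- validate_all(mutate_to_violate(d, "STRUCT-REF-RESOLVES", 1))
  expect_gt(length(rep_bad$level1), 0)
  expect_length(rep_bad$level2, 0)
})

test_that("the connection rule table is total over the interaction types", {
  table <- connection_rule_table()
  expect_setequal(names(table), mim_interaction_types())
  for (row in table)
    expect_named(row, c("allowedStart", "allowedEnd", "anchorEnd",
                        "targetCategory", "onLine", "branchable",
                        "symmetric"))
})

test_that("legal wirings of every interaction type validate clean", {
  for (type in mim_interaction_types()) {
    rep_ <- validate_all(diagram_with_type(type))
    expect_equal(n_findings(rep_), 0, info = type)
  }
})

test_that("connection violations are localized to the offending terminus", {
  # covalent modification with modifier start and SPE end is legal
  d <- diagram_with_type("covalent-modification")
  expect_length(check_connection_rules(d), 0)

  # swapping in an SPE start violates CONNECT-START
  d2 <- d
  d2$interactions[["target"]]$points[[1]]$visRef <- "B"
  expect_rules(check_connection_rules(d2), "CONNECT-START")

  # a stimulation ending on an anchor is legal; directly on an SPE is not
  d3 <- diagram_with_type("stimulation")
  expect_length(check_connection_rules(d3), 0)
  d4 <- d3
  d4$interactions[["target"]]$points[[2]]$visRef <- "B"
  expect_rules(check_connection_rules(d4), "CONNECT-END")

  # catalysis may only accelerate reactions
  d5 <- diagram_with_type("stimulation")
  d5 <- add_anchor(d5, "target", 0.5, id = "target.a")
  d5 <- add_interaction(d5, "catalysis",
                        mim_points("catalysis", "B", "target.a"),
                        id = "cat")
  expect_rules(check_connection_rules(d5), "CONNECT-TARGET-CATEGORY")
})

test_that("entity termini outside a row fire under both orientations only", {
  # brute-force: a binding terminus drawn from every entity kind
  d0 <- binding_pair()
  d0 <- add_entity(d0, "modifier", "P", id = "P",
                   geometry = geo_at(10, 150, 24, 16))
  d0 <- add_entity(d0, "source-sink", id = "sink",
                   geometry = geo_at(60, 150, 20, 20))
  d0 <- add_entity(d0, "conceptual-entity", "idea", id = "idea",
                   geometry = geo_at(120, 150))
  allowed <- connection_rule_table()[["non-covalent-reversible-binding"]]
  for (end in c("P", "sink", "idea")) {
    kind <- d0$entities[[end]]$kind
    for (slot in 1:2) {
      d <- d0
      d$interactions[["bindAB"]]$points[[slot]]$visRef <- end
      fs <- check_connection_rules(d)
      if (kind %in% allowed$allowedStart) {
        expect_length(fs, 0)
      } else {
        expect_gt(length(fs), 0)
        expect_true(all(vapply(fs, `[[`, "", "rule") %in%
                          c("CONNECT-START", "CONNECT-END")))
      }
    }
  }
})

test_that("arrowhead signatures are enforced with Schematron-style diagnostics", {
  d <- binding_pair()
  expect_length(check_arrowhead_usage(d), 0)
  expect_length(check_arrowhead_usage(mim_diagram(5, 5)), 0)

  d$interactions[["bindAB"]]$points[[2]]$arrowhead <- "filled-triangle"
  fs <- check_arrowhead_usage(d)
  expect_length(fs, 1)
  expect_equal(fs[[1]]$diagnostics[["inter-start-arrowhead"]], "barbed")
  expect_equal(fs[[1]]$diagnostics[["inter-end-arrowhead"]],
               "filled-triangle")

  # a directed line stored in reverse orientation is still legal
  d2 <- mim_diagram(300, 100)
  d2 <- add_entity(d2, "simple-physical-entity", "A", id = "A",
                   geometry = geo_at(10, 10))
  d2 <- add_entity(d2, "simple-physical-entity", "B", id = "B",
                   geometry = geo_at(200, 10))
  d2 <- add_interaction(d2, "stoichiometric-conversion",
                        list(mim_point(0, 0, "filled-triangle", "B"),
                             mim_point(9, 0, "none", "A")), id = "i")
  expect_length(check_arrowhead_usage(d2), 0)
})

test_that("explicit complexes are allowed on exactly the four host types", {
  hosts <- mim_explicit_complex_hosts()
  expect_setequal(hosts, c("covalent-modification",
                           "non-covalent-reversible-binding",
                           "covalent-irreversible-binding",
                           "state-combination"))
  violating <- character()
  for (type in mim_interaction_types()) {
    d <- diagram_with_type(type)
    d <- add_entity(d, "explicit-complex", id = "cplx", lineRef = "target",
                    linePosition = 0.5)
    fs <- check_online_symbols(d)
    fs <- fs[vapply(fs, function(f)
      f$rule == "ONLINE-EXPLICIT-COMPLEX", TRUE)]
    if (length(fs)) {
      violating <- c(violating, type)
      expect_setequal(names(fs[[1]]$diagnostics),
                      c("vis-id", "inter-vis-id", "inter-start-arrowhead",
                        "inter-end-arrowhead"))
      expect_equal(fs[[1]]$diagnostics[["vis-id"]], "cplx")
      expect_equal(fs[[1]]$diagnostics[["inter-vis-id"]], "target")
    }
  }
  expect_length(violating, 8)
  expect_setequal(violating, setdiff(mim_interaction_types(), hosts))
})

test_that("the intramolecular mark needs a single-molecule reaction", {
  d <- worked_example("camk")
  expect_length(check_online_symbols(d), 0)

  # marking the calmodulin binding (two molecules) is a violation
  d2 <- d
  d2$interactions[["bindCaM"]]$intramolecular <- TRUE
  expect_rules(check_online_symbols(d2), "ONLINE-INTRAMOLECULAR")

  # marking a catalysis (not a reaction) is a violation
  d3 <- d
  d3$interactions[["catKin"]]$intramolecular <- TRUE
  expect_rules(check_online_symbols(d3), "ONLINE-INTRAMOLECULAR")
})

test_that("label rules cover empties, length and parent collisions", {
  d <- worked_example("camk")
  expect_length(check_labels(d), 0)

  d2 <- d
  d2$entities[["CaM"]]$label <- ""
  expect_rules(check_labels(d2), "LABEL-FORMAT")

  d3 <- d
  d3$entities[["P"]]$label <- strrep("x", 17)
  expect_rules(check_labels(d3), "LABEL-FORMAT")

  d4 <- d
  d4$entities[["CaMK_kin"]]$label <- "CaMK"
  expect_rules(check_labels(d4), "LABEL-FORMAT")
})

test_that("restricted copies may only bind their parent", {
  d <- binding_pair()
  d <- add_entity(d, "restricted-copy", id = "Acopy", parentRef = "A")
  d <- add_interaction(d, "non-covalent-reversible-binding",
                       mim_points("non-covalent-reversible-binding",
                                  "A", "Acopy"), id = "homo")
  expect_length(check_restricted_copies(d), 0)

  # bound to a different SPE
  d2 <- d
  d2$interactions[["homo"]]$points[[1]]$visRef <- "B"
  expect_rules(check_restricted_copies(d2), "RESTRICTED-COPY-USE")

  # used as the reactant of a conversion
  d3 <- d
  d3 <- add_interaction(d3, "stoichiometric-conversion",
                        mim_points("stoichiometric-conversion",
                                   "Acopy", "B"), id = "conv")
  expect_rules(check_restricted_copies(d3), "RESTRICTED-COPY-USE")
})

test_that("only producing reactions may branch", {
  d <- worked_example("conversion-branch")
  expect_length(check_branch_use(d), 0)
  bad <- mutate_to_violate(binding_pair(), "BRANCH-USE", 1)
  expect_rules(check_branch_use(bad), "BRANCH-USE")
})

test_that("findings are sorted and invariant to storage order", {
  d <- generate_valid_diagram(generator_config(seed = 23,
                                               n_entities = 12,
                                               n_interactions = 10))
  d <- mutate_to_violate(d, "ARROWHEAD-USE", 1)
  d <- mutate_to_violate(d, "LABEL-FORMAT", 2)
  r1 <- validate_all(d)
  d2 <- d
  d2$entities <- rev(d2$entities)
  d2$interactions <- rev(d2$interactions)
  r2 <- validate_all(d2)
  expect_identical(r1$level2, r2$level2)
  keys <- vapply(r1$level2, function(f) paste(f$contextId, f$rule), "")
  expect_identical(keys, sort(keys, method = "radix"))
})

test_that("validation is invariant under color changes", {
  d <- generate_valid_diagram(generator_config(seed = 9))
  d2 <- d
  for (id in names(d2$entities)) d2$entities[[id]]$color <- "#ff00ff"
  expect_identical(validate_all(d)[c("level1", "level2")],
                   validate_all(d2)[c("level1", "level2")])
  bad <- mutate_to_violate(d, "ARROWHEAD-USE", 4)
  bad2 <- bad
  for (id in names(bad2$entities)) bad2$entities[[id]]$color <- "#00ff00"
  expect_identical(validate_all(bad)[c("level1", "level2")],
                   validate_all(bad2)[c("level1", "level2")])
})

test_that("symmetric interactions validate identically under terminus swap", {
  for (s in 1:30) {
    d <- generate_valid_diagram(generator_config(
      seed = s, n_entities = 10, n_interactions = 8))
    d2 <- d
    swapped <- FALSE
    for (id in names(d2$interactions)) {
      i <- d2$interactions[[id]]
      if (i$type %in% mim_symmetric_types()) {
        n <- length(i$points)
        r1 <- i$points[[1]]$visRef; r2 <- i$points[[n]]$visRef
        i$points[[1]]$visRef <- r2; i$points[[n]]$visRef <- r1
        d2$interactions[[id]] <- i
        swapped <- TRUE
      }
    }
    if (!swapped) next
    expect_identical(validate_all(d)[c("level1", "level2")],
                     validate_all(d2)[c("level1", "level2")])
  }
})

test_that("SVRL output is schema-valid, located, and invertible", {
  d <- worked_example("trimer")
  clean <- validate_all(d)
  svrl_clean <- report_to_svrl(clean)
  xsd <- xml2::read_xml(system.file("extdata", "svrl-subset.xsd",
                                    package = "mimml"))
  expect_true(xml2::xml_validate(xml2::read_xml(svrl_clean), xsd))
  expect_false(grepl("failed-assert", svrl_clean))
  expect_equal(sum(gregexpr("fired-rule", svrl_clean)[[1]] > 0),
               length(mim_rule_ids()))

  bad <- mutate_to_violate(worked_example("camk"),
                           "ONLINE-EXPLICIT-COMPLEX", 1)
  report <- validate_all(bad)
  svrl <- report_to_svrl(report)
  expect_true(xml2::xml_validate(xml2::read_xml(svrl), xsd))
  back <- svrl_to_findings(svrl)
  expect_identical(back$level2, report$level2)
  expect_identical(back$level1, report$level1)

  # every failed-assert location resolves to exactly one element of the
  # serialized document
  doc <- xml2::read_xml(write_mimml(bad))
  for (f in c(report$level1, report$level2))
    expect_length(xml2::xml_find_all(doc, f$locationPath), 1)
})

test_that("JSON reports round-trip losslessly with stable keys", {
  d <- mutate_to_violate(worked_example("camk"), "ARROWHEAD-USE", 2)
  report <- validate_all(d)
  js <- report_to_json(report)
  expect_match(js, '"diagramId"')
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_named(parsed, c("diagramId", "checkedRules", "level1", "level2"))
  back <- json_to_report(js)
  expect_identical(back$level2, report$level2)
  expect_identical(back$diagramId, report$diagramId)
  clean <- validate_all(worked_example("phospho"))
  expect_identical(json_to_report(report_to_json(clean))$level1, list())
})

test_that("an empty diagram yields a clean report listing all rules", {
  rep_ <- validate_all(mim_diagram(5, 5))
  expect_equal(n_findings(rep_), 0)
  expect_setequal(rep_$checkedRules, mim_rule_ids())
})
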