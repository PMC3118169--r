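# tiny hand-built diagrams used across the suite

geo_at <- function(x, y, w = 60, h = 24)
  list(centerX = x, centerY = y, width = w, height = h)

# two SPEs A and B joined by a non-covalent reversible binding
binding_pair <- function(type = "non-covalent-reversible-binding") {
  d <- mim_diagram(400, 200)
  d <- add_entity(d, "simple-physical-entity", "A", id = "A",
                  geometry = geo_at(60, 60))
  d <- add_entity(d, "simple-physical-entity", "B", id = "B",
                  geometry = geo_at(300, 60))
  add_interaction(d, type, mim_points(type, "A", "B", 90, 60, 270, 60),
                  id = "bindAB")
}

# one interaction of the given type wired legally against the rule table,
# used for exhaustive per-type enumeration
diagram_with_type <- function(type) {
  d <- mim_diagram(500, 300)
  d <- add_entity(d, "simple-physical-entity", "A", id = "A",
                  geometry = geo_at(60, 60))
  d <- add_entity(d, "simple-physical-entity", "B", id = "B",
                  geometry = geo_at(300, 60))
  d <- add_entity(d, "modifier", "P", id = "P", geometry = geo_at(60, 160, 24, 16))
  if (type %in% c("stimulation", "necessary-stimulation", "inhibition",
                  "catalysis")) {
    # contingencies and catalysis need a target reaction anchor
    d <- add_interaction(d, "stoichiometric-conversion",
                         mim_points("stoichiometric-conversion", "A", "B",
                                    90, 60, 270, 60), id = "conv")
    d <- add_anchor(d, "conv", 0.5, id = "conv.a")
    d <- add_interaction(d, type, mim_points(type, "P", "conv.a",
                                             60, 150, 180, 70),
                         id = "target")
  } else if (type == "covalent-modification") {
    d <- add_interaction(d, type, mim_points(type, "P", "A", 60, 150, 60, 75),
                         id = "target")
  } else {
    d <- add_interaction(d, type, mim_points(type, "A", "B", 90, 60, 270, 60),
                         id = "target")
  }
  d
}

expect_rules <- function(findings, rules) {
  expect_setequal(unique(vapply(findings, `[[`, "", "rule")), rules)
}

rules_in <- function(report)
  vapply(c(report$level1, report$level2), `[[`, "", "rule")
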