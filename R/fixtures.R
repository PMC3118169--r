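# Seeded diagram generation, targeted invalid mutants, and worked-example
# builders. The generator samples interactions only from rows of the
# connection rule table, so its output is valid by construction; the
# mutation operator is the test surface for the rule engine: each mutation
# edits or adds a single element so that exactly the requested rule family
# is provoked.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration for the diagram generator
#'
#' @param seed integer seed for the pseudorandom stream (R's default
#'   Mersenne-Twister generator).
#' @param n_entities positive number of entity glyphs to create.
#' @param n_interactions non-negative number of interaction glyphs.
#' @param p_complex probability of decorating an eligible interaction with
#'   an explicit complex.
#' @param p_contingency probability that a sampled interaction is a
#'   contingency or catalysis rather than a reaction.
#' @param p_metadata probability of attaching an annotation to a glyph.
#' @return A \code{mim_generator_config} list.
#' @export
generator_config <- function(seed = 1L, n_entities = 10L,
                             n_interactions = 8L, p_complex = 0.3,
                             p_contingency = 0.3, p_metadata = 0.2) {
  probs <- c(p_complex, p_contingency, p_metadata)
  if (any(probs < 0 | probs > 1))
    stop_mim("mim_argument_error", "probabilities must lie in [0,1]")
  if (n_entities < 1)
    stop_mim("mim_argument_error", "n_entities must be positive")
  if (n_interactions < 0)
    stop_mim("mim_argument_error", "n_interactions must be non-negative")
  structure(list(seed = as.integer(seed), n_entities = as.integer(n_entities),
                 n_interactions = as.integer(n_interactions),
                 p_complex = p_complex, p_contingency = p_contingency,
                 p_metadata = p_metadata), class = "mim_generator_config")
}

grid_geo <- function(k, w = 80, h = 30) {
  list(centerX = 60 + ((k - 1) %% 8) * 110,
       centerY = 40 + ((k - 1) %/% 8) * 70,
       width = w, height = h)
}

entity_ids_of_kind <- function(d, kinds) {
  ids <- names(d$entities)
  ids[vapply(d$entities, function(e) e$kind %in% kinds, TRUE)]
}

# coordinates for a terminus referent: entity center when it has geometry,
# otherwise a deterministic fallback
ref_xy <- function(d, id, fallback) {
  e <- d$entities[[id]]
  if (!is.null(e) && !is.null(e$geometry))
    return(c(e$geometry$centerX, e$geometry$centerY))
  fallback
}

#' Generate a valid diagram
#'
#' Builds entities first (simple physical entities dominating, with
#' entity features, modifiers, conceptual entities, source/sinks and
#' implicit complexes mixed in), then samples interactions only from rows
#' of the connection rule table so that the result always validates
#' clean. Binding-family interactions are decorated with explicit
#' complexes with probability \code{p_complex}; homodimers (restricted
#' copies), intramolecular bindings, branched conversions, contingencies
#' and catalysis all occur so the full glyph taxonomy is exercised. When
#' \code{n_interactions >= 3} at least one reaction, one contingency and
#' one catalysis are always present.
#'
#' @param config a \code{generator_config()}.
#' @return A \code{mim_diagram} with zero validation findings.
#' @examples
#' d <- generate_valid_diagram(generator_config(seed = 7))
#' n_findings(validate_all(d))
#' @export
generate_valid_diagram <- function(config = generator_config()) {
  stopifnot(inherits(config, "mim_generator_config"))
  if (config$n_interactions > 0 && config$n_entities < 2)
    stop_mim("mim_argument_error",
             "interactions require at least 2 entities")
  with_seed(config$seed, {
    d <- mim_diagram(1000, 80 + ceiling(config$n_entities / 8) * 140)
    d <- set_diagram_terms(
      d, title = sprintf("generated diagram (seed %d)", config$seed),
      creator = "mimml generator",
      identifier = sprintf("gen-%d", config$seed))

    modifier_labels <- c("P", "Me", "Ub", "Ac", "SUMO")
    for (k in seq_len(config$n_entities)) {
      spe_ids <- entity_ids_of_kind(d, "simple-physical-entity")
      kind <- if (k <= min(2L, config$n_entities) &&
                  config$n_interactions > 0) {
        "simple-physical-entity"   # guarantee feasible reactions
      } else {
        sample(c("simple-physical-entity", "entity-feature", "modifier",
                 "conceptual-entity", "source-sink", "implicit-complex"),
               1, prob = c(0.5, 0.15, 0.1, 0.1, 0.05, 0.1))
      }
      if (kind == "entity-feature" && !length(spe_ids))
        kind <- "simple-physical-entity"
      member_pool <- entity_ids_of_kind(
        d, c("simple-physical-entity", "conceptual-entity", "modifier"))
      if (kind == "implicit-complex" && length(member_pool) < 1)
        kind <- "simple-physical-entity"
      d <- switch(kind,
        "entity-feature" = add_entity(
          d, kind, label = sprintf("E%d domain", k),
          parentRef = sample(spe_ids, 1), geometry = grid_geo(k, 70, 20)),
        "modifier" = add_entity(
          d, kind, label = sample(modifier_labels, 1),
          geometry = grid_geo(k, 24, 16)),
        "implicit-complex" = add_entity(
          d, kind, label = sprintf("E%d complex", k),
          memberRefs = sample(member_pool, min(length(member_pool),
                                               sample(1:3, 1))),
          geometry = grid_geo(k, 100, 50)),
        "source-sink" = add_entity(d, kind, label = "",
                                   geometry = grid_geo(k, 20, 20)),
        add_entity(d, kind, label = sprintf("E%d", k),
                   bioType = if (stats::runif(1) < 0.5)
                     sample(mim_bio_types(), 1) else NULL,
                   geometry = grid_geo(k)))
    }

    reactions <- character(); contingencies <- character()
    nxy <- 0
    line_xy <- function() {
      nxy <<- nxy + 1
      c(5 * nxy, 900 + 3 * nxy)
    }
    add_line <- function(d, type, from, to, intramolecular = FALSE,
                         branch_to = NULL) {
      sig <- mim_arrowhead_signature(type)
      fb <- line_xy()
      p0 <- ref_xy(d, from, fb); p1 <- ref_xy(d, to, fb + c(40, 0))
      pts <- list(mim_point(p0[1], p0[2], sig[1], from),
                  mim_point(p1[1], p1[2], sig[2], to))
      branches <- list()
      if (!is.null(branch_to)) {
        bxy <- ref_xy(d, branch_to, fb + c(40, 40))
        branches <- list(list(position = 0.5, points = list(
          mim_point(bxy[1], bxy[2], sig[2], branch_to))))
      }
      add_interaction(d, type, pts, branches = branches,
                      intramolecular = intramolecular)
    }

    decorate_complex <- function(d, line_id) {
      if (stats::runif(1) >= config$p_complex) return(d)
      add_entity(d, "explicit-complex", lineRef = line_id,
                 linePosition = round(stats::runif(1, 0.3, 0.7), 3))
    }

    make_reaction <- function(d) {
      spes <- entity_ids_of_kind(d, "simple-physical-entity")
      binding_pool <- entity_ids_of_kind(
        d, c("simple-physical-entity", "entity-feature", "conceptual-entity",
             "explicit-complex", "implicit-complex"))
      conv_pool <- entity_ids_of_kind(
        d, c("simple-physical-entity", "entity-feature", "conceptual-entity",
             "explicit-complex", "implicit-complex", "source-sink"))
      state_pool <- entity_ids_of_kind(
        d, c("simple-physical-entity", "entity-feature", "explicit-complex"))
      modifiers <- entity_ids_of_kind(d, "modifier")
      mod_targets <- entity_ids_of_kind(
        d, c("simple-physical-entity", "entity-feature", "explicit-complex"))
      # entity features grouped by parent, for intramolecular bindings
      feat_pairs <- list()
      feats <- entity_ids_of_kind(d, "entity-feature")
      if (length(feats) >= 2) {
        parents <- vapply(feats, function(f) d$entities[[f]]$parentRef, "")
        for (p in unique(parents))
          if (sum(parents == p) >= 2)
            feat_pairs[[p]] <- feats[parents == p]
      }
      feasible <- c(
        if (length(binding_pool) >= 2) c("binding", "binding"),
        if (length(spes) >= 1) "homodimer",
        if (length(feat_pairs)) "intramolecular",
        if (length(modifiers) && length(mod_targets)) "covalent-modification",
        if (length(conv_pool) >= 2) c("conversion", "conversion"),
        if (length(state_pool) >= 2) "state-combination")
      variant <- sample(feasible, 1)
      if (variant == "binding") {
        type <- sample(c("non-covalent-reversible-binding",
                         "covalent-irreversible-binding"), 1,
                       prob = c(0.8, 0.2))
        ends <- sample(binding_pool, 2)
        d <- add_line(d, type, ends[1], ends[2])
        d <- decorate_complex(d, last_id2 <- attr(d, "last_id"))
      } else if (variant == "homodimer") {
        parent <- sample(spes, 1)
        d <- add_entity(d, "restricted-copy", parentRef = parent)
        copy <- last_id(d)
        d <- add_line(d, "non-covalent-reversible-binding", parent, copy)
        d <- decorate_complex(d, attr(d, "last_id"))
      } else if (variant == "intramolecular") {
        fp <- feat_pairs[[sample(length(feat_pairs), 1)]]
        ends <- sample(fp, 2)
        d <- add_line(d, "non-covalent-reversible-binding",
                      ends[1], ends[2], intramolecular = TRUE)
      } else if (variant == "covalent-modification") {
        d <- add_line(d, "covalent-modification",
                      sample(modifiers, 1), sample(mod_targets, 1))
        d <- decorate_complex(d, attr(d, "last_id"))
      } else if (variant == "conversion") {
        type <- sample(mim_branchable_types(), 1)
        ends <- sample(conv_pool, 2)
        branch_to <- NULL
        extra <- setdiff(conv_pool, ends)
        if (length(extra) && stats::runif(1) < 0.3)
          branch_to <- sample(extra, 1)
        d <- add_line(d, type, ends[1], ends[2], branch_to = branch_to)
      } else {
        ends <- sample(state_pool, 2)
        d <- add_line(d, "state-combination", ends[1], ends[2])
        d <- decorate_complex(d, attr(d, "last_id"))
      }
      d
    }

    controller_pool <- function(d) entity_ids_of_kind(
      d, setdiff(mim_entity_kinds(), c("source-sink", "restricted-copy")))

    make_contingency <- function(d) {
      targets <- c(reactions, contingencies)
      type <- sample(c("stimulation", "necessary-stimulation",
                       "inhibition"), 1)
      target <- sample(targets, 1)
      d <- add_anchor(d, target, position = round(stats::runif(1, 0.2, 0.8), 3))
      anchor <- last_id(d)
      d <- add_line(d, type, sample(controller_pool(d), 1), anchor)
      d
    }

    make_catalysis <- function(d) {
      target <- sample(reactions, 1)
      d <- add_anchor(d, target, position = round(stats::runif(1, 0.2, 0.8), 3))
      anchor <- last_id(d)
      d <- add_line(d, "catalysis", sample(controller_pool(d), 1), anchor)
      d
    }

    n <- config$n_interactions
    if (n > 0) {
      cats <- sample(c("reaction", "contingency", "catalysis"), n,
                     replace = TRUE,
                     prob = c(1 - config$p_contingency,
                              config$p_contingency * 2 / 3,
                              config$p_contingency / 3))
      if (n >= 3) cats[1:3] <- c("reaction", "contingency", "catalysis")
      for (cat_ in cats) {
        if (cat_ != "reaction" && !length(reactions)) cat_ <- "reaction"
        if (cat_ == "reaction") {
          d <- make_reaction(d)
          # the reaction line is the most recently added interaction
          reactions <- c(reactions,
                         names(d$interactions)[length(d$interactions)])
        } else if (cat_ == "contingency") {
          d <- make_contingency(d)
          contingencies <- c(contingencies, last_id(d))
        } else {
          d <- make_catalysis(d)
        }
      }
    }

    # annotate a sample of glyphs
    for (id in names(d$interactions)) {
      if (stats::runif(1) < config$p_metadata) {
        d <- add_annotation(d, sprintf("evidence for %s", id),
                            pubDb = "PubMed",
                            pubDbId = as.character(sample(1e6, 1)))
        d$interactions[[id]]$metadataRefs <- last_id(d)
      }
    }
    spes <- entity_ids_of_kind(d, "simple-physical-entity")
    if (length(spes) && stats::runif(1) < config$p_metadata) {
      d <- add_cross_reference(d, "UniProt",
                               sprintf("Q%05d", sample(99999, 1)))
      d$entities[[spes[1]]]$metadataRefs <- last_id(d)
    }
    d
  })
}

# --- targeted mutations -----------------------------------------------------

.mutation_catalogue <- c("STRUCT-ID-UNIQUE", "STRUCT-REF-RESOLVES",
                         "STRUCT-ENUM-TOKEN", "LABEL-FORMAT",
                         "ARROWHEAD-USE", "ONLINE-EXPLICIT-COMPLEX",
                         "ONLINE-INTRAMOLECULAR", "CONNECT-START",
                         "CONNECT-END", "CONNECT-TARGET-CATEGORY",
                         "RESTRICTED-COPY-USE", "BRANCH-USE")

#' Rules the mutation operator can target
#' @return Character vector of rule identifiers.
#' @export
mutation_catalogue <- function() .mutation_catalogue

pick <- function(x) if (length(x) == 1) x else sample(x, 1)

#' Mutate a clean diagram to violate one rule
#'
#' Applies a minimal mutation (one element edited or added) so that
#' validation of the result yields at least one finding with the requested
#' rule identifier. When the diagram offers no eligible element for the
#' requested rule an infeasibility error is raised.
#'
#' @param diagram a \code{mim_diagram} that validates clean.
#' @param rule a rule id from \code{mutation_catalogue()}.
#' @param seed integer seed deciding which eligible element is mutated.
#' @return The mutated \code{mim_diagram}.
#' @examples
#' d <- worked_example("trimer")
#' bad <- mutate_to_violate(d, "ARROWHEAD-USE", seed = 3)
#' print(validate_all(bad))
#' @export
mutate_to_violate <- function(diagram, rule, seed = 1L) {
  stopifnot(inherits(diagram, "mim_diagram"))
  if (!rule %in% .mutation_catalogue)
    stop_mim("mim_argument_error", "rule '", rule,
             "' is not in the mutation catalogue")
  infeasible <- function(why)
    stop_mim("mim_infeasible_error", "cannot violate ", rule, ": ", why)
  with_seed(seed, {
    d <- diagram
    ents <- names(d$entities); ints <- names(d$interactions)
    kinds <- vapply(d$entities, `[[`, "", "kind")
    types <- vapply(d$interactions, `[[`, "", "type")
    if (rule == "STRUCT-ID-UNIQUE") {
      if (length(ents) < 2) infeasible("fewer than two entities")
      pair <- sample(ents, 2)
      dup <- d$entities[[pair[2]]]
      dup$id <- pair[1]
      d$entities[[pair[2]]] <- NULL
      d$entities <- c(d$entities, stats::setNames(list(dup), pair[1]))
    } else if (rule == "STRUCT-REF-RESOLVES") {
      if (length(ints)) {
        id <- pick(ints)
        d$interactions[[id]]$points[[1]]$visRef <- "unresolved_ref"
      } else {
        withref <- ents[vapply(d$entities, function(e)
          !is.null(e$parentRef), TRUE)]
        if (!length(withref)) infeasible("no references to break")
        eid <- pick(withref)
        d$entities[[eid]]$parentRef <- "unresolved_ref"
      }
    } else if (rule == "STRUCT-ENUM-TOKEN") {
      if (length(ints)) {
        id <- pick(ints)
        d$interactions[[id]]$points[[1]]$arrowhead <- "wavy"
      } else if (length(ents)) {
        eid <- pick(ents)
        d$entities[[eid]]$kind <- "blob"
      } else infeasible("empty diagram")
    } else if (rule == "LABEL-FORMAT") {
      labeled <- ents[!kinds %in% c("explicit-complex", "restricted-copy",
                                    "source-sink")]
      if (!length(labeled)) infeasible("no labeled entities")
      eid <- pick(labeled)
      d$entities[[eid]]$label <- ""
    } else if (rule == "ARROWHEAD-USE") {
      if (!length(ints)) infeasible("no interactions")
      id <- pick(ints)
      i <- d$interactions[[id]]
      sig <- mim_arrowhead_signature(i$type)
      wrong <- pick(setdiff(mim_arrowhead_tokens(), c(sig, "none")))
      i$points[[length(i$points)]]$arrowhead <- wrong
      d$interactions[[id]] <- i
    } else if (rule == "ONLINE-EXPLICIT-COMPLEX") {
      hosts <- ints[!types %in% mim_explicit_complex_hosts()]
      if (!length(hosts)) infeasible("no interaction of a disallowed type")
      host <- pick(hosts)
      complexes <- ents[kinds == "explicit-complex"]
      if (length(complexes)) {
        eid <- pick(complexes)
        d$entities[[eid]]$lineRef <- host
      } else {
        d <- add_entity(d, "explicit-complex", lineRef = host,
                        linePosition = 0.5)
      }
    } else if (rule == "ONLINE-INTRAMOLECULAR") {
      bad_host <- function(id) {
        i <- d$interactions[[id]]
        if (isTRUE(i$intramolecular)) return(FALSE)
        if (mim_interaction_category(i$type) != "reaction") return(TRUE)
        tp <- terminal_points(i)
        s1 <- owning_spe(d, tp$first$visRef)
        s2 <- owning_spe(d, tp$last$visRef)
        is.na(s1) || is.na(s2) || s1 != s2
      }
      hosts <- ints[vapply(ints, bad_host, TRUE)]
      if (!length(hosts)) infeasible("no eligible interaction")
      hid <- pick(hosts)
      d$interactions[[hid]]$intramolecular <- TRUE
    } else if (rule %in% c("CONNECT-START", "CONNECT-END")) {
      table <- connection_rule_table()
      at_start <- rule == "CONNECT-START"
      found <- FALSE
      for (id in sample(ints, length(ints))) {
        i <- d$interactions[[id]]
        row <- table[[i$type]]
        # a kind outside the row makes both orientations fail for
        # symmetric types (their start/end sets coincide)
        banned <- if (row$anchorEnd && at_start)
          setdiff(mim_entity_kinds(),
                  c(row$allowedStart, "restricted-copy"))
        else if (row$anchorEnd)
          mim_entity_kinds()   # any entity at a contingency end is illegal
        else
          setdiff(mim_entity_kinds(),
                  c(row$allowedStart, row$allowedEnd, "restricted-copy",
                    "explicit-complex"))
        candidates <- ents[kinds %in% banned]
        if (!length(candidates)) next
        tm <- termini(i)
        ref <- pick(candidates)
        # locate the stored point holding the terminus to re-point
        slot <- if (row$symmetric || row$anchorEnd) {
          if (at_start) 1L else length(i$points)
        } else {
          first_is_start <- identical(i$points[[1]]$visRef, tm$startRef)
          if (at_start == first_is_start) 1L else length(i$points)
        }
        i$points[[slot]]$visRef <- ref
        d$interactions[[id]] <- i
        found <- TRUE
        break
      }
      if (!found) infeasible("no interaction with an eligible bad terminus")
    } else if (rule == "CONNECT-TARGET-CATEGORY") {
      cats <- mim_interaction_category(types)
      catalyses <- ints[cats == "catalysis"]
      conts <- ints[cats == "contingency"]
      if (!length(catalyses) || !length(conts))
        infeasible("needs a catalysis and a contingency")
      target <- pick(conts)
      d <- add_anchor(d, target, position = 0.5)
      anchor <- last_id(d)
      id <- pick(catalyses)
      i <- d$interactions[[id]]
      i$points[[length(i$points)]]$visRef <- anchor
      d$interactions[[id]] <- i
    } else if (rule == "RESTRICTED-COPY-USE") {
      copies <- ents[kinds == "restricted-copy"]
      found <- FALSE
      for (cp in copies) {
        parent <- d$entities[[cp]]$parentRef
        others <- ents[kinds == "simple-physical-entity" & ents != parent]
        if (!length(others)) next
        for (u in terminus_uses(d, cp)) {
          if (u$role == "branch") next
          id <- u$interaction$id
          i <- d$interactions[[id]]
          slot <- if (u$role == "start") length(i$points) else 1L
          i$points[[slot]]$visRef <- pick(others)
          d$interactions[[id]] <- i
          found <- TRUE
          break
        }
        if (found) break
      }
      if (!found)
        infeasible("no homodimer with an alternative partner available")
    } else if (rule == "BRANCH-USE") {
      hosts <- ints[!types %in% mim_branchable_types()]
      if (!length(hosts) || !length(ents))
        infeasible("no non-branchable interaction")
      id <- pick(hosts)
      i <- d$interactions[[id]]
      ref <- pick(ents)
      bxy <- ref_xy(d, ref, c(0, 0))
      i$branches <- c(i$branches, list(list(position = 0.5, points = list(
        mim_point(bxy[1], bxy[2], "none", ref)))))
      d$interactions[[id]] <- i
    }
    d
  })
}

# --- worked examples --------------------------------------------------------

#' Worked example diagrams
#'
#' Small builders covering the notation's characteristic constructions:
#' \describe{
#'   \item{trimer}{SPEs A, B, C; the explicit complex on the A-B binding
#'     denotes the dimer A:B, and the binding between that complex and C
#'     the trimer A:B:C, encoding that C must dissociate before A and B
#'     can.}
#'   \item{phospho}{formation of a phosphorylated entity: a covalent
#'     modification from a phosphate modifier to an SPE, with the explicit
#'     complex on the line representing the modified entity.}
#'   \item{conversion-branch}{a stoichiometric conversion of A into both B
#'     and C via a branch segment.}
#'   \item{cleavage}{cleavage of phosphate from the kinase CaMK, with
#'     diagram title/identifier metadata and a publication
#'     cross-reference.}
#'   \item{camk}{intramolecular regulation of CaMK: the CaMK protein with
#'     its kinase and regulation domains as entity features, calmodulin
#'     binding to the regulation domain, an intramolecular binding between
#'     the two domains, and phosphorylation of substrates catalyzed by the
#'     kinase domain.}
#' }
#' Every example validates with zero findings.
#'
#' @param name one of \code{"trimer"}, \code{"phospho"},
#'   \code{"conversion-branch"}, \code{"cleavage"}, \code{"camk"}.
#' @return A \code{mim_diagram}.
#' @examples
#' d <- worked_example("trimer")
#' print(validate_all(d))
#' @export
worked_example <- function(name) {
  geo <- function(x, y, w = 70, h = 28)
    list(centerX = x, centerY = y, width = w, height = h)
  spe <- function(d, label, x, y, id)
    add_entity(d, "simple-physical-entity", label, id = id,
               geometry = geo(x, y))
  switch(name,
    "trimer" = {
      d <- mim_diagram(400, 260)
      d <- set_diagram_terms(d, title = "Trimer A:B:C",
                             creator = "mimml examples",
                             identifier = "example-trimer")
      d <- spe(d, "A", 70, 60, "A")
      d <- spe(d, "B", 280, 60, "B")
      d <- spe(d, "C", 175, 200, "C")
      d <- add_interaction(
        d, "non-covalent-reversible-binding",
        mim_points("non-covalent-reversible-binding", "A", "B",
                   105, 60, 245, 60), id = "bindAB")
      d <- add_entity(d, "explicit-complex", id = "cplxAB",
                      lineRef = "bindAB", linePosition = 0.5)
      d <- add_interaction(
        d, "non-covalent-reversible-binding",
        mim_points("non-covalent-reversible-binding", "cplxAB", "C",
                   175, 60, 175, 186), id = "bindABC")
      d <- add_entity(d, "explicit-complex", id = "cplxABC",
                      lineRef = "bindABC", linePosition = 0.5)
      d
    },
    "phospho" = {
      d <- mim_diagram(360, 160)
      d <- set_diagram_terms(d, title = "Phosphorylation of A",
                             creator = "mimml examples",
                             identifier = "example-phospho")
      d <- spe(d, "A", 260, 80, "A")
      d <- add_entity(d, "modifier", "P", id = "P",
                      geometry = geo(70, 80, 24, 16))
      d <- add_interaction(
        d, "covalent-modification",
        mim_points("covalent-modification", "P", "A", 84, 80, 225, 80),
        id = "phosA")
      d <- add_entity(d, "explicit-complex", id = "phosA_cplx",
                      lineRef = "phosA", linePosition = 0.5)
      d
    },
    "conversion-branch" = {
      d <- mim_diagram(420, 220)
      d <- set_diagram_terms(d, title = "Conversion of A to B and C",
                             creator = "mimml examples",
                             identifier = "example-conversion-branch")
      d <- spe(d, "A", 70, 110, "A")
      d <- spe(d, "B", 340, 60, "B")
      d <- spe(d, "C", 340, 160, "C")
      sig <- mim_arrowhead_signature("stoichiometric-conversion")
      d <- add_interaction(
        d, "stoichiometric-conversion",
        list(mim_point(105, 110, sig[1], "A"),
             mim_point(305, 60, sig[2], "B")),
        branches = list(list(position = 0.5, points = list(
          mim_point(305, 160, sig[2], "C")))),
        id = "convABC")
      d
    },
    "cleavage" = {
      d <- mim_diagram(360, 160)
      d <- set_diagram_terms(d, title = "Cleavage of phosphate from CaMK",
                             creator = "mimml examples",
                             identifier = "example-cleavage")
      d <- spe(d, "CaMK", 90, 80, "CaMK")
      d <- add_entity(d, "modifier", "P", id = "P",
                      geometry = geo(290, 80, 24, 16))
      d <- add_interaction(
        d, "cleavage",
        mim_points("cleavage", "CaMK", "P", 126, 80, 276, 80),
        id = "cleavP")
      d <- add_cross_reference(d, "PubMed", "16890956",
                               relationship = "see-also", id = "pub1")
      d$interactions[["cleavP"]]$metadataRefs <- "pub1"
      d
    },
    "camk" = {
      d <- mim_diagram(640, 420)
      d <- set_diagram_terms(d, title = "CaMK regulation",
                             creator = "mimml examples",
                             identifier = "example-camk")
      d <- spe(d, "CaMK", 300, 60, "CaMK")
      d <- add_entity(d, "entity-feature", "kinase domain",
                      id = "CaMK_kin", parentRef = "CaMK",
                      geometry = geo(180, 130, 90, 24))
      d <- add_entity(d, "entity-feature", "regulation domain",
                      id = "CaMK_reg", parentRef = "CaMK",
                      geometry = geo(420, 130, 110, 24))
      d <- spe(d, "calmodulin", 540, 260, "CaM")
      d <- spe(d, "Substrates", 120, 330, "Substrates")
      d <- add_entity(d, "modifier", "P", id = "P",
                      geometry = geo(300, 330, 24, 16))
      # intramolecular inhibition of the kinase by the regulation domain:
      # a binding between the two domains of one molecule
      d <- add_interaction(
        d, "non-covalent-reversible-binding",
        mim_points("non-covalent-reversible-binding", "CaMK_kin", "CaMK_reg",
                   225, 130, 365, 130),
        intramolecular = TRUE, id = "intra")
      # calmodulin binds the regulation domain
      d <- add_interaction(
        d, "non-covalent-reversible-binding",
        mim_points("non-covalent-reversible-binding", "CaM", "CaMK_reg",
                   540, 246, 440, 142),
        id = "bindCaM")
      d <- add_entity(d, "explicit-complex", id = "cplxCaM",
                      lineRef = "bindCaM", linePosition = 0.5)
      # the kinase domain catalyzes phosphorylation of substrates
      d <- add_interaction(
        d, "covalent-modification",
        mim_points("covalent-modification", "P", "Substrates",
                   288, 330, 158, 330),
        id = "phosSub")
      d <- add_anchor(d, "phosSub", position = 0.5, id = "phosSub.site")
      d <- add_interaction(
        d, "catalysis",
        mim_points("catalysis", "CaMK_kin", "phosSub.site",
                   180, 142, 223, 318),
        id = "catKin")
      d <- add_annotation(d, "kinase activity of the catalytic domain",
                          pubDb = "PubMed", pubDbId = "16890956",
                          id = "note1")
      d$interactions[["catKin"]]$metadataRefs <- "note1"
      d
    },
    stop_mim("mim_lookup_error", "unknown worked example: ", name))
}

#' Names of the worked examples
#' @return Character vector of valid \code{worked_example()} names.
#' @export
worked_example_names <- function() {
  c("trimer", "phospho", "conversion-branch", "cleavage", "camk")
}
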