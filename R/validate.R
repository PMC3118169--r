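# Two-level validation of MIM diagrams.
#
# Level 1 checks the structural grammar: identifier uniqueness, reference
# resolution, closed-vocabulary tokens, minimum point counts and
# kind-specific attribute usage. Level 2 is the syntax-rule engine checking
# the five rule families of the notation: attribute use, label formats,
# arrowhead usage, placement of on-line symbols (explicit complex,
# intramolecular), and connection of interactions to entities or other
# interactions. All problems are findings, never exceptions: a validator
# must report, not crash, on bad input.

#' Rule identifiers of the validation engine
#'
#' @return Character vector of all rule identifiers, level-1 structural
#'   rules first.
#' @export
mim_rule_ids <- function() {
  c("STRUCT-ID-UNIQUE", "STRUCT-REF-RESOLVES", "STRUCT-ENUM-TOKEN",
    "STRUCT-POINTS-MIN", "ATTR-USE",
    "LABEL-FORMAT", "ARROWHEAD-USE", "ONLINE-EXPLICIT-COMPLEX",
    "ONLINE-INTRAMOLECULAR", "CONNECT-START", "CONNECT-END",
    "CONNECT-TARGET-CATEGORY", "RESTRICTED-COPY-USE", "BRANCH-USE")
}

.level1_rules <- c("STRUCT-ID-UNIQUE", "STRUCT-REF-RESOLVES",
                   "STRUCT-ENUM-TOKEN", "STRUCT-POINTS-MIN", "ATTR-USE")

finding <- function(rule, contextId, message, diagnostics = list(),
                    locationPath = NULL) {
  if (is.null(locationPath))
    locationPath <- sprintf("//*[@visId='%s']", contextId)
  list(rule = rule, contextId = contextId, locationPath = locationPath,
       message = message,
       diagnostics = lapply(diagnostics, as.character))
}

sort_findings <- function(findings) {
  if (!length(findings)) return(findings)
  key_ctx <- vapply(findings, `[[`, "", "contextId")
  key_rule <- vapply(findings, `[[`, "", "rule")
  key_msg <- vapply(findings, `[[`, "", "message")
  findings[order(key_ctx, key_rule, key_msg, method = "radix")]
}

#' The connection rule table
#'
#' One row per interaction type stating which entity kinds may occupy the
#' start and end of the line, whether the end may instead be an anchor on
#' another interaction (and of which categories), which symbols may sit on
#' the line itself, and whether the type may branch or is symmetric. The
#' table is plain data: adjusting a rule means editing a row, never the
#' engine.
#'
#' @return Named list of rows keyed by interaction type; each row has
#'   fields \code{allowedStart}, \code{allowedEnd}, \code{anchorEnd},
#'   \code{targetCategory}, \code{onLine}, \code{branchable},
#'   \code{symmetric}.
#' @export
connection_rule_table <- function() {
  binding_kinds <- c("simple-physical-entity", "entity-feature",
                     "conceptual-entity", "explicit-complex",
                     "implicit-complex", "restricted-copy")
  conv_kinds <- c("simple-physical-entity", "entity-feature",
                  "conceptual-entity", "explicit-complex",
                  "implicit-complex", "source-sink")
  controller_kinds <- setdiff(mim_entity_kinds(),
                              c("source-sink", "restricted-copy"))
  state_kinds <- c("simple-physical-entity", "entity-feature",
                   "explicit-complex")
  row <- function(start, end, anchorEnd = FALSE, target = character(),
                  onLine = character(), branchable = FALSE,
                  symmetric = FALSE)
    list(allowedStart = start, allowedEnd = end, anchorEnd = anchorEnd,
         targetCategory = target, onLine = onLine, branchable = branchable,
         symmetric = symmetric)
  conv_row <- row(conv_kinds, conv_kinds, branchable = TRUE)
  list(
    "non-covalent-reversible-binding" = row(
      binding_kinds, binding_kinds,
      onLine = c("explicit-complex", "intramolecular"), symmetric = TRUE),
    "covalent-irreversible-binding" = row(
      binding_kinds, binding_kinds,
      onLine = c("explicit-complex", "intramolecular"), symmetric = TRUE),
    "covalent-modification" = row(
      "modifier",
      c("simple-physical-entity", "entity-feature", "explicit-complex"),
      onLine = "explicit-complex"),
    "stoichiometric-conversion" = conv_row,
    "production-without-loss" = conv_row,
    "template-reaction" = conv_row,
    # a cleavage may release a small molecule (e.g. phosphate), so its
    # product side additionally admits modifier entities
    "cleavage" = row(conv_kinds, c(conv_kinds, "modifier"),
                     branchable = TRUE),
    "state-combination" = row(
      state_kinds, state_kinds, onLine = "explicit-complex",
      symmetric = TRUE),
    "stimulation" = row(
      controller_kinds, character(), anchorEnd = TRUE,
      target = c("reaction", "contingency")),
    "necessary-stimulation" = row(
      controller_kinds, character(), anchorEnd = TRUE,
      target = c("reaction", "contingency")),
    "inhibition" = row(
      controller_kinds, character(), anchorEnd = TRUE,
      target = c("reaction", "contingency")),
    "catalysis" = row(
      controller_kinds, character(), anchorEnd = TRUE,
      target = "reaction")
  )
}

# classify what an identifier refers to: an entity kind token,
# "anchor-on-interaction", "interaction", or NA when unresolved
referent_class <- function(diagram, id) {
  if (is.null(id)) return(NA_character_)
  ent <- diagram$entities[[id]]
  if (!is.null(ent)) return(ent$kind)
  if (!is.null(diagram$interactions[[id]])) return("interaction")
  for (inter in diagram$interactions)
    for (a in inter$anchors)
      if (a$id == id) return("anchor-on-interaction")
  NA_character_
}

anchor_owner <- function(diagram, anchor_id) {
  for (inter in diagram$interactions)
    for (a in inter$anchors)
      if (a$id == anchor_id) return(inter)
  NULL
}

# resolve a terminus through parentRef to its simple physical entity, or NA
owning_spe <- function(diagram, id) {
  ent <- diagram$entities[[id]]
  if (is.null(ent)) return(NA_character_)
  if (ent$kind == "simple-physical-entity") return(ent$id)
  if (ent$kind %in% c("entity-feature", "restricted-copy") &&
      !is.null(ent$parentRef))
    return(ent$parentRef)
  NA_character_
}

terminal_points <- function(inter) {
  list(first = inter$points[[1]],
       last = inter$points[[length(inter$points)]])
}

arrow_diag <- function(inter) {
  tp <- terminal_points(inter)
  list("inter-vis-id" = inter$id,
       "inter-start-arrowhead" = tp$first$arrowhead,
       "inter-end-arrowhead" = tp$last$arrowhead)
}

# --- level 1 ----------------------------------------------------------------

diagram_structure_findings <- function(diagram) {
  out <- list()
  add <- function(f) out[[length(out) + 1L]] <<- f

  ids <- all_ids(diagram)
  for (dup in unique(ids[duplicated(ids)]))
    add(finding("STRUCT-ID-UNIQUE", dup,
                sprintf("identifier '%s' is used by %d elements",
                        dup, sum(ids == dup)),
                list("vis-id" = dup)))

  check_tok <- function(ctx, value, vocab, what) {
    if (!is.null(value) && !value %in% vocab)
      add(finding("STRUCT-ENUM-TOKEN", ctx,
                  sprintf("'%s' is not a valid %s token", value, what),
                  list(token = value)))
  }
  check_res <- function(ctx, ref, what) {
    if (!is.null(ref) && !ref %in% ids)
      add(finding("STRUCT-REF-RESOLVES", ctx,
                  sprintf("%s '%s' does not resolve", what, ref),
                  list(ref = ref)))
  }

  for (e in diagram$entities) {
    if (!is_identifier(e$id))
      add(finding("ATTR-USE", e$id,
                  sprintf("'%s' is not a well-formed identifier", e$id),
                  locationPath = "/*"))
    check_tok(e$id, e$kind, mim_entity_kinds(), "entity kind")
    check_tok(e$id, e$bioType, mim_bio_types(), "biological type")
    check_res(e$id, e$parentRef, "parentRef")
    for (m in e$memberRefs) check_res(e$id, m, "memberRef")
    check_res(e$id, e$lineRef, "lineRef")
    for (m in e$metadataRefs) check_res(e$id, m, "metadataRef")
    if (!e$kind %in% mim_entity_kinds()) next

    dot_kind <- e$kind %in% c("explicit-complex", "restricted-copy")
    if (dot_kind && !is.null(e$geometry))
      add(finding("ATTR-USE", e$id,
                  sprintf("%s is a line-attached dot and carries no geometry",
                          e$kind)))
    if (!dot_kind && is.null(e$geometry))
      add(finding("ATTR-USE", e$id,
                  sprintf("%s requires geometry (centerX, centerY, width, height)",
                          e$kind)))
    if (e$kind %in% c("entity-feature", "restricted-copy")) {
      if (is.null(e$parentRef))
        add(finding("ATTR-USE", e$id,
                    sprintf("%s requires a parentRef", e$kind)))
      else if (e$parentRef %in% ids) {
        p <- diagram$entities[[e$parentRef]]
        if (is.null(p) || p$kind != "simple-physical-entity")
          add(finding("ATTR-USE", e$id,
                      sprintf("parentRef of %s must name a simple-physical-entity",
                              e$kind)))
      }
    }
    if (e$kind == "implicit-complex") {
      if (!length(e$memberRefs))
        add(finding("ATTR-USE", e$id,
                    "implicit-complex requires non-empty memberRefs"))
      for (m in e$memberRefs) {
        if (!m %in% ids) next
        mm <- diagram$entities[[m]]
        if (is.null(mm))
          add(finding("ATTR-USE", e$id,
                      sprintf("memberRef '%s' must name an entity glyph", m)))
        else if (mm$kind == "source-sink")
          add(finding("ATTR-USE", e$id,
                      "implicit-complex member may not be a source-sink"))
      }
    }
    if (e$kind == "explicit-complex") {
      if (is.null(e$lineRef) || is.null(e$linePosition))
        add(finding("ATTR-USE", e$id,
                    "explicit-complex requires lineRef and linePosition"))
      else {
        if (e$lineRef %in% ids && is.null(diagram$interactions[[e$lineRef]]))
          add(finding("ATTR-USE", e$id,
                      "lineRef must name an interaction glyph"))
        if (e$linePosition < 0 || e$linePosition > 1)
          add(finding("ATTR-USE", e$id, "linePosition must lie in [0,1]"))
      }
    }
  }

  for (i in diagram$interactions) {
    check_tok(i$id, i$type, mim_interaction_types(), "interaction type")
    if (length(i$points) < 2) {
      add(finding("STRUCT-POINTS-MIN", i$id,
                  sprintf("interaction has %d point(s); at least 2 required",
                          length(i$points))))
      next
    }
    pts <- i$points
    n <- length(pts)
    for (k in seq_len(n)) {
      p <- pts[[k]]
      check_tok(i$id, p$arrowhead, mim_arrowhead_tokens(), "arrowhead")
      if (k %in% c(1L, n)) {
        if (is.null(p$visRef))
          add(finding("ATTR-USE", i$id,
                      "first and last points must carry a visRef"))
        else check_res(i$id, p$visRef, "visRef")
      } else if (!is.null(p$visRef)) {
        add(finding("ATTR-USE", i$id,
                    "interior points must not carry a visRef"))
      }
    }
    for (b in i$branches) {
      if (!length(b$points)) {
        add(finding("ATTR-USE", i$id, "branch needs at least one point"))
        next
      }
      for (p in b$points)
        check_tok(i$id, p$arrowhead, mim_arrowhead_tokens(), "arrowhead")
      endp <- b$points[[length(b$points)]]
      if (is.null(endp$visRef))
        add(finding("ATTR-USE", i$id,
                    "branch terminal point must carry a visRef"))
      else check_res(i$id, endp$visRef, "visRef")
    }
    for (m in i$metadataRefs) check_res(i$id, m, "metadataRef")
  }

  for (x in diagram$metadata$crossReferences)
    check_tok(x$id, x$relationship, mim_xref_relationships(),
              "cross-reference relationship")
  for (a in diagram$metadata$annotations)
    if (!is.null(a$pubDb) && (!nzchar(a$pubDb) || !nzchar(a$pubDbId)))
      add(finding("ATTR-USE", a$id,
                  "publication cross-reference db/dbId must be non-empty"))
  out
}

#' Level-1 structural validation
#'
#' Checks the structural grammar of a diagram or MIMML document:
#' identifier uniqueness, reference resolution, closed-vocabulary tokens,
#' the two-point minimum for interaction lines, and kind-specific
#' attribute usage. All problems are returned as findings.
#'
#' @param x a \code{mim_diagram}, an XML string/file path, or an
#'   \code{xml2} document.
#' @return List of findings (empty when the input conforms).
#' @export
validate_structure <- function(x) {
  if (!inherits(x, "mim_diagram")) {
    dialect <- list()
    x <- withCallingHandlers(
      read_mimml(x, strict = FALSE),
      warning = function(w) {
        dialect[[length(dialect) + 1L]] <<-
          finding("ATTR-USE", "", conditionMessage(w), locationPath = "/*")
        invokeRestart("muffleWarning")
      })
    return(sort_findings(c(dialect, diagram_structure_findings(x))))
  }
  sort_findings(diagram_structure_findings(x))
}

# --- level 2 ----------------------------------------------------------------

# level-2 checks assume a resolvable model; interactions or entities whose
# tokens are outside the vocabularies are skipped here (already reported
# at level 1)
known_interactions <- function(diagram) {
  Filter(function(i) i$type %in% mim_interaction_types() &&
           length(i$points) >= 2, diagram$interactions)
}

#' Arrowhead-usage check
#'
#' Each interaction's terminal arrowheads must match its type's signature.
#' Directed lines may be stored in either orientation, so the pair is
#' compared as an unordered pair.
#'
#' @param diagram a structurally valid \code{mim_diagram}.
#' @return List of \code{ARROWHEAD-USE} findings.
#' @export
check_arrowhead_usage <- function(diagram) {
  out <- list()
  for (i in known_interactions(diagram)) {
    sig <- mim_arrowhead_signature(i$type)
    tp <- terminal_points(i)
    got <- c(tp$first$arrowhead, tp$last$arrowhead)
    ok <- identical(got, sig) || identical(got, rev(sig))
    if (!ok)
      out[[length(out) + 1L]] <- finding(
        "ARROWHEAD-USE", i$id,
        sprintf("terminal arrowheads (%s, %s) do not match the %s signature (%s, %s)",
                got[1], got[2], i$type, sig[1], sig[2]),
        arrow_diag(i))
  }
  sort_findings(out)
}

#' On-line symbol placement check
#'
#' Explicit complexes may sit only on covalent modification, non-covalent
#' reversible binding, covalent irreversible binding and state combination
#' lines. The intramolecular mark may sit only on a reaction whose two
#' termini belong (through their parent references) to the same simple
#' physical entity.
#'
#' @param diagram a structurally valid \code{mim_diagram}.
#' @return List of \code{ONLINE-EXPLICIT-COMPLEX} and
#'   \code{ONLINE-INTRAMOLECULAR} findings.
#' @export
check_online_symbols <- function(diagram) {
  out <- list()
  allowed <- mim_explicit_complex_hosts()
  for (e in diagram$entities) {
    if (!identical(e$kind, "explicit-complex") || is.null(e$lineRef)) next
    host <- diagram$interactions[[e$lineRef]]
    if (is.null(host) || !host$type %in% mim_interaction_types()) next
    if (!host$type %in% allowed)
      out[[length(out) + 1L]] <- finding(
        "ONLINE-EXPLICIT-COMPLEX", e$id,
        sprintf("explicit complex may not sit on a %s line", host$type),
        c(list("vis-id" = e$id), arrow_diag(host)))
  }
  for (i in known_interactions(diagram)) {
    if (!isTRUE(i$intramolecular)) next
    bad <- NULL
    if (mim_interaction_category(i$type) != "reaction") {
      bad <- sprintf("intramolecular mark on a %s, not a reaction",
                     mim_interaction_category(i$type))
    } else {
      tp <- terminal_points(i)
      s1 <- owning_spe(diagram, tp$first$visRef)
      s2 <- owning_spe(diagram, tp$last$visRef)
      if (is.na(s1) || is.na(s2) || s1 != s2)
        bad <- "intramolecular termini do not belong to one simple physical entity"
    }
    if (!is.null(bad))
      out[[length(out) + 1L]] <- finding(
        "ONLINE-INTRAMOLECULAR", i$id, bad, arrow_diag(i))
  }
  sort_findings(out)
}

#' Connection-rule check
#'
#' Checks every interaction terminus against the connection rule table:
#' which entity kinds may occupy the start and the end, and, for
#' contingencies and catalysis, that the end is an anchor on an
#' interaction of an allowed category. Symmetric types are evaluated under
#' both orientations and reported only when neither satisfies the row.
#'
#' @param diagram a structurally valid \code{mim_diagram}.
#' @param table a rule table from \code{connection_rule_table()}.
#' @return List of \code{CONNECT-START}, \code{CONNECT-END} and
#'   \code{CONNECT-TARGET-CATEGORY} findings.
#' @export
check_connection_rules <- function(diagram, table = connection_rule_table()) {
  out <- list()
  add <- function(f) out[[length(out) + 1L]] <<- f
  for (i in known_interactions(diagram)) {
    row <- table[[i$type]]
    tp <- terminal_points(i)
    k1 <- referent_class(diagram, tp$first$visRef)
    k2 <- referent_class(diagram, tp$last$visRef)
    if (is.na(k1) || is.na(k2)) next  # dangling: level-1 territory

    if (row$anchorEnd) {
      # contingency/catalysis: start is an entity, end an anchor
      start_ok <- k1 %in% row$allowedStart
      if (!start_ok)
        add(finding("CONNECT-START", i$id,
                    sprintf("%s may not start on a %s", i$type, k1),
                    c(list("start-kind" = k1), arrow_diag(i))))
      if (k2 != "anchor-on-interaction") {
        add(finding("CONNECT-END", i$id,
                    sprintf("%s must end on an anchor of an interaction, not a %s",
                            i$type, k2),
                    c(list("end-kind" = k2), arrow_diag(i))))
      } else {
        owner <- anchor_owner(diagram, tp$last$visRef)
        if (!is.null(owner) && owner$type %in% mim_interaction_types()) {
          cat_ <- mim_interaction_category(owner$type)
          if (!cat_ %in% row$targetCategory)
            add(finding("CONNECT-TARGET-CATEGORY", i$id,
                        sprintf("%s may not target a %s (allowed: %s)",
                                i$type, cat_,
                                paste(row$targetCategory, collapse = ", ")),
                        c(list("target-category" = cat_), arrow_diag(i))))
        }
      }
    } else if (row$symmetric) {
      ok_fwd <- k1 %in% row$allowedStart && k2 %in% row$allowedEnd
      ok_rev <- k2 %in% row$allowedStart && k1 %in% row$allowedEnd
      if (!ok_fwd && !ok_rev) {
        if (!k1 %in% row$allowedStart)
          add(finding("CONNECT-START", i$id,
                      sprintf("%s may not connect to a %s", i$type, k1),
                      c(list("start-kind" = k1), arrow_diag(i))))
        if (!k2 %in% row$allowedEnd)
          add(finding("CONNECT-END", i$id,
                      sprintf("%s may not connect to a %s", i$type, k2),
                      c(list("end-kind" = k2), arrow_diag(i))))
      }
    } else {
      # directed reaction: orient by arrowheads
      tm <- termini(i)
      ks <- referent_class(diagram, tm$startRef)
      ke <- referent_class(diagram, tm$endRef)
      if (!ks %in% row$allowedStart)
        add(finding("CONNECT-START", i$id,
                    sprintf("%s may not start on a %s", i$type, ks),
                    c(list("start-kind" = ks), arrow_diag(i))))
      if (!ke %in% row$allowedEnd)
        add(finding("CONNECT-END", i$id,
                    sprintf("%s may not end on a %s", i$type, ke),
                    c(list("end-kind" = ke), arrow_diag(i))))
      for (b in i$branches) {
        ref <- b$points[[length(b$points)]]$visRef
        kb <- referent_class(diagram, ref)
        if (!is.na(kb) && !kb %in% row$allowedEnd)
          add(finding("CONNECT-END", i$id,
                      sprintf("%s branch may not end on a %s", i$type, kb),
                      c(list("end-kind" = kb), arrow_diag(i))))
      }
    }
  }
  sort_findings(out)
}

#' Label-format check
#'
#' Entity labels must be non-empty except for the symbol-only kinds
#' (explicit complex, restricted copy, source/sink); modifier labels are
#' short small-molecule tokens of at most 16 characters; an entity
#' feature's label must differ from its parent's.
#'
#' @param diagram a structurally valid \code{mim_diagram}.
#' @return List of \code{LABEL-FORMAT} findings.
#' @export
check_labels <- function(diagram) {
  out <- list()
  symbol_only <- c("explicit-complex", "restricted-copy", "source-sink")
  for (e in diagram$entities) {
    if (!e$kind %in% mim_entity_kinds()) next
    if (!e$kind %in% symbol_only && !nzchar(e$label))
      out[[length(out) + 1L]] <- finding(
        "LABEL-FORMAT", e$id,
        sprintf("%s requires a non-empty label", e$kind),
        list("vis-id" = e$id))
    if (e$kind == "modifier" && nchar(e$label) > 16)
      out[[length(out) + 1L]] <- finding(
        "LABEL-FORMAT", e$id,
        sprintf("modifier label '%s' exceeds 16 characters", e$label),
        list("vis-id" = e$id, label = e$label))
    if (e$kind == "entity-feature" && !is.null(e$parentRef)) {
      p <- diagram$entities[[e$parentRef]]
      if (!is.null(p) && nzchar(e$label) && identical(e$label, p$label))
        out[[length(out) + 1L]] <- finding(
          "LABEL-FORMAT", e$id,
          "entity-feature label must differ from its parent's label",
          list("vis-id" = e$id, label = e$label))
    }
  }
  sort_findings(out)
}

# all places an identifier is referenced as a line terminus or branch end;
# returns a list of list(interaction, role)
terminus_uses <- function(diagram, id) {
  uses <- list()
  for (i in known_interactions(diagram)) {
    tp <- terminal_points(i)
    if (identical(tp$first$visRef, id))
      uses[[length(uses) + 1L]] <- list(interaction = i, role = "start")
    if (identical(tp$last$visRef, id))
      uses[[length(uses) + 1L]] <- list(interaction = i, role = "end")
    for (b in i$branches)
      if (identical(b$points[[length(b$points)]]$visRef, id))
        uses[[length(uses) + 1L]] <- list(interaction = i, role = "branch")
  }
  uses
}

#' Restricted-copy usage check
#'
#' A restricted copy exists solely to diagram homo-oligomerization: its
#' only permitted use is as one terminus of a binding interaction whose
#' other terminus is the copy's parent simple physical entity. Any other
#' reference to the copy is a violation.
#'
#' @param diagram a structurally valid \code{mim_diagram}.
#' @return List of \code{RESTRICTED-COPY-USE} findings.
#' @export
check_restricted_copies <- function(diagram) {
  out <- list()
  bindings <- c("non-covalent-reversible-binding",
                "covalent-irreversible-binding")
  for (e in diagram$entities) {
    if (!identical(e$kind, "restricted-copy")) next
    for (u in terminus_uses(diagram, e$id)) {
      i <- u$interaction
      ok <- FALSE
      if (u$role != "branch" && i$type %in% bindings) {
        tp <- terminal_points(i)
        other <- if (u$role == "start") tp$last$visRef else tp$first$visRef
        ok <- identical(other, e$parentRef)
      }
      if (!ok)
        out[[length(out) + 1L]] <- finding(
          "RESTRICTED-COPY-USE", e$id,
          sprintf("restricted copy may only bind its parent SPE; used as %s of %s '%s'",
                  u$role, i$type, i$id),
          c(list("vis-id" = e$id), arrow_diag(i)))
    }
    # membership in an implicit complex is also a use
    for (ic in diagram$entities) {
      if (identical(ic$kind, "implicit-complex") && e$id %in% ic$memberRefs)
        out[[length(out) + 1L]] <- finding(
          "RESTRICTED-COPY-USE", e$id,
          sprintf("restricted copy may not be a member of implicit complex '%s'",
                  ic$id),
          list("vis-id" = e$id))
    }
  }
  sort_findings(out)
}

#' Branch-usage check
#'
#' Only the producing reaction types (stoichiometric conversion,
#' production without loss, template reaction, cleavage) may own branch
#' segments.
#'
#' @param diagram a structurally valid \code{mim_diagram}.
#' @return List of \code{BRANCH-USE} findings.
#' @export
check_branch_use <- function(diagram) {
  out <- list()
  for (i in known_interactions(diagram)) {
    if (length(i$branches) && !i$type %in% mim_branchable_types())
      out[[length(out) + 1L]] <- finding(
        "BRANCH-USE", i$id,
        sprintf("%s may not own branch segments", i$type),
        arrow_diag(i))
  }
  sort_findings(out)
}

#' Full two-level validation
#'
#' Runs the structural grammar checks (level 1) and, when the model is
#' resolvable (no duplicate or dangling identifiers), the syntax-rule
#' engine (level 2): label formats, arrowhead usage, on-line symbol
#' placement, connection rules, restricted-copy usage and branch usage.
#'
#' @param diagram a \code{mim_diagram} (or MIMML source accepted by
#'   \code{validate_structure}).
#' @param table connection rule table; defaults to the notation's.
#' @return A \code{mim_report} with fields \code{diagramId},
#'   \code{level1}, \code{level2} and \code{checkedRules}.
#' @examples
#' report <- validate_all(worked_example("camk"))
#' report
#' @export
validate_all <- function(diagram, table = connection_rule_table()) {
  if (!inherits(diagram, "mim_diagram"))
    diagram <- suppressWarnings(read_mimml(diagram, strict = FALSE))
  level1 <- validate_structure(diagram)
  l1_rules <- vapply(level1, `[[`, "", "rule")
  resolvable <- !any(l1_rules %in% c("STRUCT-REF-RESOLVES",
                                     "STRUCT-ID-UNIQUE"))
  level2 <- list()
  checked <- .level1_rules
  if (resolvable) {
    level2 <- sort_findings(c(
      check_labels(diagram),
      check_arrowhead_usage(diagram),
      check_online_symbols(diagram),
      check_connection_rules(diagram, table),
      check_restricted_copies(diagram),
      check_branch_use(diagram)))
    checked <- mim_rule_ids()
  }
  structure(list(
    diagramId = if ("identifier" %in% names(diagram$metadata$diagramTerms))
      unname(diagram$metadata$diagramTerms[["identifier"]]) else "",
    level1 = level1, level2 = level2, checkedRules = checked),
    class = "mim_report")
}

#' @export
print.mim_report <- function(x, ...) {
  cat(sprintf("MIM validation report%s\n",
              if (nzchar(x$diagramId)) paste0(" for '", x$diagramId, "'")
              else ""))
  cat(sprintf("  level 1 (structure):   %d finding(s)\n", length(x$level1)))
  cat(sprintf("  level 2 (syntax rules): %d finding(s)\n", length(x$level2)))
  for (f in c(x$level1, x$level2))
    cat(sprintf("  [%s] %s: %s\n", f$rule, f$contextId, f$message))
  invisible(x)
}

#' Total number of findings in a report
#' @param report a \code{mim_report}.
#' @return Integer count across both levels.
#' @export
n_findings <- function(report) length(report$level1) + length(report$level2)

# --- SVRL -------------------------------------------------------------------

SVRL_NS <- "http://purl.oclc.org/dsdl/svrl"

# context class each rule is evaluated against, for fired-rule elements
rule_context <- function(rule) {
  switch(rule,
    "STRUCT-ID-UNIQUE" = "//*[@visId]",
    "STRUCT-REF-RESOLVES" = "//*[@visRef or @parentRef or @lineRef or @memberRefs or @metadataRefs]",
    "STRUCT-ENUM-TOKEN" = "//*[@type or @arrowHead or @bioType or @relationship]",
    "STRUCT-POINTS-MIN" = "//InteractionGlyph",
    "ATTR-USE" = "//EntityGlyph | //InteractionGlyph",
    "LABEL-FORMAT" = "//EntityGlyph",
    "ARROWHEAD-USE" = "//InteractionGlyph",
    "ONLINE-EXPLICIT-COMPLEX" = "//EntityGlyph[@type='explicit-complex']",
    "ONLINE-INTRAMOLECULAR" = "//InteractionGlyph[@intramolecular='true']",
    "CONNECT-START" = "//InteractionGlyph",
    "CONNECT-END" = "//InteractionGlyph",
    "CONNECT-TARGET-CATEGORY" = "//InteractionGlyph",
    "RESTRICTED-COPY-USE" = "//EntityGlyph[@type='restricted-copy']",
    "BRANCH-USE" = "//InteractionGlyph[Branch]",
    "//*")
}

#' Render a validation report as SVRL
#'
#' Produces a Schematron Validation Report Language subset document: one
#' \code{fired-rule} element per rule evaluated and one
#' \code{failed-assert} per finding, carrying the rule id, the XPath
#' location of the offending element, a \code{text} message and one
#' \code{diagnostic-reference} per diagnostic entry. The output is valid
#' against the SVRL-subset grammar bundled at
#' \code{system.file("extdata", "svrl-subset.xsd", package = "mimml")}.
#'
#' @param report a \code{mim_report}.
#' @return The SVRL document as a single string.
#' @export
report_to_svrl <- function(report) {
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             paste0('<svrl:schematron-output xmlns:svrl="', SVRL_NS,
                    '" title="MIM syntax validation"',
                    ' schemaVersion="', esc_attr(report$diagramId), '">'))
  for (r in report$checkedRules)
    lines <- c(lines, sprintf(
      '  <svrl:fired-rule id="%s" context="%s"/>',
      r, esc_attr(rule_context(r))))
  emit <- function(f, flag) {
    out <- sprintf('  <svrl:failed-assert id="%s" flag="%s" location="%s">',
                   f$rule, flag, esc_attr(f$locationPath))
    out <- c(out, sprintf('    <svrl:text>%s</svrl:text>',
                          esc_text(f$message)))
    for (nm in names(f$diagnostics))
      out <- c(out, sprintf(
        '    <svrl:diagnostic-reference diagnostic="%s">%s</svrl:diagnostic-reference>',
        esc_attr(nm), esc_text(f$diagnostics[[nm]])))
    c(out, "  </svrl:failed-assert>")
  }
  for (f in report$level1) lines <- c(lines, emit(f, "level1"))
  for (f in report$level2) lines <- c(lines, emit(f, "level2"))
  lines <- c(lines, "</svrl:schematron-output>")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse an SVRL document back into findings
#'
#' Inverse of \code{report_to_svrl} for the failed-assert payload.
#'
#' @param svrl SVRL document string (or xml2 document).
#' @return A list with \code{level1} and \code{level2} finding lists and
#'   \code{checkedRules}.
#' @export
svrl_to_findings <- function(svrl) {
  doc <- if (inherits(svrl, "xml_document")) svrl else xml2::read_xml(svrl)
  ns <- c(svrl = SVRL_NS)
  fired <- xml2::xml_find_all(doc, ".//svrl:fired-rule", ns)
  checked <- xml2::xml_attr(fired, "id")
  parse_fa <- function(node) {
    diags <- xml2::xml_find_all(node, "./svrl:diagnostic-reference", ns)
    dv <- as.list(xml2::xml_text(diags))
    names(dv) <- xml2::xml_attr(diags, "diagnostic")
    loc <- xml2::xml_attr(node, "location")
    ctx <- sub("^//\\*\\[@visId='(.*)'\\]$", "\\1", loc)
    if (identical(ctx, loc)) ctx <- ""
    finding(xml2::xml_attr(node, "id"), ctx,
            xml2::xml_text(xml2::xml_find_first(node, "./svrl:text", ns)),
            dv, locationPath = loc)
  }
  fas <- xml2::xml_find_all(doc, ".//svrl:failed-assert", ns)
  flags <- xml2::xml_attr(fas, "flag")
  list(level1 = lapply(fas[flags == "level1"], parse_fa),
       level2 = lapply(fas[flags == "level2"], parse_fa),
       checkedRules = checked)
}

# --- JSON -------------------------------------------------------------------

finding_to_list <- function(f) {
  list(rule = f$rule, contextId = f$contextId,
       locationPath = f$locationPath, message = f$message,
       diagnostics = if (length(f$diagnostics)) f$diagnostics
       else stats::setNames(list(), character()))
}

#' Render a validation report as JSON
#'
#' Lossless JSON rendering with stable key order: \code{diagramId},
#' \code{checkedRules}, \code{level1}, \code{level2}.
#'
#' @param report a \code{mim_report}.
#' @return A JSON string.
#' @export
report_to_json <- function(report) {
  obj <- list(diagramId = report$diagramId,
              checkedRules = report$checkedRules,
              level1 = lapply(report$level1, finding_to_list),
              level2 = lapply(report$level2, finding_to_list))
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE))
}

#' Parse a JSON report back into a \code{mim_report}
#'
#' @param json JSON string produced by \code{report_to_json}.
#' @return A \code{mim_report}.
#' @export
json_to_report <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  fix <- function(f) finding(f$rule, f$contextId, f$message,
                             lapply(f$diagnostics, as.character),
                             locationPath = f$locationPath)
  structure(list(diagramId = obj$diagramId,
                 level1 = lapply(obj$level1, fix),
                 level2 = lapply(obj$level2, fix),
                 checkedRules = as.character(unlist(obj$checkedRules))),
            class = "mim_report")
}
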