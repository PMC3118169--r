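# In-memory model of a MIM diagram.
#
# A diagram is a plain list (class "mim_diagram") holding named lists of
# entity glyphs and interaction glyphs plus a metadata store. Authoring
# operations enforce referential invariants at construction time; the
# validation engine (validate.R) re-checks everything as findings so that
# documents read from untrusted MIMML are reported on rather than rejected.

stop_mim <- function(class, ...) {
  stop(structure(class = c(class, "mim_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Create an empty MIM diagram
#'
#' The diagram is the root container for entity glyphs, interaction glyphs
#' and biological metadata. Coordinates use real-valued user units with the
#' origin at the top-left corner and y increasing downward.
#'
#' @param width,height positive canvas dimensions in user units.
#' @return An object of class \code{mim_diagram}.
#' @examples
#' d <- mim_diagram(800, 600)
#' d
#' @export
mim_diagram <- function(width = 800, height = 600) {
  if (!is.numeric(width) || length(width) != 1 || is.na(width) || width <= 0 ||
      !is.numeric(height) || length(height) != 1 || is.na(height) || height <= 0)
    stop_mim("mim_argument_error", "width and height must be positive reals")
  structure(list(
    width = as.numeric(width),
    height = as.numeric(height),
    entities = list(),
    interactions = list(),
    metadata = list(diagramTerms = character(),
                    crossReferences = list(),
                    annotations = list())
  ), class = "mim_diagram")
}

#' @export
print.mim_diagram <- function(x, ...) {
  kinds <- vapply(x$entities, `[[`, "", "kind")
  cats <- if (length(x$interactions))
    mim_interaction_category(vapply(x$interactions, `[[`, "", "type"))
  else character()
  cat(sprintf("MIM diagram: %g x %g user units\n", x$width, x$height))
  cat(sprintf("  entities:     %d", length(x$entities)))
  if (length(kinds)) {
    tab <- table(kinds)
    cat("  (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  cat(sprintf("  interactions: %d", length(x$interactions)))
  if (length(cats)) {
    tab <- table(cats)
    cat("  (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  cat(sprintf("  metadata:     %d cross-references, %d annotations\n",
              length(x$metadata$crossReferences),
              length(x$metadata$annotations)))
  invisible(x)
}

# every identifier currently claimed in the diagram: glyphs, anchors,
# metadata records
all_ids <- function(diagram) {
  anchor_ids <- unlist(lapply(diagram$interactions, function(i)
    vapply(i$anchors, `[[`, "", "id")), use.names = FALSE)
  c(names(diagram$entities), names(diagram$interactions), anchor_ids,
    names(diagram$metadata$crossReferences),
    names(diagram$metadata$annotations))
}

next_id <- function(diagram, prefix) {
  ids <- all_ids(diagram)
  n <- 1L
  repeat {
    cand <- paste0(prefix, n)
    if (!cand %in% ids) return(cand)
    n <- n + 1L
  }
}

#' Identifier of the element most recently added to a diagram
#'
#' Authoring functions return the updated diagram; the identifier they
#' assigned is recorded on it and retrievable with this accessor.
#'
#' @param diagram a \code{mim_diagram}.
#' @return A single identifier string, or \code{NULL} for a fresh diagram.
#' @export
last_id <- function(diagram) attr(diagram, "last_id")

check_ref <- function(diagram, ref, what, allowed_kinds = NULL) {
  ids <- all_ids(diagram)
  if (!ref %in% ids)
    stop_mim("mim_reference_error", what, " '", ref, "' does not resolve")
  if (!is.null(allowed_kinds)) {
    ent <- diagram$entities[[ref]]
    if (is.null(ent) || !ent$kind %in% allowed_kinds)
      stop_mim("mim_model_error", what, " '", ref, "' must resolve to a ",
               paste(allowed_kinds, collapse = " or "))
  }
  invisible(TRUE)
}

#' Add an entity glyph to a diagram
#'
#' Entity kinds and their constraints: \describe{
#'   \item{simple-physical-entity}{a molecule (protein, DNA, RNA, ...) not in
#'     complex; labeled rounded rectangle, normally drawn once per diagram.}
#'   \item{entity-feature}{a named region (domain, motif, site) of an SPE;
#'     requires \code{parentRef} naming its simple physical entity.}
#'   \item{restricted-copy}{a dot acting as a copy of an SPE, used solely to
#'     diagram homo-oligomerization; requires \code{parentRef}.}
#'   \item{modifier}{borderless label for a small molecule (phosphate,
#'     methyl, ubiquitin) that may appear many times.}
#'   \item{conceptual-entity}{a rectangular glyph for objects without clear
#'     physical structure (e.g. ionizing radiation).}
#'   \item{source-sink}{the empty-set symbol: an unspecified source or
#'     degradation product.}
#'   \item{explicit-complex}{a filled dot sitting on an interaction line
#'     (the bound product); requires \code{lineRef} and \code{linePosition}.}
#'   \item{implicit-complex}{an enclosure of entities; requires non-empty
#'     \code{memberRefs}, none of which may be a source-sink.}
#' }
#'
#' @param diagram a \code{mim_diagram}.
#' @param kind one of \code{mim_entity_kinds()}.
#' @param label display label; symbol-only kinds (explicit-complex,
#'   restricted-copy, source-sink) conventionally leave it empty.
#' @param id identifier to assign; autogenerated when \code{NULL}.
#' @param geometry \code{list(centerX, centerY, width, height)} or
#'   \code{NULL} for the line-attached dot kinds.
#' @param bioType optional biological type from \code{mim_bio_types()}.
#' @param parentRef parent SPE identifier (entity-feature, restricted-copy).
#' @param memberRefs member identifiers (implicit-complex).
#' @param lineRef,linePosition hosting interaction and position in [0,1]
#'   along it (explicit-complex).
#' @param color optional presentation color; never affects semantics.
#' @param metadataRefs identifiers of metadata records attached to the glyph.
#' @return The updated diagram; the new identifier is available via
#'   \code{last_id()}.
#' @examples
#' d <- mim_diagram()
#' d <- add_entity(d, "simple-physical-entity", "CaMK",
#'                 geometry = list(centerX = 100, centerY = 100,
#'                                 width = 80, height = 30))
#' camk <- last_id(d)
#' d <- add_entity(d, "entity-feature", "kinase domain", parentRef = camk,
#'                 geometry = list(centerX = 80, centerY = 130,
#'                                 width = 70, height = 20))
#' @export
add_entity <- function(diagram, kind, label = "", id = NULL, geometry = NULL,
                       bioType = NULL, parentRef = NULL,
                       memberRefs = character(), lineRef = NULL,
                       linePosition = NULL, color = NULL,
                       metadataRefs = character()) {
  stopifnot(inherits(diagram, "mim_diagram"))
  if (!kind %in% mim_entity_kinds())
    stop_mim("mim_model_error", "unknown entity kind: ", kind)
  if (is.null(id)) id <- next_id(diagram, "e") else check_identifier(id, "id")
  if (id %in% all_ids(diagram))
    stop_mim("mim_conflict_error", "duplicate identifier: ", id)

  if (kind %in% c("entity-feature", "restricted-copy")) {
    if (is.null(parentRef))
      stop_mim("mim_model_error", kind, " requires parentRef")
    check_ref(diagram, parentRef, "parentRef", "simple-physical-entity")
  }
  if (kind == "implicit-complex") {
    if (length(memberRefs) == 0)
      stop_mim("mim_model_error", "implicit-complex requires memberRefs")
    for (m in memberRefs) {
      check_ref(diagram, m, "memberRef")
      ent <- diagram$entities[[m]]
      if (is.null(ent))
        stop_mim("mim_model_error", "memberRef '", m,
                 "' must resolve to an entity glyph")
      if (ent$kind == "source-sink")
        stop_mim("mim_model_error", "implicit-complex member may not be ",
                 "a source-sink")
    }
  }
  if (kind == "explicit-complex") {
    if (is.null(lineRef) || is.null(linePosition))
      stop_mim("mim_model_error",
               "explicit-complex requires lineRef and linePosition")
    check_ref(diagram, lineRef, "lineRef")
    if (is.null(diagram$interactions[[lineRef]]))
      stop_mim("mim_model_error", "lineRef '", lineRef,
               "' must resolve to an interaction glyph")
    if (!is.numeric(linePosition) || linePosition < 0 || linePosition > 1)
      stop_mim("mim_model_error", "linePosition must lie in [0,1]")
  }
  if (!is.null(geometry)) {
    need <- c("centerX", "centerY", "width", "height")
    if (!all(need %in% names(geometry)))
      stop_mim("mim_argument_error", "geometry needs ",
               paste(need, collapse = ", "))
    if (geometry$width <= 0 || geometry$height <= 0)
      stop_mim("mim_argument_error", "geometry width/height must be positive")
    geometry <- lapply(geometry[need], as.numeric)
  }
  if (!is.null(bioType) && !bioType %in% mim_bio_types())
    stop_mim("mim_model_error", "unknown bioType: ", bioType)
  for (m in metadataRefs) check_ref(diagram, m, "metadataRef")

  diagram$entities[[id]] <- list(
    id = id, kind = kind, label = as.character(label), geometry = geometry,
    bioType = bioType, parentRef = parentRef,
    memberRefs = as.character(memberRefs), lineRef = lineRef,
    linePosition = if (is.null(linePosition)) NULL else as.numeric(linePosition),
    color = color, metadataRefs = as.character(metadataRefs))
  attr(diagram, "last_id") <- id
  diagram
}

#' Build a point of an interaction line
#'
#' @param x,y coordinates in user units.
#' @param arrowhead an arrowhead token (\code{mim_arrowhead_tokens()}).
#' @param visRef identifier of the glyph or anchor this line end connects
#'   to; present only on the first and last point of a line.
#' @return A point record for \code{add_interaction()}.
#' @export
mim_point <- function(x, y, arrowhead = "none", visRef = NULL) {
  list(x = as.numeric(x), y = as.numeric(y),
       arrowhead = arrowhead, visRef = visRef)
}

#' Straight two-point line between two referents
#'
#' Convenience builder producing the two terminal points of an interaction
#' with the arrowhead signature of its type.
#'
#' @param type interaction type token (decides the arrowhead pair).
#' @param from,to identifiers the line start/end connect to.
#' @param x0,y0,x1,y1 terminal coordinates.
#' @return A list of two points.
#' @export
mim_points <- function(type, from, to, x0 = 0, y0 = 0, x1 = 100, y1 = 0) {
  sig <- mim_arrowhead_signature(type)
  list(mim_point(x0, y0, sig[1], from), mim_point(x1, y1, sig[2], to))
}

#' Add an interaction glyph to a diagram
#'
#' An interaction is a typed line through an ordered chain of points. The
#' first and last points carry \code{visRef} attributes naming the glyphs
#' (or anchors on other interactions) the line connects; interior points
#' only route the line. Branch segments let the producing reaction types
#' (stoichiometric conversion, production without loss, template reaction,
#' cleavage) fan out to multiple products. Anchors are named attachment
#' points on the line, the legal targets of contingencies and catalysis.
#'
#' @param diagram a \code{mim_diagram}.
#' @param type one of \code{mim_interaction_types()}.
#' @param points ordered list of \code{mim_point()} records, length >= 2,
#'   with \code{visRef} on the first and last point only.
#' @param id identifier; autogenerated when \code{NULL}.
#' @param branches list of branch segments, each
#'   \code{list(position =, points = list(...))} with the branch's last
#'   point carrying arrowhead and \code{visRef}.
#' @param anchors list of \code{list(id =, position =)} anchor records;
#'   ids autogenerated when absent.
#' @param intramolecular logical: the interaction occurs within a single
#'   molecule (both termini must belong to one SPE for the diagram to
#'   validate).
#' @param metadataRefs metadata record identifiers.
#' @return The updated diagram; new identifier via \code{last_id()}.
#' @examples
#' d <- mim_diagram()
#' d <- add_entity(d, "simple-physical-entity", "A",
#'                 geometry = list(centerX = 50, centerY = 50,
#'                                 width = 60, height = 30))
#' a <- last_id(d)
#' d <- add_entity(d, "simple-physical-entity", "B",
#'                 geometry = list(centerX = 250, centerY = 50,
#'                                 width = 60, height = 30))
#' b <- last_id(d)
#' d <- add_interaction(d, "non-covalent-reversible-binding",
#'                      mim_points("non-covalent-reversible-binding", a, b,
#'                                 80, 50, 220, 50))
#' @export
add_interaction <- function(diagram, type, points, id = NULL,
                            branches = list(), anchors = list(),
                            intramolecular = FALSE,
                            metadataRefs = character()) {
  stopifnot(inherits(diagram, "mim_diagram"))
  if (!type %in% mim_interaction_types())
    stop_mim("mim_model_error", "unknown interaction type: ", type)
  if (is.null(id)) id <- next_id(diagram, "i") else check_identifier(id, "id")
  if (id %in% all_ids(diagram))
    stop_mim("mim_conflict_error", "duplicate identifier: ", id)
  if (length(points) < 2)
    stop_mim("mim_model_error", "an interaction needs at least 2 points")
  first <- points[[1]]; last <- points[[length(points)]]
  if (is.null(first$visRef) || is.null(last$visRef))
    stop_mim("mim_model_error",
             "first and last points must carry a visRef")
  check_ref(diagram, first$visRef, "visRef")
  check_ref(diagram, last$visRef, "visRef")
  for (b in branches) {
    if (is.null(b$points) || length(b$points) < 1)
      stop_mim("mim_model_error", "branch needs at least one point")
    endp <- b$points[[length(b$points)]]
    if (is.null(endp$visRef))
      stop_mim("mim_model_error", "branch terminal point must carry visRef")
    check_ref(diagram, endp$visRef, "visRef")
  }
  taken <- all_ids(diagram)
  anchors <- lapply(anchors, function(a) {
    if (is.null(a$id)) {
      n <- 1L
      repeat {
        cand <- paste0(id, ".a", n)
        if (!cand %in% taken) break
        n <- n + 1L
      }
      a$id <- cand
    } else {
      check_identifier(a$id, "anchor id")
      if (a$id %in% taken)
        stop_mim("mim_conflict_error", "duplicate identifier: ", a$id)
    }
    taken <<- c(taken, a$id)
    if (is.null(a$position) || a$position < 0 || a$position > 1)
      stop_mim("mim_model_error", "anchor position must lie in [0,1]")
    list(id = a$id, position = as.numeric(a$position))
  })
  for (m in metadataRefs) check_ref(diagram, m, "metadataRef")

  diagram$interactions[[id]] <- list(
    id = id, type = type, points = points, branches = branches,
    anchors = anchors, intramolecular = isTRUE(intramolecular),
    metadataRefs = as.character(metadataRefs))
  attr(diagram, "last_id") <- id
  diagram
}

#' Add an anchor to an existing interaction
#'
#' @param diagram a \code{mim_diagram}.
#' @param interaction_id identifier of the owning interaction.
#' @param position position in [0,1] along the interaction trunk.
#' @param id anchor identifier; autogenerated when \code{NULL}.
#' @return The updated diagram; new anchor identifier via \code{last_id()}.
#' @export
add_anchor <- function(diagram, interaction_id, position, id = NULL) {
  inter <- diagram$interactions[[interaction_id]]
  if (is.null(inter))
    stop_mim("mim_lookup_error", "no interaction with id '",
             interaction_id, "'")
  if (is.null(id)) {
    n <- length(inter$anchors) + 1L
    repeat {
      cand <- paste0(interaction_id, ".a", n)
      if (!cand %in% all_ids(diagram)) break
      n <- n + 1L
    }
    id <- cand
  } else {
    check_identifier(id, "anchor id")
    if (id %in% all_ids(diagram))
      stop_mim("mim_conflict_error", "duplicate identifier: ", id)
  }
  if (position < 0 || position > 1)
    stop_mim("mim_model_error", "anchor position must lie in [0,1]")
  inter$anchors[[length(inter$anchors) + 1L]] <-
    list(id = id, position = as.numeric(position))
  diagram$interactions[[interaction_id]] <- inter
  attr(diagram, "last_id") <- id
  diagram
}

#' Set Dublin-Core-style diagram terms
#'
#' @param diagram a \code{mim_diagram}.
#' @param ... named term = value pairs (e.g. \code{title}, \code{creator},
#'   \code{identifier}).
#' @return The updated diagram.
#' @export
set_diagram_terms <- function(diagram, ...) {
  terms <- c(...)
  stopifnot(is.character(terms), !is.null(names(terms)))
  existing <- diagram$metadata$diagramTerms
  existing[names(terms)] <- terms
  diagram$metadata$diagramTerms <- existing
  diagram
}

#' Add a database cross-reference metadata record
#'
#' @param diagram a \code{mim_diagram}.
#' @param db,dbId external database name and record identifier.
#' @param relationship \code{"identity"} or \code{"see-also"}.
#' @param id record identifier; autogenerated when \code{NULL}.
#' @return The updated diagram; new identifier via \code{last_id()}.
#' @export
add_cross_reference <- function(diagram, db, dbId,
                                relationship = "identity", id = NULL) {
  if (!relationship %in% mim_xref_relationships())
    stop_mim("mim_model_error", "unknown relationship: ", relationship)
  if (is.null(id)) id <- next_id(diagram, "x") else check_identifier(id, "id")
  if (id %in% all_ids(diagram))
    stop_mim("mim_conflict_error", "duplicate identifier: ", id)
  diagram$metadata$crossReferences[[id]] <-
    list(id = id, db = as.character(db), dbId = as.character(dbId),
         relationship = relationship)
  attr(diagram, "last_id") <- id
  diagram
}

#' Add an annotation metadata record
#'
#' Annotations carry a free-text comment and, optionally, a publication
#' cross-reference mapping the annotated element to the article providing
#' evidence for it.
#'
#' @param diagram a \code{mim_diagram}.
#' @param comment free-text comment.
#' @param pubDb,pubDbId publication database and identifier (both or
#'   neither).
#' @param id record identifier; autogenerated when \code{NULL}.
#' @return The updated diagram; new identifier via \code{last_id()}.
#' @export
add_annotation <- function(diagram, comment, pubDb = NULL, pubDbId = NULL,
                           id = NULL) {
  if (xor(is.null(pubDb), is.null(pubDbId)))
    stop_mim("mim_model_error",
             "publication cross-reference needs both pubDb and pubDbId")
  if (!is.null(pubDb) && (!nzchar(pubDb) || !nzchar(pubDbId)))
    stop_mim("mim_model_error",
             "publication cross-reference db/dbId must be non-empty")
  if (is.null(id)) id <- next_id(diagram, "n") else check_identifier(id, "id")
  if (id %in% all_ids(diagram))
    stop_mim("mim_conflict_error", "duplicate identifier: ", id)
  diagram$metadata$annotations[[id]] <-
    list(id = id, comment = as.character(comment),
         pubDb = pubDb, pubDbId = pubDbId)
  attr(diagram, "last_id") <- id
  diagram
}

#' Resolve an identifier within a diagram
#'
#' Looks an identifier up across entity glyphs, interaction glyphs, anchors
#' and metadata records.
#'
#' @param diagram a \code{mim_diagram}.
#' @param id identifier to look up.
#' @return The element: an entity record, an interaction record, a
#'   \code{list(anchor =, interaction =)} pair for anchors, or a metadata
#'   record. Unknown identifiers raise a lookup error.
#' @export
resolve <- function(diagram, id) {
  stopifnot(inherits(diagram, "mim_diagram"))
  if (!is.null(diagram$entities[[id]])) return(diagram$entities[[id]])
  if (!is.null(diagram$interactions[[id]])) return(diagram$interactions[[id]])
  for (inter in diagram$interactions) {
    for (a in inter$anchors)
      if (a$id == id) return(list(anchor = a, interaction = inter))
  }
  if (!is.null(diagram$metadata$crossReferences[[id]]))
    return(diagram$metadata$crossReferences[[id]])
  if (!is.null(diagram$metadata$annotations[[id]]))
    return(diagram$metadata$annotations[[id]])
  stop_mim("mim_lookup_error", "no element with id '", id, "'")
}

#' Start and end referents of an interaction
#'
#' For symmetric interaction types (non-covalent reversible binding,
#' covalent irreversible binding, state combination) either terminus of the
#' line may be considered the start; the pair is canonicalized by returning
#' the lexicographically smaller referent first. For all other types the
#' line terminus without an arrowhead is the start.
#'
#' @param interaction an interaction record from a \code{mim_diagram}.
#' @return \code{list(startRef, endRef, canonical)}; \code{canonical} is
#'   \code{TRUE} when the order was imposed by canonicalization rather than
#'   read off the arrowheads.
#' @export
termini <- function(interaction) {
  pts <- interaction$points
  a <- pts[[1]]; b <- pts[[length(pts)]]
  if (interaction$type %in% .symmetric_types) {
    refs <- sort(c(a$visRef, b$visRef), method = "radix")
    return(list(startRef = refs[1], endRef = refs[2], canonical = TRUE))
  }
  # directed: the arrowhead-free terminus is the start regardless of
  # storage order
  if (identical(a$arrowhead, "none") || !identical(b$arrowhead, "none"))
    list(startRef = a$visRef, endRef = b$visRef, canonical = FALSE)
  else
    list(startRef = b$visRef, endRef = a$visRef, canonical = FALSE)
}

#' Referents an interaction produces or points at
#'
#' The trunk's end referent plus, for branched producing reactions, each
#' branch's terminal referent, in stored order.
#'
#' @param interaction an interaction record.
#' @return Character vector of identifiers.
#' @export
effective_targets <- function(interaction) {
  trunk <- termini(interaction)$endRef
  branch_ends <- vapply(interaction$branches, function(b)
    b$points[[length(b$points)]]$visRef, "")
  c(trunk, branch_ends)
}
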