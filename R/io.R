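# MIMML reading and writing.
#
# The writer emits a bit-exact normal form (UTF-8, LF, 2-space indent,
# entities then interactions sorted by id, metadata last) so that equal
# semantic models always serialize byte-identically. The reader is strict
# about the dialect's element/attribute names but permissive about token
# values and references: bad tokens and dangling references are preserved
# in the model and reported by the validation engine, never raised as
# parse failures.

MIMML_NS <- "urn:mimml:1.0"

# NULL-safe id sort (names() of an empty list is NULL)
sort_ids <- function(ids) {
  if (is.null(ids)) character() else sort(ids, method = "radix")
}

fmt_num <- function(x) {
  trimws(formatC(as.numeric(x), format = "g", digits = 9,
                 decimal.mark = "."))
}

esc_attr <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

esc_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

attr_str <- function(...) {
  kv <- c(...)
  kv <- kv[!vapply(kv, is.null, TRUE)]
  if (!length(kv)) return("")
  paste0(" ", paste(sprintf('%s="%s"', names(kv), esc_attr(unlist(kv))),
                    collapse = " "))
}

point_line <- function(p, indent) {
  paste0(indent, "<Point", attr_str(
    x = fmt_num(p$x), y = fmt_num(p$y), arrowHead = p$arrowhead,
    visRef = p$visRef), "/>")
}

entity_lines <- function(e) {
  attrs <- c(
    visId = e$id, type = e$kind,
    label = if (nzchar(e$label)) e$label else NULL)
  if (!is.null(e$geometry))
    attrs <- c(attrs,
               centerX = fmt_num(e$geometry$centerX),
               centerY = fmt_num(e$geometry$centerY),
               width = fmt_num(e$geometry$width),
               height = fmt_num(e$geometry$height))
  attrs <- c(attrs,
             color = e$color, bioType = e$bioType, parentRef = e$parentRef,
             memberRefs = if (length(e$memberRefs))
               paste(e$memberRefs, collapse = " ") else NULL,
             lineRef = e$lineRef,
             linePosition = if (!is.null(e$linePosition))
               fmt_num(e$linePosition) else NULL,
             metadataRefs = if (length(e$metadataRefs))
               paste(e$metadataRefs, collapse = " ") else NULL)
  paste0("  <EntityGlyph", attr_str(attrs), "/>")
}

interaction_lines <- function(i) {
  attrs <- c(visId = i$id, type = i$type,
             intramolecular = if (isTRUE(i$intramolecular)) "true" else NULL,
             metadataRefs = if (length(i$metadataRefs))
               paste(i$metadataRefs, collapse = " ") else NULL)
  out <- paste0("  <InteractionGlyph", attr_str(attrs), ">")
  for (p in i$points) out <- c(out, point_line(p, "    "))
  for (b in i$branches) {
    out <- c(out, paste0("    <Branch",
                         attr_str(position = fmt_num(b$position)), ">"))
    for (p in b$points) out <- c(out, point_line(p, "      "))
    out <- c(out, "    </Branch>")
  }
  for (a in i$anchors)
    out <- c(out, paste0("    <Anchor", attr_str(
      visId = a$id, position = fmt_num(a$position)), "/>"))
  c(out, "  </InteractionGlyph>")
}

metadata_lines <- function(md) {
  has <- length(md$diagramTerms) || length(md$crossReferences) ||
    length(md$annotations)
  if (!has) return(character())
  out <- "  <MimBio>"
  if (length(md$diagramTerms)) {
    terms <- md$diagramTerms[order(names(md$diagramTerms), method = "radix")]
    for (nm in names(terms))
      out <- c(out, sprintf("    <dc-%s>%s</dc-%s>",
                            nm, esc_text(terms[[nm]]), nm))
  }
  for (id in sort_ids(names(md$crossReferences))) {
    x <- md$crossReferences[[id]]
    out <- c(out, paste0("    <CrossReference", attr_str(
      visId = x$id, db = x$db, dbId = x$dbId,
      relationship = x$relationship), "/>"))
  }
  for (id in sort_ids(names(md$annotations))) {
    a <- md$annotations[[id]]
    if (is.null(a$pubDb)) {
      out <- c(out, paste0("    <Annotation", attr_str(
        visId = a$id, comment = a$comment), "/>"))
    } else {
      out <- c(out,
               paste0("    <Annotation", attr_str(
                 visId = a$id, comment = a$comment), ">"),
               paste0("      <PublicationXref", attr_str(
                 db = a$pubDb, dbId = a$pubDbId), "/>"),
               "    </Annotation>")
    }
  }
  c(out, "  </MimBio>")
}

#' Serialize a diagram to MIMML
#'
#' Emits the MIMML normal form: XML declaration, UTF-8, LF line endings,
#' two-space indentation, entities then interactions sorted by identifier,
#' metadata last, numbers with up to nine significant digits. Equal
#' semantic models serialize byte-identically, which makes golden-file
#' comparisons meaningful.
#'
#' @param diagram a \code{mim_diagram} satisfying the model's referential
#'   invariants (serialization of a diagram with duplicate or dangling
#'   identifiers is refused).
#' @param path optional file path; when \code{NULL} the document is only
#'   returned.
#' @return The MIMML document as a single string, invisibly when written
#'   to a file.
#' @examples
#' d <- mim_diagram(200, 100)
#' cat(write_mimml(d))
#' @export
write_mimml <- function(diagram, path = NULL) {
  stopifnot(inherits(diagram, "mim_diagram"))
  bad <- diagram_structure_findings(diagram)
  bad <- bad[vapply(bad, function(f)
    f$rule %in% c("STRUCT-ID-UNIQUE", "STRUCT-REF-RESOLVES",
                  "STRUCT-POINTS-MIN"), TRUE)]
  if (length(bad))
    stop_mim("mim_model_error",
             "refusing to serialize a diagram violating referential ",
             "invariants: ", bad[[1]]$message)

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0("<Diagram", attr_str(xmlns = MIMML_NS,
                                width = fmt_num(diagram$width),
                                height = fmt_num(diagram$height)),
           if (length(diagram$entities) || length(diagram$interactions) ||
               length(metadata_lines(diagram$metadata))) ">" else "/>"))
  empty <- endsWith(lines[2], "/>")
  if (!empty) {
    for (id in sort_ids(names(diagram$entities)))
      lines <- c(lines, entity_lines(diagram$entities[[id]]))
    for (id in sort_ids(names(diagram$interactions)))
      lines <- c(lines, interaction_lines(diagram$interactions[[id]]))
    lines <- c(lines, metadata_lines(diagram$metadata), "</Diagram>")
  }
  doc <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(doc), con)
    return(invisible(doc))
  }
  doc
}

# --- reader -----------------------------------------------------------------

.known_attrs <- list(
  Diagram = c("width", "height"),
  EntityGlyph = c("visId", "type", "label", "centerX", "centerY", "width",
                  "height", "color", "parentRef", "memberRefs", "lineRef",
                  "linePosition", "bioType", "metadataRefs"),
  InteractionGlyph = c("visId", "type", "intramolecular", "metadataRefs"),
  Point = c("x", "y", "arrowHead", "visRef"),
  Anchor = c("visId", "position"),
  Branch = c("position"),
  MimBio = character(),
  CrossReference = c("visId", "db", "dbId", "relationship"),
  Annotation = c("visId", "comment"),
  PublicationXref = c("db", "dbId")
)

dialect_problem <- function(strict, ...) {
  msg <- paste0(...)
  if (strict) stop_mim("mim_dialect_error", msg)
  warning(msg, call. = FALSE)
  invisible(NULL)
}

check_node <- function(node, expected, strict) {
  nm <- xml2::xml_name(node)
  known <- .known_attrs[[nm]]
  attrs <- xml2::xml_attrs(node)
  # drop namespace declarations reported as attributes
  attrs <- attrs[!grepl("^xmlns", names(attrs))]
  unknown <- setdiff(names(attrs), known)
  if (length(unknown))
    dialect_problem(strict, "unknown attribute(s) on <", nm, ">: ",
                    paste(unknown, collapse = ", "))
  invisible(attrs)
}

aval <- function(attrs, name, default = NULL) {
  if (name %in% names(attrs)) unname(attrs[[name]]) else default
}

anum <- function(attrs, name, default = NULL) {
  v <- aval(attrs, name)
  if (is.null(v)) default else as.numeric(v)
}

split_refs <- function(x) {
  if (is.null(x) || !nzchar(x)) character() else
    strsplit(trimws(x), "[[:space:]]+")[[1]]
}

parse_point <- function(node, strict) {
  attrs <- check_node(node, NULL, strict)
  mim_point(anum(attrs, "x", 0), anum(attrs, "y", 0),
            aval(attrs, "arrowHead", "none"), aval(attrs, "visRef"))
}

parse_entity <- function(node, strict) {
  attrs <- check_node(node, NULL, strict)
  geom_attrs <- c("centerX", "centerY", "width", "height")
  present <- geom_attrs %in% names(attrs)
  geometry <- NULL
  if (any(present)) {
    if (!all(present)) {
      dialect_problem(strict, "EntityGlyph geometry attributes must appear ",
                      "together (centerX, centerY, width, height)")
    } else {
      geometry <- list(centerX = anum(attrs, "centerX"),
                       centerY = anum(attrs, "centerY"),
                       width = anum(attrs, "width"),
                       height = anum(attrs, "height"))
    }
  }
  lp <- aval(attrs, "linePosition")
  list(id = aval(attrs, "visId", ""),
       kind = aval(attrs, "type", ""),
       label = aval(attrs, "label", ""),
       geometry = geometry,
       bioType = aval(attrs, "bioType"),
       parentRef = aval(attrs, "parentRef"),
       memberRefs = split_refs(aval(attrs, "memberRefs")),
       lineRef = aval(attrs, "lineRef"),
       linePosition = if (is.null(lp)) NULL else as.numeric(lp),
       color = aval(attrs, "color"),
       metadataRefs = split_refs(aval(attrs, "metadataRefs")))
}

parse_interaction <- function(node, strict) {
  attrs <- check_node(node, NULL, strict)
  points <- list(); branches <- list(); anchors <- list()
  for (child in xml2::xml_children(node)) {
    cn <- xml2::xml_name(child)
    if (cn == "Point") {
      points[[length(points) + 1L]] <- parse_point(child, strict)
    } else if (cn == "Anchor") {
      ca <- check_node(child, NULL, strict)
      anchors[[length(anchors) + 1L]] <-
        list(id = aval(ca, "visId", ""), position = anum(ca, "position", 0))
    } else if (cn == "Branch") {
      ca <- check_node(child, NULL, strict)
      bp <- list()
      for (pc in xml2::xml_children(child)) {
        if (xml2::xml_name(pc) == "Point")
          bp[[length(bp) + 1L]] <- parse_point(pc, strict)
        else dialect_problem(strict, "unknown element <",
                             xml2::xml_name(pc), "> inside Branch")
      }
      branches[[length(branches) + 1L]] <-
        list(position = anum(ca, "position", 0), points = bp)
    } else {
      dialect_problem(strict, "unknown element <", cn,
                      "> inside InteractionGlyph")
    }
  }
  list(id = aval(attrs, "visId", ""),
       type = aval(attrs, "type", ""),
       points = points, branches = branches, anchors = anchors,
       intramolecular = identical(aval(attrs, "intramolecular"), "true"),
       metadataRefs = split_refs(aval(attrs, "metadataRefs")))
}

parse_mimbio <- function(node, strict) {
  md <- list(diagramTerms = character(), crossReferences = list(),
             annotations = list())
  for (child in xml2::xml_children(node)) {
    cn <- xml2::xml_name(child)
    if (grepl("^dc-", cn)) {
      term <- sub("^dc-", "", cn)
      md$diagramTerms[[term]] <- xml2::xml_text(child)
    } else if (cn == "CrossReference") {
      ca <- check_node(child, NULL, strict)
      id <- aval(ca, "visId", "")
      md$crossReferences <- c(md$crossReferences, stats::setNames(list(
        list(id = id, db = aval(ca, "db", ""), dbId = aval(ca, "dbId", ""),
             relationship = aval(ca, "relationship", "identity"))), id))
    } else if (cn == "Annotation") {
      ca <- check_node(child, NULL, strict)
      pub <- NULL
      for (pc in xml2::xml_children(child)) {
        if (xml2::xml_name(pc) == "PublicationXref") {
          pa <- check_node(pc, NULL, strict)
          pub <- list(db = aval(pa, "db", ""), dbId = aval(pa, "dbId", ""))
        } else {
          dialect_problem(strict, "unknown element <", xml2::xml_name(pc),
                          "> inside Annotation")
        }
      }
      id <- aval(ca, "visId", "")
      md$annotations <- c(md$annotations, stats::setNames(list(
        list(id = id, comment = aval(ca, "comment", ""),
             pubDb = if (is.null(pub)) NULL else pub$db,
             pubDbId = if (is.null(pub)) NULL else pub$dbId)), id))
    } else {
      dialect_problem(strict, "unknown element <", cn, "> inside MimBio")
    }
  }
  md
}

#' Read a MIMML document
#'
#' Parses a MIMML data stream into a \code{mim_diagram}. Dialect errors
#' (unknown elements or attributes) are raised in strict mode and logged
#' and dropped in lenient mode. Token and reference problems are never
#' parse failures: they stay in the model and surface as findings when the
#' diagram is validated.
#'
#' @param source a file path, an XML string, or an \code{xml2} document.
#' @param strict logical; \code{TRUE} (default) rejects unknown dialect
#'   constructs and requires the MIMML namespace, \code{FALSE} accepts
#'   un-namespaced input and drops unknown constructs with a warning.
#' @return A \code{mim_diagram}.
#' @examples
#' d <- read_mimml('<Diagram xmlns="urn:mimml:1.0" width="10" height="10"/>')
#' @export
read_mimml <- function(source, strict = TRUE) {
  doc <- if (inherits(source, "xml_document")) source else
    tryCatch(xml2::read_xml(source),
             error = function(e)
               stop_mim("mim_parse_error", "malformed XML: ",
                        conditionMessage(e)))
  ns_uris <- unique(unname(unlist(xml2::xml_ns(doc))))
  if (strict && !MIMML_NS %in% ns_uris)
    stop_mim("mim_dialect_error", "document does not declare the MIMML ",
             "namespace ", MIMML_NS, " (lenient mode accepts un-namespaced ",
             "input)")
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "Diagram")
    stop_mim("mim_dialect_error", "root element must be Diagram, found <",
             xml2::xml_name(root), ">")
  attrs <- check_node(root, NULL, strict)
  if (!all(c("width", "height") %in% names(attrs)))
    stop_mim("mim_dialect_error", "Diagram requires width and height")

  d <- mim_diagram(anum(attrs, "width"), anum(attrs, "height"))
  entities <- list(); interactions <- list()
  for (child in xml2::xml_children(root)) {
    cn <- xml2::xml_name(child)
    if (cn == "EntityGlyph") {
      e <- parse_entity(child, strict)
      entities <- c(entities, stats::setNames(list(e), e$id))
    } else if (cn == "InteractionGlyph") {
      i <- parse_interaction(child, strict)
      interactions <- c(interactions, stats::setNames(list(i), i$id))
    } else if (cn == "MimBio") {
      check_node(child, NULL, strict)
      d$metadata <- parse_mimbio(child, strict)
    } else {
      dialect_problem(strict, "unknown element <", cn, "> inside Diagram")
    }
  }
  d$entities <- entities
  d$interactions <- interactions
  d
}

# --- semantic equality ------------------------------------------------------

canon_value <- function(x) {
  if (is.list(x)) {
    x <- x[!vapply(x, is.null, TRUE)]
    lapply(x, canon_value)
  } else if (is.numeric(x)) {
    as.numeric(x)
  } else x
}

values_equal <- function(a, b, tol = 1e-9) {
  if (is.list(a) && is.list(b)) {
    if (length(a) != length(b)) return(FALSE)
    if (!identical(names(a), names(b))) return(FALSE)
    for (k in seq_along(a)) if (!values_equal(a[[k]], b[[k]], tol))
      return(FALSE)
    return(TRUE)
  }
  if (is.numeric(a) && is.numeric(b))
    return(length(a) == length(b) && all(abs(a - b) <= tol))
  identical(a, b)
}

canon_diagram <- function(d) {
  ord <- function(x) x[sort_ids(names(x))]
  list(width = d$width, height = d$height,
       entities = canon_value(ord(d$entities)),
       interactions = canon_value(ord(d$interactions)),
       metadata = list(
         diagramTerms = as.list(ord(d$metadata$diagramTerms)),
         crossReferences = canon_value(ord(d$metadata$crossReferences)),
         annotations = canon_value(ord(d$metadata$annotations))))
}

#' Semantic equality of two diagrams
#'
#' Diagrams are equal when their entity, interaction and metadata content
#' agree up to element storage order and up to a floating-point tolerance
#' of 1e-9 on coordinates.
#'
#' @param a,b \code{mim_diagram} objects.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
semantic_equal <- function(a, b) {
  stopifnot(inherits(a, "mim_diagram"), inherits(b, "mim_diagram"))
  values_equal(canon_diagram(a), canon_diagram(b))
}
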