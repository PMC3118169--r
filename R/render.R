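# Deterministic SVG rendering of MIM diagrams.
#
# One <g> per glyph carrying the glyph's identifier; interactions are
# polylines through their stored points with a marker per arrowhead token.
# No automatic routing or label collision avoidance: the renderer draws
# the stored geometry verbatim. Marker and shape geometry constants live
# in one style table so visual tweaks never touch logic.

.glyph_styles <- list(
  "simple-physical-entity" = list(shape = "rounded-rect", fill = "#ffffff",
                                  stroke = "#000000", fontSize = 12),
  "entity-feature"   = list(shape = "rounded-rect", fill = "#f0f0f0",
                            stroke = "#000000", fontSize = 10),
  "conceptual-entity" = list(shape = "rect", fill = "#ffffff",
                             stroke = "#000000", fontSize = 12),
  "modifier"         = list(shape = "label-only", fill = "none",
                            stroke = "none", fontSize = 11),
  "source-sink"      = list(shape = "empty-set-symbol", fill = "none",
                            stroke = "#000000", fontSize = 12),
  "explicit-complex" = list(shape = "filled-dot", fill = "#000000",
                            stroke = "#000000", fontSize = 0),
  "restricted-copy"  = list(shape = "filled-dot", fill = "#000000",
                            stroke = "#000000", fontSize = 0),
  "implicit-complex" = list(shape = "dashed-enclosure", fill = "none",
                            stroke = "#000000", fontSize = 11)
)

#' Style table entry for an entity kind
#' @param kind an entity kind token.
#' @return List with \code{shape}, \code{fill}, \code{stroke},
#'   \code{fontSize}.
#' @export
glyph_style <- function(kind) {
  st <- .glyph_styles[[kind]]
  if (is.null(st)) stop_mim("mim_lookup_error", "unknown entity kind: ", kind)
  st
}

# marker geometries; refX places the tip on the line end
.marker_paths <- list(
  "barbed" = '<path d="M0,0 L10,4 L0,8" fill="none" stroke="#000"/>',
  "barbed-covalent" = paste0('<path d="M0,0 L10,4 L0,8" fill="none" stroke="#000"/>',
                             '<line x1="3" y1="0" x2="3" y2="8" stroke="#000"/>'),
  "filled-triangle" = '<path d="M0,0 L10,4 L0,8 Z" fill="#000" stroke="#000"/>',
  "open-triangle" = '<path d="M0,0 L10,4 L0,8 Z" fill="#fff" stroke="#000"/>',
  "open-triangle-bar" = paste0('<path d="M2,0 L12,4 L2,8 Z" fill="#fff" stroke="#000"/>',
                               '<line x1="0" y1="0" x2="0" y2="8" stroke="#000"/>'),
  "bar" = '<line x1="5" y1="0" x2="5" y2="8" stroke="#000" stroke-width="2"/>',
  # placeholder geometries for marks the notation names but whose visual
  # form is fixed only in the full glyph reference
  "production-mark" = '<circle cx="5" cy="4" r="3" fill="#fff" stroke="#000"/>',
  "template-mark" = '<path d="M0,8 L5,0 L10,8" fill="none" stroke="#000"/>',
  "cleavage-mark" = paste0('<line x1="0" y1="0" x2="10" y2="8" stroke="#000"/>',
                           '<line x1="0" y1="8" x2="10" y2="0" stroke="#000"/>'),
  "state-combination-mark" = '<rect x="1" y="1" width="8" height="6" fill="#fff" stroke="#000"/>',
  "catalysis-mark" = '<circle cx="5" cy="4" r="4" fill="#fff" stroke="#000"/>'
)

#' SVG marker definition for an arrowhead token
#'
#' @param token an arrowhead token; \code{"none"} yields an empty string
#'   (no marker is attached).
#' @return A \code{<marker>} element string.
#' @export
marker_for <- function(token) {
  if (identical(token, "none")) return("")
  body <- .marker_paths[[token]]
  if (is.null(body))
    stop_mim("mim_lookup_error", "unknown arrowhead token: ", token)
  sprintf(paste0('<marker id="mk-%s" markerWidth="14" markerHeight="10" ',
                 'refX="10" refY="4" orient="auto" markerUnits="userSpaceOnUse">%s</marker>'),
          token, body)
}

svg_text <- function(x, y, label, size) {
  sprintf('<text x="%s" y="%s" font-size="%s" text-anchor="middle" font-family="sans-serif">%s</text>',
          fmt_num(x), fmt_num(y), fmt_num(size), esc_text(label))
}

# position of a line-attached dot: interpolate along the host line, or the
# terminus point whose visRef names the dot
dot_position <- function(diagram, e) {
  if (!is.null(e$lineRef)) {
    host <- diagram$interactions[[e$lineRef]]
    if (!is.null(host) && length(host$points) >= 2) {
      p0 <- host$points[[1]]; p1 <- host$points[[length(host$points)]]
      t <- if (is.null(e$linePosition)) 0.5 else e$linePosition
      return(c(p0$x + t * (p1$x - p0$x), p0$y + t * (p1$y - p0$y)))
    }
  }
  for (i in diagram$interactions) {
    for (p in list(i$points[[1]], i$points[[length(i$points)]]))
      if (identical(p$visRef, e$id)) return(c(p$x, p$y))
  }
  c(0, 0)
}

render_entity <- function(diagram, e) {
  st <- glyph_style(e$kind)
  stroke <- if (!is.null(e$color)) e$color else st$stroke
  out <- sprintf('<g id="%s">', esc_attr(e$id))
  g <- e$geometry
  if (st$shape %in% c("rounded-rect", "rect", "dashed-enclosure") &&
      !is.null(g)) {
    extra <- switch(st$shape,
                    "rounded-rect" = ' rx="8"',
                    "dashed-enclosure" = ' stroke-dasharray="5,3"',
                    "")
    out <- c(out, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s"%s/>',
      fmt_num(g$centerX - g$width / 2), fmt_num(g$centerY - g$height / 2),
      fmt_num(g$width), fmt_num(g$height), st$fill, stroke, extra))
    if (nzchar(e$label))
      out <- c(out, svg_text(g$centerX, g$centerY + st$fontSize / 3,
                             e$label, st$fontSize))
  } else if (st$shape == "label-only" && !is.null(g)) {
    out <- c(out, svg_text(g$centerX, g$centerY + st$fontSize / 3,
                           e$label, st$fontSize))
  } else if (st$shape == "empty-set-symbol" && !is.null(g)) {
    r <- min(g$width, g$height) / 2
    out <- c(out, sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="none" stroke="%s"/>',
      fmt_num(g$centerX), fmt_num(g$centerY), fmt_num(r), stroke),
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s"/>',
              fmt_num(g$centerX - r), fmt_num(g$centerY + r),
              fmt_num(g$centerX + r), fmt_num(g$centerY - r), stroke))
  } else if (st$shape == "filled-dot") {
    xy <- dot_position(diagram, e)
    out <- c(out, sprintf('<circle cx="%s" cy="%s" r="4" fill="%s"/>',
                          fmt_num(xy[1]), fmt_num(xy[2]), st$fill))
  }
  c(out, "</g>")
}

render_polyline <- function(points, start_head, end_head) {
  coords <- paste(vapply(points, function(p)
    paste0(fmt_num(p$x), ",", fmt_num(p$y)), ""), collapse = " ")
  markers <- paste0(
    if (!identical(start_head, "none"))
      sprintf(' marker-start="url(#mk-%s)"', start_head) else "",
    if (!identical(end_head, "none"))
      sprintf(' marker-end="url(#mk-%s)"', end_head) else "")
  sprintf('<polyline points="%s" fill="none" stroke="#000"%s/>',
          coords, markers)
}

render_interaction <- function(i) {
  pts <- i$points
  out <- sprintf('<g id="%s">', esc_attr(i$id))
  out <- c(out, render_polyline(pts, pts[[1]]$arrowhead,
                                pts[[length(pts)]]$arrowhead))
  for (b in i$branches) {
    p0 <- pts[[1]]; p1 <- pts[[length(pts)]]
    t <- if (is.null(b$position)) 0.5 else b$position
    origin <- mim_point(p0$x + t * (p1$x - p0$x), p0$y + t * (p1$y - p0$y))
    bp <- c(list(origin), b$points)
    out <- c(out, render_polyline(
      bp, "none", b$points[[length(b$points)]]$arrowhead))
  }
  if (isTRUE(i$intramolecular)) {
    p0 <- pts[[1]]; p1 <- pts[[length(pts)]]
    out <- c(out, svg_text((p0$x + p1$x) / 2, (p0$y + p1$y) / 2 - 6,
                           "intra", 9))
  }
  for (a in i$anchors) {
    p0 <- pts[[1]]; p1 <- pts[[length(pts)]]
    out <- c(out, sprintf(
      '<circle id="%s" cx="%s" cy="%s" r="2.5" fill="#fff" stroke="#000"/>',
      esc_attr(a$id),
      fmt_num(p0$x + a$position * (p1$x - p0$x)),
      fmt_num(p0$y + a$position * (p1$y - p0$y))))
  }
  c(out, "</g>")
}

#' Render a diagram to SVG
#'
#' Draws every glyph of the MIM vocabulary: labeled rounded rectangles for
#' simple physical entities, rectangles for conceptual entities,
#' borderless labels for modifiers, the empty-set symbol for source/sink,
#' filled dots for explicit complexes and restricted copies, dashed
#' enclosures for implicit complexes, and polylines with per-type arrowhead
#' markers for interactions. Rendering is byte-deterministic for equal
#' models. Structurally invalid diagrams are refused.
#'
#' @param diagram a structurally valid \code{mim_diagram}.
#' @param path optional file path to write the SVG to.
#' @return The SVG document as a single string.
#' @examples
#' svg <- render_svg(worked_example("trimer"))
#' @export
render_svg <- function(diagram, path = NULL) {
  stopifnot(inherits(diagram, "mim_diagram"))
  structural <- diagram_structure_findings(diagram)
  if (length(structural))
    stop_mim("mim_model_error", "refusing to render a structurally ",
             "invalid diagram: ", structural[[1]]$message)
  used <- unique(unlist(lapply(diagram$interactions, function(i) {
    c(vapply(i$points, `[[`, "", "arrowhead"),
      unlist(lapply(i$branches, function(b)
        vapply(b$points, `[[`, "", "arrowhead"))))
  })))
  used <- sort_ids(as.character(setdiff(used, "none")))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt_num(diagram$width), fmt_num(diagram$height),
            fmt_num(diagram$width), fmt_num(diagram$height)),
    if (length(used)) c("<defs>", vapply(used, marker_for, ""), "</defs>"))
  for (id in sort_ids(names(diagram$interactions)))
    lines <- c(lines, render_interaction(diagram$interactions[[id]]))
  for (id in sort_ids(names(diagram$entities)))
    lines <- c(lines, render_entity(diagram, diagram$entities[[id]]))
  lines <- c(lines, "</svg>")
  doc <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(doc), con)
    return(invisible(doc))
  }
  doc
}
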