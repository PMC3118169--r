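#' Closed vocabularies of the MIM notation
#'
#' The MIM notation is a closed glyph system: eight entity glyph kinds,
#' twelve interaction types falling into three categories, and a fixed set
#' of arrowhead tokens. Ad hoc glyph creation is not permitted; any token
#' outside these lists is a structural error at validation time.
#'
#' @return A character vector of the tokens in the vocabulary.
#' @examples
#' mim_entity_kinds()
#' mim_interaction_types()
#' mim_interaction_category("stimulation")
#' @name mim-vocab
NULL

#' @rdname mim-vocab
#' @export
mim_entity_kinds <- function() {
  c("simple-physical-entity", "entity-feature", "restricted-copy",
    "modifier", "conceptual-entity", "source-sink",
    "explicit-complex", "implicit-complex")
}

# interaction type -> category map; the single source of truth for the
# three-category taxonomy (reaction / contingency / catalysis)
.interaction_categories <- c(
  "non-covalent-reversible-binding" = "reaction",
  "covalent-irreversible-binding"   = "reaction",
  "covalent-modification"           = "reaction",
  "stoichiometric-conversion"       = "reaction",
  "production-without-loss"         = "reaction",
  "template-reaction"               = "reaction",
  "cleavage"                        = "reaction",
  "state-combination"               = "reaction",
  "stimulation"                     = "contingency",
  "necessary-stimulation"           = "contingency",
  "inhibition"                      = "contingency",
  "catalysis"                       = "catalysis"
)

#' @rdname mim-vocab
#' @export
mim_interaction_types <- function() {
  names(.interaction_categories)
}

#' @rdname mim-vocab
#' @param type an interaction type token.
#' @export
mim_interaction_category <- function(type) {
  out <- unname(.interaction_categories[type])
  if (anyNA(out)) stop("unknown interaction type: ",
                       paste(type[is.na(out)], collapse = ", "))
  out
}

#' @rdname mim-vocab
#' @export
mim_interaction_categories <- function() {
  unique(unname(.interaction_categories))
}

#' @rdname mim-vocab
#' @export
mim_arrowhead_tokens <- function() {
  c("none", "barbed", "barbed-covalent", "filled-triangle",
    "production-mark", "template-mark", "cleavage-mark",
    "state-combination-mark", "open-triangle", "open-triangle-bar",
    "bar", "catalysis-mark")
}

#' @rdname mim-vocab
#' @export
mim_bio_types <- function() {
  c("protein", "dna", "rna", "small-molecule", "complex",
    "physical-entity", "other")
}

#' @rdname mim-vocab
#' @export
mim_xref_relationships <- function() {
  c("identity", "see-also")
}

# terminal arrowhead signature per interaction type: c(start, end).
# Symmetric types carry the same mark at both ends; directed types carry
# their mark at the end ("the line terminus without an arrowhead is the
# start").
.arrowhead_signatures <- list(
  "non-covalent-reversible-binding" = c("barbed", "barbed"),
  "covalent-irreversible-binding"   = c("barbed-covalent", "barbed-covalent"),
  "covalent-modification"           = c("none", "barbed"),
  "stoichiometric-conversion"       = c("none", "filled-triangle"),
  "production-without-loss"         = c("none", "production-mark"),
  "template-reaction"               = c("none", "template-mark"),
  "cleavage"                        = c("none", "cleavage-mark"),
  "state-combination"               = c("state-combination-mark",
                                        "state-combination-mark"),
  "stimulation"                     = c("none", "open-triangle"),
  "necessary-stimulation"           = c("none", "open-triangle-bar"),
  "inhibition"                      = c("none", "bar"),
  "catalysis"                       = c("none", "catalysis-mark")
)

#' Arrowhead signature of an interaction type
#'
#' Every interaction type has a fixed pair of terminal arrowhead tokens:
#' symmetric types (reversible/irreversible binding, state combination)
#' carry the same mark on both ends; all other types are directed with a
#' plain start and a type-specific end mark.
#'
#' @param type an interaction type token.
#' @return Character vector of length 2: the start and end arrowhead tokens.
#' @export
mim_arrowhead_signature <- function(type) {
  sig <- .arrowhead_signatures[[type]]
  if (is.null(sig)) stop("unknown interaction type: ", type)
  sig
}

.symmetric_types <- c("non-covalent-reversible-binding",
                      "covalent-irreversible-binding",
                      "state-combination")

.branchable_types <- c("stoichiometric-conversion", "production-without-loss",
                       "template-reaction", "cleavage")

#' @rdname mim-vocab
#' @export
mim_symmetric_types <- function() .symmetric_types

#' @rdname mim-vocab
#' @export
mim_branchable_types <- function() .branchable_types

# interaction types that may carry an explicit-complex node on the line
.explicit_complex_hosts <- c("covalent-modification",
                             "non-covalent-reversible-binding",
                             "covalent-irreversible-binding",
                             "state-combination")

#' Interaction types that may host an explicit complex
#'
#' An explicit complex is a filled dot on an interaction line denoting the
#' bound (or modified) product. Only four interaction types may carry one:
#' covalent modification, non-covalent reversible binding, covalent
#' irreversible binding, and state combination.
#'
#' @return Character vector of the four allowed interaction types.
#' @export
mim_explicit_complex_hosts <- function() .explicit_complex_hosts

is_identifier <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", x)
}

check_identifier <- function(x, what = "identifier") {
  if (!is_identifier(x)) {
    stop(what, " must match [A-Za-z_][A-Za-z0-9_.-]*, got: ",
         deparse(substitute(x)), " = ",
         if (is.character(x)) paste0("'", x, "'") else class(x)[1],
         call. = FALSE)
  }
  invisible(x)
}
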