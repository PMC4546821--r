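# In-memory pathway document model: typed, identifier-annotated nodes and
# interactions with centre-based geometry (y grows downward, abstract units).

NODE_TYPES <- c("GeneProduct", "Protein", "Metabolite", "Rna", "Pathway", "Unknown")
INTERACTION_TYPES <- c("line", "arrow", "t-bar", "conversion", "catalysis")

# Default node extent in diagram units (GPML-typical gene box).
DEFAULT_NODE_WIDTH <- 80
DEFAULT_NODE_HEIGHT <- 20
DEFAULT_BOARD_WIDTH <- 500
DEFAULT_BOARD_HEIGHT <- 500

# Auto-layout grid for nodes added without coordinates: left-to-right rows
# of 10, fixed cell pitch.
LAYOUT_COLS <- 10L
LAYOUT_PITCH_X <- 100
LAYOUT_PITCH_Y <- 40

#' Create a database cross-reference
#'
#' An `xref` pairs an external database accession with the short system
#' code of the database it comes from (see [system_codes()]).
#'
#' @param identifier Accession string; must be non-empty.
#' @param system_code Registered datasource code, e.g. `"L"` (Entrez Gene)
#'   or `"En"` (Ensembl).
#' @return An object of class `xref`.
#' @export
#' @examples
#' xref("1234", "L")
xref <- function(identifier, system_code) {
  check_system_code(system_code)
  if (!is.character(identifier) || length(identifier) != 1L || !nzchar(identifier)) {
    stop("xref identifier must be a non-empty string", call. = FALSE)
  }
  structure(list(identifier = identifier, system_code = system_code),
            class = "xref")
}

#' @export
print.xref <- function(x, ...) {
  cat(sprintf("<xref %s:%s>\n", x$system_code, x$identifier))
  invisible(x)
}

#' Create an empty pathway document
#'
#' A pathway document holds an ordered collection of data nodes,
#' interactions and free labels on a drawing board.  Documents have
#' reference semantics: the editing operations ([add_data_node()],
#' [add_interaction()], [remove_element()]) modify the document in place
#' and return the id of the element they touched.
#'
#' @param name Pathway title; must be non-empty.
#' @param organism Latin binomial of the species, e.g. `"Mus musculus"`.
#' @param board_width,board_height Drawing extents in diagram units.
#' @return An object of class `PathwayDoc`.
#' @export
#' @examples
#' doc <- create_pathway("Glycolysis", "Homo sapiens")
#' element_count(doc)
create_pathway <- function(name, organism = "Homo sapiens",
                           board_width = DEFAULT_BOARD_WIDTH,
                           board_height = DEFAULT_BOARD_HEIGHT) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("pathway name must be a non-empty string", call. = FALSE)
  }
  if (!is.character(organism) || length(organism) != 1L) {
    stop("organism must be a string", call. = FALSE)
  }
  doc <- new.env(parent = emptyenv())
  doc$name <- name
  doc$organism <- organism
  doc$board_width <- as.numeric(board_width)
  doc$board_height <- as.numeric(board_height)
  doc$elements <- list()      # named by element_id, insertion-ordered
  doc$passthrough <- character(0)  # opaque XML blobs preserved on read
  doc$next_id <- 1L
  class(doc) <- "PathwayDoc"
  doc
}

#' @export
print.PathwayDoc <- function(x, ...) {
  kinds <- vapply(x$elements, `[[`, "", "kind")
  cat(sprintf("<PathwayDoc \"%s\" (%s): %d data nodes, %d interactions, %d labels>\n",
              x$name, x$organism,
              sum(kinds == "DataNode"), sum(kinds == "Interaction"),
              sum(kinds == "Label")))
  invisible(x)
}

is_pathway_doc <- function(x) inherits(x, "PathwayDoc")

new_element_id <- function(doc, prefix) {
  repeat {
    id <- sprintf("%s%d", prefix, doc$next_id)
    doc$next_id <- doc$next_id + 1L
    if (is.null(doc$elements[[id]])) return(id)
  }
}

#' Number of elements in a pathway document
#' @param doc A `PathwayDoc`.
#' @param kind Optional filter: `"DataNode"`, `"Interaction"` or `"Label"`.
#' @return Integer count.
#' @export
element_count <- function(doc, kind = NULL) {
  stopifnot(is_pathway_doc(doc))
  if (is.null(kind)) return(length(doc$elements))
  sum(vapply(doc$elements, `[[`, "", "kind") == kind)
}

#' Retrieve an element by id
#' @param doc A `PathwayDoc`.
#' @param element_id Element id string.
#' @return The element record (a list), or an error for unknown ids.
#' @export
get_element <- function(doc, element_id) {
  stopifnot(is_pathway_doc(doc))
  el <- doc$elements[[element_id]]
  if (is.null(el)) stop(sprintf("no element with id %s", dQuote(element_id)), call. = FALSE)
  el
}

#' Ids of all elements (optionally of one kind)
#' @inheritParams element_count
#' @return Character vector of element ids in insertion order.
#' @export
element_ids <- function(doc, kind = NULL) {
  stopifnot(is_pathway_doc(doc))
  ids <- names(doc$elements)
  if (is.null(kind)) return(ids)
  ids[vapply(doc$elements, `[[`, "", "kind") == kind]
}

grow_board <- function(doc, x2, y2) {
  doc$board_width <- max(doc$board_width, x2 + 20)
  doc$board_height <- max(doc$board_height, y2 + 20)
}

#' Add a data node to a pathway
#'
#' Data nodes represent biological entities (gene products, proteins,
#' metabolites, RNAs, sub-pathways).  Nodes added without coordinates are
#' placed on a grid, left to right in rows of ten, so that bare gene lists
#' can be turned into a diagram without manual layout.
#'
#' @param doc A `PathwayDoc` (modified in place).
#' @param label Display text.
#' @param node_type One of `"GeneProduct"`, `"Protein"`, `"Metabolite"`,
#'   `"Rna"`, `"Pathway"`, `"Unknown"`.
#' @param xref Optional [xref()] annotating the node.
#' @param cx,cy Centre coordinates in diagram units (y grows downward);
#'   `NULL` for auto-layout.
#' @param width,height Node extents in diagram units; must be positive.
#' @return The new element id, invisibly the same string.
#' @export
#' @examples
#' doc <- create_pathway("Toy", "Mus musculus")
#' id <- add_data_node(doc, "Fos", "GeneProduct", xref("14281", "L"))
#' get_element(doc, id)$label
add_data_node <- function(doc, label, node_type = "GeneProduct", xref = NULL,
                          cx = NULL, cy = NULL,
                          width = DEFAULT_NODE_WIDTH, height = DEFAULT_NODE_HEIGHT) {
  stopifnot(is_pathway_doc(doc))
  if (!node_type %in% NODE_TYPES) {
    stop(sprintf("unknown node_type %s; expected one of %s",
                 dQuote(node_type), paste(NODE_TYPES, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(xref) && !inherits(xref, "xref")) {
    stop("xref must be created with xref()", call. = FALSE)
  }
  if (!is.numeric(width) || width <= 0 || !is.numeric(height) || height <= 0) {
    stop("node width and height must be positive", call. = FALSE)
  }
  if (is.null(cx) || is.null(cy)) {
    k <- element_count(doc, "DataNode")
    cx <- LAYOUT_PITCH_X * (k %% LAYOUT_COLS) + LAYOUT_PITCH_X / 2
    cy <- LAYOUT_PITCH_Y * (k %/% LAYOUT_COLS) + LAYOUT_PITCH_Y / 2
  }
  if (!is.finite(cx) || !is.finite(cy)) {
    stop("node coordinates must be finite", call. = FALSE)
  }
  id <- new_element_id(doc, "dn")
  doc$elements[[id]] <- list(
    kind = "DataNode", element_id = id, label = as.character(label),
    node_type = node_type, xref = xref,
    cx = as.numeric(cx), cy = as.numeric(cy),
    width = as.numeric(width), height = as.numeric(height)
  )
  grow_board(doc, cx + width / 2, cy + height / 2)
  id
}

#' Add a free text label
#' @inheritParams add_data_node
#' @param text Label text.
#' @return The new element id.
#' @export
add_label <- function(doc, text, cx = NULL, cy = NULL,
                      width = DEFAULT_NODE_WIDTH, height = DEFAULT_NODE_HEIGHT) {
  stopifnot(is_pathway_doc(doc))
  if (is.null(cx) || is.null(cy)) {
    cx <- doc$board_width / 2
    cy <- 20
  }
  id <- new_element_id(doc, "lb")
  doc$elements[[id]] <- list(
    kind = "Label", element_id = id, label = as.character(text),
    cx = as.numeric(cx), cy = as.numeric(cy),
    width = as.numeric(width), height = as.numeric(height)
  )
  grow_board(doc, cx + width / 2, cy + height / 2)
  id
}

#' Add an interaction between two elements
#'
#' @param doc A `PathwayDoc` (modified in place).
#' @param source_id,target_id Element ids of the endpoints; both must
#'   exist in `doc`.
#' @param interaction_type One of `"line"`, `"arrow"`, `"t-bar"`,
#'   `"conversion"`, `"catalysis"`.
#' @param xref Optional [xref()].
#' @return The new element id.
#' @export
add_interaction <- function(doc, source_id, target_id,
                            interaction_type = "arrow", xref = NULL) {
  stopifnot(is_pathway_doc(doc))
  if (!interaction_type %in% INTERACTION_TYPES) {
    stop(sprintf("unknown interaction_type %s", dQuote(interaction_type)), call. = FALSE)
  }
  for (ref in c(source_id, target_id)) {
    if (is.null(doc$elements[[ref]])) {
      stop(sprintf("interaction endpoint %s does not resolve to an element",
                   dQuote(ref)), call. = FALSE)
    }
  }
  id <- new_element_id(doc, "ix")
  doc$elements[[id]] <- list(
    kind = "Interaction", element_id = id,
    source_ref = source_id, target_ref = target_id,
    interaction_type = interaction_type, xref = xref,
    dangling = FALSE
  )
  id
}

#' Remove an element from a pathway
#'
#' Interactions whose endpoint is removed are kept but flagged dangling
#' (least surprise for scripted edits); [validate_pathway()] reports them.
#'
#' @param doc A `PathwayDoc` (modified in place).
#' @param element_id Id of the element to remove; must exist.
#' @return The document, invisibly.
#' @export
remove_element <- function(doc, element_id) {
  stopifnot(is_pathway_doc(doc))
  if (is.null(doc$elements[[element_id]])) {
    stop(sprintf("no element with id %s", dQuote(element_id)), call. = FALSE)
  }
  doc$elements[[element_id]] <- NULL
  for (id in names(doc$elements)) {
    el <- doc$elements[[id]]
    if (el$kind == "Interaction" &&
        (identical(el$source_ref, element_id) || identical(el$target_ref, element_id))) {
      doc$elements[[id]]$dangling <- TRUE
    }
  }
  invisible(doc)
}

#' Validate a pathway document
#'
#' Checks the structural invariants: unique element ids, positive node
#' extents, resolvable interaction endpoints.  Self-loops and dangling
#' interactions are reported as warnings, not errors.
#'
#' @param doc A `PathwayDoc`.
#' @return List with character vectors `errors` and `warnings`; valid
#'   documents have zero errors.
#' @export
validate_pathway <- function(doc) {
  stopifnot(is_pathway_doc(doc))
  errors <- character(0)
  warnings <- character(0)
  ids <- names(doc$elements)
  if (anyDuplicated(ids)) {
    errors <- c(errors, sprintf("duplicate element id: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (el in doc$elements) {
    if (el$kind %in% c("DataNode", "Label")) {
      if (el$width <= 0 || el$height <= 0) {
        errors <- c(errors, sprintf("%s: non-positive extent", el$element_id))
      }
    } else if (el$kind == "Interaction") {
      miss <- c(el$source_ref, el$target_ref)
      miss <- miss[!miss %in% ids]
      if (length(miss)) {
        warnings <- c(warnings, sprintf("%s: dangling endpoint %s",
                                        el$element_id, paste(miss, collapse = ", ")))
      } else if (isTRUE(el$dangling)) {
        warnings <- c(warnings, sprintf("%s: flagged dangling", el$element_id))
      }
      if (identical(el$source_ref, el$target_ref)) {
        warnings <- c(warnings, sprintf("%s: self-loop", el$element_id))
      }
    }
  }
  list(errors = errors, warnings = warnings)
}

#' Semantic equality of two pathway documents
#'
#' Compares names, organisms, element ids, types, xrefs and geometry
#' (coordinates within `tol`); pass-through blobs must match verbatim.
#'
#' @param a,b `PathwayDoc` objects.
#' @param tol Numeric tolerance for geometry comparison.
#' @return `TRUE` or `FALSE`.
#' @export
pathway_equal <- function(a, b, tol = 1e-9) {
  stopifnot(is_pathway_doc(a), is_pathway_doc(b))
  if (!identical(a$name, b$name) || !identical(a$organism, b$organism)) return(FALSE)
  if (abs(a$board_width - b$board_width) > tol) return(FALSE)
  if (abs(a$board_height - b$board_height) > tol) return(FALSE)
  if (!identical(names(a$elements), names(b$elements))) return(FALSE)
  if (!identical(a$passthrough, b$passthrough)) return(FALSE)
  num_eq <- function(x, y) abs(x - y) <= tol
  for (id in names(a$elements)) {
    ea <- a$elements[[id]]; eb <- b$elements[[id]]
    if (!identical(ea$kind, eb$kind)) return(FALSE)
    if (ea$kind %in% c("DataNode", "Label")) {
      if (!identical(ea$label, eb$label)) return(FALSE)
      if (!num_eq(ea$cx, eb$cx) || !num_eq(ea$cy, eb$cy) ||
          !num_eq(ea$width, eb$width) || !num_eq(ea$height, eb$height)) return(FALSE)
    }
    if (ea$kind == "DataNode") {
      if (!identical(ea$node_type, eb$node_type)) return(FALSE)
      if (!identical(ea$xref, eb$xref)) return(FALSE)
    }
    if (ea$kind == "Interaction") {
      if (!identical(ea$source_ref, eb$source_ref) ||
          !identical(ea$target_ref, eb$target_ref) ||
          !identical(ea$interaction_type, eb$interaction_type) ||
          !identical(ea$xref, eb$xref)) return(FALSE)
    }
  }
  TRUE
}
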