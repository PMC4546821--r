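# GPML-dialect XML input/output.
#
# The dialect is a GPML-2013a-like subset: a <Pathway> root carrying Name
# and Organism attributes and a <Graphics BoardWidth BoardHeight> child;
# <DataNode> / <Label> elements with a <Graphics CenterX CenterY Width
# Height> child and an optional <Xref Database ID> child (Database holds
# the short system code); <Interaction> elements referencing endpoint
# GraphIds through Source/Target attributes.  Unrecognised children of the
# root are preserved as opaque pass-through blobs and re-emitted verbatim.
# Writing is manual string assembly with a fixed attribute order and fixed
# number formatting, so the same document always produces the same bytes.

GPML_XMLNS <- "http://pathvisio.org/GPML/2013a"

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# 15 significant digits: enough for string -> double -> string stability.
fmt_num <- function(x) {
  s <- formatC(x, format = "g", digits = 15, width = 1)
  sub("^\\s+", "", s)
}

#' Serialise a pathway document to GPML
#'
#' @param doc A `PathwayDoc`; must pass [validate_pathway()] with zero
#'   errors.
#' @param destination File path, or `NULL` to return the XML as a string.
#' @return The XML string, invisibly when written to a file.
#' @seealso [read_gpml()]
#' @export
write_gpml <- function(doc, destination = NULL) {
  stopifnot(is_pathway_doc(doc))
  v <- validate_pathway(doc)
  if (length(v$errors)) {
    stop(paste0("invalid pathway document: ", paste(v$errors, collapse = "; ")),
         call. = FALSE)
  }
  out <- character(0)
  add <- function(...) out <<- c(out, sprintf(...))
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<Pathway xmlns="%s" Name="%s" Organism="%s">',
      GPML_XMLNS, xml_escape(doc$name), xml_escape(doc$organism))
  add('  <Graphics BoardWidth="%s" BoardHeight="%s"/>',
      fmt_num(doc$board_width), fmt_num(doc$board_height))
  xref_line <- function(x, indent) {
    if (is.null(x)) return(NULL)
    sprintf('%s<Xref Database="%s" ID="%s"/>', indent,
            xml_escape(x$system_code), xml_escape(x$identifier))
  }
  for (el in doc$elements) {
    if (el$kind == "DataNode") {
      add('  <DataNode GraphId="%s" TextLabel="%s" Type="%s">',
          xml_escape(el$element_id), xml_escape(el$label), el$node_type)
      add('    <Graphics CenterX="%s" CenterY="%s" Width="%s" Height="%s"/>',
          fmt_num(el$cx), fmt_num(el$cy), fmt_num(el$width), fmt_num(el$height))
      xl <- xref_line(el$xref, "    ")
      if (!is.null(xl)) out <- c(out, xl)
      add('  </DataNode>')
    } else if (el$kind == "Label") {
      add('  <Label GraphId="%s" TextLabel="%s">',
          xml_escape(el$element_id), xml_escape(el$label))
      add('    <Graphics CenterX="%s" CenterY="%s" Width="%s" Height="%s"/>',
          fmt_num(el$cx), fmt_num(el$cy), fmt_num(el$width), fmt_num(el$height))
      add('  </Label>')
    } else if (el$kind == "Interaction") {
      xl <- xref_line(el$xref, "    ")
      if (is.null(xl)) {
        add('  <Interaction GraphId="%s" Source="%s" Target="%s" Type="%s"/>',
            xml_escape(el$element_id), xml_escape(el$source_ref),
            xml_escape(el$target_ref), el$interaction_type)
      } else {
        add('  <Interaction GraphId="%s" Source="%s" Target="%s" Type="%s">',
            xml_escape(el$element_id), xml_escape(el$source_ref),
            xml_escape(el$target_ref), el$interaction_type)
        out <- c(out, xl)
        add('  </Interaction>')
      }
    }
  }
  for (blob in doc$passthrough) {
    out <- c(out, paste0("  ", blob))
  }
  add('</Pathway>')
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(destination)) return(txt)
  con <- file(destination, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(txt), con)
  invisible(txt)
}

num_attr <- function(node, attr, default = NA_real_) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) return(default)
  as.numeric(v)
}

read_xref_child <- function(node) {
  xr <- xml2::xml_find_first(node, "./Xref")
  if (inherits(xr, "xml_missing")) return(NULL)
  id <- xml2::xml_attr(xr, "ID")
  db <- xml2::xml_attr(xr, "Database")
  if (is.na(id) || is.na(db) || !nzchar(id)) return(NULL)
  if (!is_registered_code(db)) register_system_code(db, db)
  xref(id, db)
}

#' Read a GPML-dialect pathway document
#'
#' Recognised elements (`DataNode`, `Interaction`, `Label`) are loaded into
#' the document model; any other child of the root is preserved as an
#' opaque pass-through blob and re-emitted verbatim by [write_gpml()].
#' Interactions whose endpoints do not resolve are kept and flagged
#' dangling.
#'
#' @param source File path, XML string, or raw vector.
#' @return A `PathwayDoc`.
#' @export
read_gpml <- function(source) {
  x <- tryCatch(
    xml2::read_xml(source),
    error = function(e) stop("GPML parse error: ", conditionMessage(e), call. = FALSE)
  )
  xml2::xml_ns_strip(x)
  if (xml2::xml_name(x) != "Pathway") {
    stop(sprintf("unsupported root element <%s>: expected <Pathway>", xml2::xml_name(x)),
         call. = FALSE)
  }
  name <- xml2::xml_attr(x, "Name")
  organism <- xml2::xml_attr(x, "Organism")
  if (is.na(name) || !nzchar(name)) name <- "Untitled"
  if (is.na(organism)) organism <- ""
  doc <- create_pathway(name, organism)
  auto <- 0L
  take_id <- function(node, prefix) {
    id <- xml2::xml_attr(node, "GraphId")
    if (is.na(id) || !nzchar(id) || !is.null(doc$elements[[id]])) {
      auto <<- auto + 1L
      id <- sprintf("%s_auto%d", prefix, auto)
    }
    id
  }
  board_seen <- FALSE
  for (child in xml2::xml_children(x)) {
    nm <- xml2::xml_name(child)
    if (nm == "Graphics" && !board_seen) {
      doc$board_width <- num_attr(child, "BoardWidth", DEFAULT_BOARD_WIDTH)
      doc$board_height <- num_attr(child, "BoardHeight", DEFAULT_BOARD_HEIGHT)
      board_seen <- TRUE
    } else if (nm == "DataNode") {
      g <- xml2::xml_find_first(child, "./Graphics")
      id <- take_id(child, "dn")
      type <- xml2::xml_attr(child, "Type")
      if (is.na(type) || !type %in% NODE_TYPES) type <- "Unknown"
      doc$elements[[id]] <- list(
        kind = "DataNode", element_id = id,
        label = xml2::xml_attr(child, "TextLabel", default = ""),
        node_type = type,
        xref = read_xref_child(child),
        cx = num_attr(g, "CenterX", 0), cy = num_attr(g, "CenterY", 0),
        width = num_attr(g, "Width", DEFAULT_NODE_WIDTH),
        height = num_attr(g, "Height", DEFAULT_NODE_HEIGHT)
      )
    } else if (nm == "Label") {
      g <- xml2::xml_find_first(child, "./Graphics")
      id <- take_id(child, "lb")
      doc$elements[[id]] <- list(
        kind = "Label", element_id = id,
        label = xml2::xml_attr(child, "TextLabel", default = ""),
        cx = num_attr(g, "CenterX", 0), cy = num_attr(g, "CenterY", 0),
        width = num_attr(g, "Width", DEFAULT_NODE_WIDTH),
        height = num_attr(g, "Height", DEFAULT_NODE_HEIGHT)
      )
    } else if (nm == "Interaction") {
      id <- take_id(child, "ix")
      type <- xml2::xml_attr(child, "Type")
      if (is.na(type) || !type %in% INTERACTION_TYPES) type <- "line"
      doc$elements[[id]] <- list(
        kind = "Interaction", element_id = id,
        source_ref = xml2::xml_attr(child, "Source", default = ""),
        target_ref = xml2::xml_attr(child, "Target", default = ""),
        interaction_type = type,
        xref = read_xref_child(child),
        dangling = FALSE
      )
    } else {
      blob <- sub("\\s+$", "", as.character(child))
      doc$passthrough <- c(doc$passthrough, blob)
    }
  }
  ids <- names(doc$elements)
  for (id in ids) {
    el <- doc$elements[[id]]
    if (el$kind == "Interaction" &&
        (!el$source_ref %in% ids || !el$target_ref %in% ids)) {
      doc$elements[[id]]$dangling <- TRUE
    }
  }
  doc$next_id <- length(doc$elements) + 1L
  doc
}

#' Load every GPML file in a directory
#'
#' @param dir Directory containing `*.gpml` files.
#' @return Named list of `PathwayDoc` objects; names are the file paths.
#' @export
read_gpml_collection <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.gpml$", full.names = TRUE))
  if (!length(files)) stop(sprintf("no .gpml files found in %s", dQuote(dir)), call. = FALSE)
  docs <- lapply(files, read_gpml)
  names(docs) <- files
  docs
}
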