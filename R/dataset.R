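# Measurement-table import and linking of rows to pathway nodes.

sniff_delim <- function(header_line) {
  # tab preferred, comma fallback
  if (grepl("\t", header_line, fixed = TRUE)) "\t" else ","
}

#' Import a delimited measurement table
#'
#' Reads a tab- or comma-delimited text file (delimiter sniffed from the
#' header line, tab preferred) with one identifier column, an optional
#' system-code column, and any number of value columns.  Value columns in
#' which every non-missing cell parses as a number are stored numeric;
#' unparseable cells are retained as text.  Missing cells are empty or
#' `"NA"`.
#'
#' @param path Input file.
#' @param id_column Name of the identifier column.
#' @param syscode Either the name of a column holding per-row system
#'   codes, or a registered fixed code (e.g. `"L"`) applied to every row.
#' @return A `MeasurementTable`: list with `data` (data frame whose first
#'   two columns are `identifier` and `system_code`), `value_columns`, and
#'   provenance fields.
#' @export
import_data <- function(path, id_column, syscode) {
  if (!file.exists(path)) stop(sprintf("data file not found: %s", dQuote(path)), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty data file", call. = FALSE)
  if (length(lines) == 1L) stop("data file has a header but no rows", call. = FALSE)
  delim <- sniff_delim(lines[[1L]])
  raw <- utils::read.table(text = lines, header = TRUE, sep = delim,
                           colClasses = "character", quote = "\"",
                           check.names = FALSE, comment.char = "",
                           na.strings = character(0))
  if (!id_column %in% names(raw)) {
    stop(sprintf("identifier column %s not present in file", dQuote(id_column)), call. = FALSE)
  }
  if (syscode %in% names(raw)) {
    codes <- raw[[syscode]]
    code_col <- syscode
  } else {
    check_system_code(syscode, "fixed system code")
    codes <- rep(syscode, nrow(raw))
    code_col <- NULL
  }
  value_cols <- setdiff(names(raw), c(id_column, code_col))
  data <- data.frame(identifier = raw[[id_column]], system_code = codes,
                     stringsAsFactors = FALSE, check.names = FALSE)
  for (col in value_cols) {
    cell <- raw[[col]]
    cell[cell %in% c("", "NA")] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    if (all(is.na(num) == is.na(cell))) data[[col]] <- num else data[[col]] <- cell
  }
  structure(list(data = data, value_columns = value_cols, path = path,
                 id_column = id_column, syscode = syscode),
            class = "MeasurementTable")
}

#' Construct a measurement table from a data frame
#'
#' In-memory counterpart of [import_data()] for programmatic use.
#'
#' @param df Data frame with an identifier column and value columns.
#' @inheritParams import_data
#' @return A `MeasurementTable`.
#' @export
as_measurement_table <- function(df, id_column = "identifier", syscode = "L") {
  stopifnot(is.data.frame(df), id_column %in% names(df))
  if (syscode %in% names(df)) {
    codes <- as.character(df[[syscode]]); code_col <- syscode
  } else {
    check_system_code(syscode, "fixed system code")
    codes <- rep(syscode, nrow(df)); code_col <- NULL
  }
  value_cols <- setdiff(names(df), c(id_column, code_col))
  data <- data.frame(identifier = as.character(df[[id_column]]),
                     system_code = codes, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in value_cols) data[[col]] <- df[[col]]
  structure(list(data = data, value_columns = value_cols, path = NA_character_,
                 id_column = id_column, syscode = syscode),
            class = "MeasurementTable")
}

#' @export
print.MeasurementTable <- function(x, ...) {
  cat(sprintf("<MeasurementTable: %d rows, %d value columns (%s)>\n",
              nrow(x$data), length(x$value_columns),
              paste(utils::head(x$value_columns, 6), collapse = ", ")))
  invisible(x)
}

table_row <- function(table, i) as.list(table$data[i, , drop = FALSE])

# Equivalence-set key of a (code, id) pair: the store's set when known,
# otherwise the singleton pair itself.
unified_key <- function(store, code, id) {
  s <- if (is.null(store)) NA_integer_ else store_set_id(store, code, id)
  if (is.na(s)) paste0("pair:", mkey(code, id)) else paste0("set:", s)
}

#' Link measurement rows to pathway nodes
#'
#' A row matches a node when the mapper connects the row's
#' `(system_code, identifier)` to the node's xref — either directly (same
#' system, same accession) or through the mapping store's equivalence
#' sets.  Nodes without an xref never match.
#'
#' @param table A `MeasurementTable`.
#' @param doc A `PathwayDoc`.
#' @param store A `MappingStore`, or `NULL` for direct identity matching
#'   only.
#' @return A `NodeDataLink`: list with `node_rows` (named list: node id ->
#'   integer row indices in file order), `row_nodes` (list: row index ->
#'   node ids), and `unmapped_nodes` (ids of data nodes with no match).
#' @export
link_to_pathway <- function(table, doc, store = NULL) {
  stopifnot(inherits(table, "MeasurementTable"), is_pathway_doc(doc))
  node_ids <- element_ids(doc, "DataNode")
  row_keys <- vapply(seq_len(nrow(table$data)), function(i) {
    unified_key(store, table$data$system_code[[i]], table$data$identifier[[i]])
  }, "")
  node_rows <- stats::setNames(vector("list", length(node_ids)), node_ids)
  row_nodes <- vector("list", nrow(table$data))
  for (nid in node_ids) {
    xr <- doc$elements[[nid]]$xref
    if (is.null(xr)) { node_rows[[nid]] <- integer(0); next }
    nk <- unified_key(store, xr$system_code, xr$identifier)
    hits <- which(row_keys == nk)
    node_rows[[nid]] <- hits
    for (i in hits) row_nodes[[i]] <- c(row_nodes[[i]], nid)
  }
  unmapped <- node_ids[vapply(node_rows, length, 0L) == 0L]
  structure(list(node_rows = node_rows, row_nodes = row_nodes,
                 unmapped_nodes = unmapped),
            class = "NodeDataLink")
}

#' @export
print.NodeDataLink <- function(x, ...) {
  cat(sprintf("<NodeDataLink: %d/%d nodes mapped>\n",
              length(x$node_rows) - length(x$unmapped_nodes), length(x$node_rows)))
  invisible(x)
}
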