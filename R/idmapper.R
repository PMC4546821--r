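# Identifier cross-mapping between datasource systems.
#
# The store is built from a flat TSV of pairwise links
# (source_code, source_id, target_code, target_id); cross-references are
# treated as an equivalence web, so the transitive closure is computed at
# load time with union-find.  Lookups are case-sensitive (database
# accessions are case-sensitive in general).

mkey <- function(code, id) paste0(code, "\r", id)

#' Load an identifier mapping table
#'
#' @param path TSV file with header columns `source_code`, `source_id`,
#'   `target_code`, `target_id`; UTF-8; lines starting with `#` are
#'   ignored.  Duplicate rows collapse.
#' @param species Optional Latin binomial recorded on the store.
#' @return A `MappingStore` object supporting bidirectional lookup.
#' @export
#' @seealso [map_identifier()], [is_known()]
load_mapping_table <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop(sprintf("mapping file not found: %s", dQuote(path)), call. = FALSE)
  tab <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      colClasses = "character", quote = "", check.names = FALSE),
    error = function(e) stop("cannot read mapping table: ", conditionMessage(e), call. = FALSE)
  )
  required <- c("source_code", "source_id", "target_code", "target_id")
  if (!all(required %in% names(tab))) {
    stop(sprintf("mapping table must have header columns %s",
                 paste(required, collapse = ", ")), call. = FALSE)
  }
  keep <- nzchar(tab$source_id) & nzchar(tab$target_id)
  tab <- tab[keep, , drop = FALSE]
  for (code in unique(c(tab$source_code, tab$target_code))) {
    if (!is_registered_code(code)) register_system_code(code, code)
  }
  keys <- unique(c(mkey(tab$source_code, tab$source_id),
                   mkey(tab$target_code, tab$target_id)))
  idx <- seq_along(keys)
  names(idx) <- keys
  parent <- idx  # union-find over key indices
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  if (nrow(tab)) {
    a <- idx[mkey(tab$source_code, tab$source_id)]
    b <- idx[mkey(tab$target_code, tab$target_id)]
    for (k in seq_along(a)) {
      ra <- find(a[[k]]); rb <- find(b[[k]])
      if (ra != rb) parent[[rb]] <- ra
    }
  }
  root <- vapply(idx, find, 0L)
  set_id <- match(root, unique(root))
  names(set_id) <- keys
  codes <- sub("\r.*$", "", keys)
  ids <- sub("^[^\r]*\r", "", keys)
  members <- data.frame(code = codes, id = ids, set = set_id,
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(set_of = set_id, members = members, species = species,
                 n_sets = length(unique(set_id))),
            class = "MappingStore")
}

#' @export
print.MappingStore <- function(x, ...) {
  cat(sprintf("<MappingStore: %d identifiers in %d equivalence sets%s>\n",
              nrow(x$members), x$n_sets,
              if (is.na(x$species)) "" else paste0(", ", x$species)))
  invisible(x)
}

#' An empty mapping store
#'
#' Useful when measurements and pathway annotations share one identifier
#' system and no cross-mapping is needed.
#' @return A `MappingStore` with no links.
#' @export
empty_mapping_store <- function() {
  structure(list(set_of = integer(0) |> stats::setNames(character(0)),
                 members = data.frame(code = character(0), id = character(0),
                                      set = integer(0), stringsAsFactors = FALSE),
                 species = NA_character_, n_sets = 0L),
            class = "MappingStore")
}

store_set_id <- function(store, code, id) {
  unname(store$set_of[mkey(code, id)])
}

#' Map an identifier into another datasource system
#'
#' @param store A `MappingStore`.
#' @param id Identifier string.
#' @param source_code,target_code Registered system codes.
#' @return Character vector (possibly empty) of identifiers in the target
#'   system equivalent to `id`.  When `source_code == target_code` the
#'   identifier passes through unchanged.
#' @export
map_identifier <- function(store, id, source_code, target_code) {
  stopifnot(inherits(store, "MappingStore"))
  check_system_code(source_code)
  check_system_code(target_code)
  if (identical(source_code, target_code)) return(id)
  s <- store_set_id(store, source_code, id)
  if (is.na(s)) return(character(0))
  m <- store$members
  sort(unique(m$id[m$set == s & m$code == target_code]))
}

#' Is an identifier known to the mapping store?
#'
#' @inheritParams map_identifier
#' @param code Registered system code of `id`.
#' @return `TRUE` iff `(code, id)` occurs in any equivalence set.
#' @export
is_known <- function(store, id, code) {
  stopifnot(inherits(store, "MappingStore"))
  check_system_code(code)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) return(FALSE)
  !is.na(store_set_id(store, code, id))
}
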