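# Registry of datasource system codes (BridgeDb-style short codes).

.pathora_state <- new.env(parent = emptyenv())

.default_system_codes <- c(
  L   = "Entrez Gene",
  En  = "Ensembl",
  H   = "HGNC",
  S   = "UniProt/TrEMBL",
  X   = "Affy",
  Ag  = "Agilent",
  Ce  = "ChEBI",
  Ca  = "CAS",
  Ch  = "HMDB",
  Cpc = "PubChem Compound",
  U   = "UniGene",
  Om  = "OMIM",
  Q   = "RefSeq",
  M   = "miRBase",
  Wg  = "Wikigene",
  T   = "GO"
)

#' System code table
#'
#' Short letter codes identify the database an identifier comes from
#' (for example `"L"` for Entrez Gene, `"En"` for Ensembl, `"Ce"` for
#' ChEBI).  The table ships seeded with the common codes and can be
#' extended at run time with [register_system_code()].
#'
#' @return Named character vector mapping code to datasource full name.
#' @export
#' @examples
#' system_codes()[["L"]]
system_codes <- function() {
  if (is.null(.pathora_state$syscodes)) {
    .pathora_state$syscodes <- .default_system_codes
  }
  .pathora_state$syscodes
}

#' Register an additional system code
#'
#' @param code Short code string (must be non-empty and not yet registered
#'   with a different name).
#' @param name Full datasource name.
#' @return The updated table, invisibly.
#' @export
register_system_code <- function(code, name) {
  stopifnot(is.character(code), length(code) == 1L, nzchar(code),
            is.character(name), length(name) == 1L)
  tab <- system_codes()
  tab[[code]] <- name
  .pathora_state$syscodes <- tab
  invisible(tab)
}

is_registered_code <- function(code) {
  is.character(code) && length(code) == 1L && code %in% names(system_codes())
}

check_system_code <- function(code, where = "system code") {
  if (!is_registered_code(code)) {
    stop(sprintf("unregistered %s: %s", where,
                 if (is.character(code) && length(code) == 1L) dQuote(code) else "<non-string>"),
         call. = FALSE)
  }
  invisible(code)
}
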