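# Batch analyses driven by an INI-style settings file, plus the compact
# string syntax for gradients and rules shared by the batch config, the
# CLI and the RPC surface.
#
# Config grammar: one [section] per data file; keys
#   data, id_column, syscode (column name or fixed code), species,
#   pathways (GPML file or directory), mapping (TSV, optional),
#   criterion (optional), gradient (repeatable), rule (repeatable), out
# '#' starts a comment; keys repeat to accumulate.
#
# Gradient strings:  column:value1:colour1,value2:colour2[,value3:colour3]
#   e.g.  logFC:-1:#0000FF,0:#FFFFFF,1:#FF0000
# Rule strings:      column:colour:criterion
#   e.g.  P.Value:#00FF00:[P.Value] <= 0.05

#' Parse a gradient definition string
#'
#' @param text `column:v1:c1,v2:c2[,v3:c3]`.
#' @return Named list with `column` and a `ColorGradient`.
#' @export
parse_gradient_string <- function(text) {
  first <- regexpr(":", text, fixed = TRUE)
  if (first < 0) stop(sprintf("bad gradient string: %s", dQuote(text)), call. = FALSE)
  column <- substr(text, 1L, first - 1L)
  anchors <- strsplit(substr(text, first + 1L, nchar(text)), ",", fixed = TRUE)[[1L]]
  parts <- strsplit(anchors, ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop(sprintf("bad gradient anchor in %s (want value:colour)", dQuote(text)), call. = FALSE)
  }
  values <- as.numeric(vapply(parts, `[[`, "", 1L))
  colors <- vapply(parts, `[[`, "", 2L)
  list(column = column, gradient = color_gradient(values, colors))
}

#' Parse a colour-rule definition string
#'
#' @param text `column:colour:criterion` (the criterion may itself
#'   contain colons).
#' @return Named list with `column` and a `ColorRule`.
#' @export
parse_rule_string <- function(text) {
  m <- regmatches(text, regexec("^([^:]+):([^:]+):(.+)$", text))[[1L]]
  if (length(m) != 4L) stop(sprintf("bad rule string: %s", dQuote(text)), call. = FALSE)
  list(column = m[[2L]], rule = color_rule(trimws(m[[4L]]), m[[3L]]))
}

#' Build a visualisation spec from gradient and rule strings
#'
#' Entries keep the order gradients-then-rules as given; several rule
#' strings naming the same column form one ordered rule list.
#'
#' @param gradients Character vector of gradient strings (may be empty).
#' @param rules Character vector of rule strings (may be empty).
#' @return A `VisualizationSpec`, or `NULL` when both inputs are empty.
#' @export
build_spec <- function(gradients = character(0), rules = character(0)) {
  gradients <- gradients[nzchar(gradients)]
  rules <- rules[nzchar(rules)]
  if (!length(gradients) && !length(rules)) return(NULL)
  entries <- list()
  for (g in gradients) {
    pg <- parse_gradient_string(g)
    entries[[pg$column]] <- pg$gradient
  }
  for (r in rules) {
    pr <- parse_rule_string(r)
    if (is.null(entries[[pr$column]])) entries[[pr$column]] <- list()
    if (inherits(entries[[pr$column]], "ColorGradient")) {
      stop(sprintf("column %s has both a gradient and a rule", dQuote(pr$column)),
           call. = FALSE)
    }
    entries[[pr$column]] <- c(entries[[pr$column]], list(pr$rule))
  }
  visualization_spec(entries)
}

parse_ini <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", dQuote(path)), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  entries <- list()
  current <- NULL
  for (raw in lines) {
    # '#' starts a comment only at line start or after whitespace, so
    # that #RRGGBB colour literals survive
    line <- trimws(sub("(^|[[:space:]])#.*$", "\\1", raw))
    if (!nzchar(line)) next
    if (grepl("^\\[.+\\]$", line)) {
      current <- sub("^\\[(.+)\\]$", "\\1", line)
      entries[[current]] <- list()
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0 || is.null(current)) {
      stop(sprintf("config syntax error: %s", dQuote(raw)), call. = FALSE)
    }
    key <- trimws(substr(line, 1L, eq - 1L))
    val <- trimws(substr(line, eq + 1L, nchar(line)))
    entries[[current]][[key]] <- c(entries[[current]][[key]], val)
  }
  entries
}

run_batch_entry <- function(name, e) {
  need <- function(key) {
    v <- e[[key]]
    if (is.null(v)) stop(sprintf("entry %s: missing key %s", dQuote(name), dQuote(key)),
                         call. = FALSE)
    v[[1L]]
  }
  opt <- function(key, default = NULL) if (is.null(e[[key]])) default else e[[key]]
  table <- import_data(need("data"), id_column = need("id_column"),
                       syscode = need("syscode"))
  store <- if (!is.null(e$mapping)) load_mapping_table(e$mapping[[1L]],
                                                       species = opt("species", NA_character_)[[1L]])
  pw <- need("pathways")
  docs <- if (dir.exists(pw)) read_gpml_collection(pw) else {
    d <- list(read_gpml(pw)); names(d) <- pw; d
  }
  spec <- build_spec(opt("gradient", character(0)), opt("rule", character(0)))
  out_dir <- need("out")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rendered <- list()
  for (i in seq_along(docs)) {
    doc <- docs[[i]]
    lk <- link_to_pathway(table, doc, store)
    rendered[[doc$name]] <- render_pathway(doc, lk, table, spec)
  }
  criterion <- opt("criterion")
  if (!is.null(criterion)) {
    ranked <- rank_pathways(docs, table, store, criterion[[1L]])
    write_scores(ranked, file.path(out_dir, "zscores.tsv"))
    export_report(ranked, rendered, table, spec, out_dir)
  } else {
    for (doc in docs) {
      export_pathway_html(doc, rendered[[doc$name]], table,
                          file.path(out_dir, slugify(doc$name)))
    }
  }
  out_dir
}

#' Run a batch of analyses from a settings file
#'
#' Processes every config entry independently: imports the data, loads
#' the pathway source and optional mapping table, links and renders the
#' overlay, scores the pathways when a criterion is given, and exports
#' the HTML report into the entry's output directory.  A failing entry is
#' logged and does not stop the remaining entries.
#'
#' @param config_path INI-style settings file (grammar in the package
#'   vignette; an example ships under `inst/extdata`).
#' @param quiet Suppress per-entry log lines.
#' @return A `BatchResult`: data frame with one row per entry (`entry`,
#'   `status`, `detail`) and an `exit_status` attribute (0 when every
#'   entry succeeded, 1 otherwise).
#' @export
run_batch <- function(config_path, quiet = FALSE) {
  entries <- parse_ini(config_path)
  if (!length(entries)) stop("config file defines no entries", call. = FALSE)
  rows <- lapply(names(entries), function(nm) {
    res <- tryCatch(
      list(status = "ok", detail = run_batch_entry(nm, entries[[nm]])),
      error = function(err) list(status = "failed", detail = conditionMessage(err))
    )
    if (!quiet) {
      message(sprintf("[%s] %s: %s", res$status, nm, res$detail))
    }
    data.frame(entry = nm, status = res$status, detail = res$detail,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "exit_status") <- if (all(out$status == "ok")) 0L else 1L
  class(out) <- c("BatchResult", "data.frame")
  out
}
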