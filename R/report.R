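# Navigable HTML report: two-pane index (ranked clickable pathway list +
# content iframe), per-pathway pages with PNG image maps, per-element back
# pages, and the legend.  All files are written byte-deterministically (no
# timestamps), so re-export over an existing directory is idempotent.
#
# Layout: index.html; pathways/<slug>.html; backpages/<slug>/<id>.html;
# assets/<slug>.png, assets/legend.svg.  Slugs are sanitised pathway names
# with collision suffixes.

# Database URL patterns for back-page xref links; missing pattern -> plain
# text xref.
DEFAULT_DB_LINKS <- c(
  L  = "https://www.ncbi.nlm.nih.gov/gene/%s",
  En = "https://www.ensembl.org/id/%s",
  Ce = "https://www.ebi.ac.uk/chebi/searchId.do?chebiId=%s",
  S  = "https://www.uniprot.org/uniprotkb/%s"
)

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

slugify <- function(names) {
  base <- tolower(gsub("[^A-Za-z0-9]+", "_", names))
  base <- gsub("^_+|_+$", "", base)
  base[!nzchar(base)] <- "pathway"
  out <- base
  for (i in seq_along(out)) {
    k <- 2L
    while (out[[i]] %in% out[seq_len(i - 1L)]) {
      out[[i]] <- sprintf("%s_%d", base[[i]], k)
      k <- k + 1L
    }
  }
  out
}

write_text <- function(path, text) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(text, collapse = "")), con)
}

html_page <- function(title, body) {
  paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n<title>",
    html_escape(title), "</title>\n",
    "<style>body{font-family:sans-serif;margin:16px}table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:4px 8px}th{background:#eee}</style>\n",
    "</head>\n<body>\n", body, "\n</body>\n</html>\n")
}

fmt_z <- function(z) ifelse(is.na(z), "NaN", sprintf("%.3f", z))

cell_text <- function(v) {
  if (is.null(v) || length(v) == 0L || is.na(v)) return("NA")
  if (is.numeric(v)) fmt_num(v) else html_escape(as.character(v))
}

backpage_html <- function(doc, node_id, table, link, db_links) {
  el <- doc$elements[[node_id]]
  rows <- if (is.null(link)) integer(0) else link$node_rows[[node_id]]
  if (is.null(rows)) rows <- integer(0)
  body <- c(sprintf("<h1>%s</h1>", html_escape(el$label)),
            sprintf("<p>Type: %s</p>", html_escape(el$node_type)))
  if (!is.null(el$xref)) {
    x <- el$xref
    pat <- db_links[[x$system_code]]
    ref <- sprintf("%s:%s", x$system_code, x$identifier)
    if (!is.null(pat) && !is.na(pat)) {
      body <- c(body, sprintf('<p>Annotation: <a href="%s">%s</a></p>',
                              html_escape(sprintf(pat, x$identifier)), html_escape(ref)))
    } else {
      body <- c(body, sprintf("<p>Annotation: %s</p>", html_escape(ref)))
    }
  } else {
    body <- c(body, "<p>Annotation: none</p>")
  }
  if (length(rows) == 0L || is.null(table)) {
    body <- c(body, "<p>No data uploaded for this element.</p>")
  } else {
    if (length(rows) > 1L) {
      body <- c(body, sprintf(
        "<p>%d measurement rows match this element; the first row in file order is shown on the diagram.</p>",
        length(rows)))
    }
    cols <- c("identifier", "system_code", table$value_columns)
    head <- paste0("<tr>", paste0("<th>", html_escape(cols), "</th>", collapse = ""), "</tr>")
    trs <- vapply(rows, function(i) {
      row <- table_row(table, i)
      paste0("<tr>", paste0("<td>", vapply(cols, function(cl) cell_text(row[[cl]]), ""),
                            "</td>", collapse = ""), "</tr>")
    }, "")
    body <- c(body, "<h2>Measurements</h2>", "<table>", head, trs, "</table>")
  }
  html_page(el$label, paste(body, collapse = "\n"))
}

pathway_page_html <- function(doc, rendered, slug, table, db_links) {
  areas <- vapply(seq_len(nrow(rendered$hit_regions)), function(i) {
    h <- rendered$hit_regions[i, ]
    sprintf('<area shape="rect" coords="%d,%d,%d,%d" href="../backpages/%s/%s.html" target="_blank" alt="%s"/>',
            h$x, h$y, h$x + h$width, h$y + h$height, slug, h$element_id,
            html_escape(doc$elements[[h$element_id]]$label))
  }, "")
  body <- c(
    sprintf("<h1>%s</h1>", html_escape(doc$name)),
    sprintf("<p>Organism: %s</p>", html_escape(doc$organism)),
    sprintf('<img src="../assets/%s.png" usemap="#map_%s" width="%d" height="%d" alt="%s"/>',
            slug, slug, rendered$width_px, rendered$height_px, html_escape(doc$name)),
    sprintf('<map name="map_%s">', slug),
    areas,
    "</map>")
  html_page(doc$name, paste(body, collapse = "\n"))
}

emit_pathway_files <- function(doc, rendered, slug, table, out_dir, db_links) {
  files <- character(0)
  png_rel <- file.path("assets", paste0(slug, ".png"))
  dir.create(file.path(out_dir, "assets"), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(rendered$raster, file.path(out_dir, png_rel))
  files <- c(files, png_rel)
  page_rel <- file.path("pathways", paste0(slug, ".html"))
  write_text(file.path(out_dir, page_rel),
             pathway_page_html(doc, rendered, slug, table, db_links))
  files <- c(files, page_rel)
  for (nid in element_ids(doc, "DataNode")) {
    bp_rel <- file.path("backpages", slug, paste0(nid, ".html"))
    write_text(file.path(out_dir, bp_rel),
               backpage_html(doc, nid, table, rendered$link, db_links))
    files <- c(files, bp_rel)
  }
  files
}

settings_block <- function(criterion, N, R, n_pathways, dataset) {
  paste0(
    "<h2>Settings</h2>\n<table>\n",
    sprintf("<tr><th>Criterion</th><td>%s</td></tr>\n",
            html_escape(ifelse(is.null(criterion) || is.na(criterion), "(none)", criterion))),
    sprintf("<tr><th>Measured genes (N)</th><td>%s</td></tr>\n", N),
    sprintf("<tr><th>Genes meeting criterion (R)</th><td>%s</td></tr>\n", R),
    sprintf("<tr><th>Pathways in collection</th><td>%d</td></tr>\n", n_pathways),
    sprintf("<tr><th>Dataset</th><td>%s</td></tr>\n", html_escape(dataset)),
    "</table>\n")
}

#' Export a ranked analysis as a hyperlinked HTML report
#'
#' Writes a self-contained directory: an index with the settings overview
#' and the clickable pathway list ranked by Z score, one page per pathway
#' with the rendered PNG and an image map linking every data node to its
#' back page, the legend, and the back pages themselves (element
#' annotation with database links plus the matched measurement rows).
#'
#' @param ranked A `RankedResult` from [rank_pathways()].
#' @param rendered Named list of `RenderedPathway` objects, one per ranked
#'   pathway (names must equal the ranked pathway names).
#' @param table The `MeasurementTable` that was analysed.
#' @param spec The `VisualizationSpec` used for rendering (drawn in the
#'   legend); may be `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param db_links Named character vector of per-system URL patterns for
#'   back-page annotation links (`%s` is replaced by the accession).
#' @return An `HtmlReport`: list with `out_dir`, `index` and the relative
#'   paths of all written `files`.
#' @export
export_report <- function(ranked, rendered, table, spec, out_dir,
                          db_links = DEFAULT_DB_LINKS) {
  stopifnot(inherits(ranked, "RankedResult"), is.list(rendered))
  if (is.null(names(rendered)) || !setequal(names(rendered), ranked$pathway) ||
      length(rendered) != nrow(ranked)) {
    stop("rendered must be a named list with exactly one entry per ranked pathway",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  slugs <- slugify(ranked$pathway)
  files <- character(0)
  for (i in seq_len(nrow(ranked))) {
    nm <- ranked$pathway[[i]]
    rnd <- rendered[[nm]]
    stopifnot(inherits(rnd, "RenderedPathway"))
    files <- c(files, emit_pathway_files(rnd$doc, rnd, slugs[[i]], table, out_dir, db_links))
  }
  if (!is.null(spec) && length(spec$entries)) {
    write_text(file.path(out_dir, "assets", "legend.svg"), make_legend(spec)$svg)
    files <- c(files, file.path("assets", "legend.svg"))
  }
  list_rows <- vapply(seq_len(nrow(ranked)), function(i) {
    sprintf('<tr><td><a href="pathways/%s.html" target="content">%s</a></td><td>%d</td><td>%d</td><td>%s</td></tr>',
            slugs[[i]], html_escape(ranked$pathway[[i]]),
            ranked$n[[i]], ranked$r[[i]], fmt_z(ranked$z[[i]]))
  }, "")
  legend_link <- if (file.path("assets", "legend.svg") %in% files) {
    '<p><a href="assets/legend.svg" target="content">Legend</a></p>'
  } else ""
  body <- paste0(
    "<h1>Pathway over-representation analysis</h1>\n",
    settings_block(attr(ranked, "criterion"),
                   if (nrow(ranked)) ranked$N[[1L]] else 0L,
                   if (nrow(ranked)) ranked$R[[1L]] else 0L,
                   nrow(ranked), attr(ranked, "dataset")),
    legend_link, "\n",
    "<div style=\"display:flex;gap:16px\">\n<div>\n",
    "<h2>Pathways ranked by Z score</h2>\n<table>\n",
    "<tr><th>pathway</th><th>n</th><th>r</th><th>Z</th></tr>\n",
    paste(list_rows, collapse = "\n"), "\n</table>\n</div>\n",
    "<iframe name=\"content\" style=\"flex:1;min-height:600px;border:1px solid #999\"",
    " src=\"pathways/", slugs[[1L]], ".html\"></iframe>\n</div>")
  write_text(file.path(out_dir, "index.html"),
             html_page("Pathway over-representation analysis", body))
  files <- c("index.html", files)
  structure(list(out_dir = out_dir, index = file.path(out_dir, "index.html"),
                 files = files),
            class = "HtmlReport")
}

#' Export a single pathway as a standalone HTML page
#'
#' Variant of [export_report()] for one pathway without a ranking block:
#' index page with the image map plus the per-element back pages.
#'
#' @param doc A `PathwayDoc`.
#' @param rendered The `RenderedPathway` for `doc`.
#' @param table Optional `MeasurementTable` backing the overlay.
#' @param out_dir Output directory.
#' @inheritParams export_report
#' @return An `HtmlReport`.
#' @export
export_pathway_html <- function(doc, rendered, table, out_dir,
                                db_links = DEFAULT_DB_LINKS) {
  stopifnot(is_pathway_doc(doc), inherits(rendered, "RenderedPathway"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  slug <- slugify(doc$name)
  files <- emit_pathway_files(doc, rendered, slug, table, out_dir, db_links)
  if (!is.null(rendered$spec) && length(rendered$spec$entries)) {
    write_text(file.path(out_dir, "assets", "legend.svg"),
               make_legend(rendered$spec)$svg)
    files <- c(files, file.path("assets", "legend.svg"))
  }
  body <- paste0(
    sprintf("<h1>%s</h1>\n", html_escape(doc$name)),
    sprintf('<iframe name="content" src="pathways/%s.html" style="width:100%%;min-height:600px;border:1px solid #999"></iframe>', slug))
  write_text(file.path(out_dir, "index.html"), html_page(doc$name, body))
  files <- c("index.html", files)
  structure(list(out_dir = out_dir, index = file.path(out_dir, "index.html"),
                 files = files),
            class = "HtmlReport")
}

#' @export
print.HtmlReport <- function(x, ...) {
  cat(sprintf("<HtmlReport: %d files under %s>\n", length(x$files), x$out_dir))
  invisible(x)
}
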