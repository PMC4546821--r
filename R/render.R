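# Rendering of pathway diagrams with per-node multi-column data overlays.
#
# Output is a deterministic SVG 1.1 string plus an RGB raster (PNG) at a
# fixed 2 px per diagram unit, together with per-node hit regions in
# raster pixels for HTML image maps.  Mapped nodes are divided into k
# equal-width vertical stripes (one per spec entry, left to right in spec
# order); unmapped nodes are painted solid light grey.  Text labels are
# drawn in the SVG only: the raster stays free of font-metric dependence.

RENDER_SCALE <- 2

svg_header <- function(w, h) {
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">', w, h, w, h),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#FFFFFF"/>', w, h))
}

# Integer stripe partition: boundaries round(i*w/k), widths sum exactly to w.
stripe_bounds <- function(x0, width_px, k) {
  round(x0 + (0:k) * width_px / k)
}

raster_fill <- function(raster, x0, y0, x1, y1, rgb) {
  h <- dim(raster)[1L]; w <- dim(raster)[2L]
  xs <- max(x0 + 1L, 1L):min(x1, w)
  ys <- max(y0 + 1L, 1L):min(y1, h)
  if (length(xs) < 1L || length(ys) < 1L || xs[1L] > xs[length(xs)] || ys[1L] > ys[length(ys)]) {
    return(raster)
  }
  for (ch in 1:3) raster[ys, xs, ch] <- rgb[[ch]] / 255
  raster
}

raster_line <- function(raster, x0, y0, x1, y1, rgb) {
  n <- max(abs(x1 - x0), abs(y1 - y0), 1L)
  xs <- round(seq(x0, x1, length.out = n + 1L))
  ys <- round(seq(y0, y1, length.out = n + 1L))
  h <- dim(raster)[1L]; w <- dim(raster)[2L]
  keep <- xs >= 1L & xs <= w & ys >= 1L & ys <= h
  xs <- xs[keep]; ys <- ys[keep]
  for (ch in 1:3) raster[cbind(ys, xs, ch)] <- rgb[[ch]] / 255
  raster
}

#' Render a pathway with a data overlay
#'
#' @param doc A `PathwayDoc`.
#' @param link Optional `NodeDataLink` from [link_to_pathway()]; `NULL`
#'   renders the bare diagram (all nodes white).
#' @param table Optional `MeasurementTable` backing `link`.
#' @param spec Optional `VisualizationSpec`; every spec column must exist
#'   in the table.
#' @param scale Raster pixels per diagram unit.
#' @return A `RenderedPathway`: list with `svg` (string), `raster`
#'   (height x width x 3 array in 0..1), `hit_regions` (data frame
#'   `element_id`, `x`, `y`, `width`, `height` in raster pixels, one row
#'   per data node), `width_px`, `height_px`, plus the inputs for report
#'   generation.
#' @export
render_pathway <- function(doc, link = NULL, table = NULL, spec = NULL,
                           scale = RENDER_SCALE) {
  stopifnot(is_pathway_doc(doc))
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "VisualizationSpec"))
    if (is.null(table)) stop("a spec requires a measurement table", call. = FALSE)
    absent <- setdiff(names(spec$entries), names(table$data))
    if (length(absent)) {
      stop(sprintf("spec references absent column(s): %s", paste(absent, collapse = ", ")),
           call. = FALSE)
    }
  }
  wpx <- max(1L, as.integer(ceiling(doc$board_width * scale)))
  hpx <- max(1L, as.integer(ceiling(doc$board_height * scale)))
  svg <- svg_header(wpx, hpx)
  raster <- array(1, dim = c(hpx, wpx, 3))
  black <- c(0L, 0L, 0L)

  centre_px <- function(el) c(round(el$cx * scale), round(el$cy * scale))
  # interactions first so nodes draw over them
  for (id in element_ids(doc, "Interaction")) {
    el <- doc$elements[[id]]
    s <- doc$elements[[el$source_ref]]
    t <- doc$elements[[el$target_ref]]
    if (is.null(s) || is.null(t)) next  # dangling: nothing to draw
    p0 <- centre_px(s); p1 <- centre_px(t)
    svg <- c(svg, sprintf('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="#404040" stroke-width="1"/>',
                          p0[1L], p0[2L], p1[1L], p1[2L]))
    raster <- raster_line(raster, p0[1L], p0[2L], p1[1L], p1[2L], c(64L, 64L, 64L))
  }

  regions <- list()
  for (id in element_ids(doc)) {
    el <- doc$elements[[id]]
    if (el$kind == "Interaction") next
    x0 <- as.integer(round((el$cx - el$width / 2) * scale))
    y0 <- as.integer(round((el$cy - el$height / 2) * scale))
    bw <- as.integer(round(el$width * scale))
    bh <- as.integer(round(el$height * scale))
    if (el$kind == "Label") {
      svg <- c(svg, sprintf('<text x="%d" y="%d" text-anchor="middle" dominant-baseline="central" font-family="sans-serif" font-size="12">%s</text>',
                            x0 + bw %/% 2L, y0 + bh %/% 2L, xml_escape(el$label)))
      next
    }
    rows <- if (is.null(link)) integer(0) else link$node_rows[[id]]
    if (is.null(rows)) rows <- integer(0)
    if (is.null(link)) {
      fills <- list(c(255L, 255L, 255L))
    } else if (length(rows) == 0L) {
      fills <- list(if (is.null(spec)) COLOR_UNMAPPED else spec$unmapped_color)
    } else if (is.null(spec)) {
      fills <- list(c(255L, 255L, 255L))
    } else {
      row <- table_row(table, rows[[1L]])  # first matching row in file order
      fills <- lapply(names(spec$entries), function(col) entry_color(spec, col, row))
    }
    k <- length(fills)
    bx <- stripe_bounds(x0, bw, k)
    for (j in seq_len(k)) {
      sw <- bx[[j + 1L]] - bx[[j]]
      svg <- c(svg, sprintf('<rect x="%d" y="%d" width="%d" height="%d" fill="%s"/>',
                            bx[[j]], y0, sw, bh, rgb_hex(fills[[j]])))
      raster <- raster_fill(raster, bx[[j]], y0, bx[[j + 1L]], y0 + bh, fills[[j]])
    }
    svg <- c(svg, sprintf('<rect x="%d" y="%d" width="%d" height="%d" fill="none" stroke="#000000" stroke-width="1"/>',
                          x0, y0, bw, bh))
    raster <- raster_line(raster, x0 + 1L, y0 + 1L, x0 + bw, y0 + 1L, black)
    raster <- raster_line(raster, x0 + 1L, y0 + bh, x0 + bw, y0 + bh, black)
    raster <- raster_line(raster, x0 + 1L, y0 + 1L, x0 + 1L, y0 + bh, black)
    raster <- raster_line(raster, x0 + bw, y0 + 1L, x0 + bw, y0 + bh, black)
    svg <- c(svg, sprintf('<text x="%d" y="%d" text-anchor="middle" dominant-baseline="central" font-family="sans-serif" font-size="10" clip-path="inset(0)">%s</text>',
                          x0 + bw %/% 2L, y0 + bh %/% 2L, xml_escape(el$label)))
    regions[[length(regions) + 1L]] <- data.frame(
      element_id = id, x = x0, y = y0, width = bw, height = bh,
      stringsAsFactors = FALSE)
  }
  svg <- c(svg, "</svg>")
  hit <- if (length(regions)) do.call(rbind, regions) else
    data.frame(element_id = character(0), x = integer(0), y = integer(0),
               width = integer(0), height = integer(0), stringsAsFactors = FALSE)
  structure(list(svg = paste0(paste(svg, collapse = "\n"), "\n"),
                 raster = raster, hit_regions = hit,
                 width_px = wpx, height_px = hpx,
                 doc = doc, link = link, table = table, spec = spec),
            class = "RenderedPathway")
}

#' @export
print.RenderedPathway <- function(x, ...) {
  cat(sprintf("<RenderedPathway: %dx%d px, %d hit regions>\n",
              x$width_px, x$height_px, nrow(x$hit_regions)))
  invisible(x)
}

#' Write rendered output to disk
#'
#' @param rendered A `RenderedPathway` (or legend) object.
#' @param path Output file; format chosen by extension (`.svg` or `.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(rendered, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(rendered$svg), con)
  } else if (ext == "png") {
    png::writePNG(rendered$raster, path)
  } else {
    stop(sprintf("unsupported image extension %s (use .svg or .png)", dQuote(ext)),
         call. = FALSE)
  }
  invisible(path)
}

#' Draw the legend for a visualisation spec
#'
#' One block per spec entry: a gradient bar labelled at its anchor values,
#' or the rule list with colour swatches and criterion text.
#'
#' @param spec A `VisualizationSpec`.
#' @return A legend object with `svg` and `raster` fields, writable with
#'   [write_image()].
#' @export
make_legend <- function(spec) {
  stopifnot(inherits(spec, "VisualizationSpec"))
  block_h <- 60L
  wpx <- 320L
  hpx <- max(1L, block_h * length(spec$entries))
  svg <- svg_header(wpx, hpx)
  raster <- array(1, dim = c(hpx, wpx, 3))
  y <- 0L
  bar_x <- 10L; bar_w <- 200L; bar_h <- 16L
  for (nm in names(spec$entries)) {
    e <- spec$entries[[nm]]
    svg <- c(svg, sprintf('<text x="%d" y="%d" font-family="sans-serif" font-size="12">%s</text>',
                          bar_x, y + 14L, xml_escape(nm)))
    if (inherits(e, "ColorGradient")) {
      v <- e$values
      rng <- v[length(v)] - v[1L]
      stops <- vapply(seq_along(v), function(i) {
        sprintf('<stop offset="%s%%" stop-color="%s"/>',
                fmt_num(100 * (v[[i]] - v[[1L]]) / rng), rgb_hex(e$colors[[i]]))
      }, "")
      gid <- sprintf("grad_%s", gsub("[^A-Za-z0-9]", "_", nm))
      svg <- c(svg,
               sprintf('<defs><linearGradient id="%s">%s</linearGradient></defs>', gid,
                       paste(stops, collapse = "")),
               sprintf('<rect x="%d" y="%d" width="%d" height="%d" fill="url(#%s)" stroke="#000000"/>',
                       bar_x, y + 20L, bar_w, bar_h, gid))
      for (i in seq_along(v)) {
        ax <- bar_x + round(bar_w * (v[[i]] - v[[1L]]) / rng)
        svg <- c(svg, sprintf('<text x="%d" y="%d" text-anchor="middle" font-family="sans-serif" font-size="10">%s</text>',
                              ax, y + 50L, fmt_num(v[[i]])))
      }
      for (px in 0:(bar_w - 1L)) {
        val <- v[[1L]] + rng * px / (bar_w - 1L)
        raster <- raster_fill(raster, bar_x + px, y + 20L, bar_x + px + 1L, y + 20L + bar_h,
                              interpolate_color(e, val))
      }
    } else {
      ry <- y + 20L
      for (rule in e) {
        svg <- c(svg,
                 sprintf('<rect x="%d" y="%d" width="14" height="14" fill="%s" stroke="#000000"/>',
                         bar_x, ry, rgb_hex(rule$color)),
                 sprintf('<text x="%d" y="%d" font-family="sans-serif" font-size="10">%s</text>',
                         bar_x + 20L, ry + 11L, xml_escape(attr(rule$criterion, "text"))))
        raster <- raster_fill(raster, bar_x, ry, bar_x + 14L, ry + 14L, rule$color)
        ry <- ry + 18L
      }
      svg <- c(svg,
               sprintf('<rect x="%d" y="%d" width="14" height="14" fill="%s" stroke="#000000"/>',
                       bar_x, ry, rgb_hex(spec$fallback_color)),
               sprintf('<text x="%d" y="%d" font-family="sans-serif" font-size="10">otherwise</text>',
                       bar_x + 20L, ry + 11L))
    }
    y <- y + block_h
  }
  svg <- c(svg, "</svg>")
  structure(list(svg = paste0(paste(svg, collapse = "\n"), "\n"),
                 raster = raster, width_px = wpx, height_px = hpx,
                 n_blocks = length(spec$entries)),
            class = "PathwayLegend")
}
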