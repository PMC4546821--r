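# Colour computation for data overlays: gradients and criterion rules.

# Documented display constants: unmapped nodes and mapped nodes without a
# data cell are light grey; a rule list that fires no rule falls back to
# white.
COLOR_UNMAPPED <- c(211L, 211L, 211L)
COLOR_RULE_FALLBACK <- c(255L, 255L, 255L)

as_rgb <- function(color) {
  if (is.numeric(color)) {
    stopifnot(length(color) == 3L)
    rgb <- as.integer(round(color))
  } else {
    rgb <- as.integer(grDevices::col2rgb(color)[, 1L])
  }
  if (any(rgb < 0L | rgb > 255L)) stop("colour channels must be in 0..255", call. = FALSE)
  rgb
}

rgb_hex <- function(rgb) sprintf("#%02X%02X%02X", rgb[[1L]], rgb[[2L]], rgb[[3L]])

#' Create a colour gradient
#'
#' A gradient maps a numeric value to a colour by piecewise-linear
#' interpolation per RGB channel between anchors; values outside the
#' anchor range clamp to the end anchors.  The classic fold-change scheme
#' is blue, white, red anchored at -1, 0, 1.
#'
#' @param values Numeric anchor positions, strictly increasing, length 2
#'   or 3.
#' @param colors Anchor colours (R colour names, `"#RRGGBB"` strings, or
#'   length-3 RGB vectors), one per anchor.
#' @return A `ColorGradient`.
#' @export
#' @examples
#' g <- color_gradient(c(-1, 0, 1), c("blue", "white", "red"))
#' interpolate_color(g, 0)
color_gradient <- function(values, colors) {
  if (length(values) < 2L) stop("a gradient needs at least 2 anchors", call. = FALSE)
  if (length(values) != length(colors)) {
    stop("gradient needs one colour per anchor value", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(diff(values) <= 0)) {
    stop("gradient anchor values must be finite and strictly increasing", call. = FALSE)
  }
  rgb <- lapply(colors, as_rgb)
  structure(list(values = as.numeric(values), colors = rgb),
            class = "ColorGradient")
}

#' Interpolate a gradient at a value
#'
#' @param gradient A `ColorGradient`.
#' @param value Finite numeric value.
#' @return Integer RGB triple in 0..255; channels round half up.
#' @export
interpolate_color <- function(gradient, value) {
  stopifnot(inherits(gradient, "ColorGradient"))
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("gradient value must be a finite number", call. = FALSE)
  }
  v <- gradient$values
  if (value <= v[[1L]]) return(gradient$colors[[1L]])
  if (value >= v[[length(v)]]) return(gradient$colors[[length(v)]])
  j <- findInterval(value, v, rightmost.closed = TRUE)
  t <- (value - v[[j]]) / (v[[j + 1L]] - v[[j]])
  a <- gradient$colors[[j]]
  b <- gradient$colors[[j + 1L]]
  ch <- a + t * (b - a)
  as.integer(floor(ch + 0.5))  # round half up
}

#' Create a colour rule
#'
#' @param criterion Criterion text or a parsed `CriterionAST`; the rule
#'   fires on rows where it evaluates true.
#' @param color Colour applied when the rule fires.
#' @return A `ColorRule`.
#' @export
#' @examples
#' color_rule("[P.Value] <= 0.05", "green")
color_rule <- function(criterion, color) {
  ast <- if (inherits(criterion, "CriterionAST")) criterion else parse_criterion(criterion)
  structure(list(criterion = ast, color = as_rgb(color)), class = "ColorRule")
}

#' Apply an ordered rule list to a row
#'
#' The first rule whose criterion evaluates true wins; a missing or false
#' evaluation moves on to the next rule; if none fires the fallback colour
#' is returned.
#'
#' @param rules List of [color_rule()] objects.
#' @param row Named list of cell values.
#' @param fallback Fallback colour (default white).
#' @return Integer RGB triple.
#' @export
apply_rules <- function(rules, row, fallback = COLOR_RULE_FALLBACK) {
  for (rule in rules) {
    if (isTRUE(evaluate_criterion(rule$criterion, row))) return(rule$color)
  }
  as_rgb(fallback)
}

#' Define a data-overlay visualisation
#'
#' A visualisation spec lists the value columns to paint on each node,
#' each coloured by a gradient or by an ordered rule list.  Mapped nodes
#' are divided into one vertical stripe per entry, left to right in spec
#' order; unmapped nodes are painted `unmapped_color`.
#'
#' @param entries Named list: column name -> `ColorGradient` or list of
#'   `ColorRule`s.
#' @param unmapped_color Colour for nodes with no matching data row
#'   (default light grey, RGB 211,211,211).
#' @param nodata_color Colour for a missing cell within a mapped node.
#' @param fallback_color Rule-list fallback colour (default white).
#' @return A `VisualizationSpec`.
#' @export
#' @examples
#' visualization_spec(list(
#'   logFC = color_gradient(c(-1, 0, 1), c("blue", "white", "red")),
#'   P.Value = list(color_rule("[P.Value] <= 0.05", "green"))
#' ))
visualization_spec <- function(entries,
                               unmapped_color = COLOR_UNMAPPED,
                               nodata_color = COLOR_UNMAPPED,
                               fallback_color = COLOR_RULE_FALLBACK) {
  stopifnot(is.list(entries))
  if (length(entries) && (is.null(names(entries)) || any(!nzchar(names(entries))))) {
    stop("every spec entry must be named by its data column", call. = FALSE)
  }
  if (anyDuplicated(names(entries))) stop("spec column names must be distinct", call. = FALSE)
  for (nm in names(entries)) {
    e <- entries[[nm]]
    ok <- inherits(e, "ColorGradient") ||
      (is.list(e) && length(e) > 0L && all(vapply(e, inherits, TRUE, "ColorRule")))
    if (!ok) {
      stop(sprintf("spec entry %s must be a ColorGradient or a non-empty list of ColorRules",
                   dQuote(nm)), call. = FALSE)
    }
  }
  structure(list(entries = entries,
                 unmapped_color = as_rgb(unmapped_color),
                 nodata_color = as_rgb(nodata_color),
                 fallback_color = as_rgb(fallback_color)),
            class = "VisualizationSpec")
}

# Colour of one spec entry for one row (or NULL row -> no-data colour).
entry_color <- function(spec, column, row) {
  e <- spec$entries[[column]]
  if (is.null(row)) return(spec$nodata_color)
  if (inherits(e, "ColorGradient")) {
    v <- row[[column]]
    if (length(v) != 1L) v <- v[[1L]]
    v <- suppressWarnings(as.numeric(v))
    if (is.na(v)) return(spec$nodata_color)
    return(interpolate_color(e, v))
  }
  apply_rules(e, row, spec$fallback_color)
}
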