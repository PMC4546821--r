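# Shared test helpers: independent oracles and random-input generators.

# Exact hypergeometric mean/variance by direct summation over the pmf
# computed from binomial coefficients (independent of the package's
# closed-form variance).
hyper_moments <- function(N, R, n) {
  r_min <- max(0L, n - (N - R))
  r_max <- min(n, R)
  rs <- r_min:r_max
  p <- choose(R, rs) * choose(N - R, n - rs) / choose(N, n)
  m <- sum(rs * p)
  v <- sum((rs - m)^2 * p)
  list(mean = m, var = v)
}

# Random criterion over columns a..d, built as a tree; returns the package
# dialect text and an equivalent base-R expression whose NA semantics are
# exactly three-valued logic.
random_criterion <- function(depth = 3L, columns = c("a", "b", "c", "d")) {
  operand <- function() {
    if (stats::runif(1) < 0.7) {
      col <- sample(columns, 1L)
      list(text = sprintf("[%s]", col), rexpr = col)
    } else {
      lit <- sample(c(0, 0.5, 1), 1L)
      list(text = as.character(lit), rexpr = as.character(lit))
    }
  }
  comparison <- function() {
    ops <- c("<", "<=", ">", ">=", "=", "<>")
    rops <- c("<", "<=", ">", ">=", "==", "!=")
    k <- sample(length(ops), 1L)
    l <- operand(); r <- operand()
    list(text = sprintf("%s %s %s", l$text, ops[[k]], r$text),
         rexpr = sprintf("(%s %s %s)", l$rexpr, rops[[k]], r$rexpr))
  }
  build <- function(d) {
    if (d <= 0L || stats::runif(1) < 0.4) return(comparison())
    which <- sample(c("and", "or", "not"), 1L)
    if (which == "not") {
      a <- build(d - 1L)
      return(list(text = sprintf("NOT (%s)", a$text),
                  rexpr = sprintf("(!%s)", a$rexpr)))
    }
    a <- build(d - 1L); b <- build(d - 1L)
    op <- if (which == "and") c("AND", "&") else c("OR", "|")
    list(text = sprintf("(%s) %s (%s)", a$text, op[[1L]], b$text),
         rexpr = sprintf("(%s %s %s)", a$rexpr, op[[2L]], b$rexpr))
  }
  build(depth)
}

# All assignments of values (0, 1, NA) to the given columns.
all_assignments <- function(columns, values = list(0, 1, NA)) {
  grids <- do.call(expand.grid, c(stats::setNames(
    rep(list(seq_along(values)), length(columns)), columns),
    list(KEEP.OUT.ATTRS = FALSE)))
  lapply(seq_len(nrow(grids)), function(i) {
    stats::setNames(lapply(seq_along(columns),
                           function(j) values[[grids[i, j]]]), columns)
  })
}

# Direct per-channel linear interpolation formula (gradient oracle).
gradient_oracle <- function(values, colors_rgb, x) {
  if (x <= values[[1L]]) return(colors_rgb[[1L]])
  k <- length(values)
  if (x >= values[[k]]) return(colors_rgb[[k]])
  j <- max(which(values <= x))
  if (values[[j]] == x) return(colors_rgb[[j]])
  t <- (x - values[[j]]) / (values[[j + 1L]] - values[[j]])
  as.integer(floor(colors_rgb[[j]] + t * (colors_rgb[[j + 1L]] - colors_rgb[[j]]) + 0.5))
}

# Random pathway document exercising escaping, xrefs, geometry,
# interactions (including self-loops) and labels.
random_pathway_doc <- function() {
  nm <- paste0(sample(c(letters, LETTERS, " ", "&", "<", "\"", "'"),
                      sample(3:12, 1L), replace = TRUE), collapse = "")
  doc <- create_pathway(nm, sample(c("Homo sapiens", "Mus musculus"), 1L))
  n_nodes <- sample(1:8, 1L)
  ids <- character(n_nodes)
  for (i in seq_len(n_nodes)) {
    xr <- if (stats::runif(1) < 0.6) {
      xref(paste0(sample(c(LETTERS, 0:9), 6, replace = TRUE), collapse = ""),
           sample(c("L", "En", "Ce"), 1L))
    }
    ids[[i]] <- add_data_node(
      doc, label = paste0(sample(c(letters, "&", ">"), 5, replace = TRUE), collapse = ""),
      node_type = sample(c("GeneProduct", "Protein", "Metabolite", "Rna"), 1L),
      xref = xr,
      cx = stats::runif(1, 10, 400), cy = stats::runif(1, 10, 400),
      width = stats::runif(1, 20, 120), height = stats::runif(1, 10, 40))
  }
  for (k in seq_len(sample(0:3, 1L))) {
    add_interaction(doc, sample(ids, 1L), sample(ids, 1L),
                    sample(c("line", "arrow", "t-bar", "conversion", "catalysis"), 1L))
  }
  if (stats::runif(1) < 0.3) add_label(doc, "free text & more")
  doc
}

# Tiny two-system fixture world shared by mapper/dataset tests: four genes
# known to the store (L <-> En bijection), one L-only identifier.
write_tiny_mapping <- function(path) {
  writeLines(c(
    "source_code\tsource_id\ttarget_code\ttarget_id",
    "# toy links",
    "L\t1001\tEn\tENST0001",
    "L\t1002\tEn\tENST0002",
    "L\t1003\tEn\tENST0003",
    "L\t1004\tEn\tENST0004",
    "L\t1005\tL\t1005"
  ), path)
  path
}

# Crawl an exported HTML report from its index: follow every local href /
# src recursively and return any link whose target file does not exist.
crawl_report <- function(out_dir) {
  seen <- character(0)
  missing <- character(0)
  visit <- function(rel) {
    if (rel %in% seen) return(invisible())
    seen <<- c(seen, rel)
    path <- file.path(out_dir, rel)
    if (!file.exists(path)) {
      missing <<- c(missing, rel)
      return(invisible())
    }
    if (!grepl("\\.html$", rel)) return(invisible())
    html <- paste(readLines(path, warn = FALSE), collapse = "\n")
    refs <- c(
      regmatches(html, gregexpr('href="[^"]+"', html))[[1L]],
      regmatches(html, gregexpr('src="[^"]+"', html))[[1L]]
    )
    refs <- sub('^(href|src)="', "", refs)
    refs <- sub('"$', "", refs)
    refs <- refs[!grepl("^https?://|^#|^mailto:", refs)]
    base <- dirname(rel)
    for (r in refs) {
      target <- if (base == ".") r else file.path(base, r)
      # resolve ".." components
      parts <- strsplit(target, "/", fixed = TRUE)[[1L]]
      stack <- character(0)
      for (p in parts) {
        if (p == "..") stack <- stack[-length(stack)] else if (p != ".") stack <- c(stack, p)
      }
      visit(paste(stack, collapse = "/"))
    }
  }
  visit("index.html")
  list(visited = seen, missing = missing)
}

# Parse the <rect> elements of a rendered SVG (fill, x, width) for stripe
# geometry checks.
svg_rects <- function(svg) {
  x <- xml2::read_xml(svg)
  xml2::xml_ns_strip(x)
  rects <- xml2::xml_find_all(x, ".//rect")
  data.frame(
    x = as.numeric(xml2::xml_attr(rects, "x")),
    y = as.numeric(xml2::xml_attr(rects, "y")),
    width = as.numeric(xml2::xml_attr(rects, "width")),
    height = as.numeric(xml2::xml_attr(rects, "height")),
    fill = xml2::xml_attr(rects, "fill"),
    stringsAsFactors = FALSE
  )
}
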