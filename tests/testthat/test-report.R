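report_world <- function(tmp, seed = 17) {
  fx <- make_fixture(fixture_spec(seed = seed, n_genes = 50, n_pathways = 3,
                                  genes_per_pathway = 8), dir = tmp)
  spec <- visualization_spec(list(
    logFC = color_gradient(c(-1, 0, 1), c("blue", "white", "red")),
    P.Value = list(color_rule("[P.Value] <= 0.05", "green"))))
  ranked <- rank_pathways(fx$docs, fx$table, fx$store, "[P.Value] < 0.05")
  rendered <- list()
  for (doc in fx$docs) {
    lk <- link_to_pathway(fx$table, doc, fx$store)
    rendered[[doc$name]] <- render_pathway(doc, lk, fx$table, spec)
  }
  list(fx = fx, spec = spec, ranked = ranked, rendered = rendered)
}

test_that("the report lists pathways in rank order and links resolve end to end", {
  tmp <- withr::local_tempdir()
  w <- report_world(file.path(tmp, "fx"))
  out <- file.path(tmp, "report")
  rep <- export_report(w$ranked, w$rendered, w$fx$table, w$spec, out)
  expect_true(file.exists(rep$index))
  index <- paste(readLines(rep$index, warn = FALSE), collapse = "\n")
  # ranked order preserved in the index list
  pos <- vapply(slugify_names <- gsub("[^a-z0-9]+", "_", tolower(w$ranked$pathway)),
                function(s) regexpr(paste0("pathways/", s, ".html"), index, fixed = TRUE)[[1]],
                0L)
  expect_true(all(diff(pos) > 0))
  expect_match(index, "Criterion")
  expect_match(index, "\\[P.Value\\] &lt; 0.05")
  crawl <- crawl_report(out)
  expect_equal(crawl$missing, character(0))
  # every written file is reachable from the index
  expect_true(all(rep$files %in% crawl$visited))
})

test_that("image maps carry one area per data node matching the hit regions", {
  tmp <- withr::local_tempdir()
  w <- report_world(file.path(tmp, "fx"))
  out <- file.path(tmp, "report")
  export_report(w$ranked, w$rendered, w$fx$table, w$spec, out)
  for (nm in names(w$rendered)) {
    slug <- gsub("[^a-z0-9]+", "_", tolower(nm))
    page <- paste(readLines(file.path(out, "pathways", paste0(slug, ".html")),
                            warn = FALSE), collapse = "\n")
    areas <- regmatches(page, gregexpr('<area shape="rect" coords="[^"]+"', page))[[1]]
    expect_length(areas, element_count(w$rendered[[nm]]$doc, "DataNode"))
    h <- w$rendered[[nm]]$hit_regions[1, ]
    expect_match(page, sprintf('coords="%d,%d,%d,%d"', h$x, h$y,
                               h$x + h$width, h$y + h$height), fixed = TRUE)
  }
})

test_that("back pages show the matched measurement cells or state the absence of data", {
  df <- data.frame(identifier = c("42", "42"),
                   d1 = c(1.5, 1.4), d2 = c(0.2, 0.1), d5 = c(-1, -0.9),
                   p1 = c(0.01, 0.02), p2 = c(0.5, 0.4), p5 = c(0.9, 0.8),
                   stringsAsFactors = FALSE)
  tab <- as_measurement_table(df, id_column = "identifier", syscode = "L")
  doc <- create_pathway("six columns", "Mus musculus")
  hit <- add_data_node(doc, "Fos", xref = xref("42", "L"))
  dry <- add_data_node(doc, "dry")
  lk <- link_to_pathway(tab, doc, NULL)
  rendered <- render_pathway(doc, lk, tab, NULL)
  out <- withr::local_tempdir()
  export_pathway_html(doc, rendered, tab, out)
  slug <- "six_columns"
  bp <- paste(readLines(file.path(out, "backpages", slug, paste0(hit, ".html")),
                        warn = FALSE), collapse = "\n")
  for (col in c("d1", "d2", "d5", "p1", "p2", "p5")) {
    expect_match(bp, sprintf("<th>%s</th>", col), fixed = TRUE)
  }
  expect_match(bp, "<td>1.5</td>", fixed = TRUE)
  expect_match(bp, "2 measurement rows match")  # multiplicity flagged
  expect_match(bp, "https://www.ncbi.nlm.nih.gov/gene/42")
  bp_dry <- paste(readLines(file.path(out, "backpages", slug, paste0(dry, ".html")),
                            warn = FALSE), collapse = "\n")
  expect_match(bp_dry, "No data uploaded")
})

test_that("single-pathway export works for degenerate documents", {
  doc <- create_pathway("lonely", "Homo sapiens")
  add_data_node(doc, "only")
  out <- withr::local_tempdir()
  rep <- export_pathway_html(doc, render_pathway(doc), NULL, out)
  crawl <- crawl_report(out)
  expect_equal(crawl$missing, character(0))
  empty_doc <- create_pathway("bare", "Homo sapiens")
  out2 <- withr::local_tempdir()
  rep2 <- export_pathway_html(empty_doc, render_pathway(empty_doc), NULL, out2)
  page <- paste(readLines(file.path(out2, "pathways", "bare.html"), warn = FALSE),
                collapse = "\n")
  expect_match(page, "<map")
  expect_no_match(page, "<area")
})

test_that("re-export over an existing directory is byte-idempotent", {
  tmp <- withr::local_tempdir()
  w <- report_world(file.path(tmp, "fx"))
  out <- file.path(tmp, "report")
  rep <- export_report(w$ranked, w$rendered, w$fx$table, w$spec, out)
  digest <- function() {
    vapply(sort(rep$files), function(f) {
      paste(as.character(readBin(file.path(out, f), "raw",
                                 n = file.size(file.path(out, f)))), collapse = "")
    }, "")
  }
  first <- digest()
  export_report(w$ranked, w$rendered, w$fx$table, w$spec, out)
  expect_identical(digest(), first)
})

test_that("mismatched ranked/rendered sets are rejected", {
  tmp <- withr::local_tempdir()
  w <- report_world(file.path(tmp, "fx"))
  expect_error(export_report(w$ranked, w$rendered[-1], w$fx$table, w$spec,
                             file.path(tmp, "bad")), "one entry per ranked pathway")
})
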