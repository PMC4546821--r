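write_stats_file <- function(path, sep = "\t") {
  header <- paste(c("GeneID", "SysCode", "logFC_d1", "logFC_d2", "logFC_d5",
                    "P_d1", "P_d2", "P_d5"), collapse = sep)
  rows <- c(
    paste(c("1001", "L", "1.5", "0.2", "-0.1", "0.01", "0.3", "0.9"), collapse = sep),
    paste(c("1002", "L", "-2.0", "-1.1", "0.0", "0.001", "0.04", "0.5"), collapse = sep),
    paste(c("1003", "L", "NA", "0.5", "", "0.2", "NA", "0.6"), collapse = sep),
    paste(c("1004", "L", "high", "0.1", "0.2", "0.7", "0.8", "0.9"), collapse = sep))
  writeLines(c(header, rows), path)
  path
}

test_that("import parses numeric cells, keeps text, marks missing", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_stats_file(tmp)
  tab <- import_data(tmp, id_column = "GeneID", syscode = "SysCode")
  expect_length(tab$value_columns, 6L)
  expect_equal(tab$data$identifier, c("1001", "1002", "1003", "1004"))
  expect_type(tab$data$P_d1, "double")
  expect_true(is.na(tab$data$P_d2[[3]]))      # "NA" marker in a numeric column
  expect_true(is.na(tab$data$logFC_d5[[3]]))  # empty cell
  expect_true(is.na(tab$data$logFC_d1[[3]]))  # "NA" marker in a text column
  expect_type(tab$data$logFC_d1, "character")  # "high" keeps the column text
  expect_equal(tab$data$logFC_d1[[1]], "1.5")
})

test_that("comma files are sniffed and fixed system codes apply to all rows", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,score", "g1,0.5", "g2,0.7"), tmp)
  tab <- import_data(tmp, id_column = "id", syscode = "L")
  expect_equal(unique(tab$data$system_code), "L")
  expect_equal(tab$data$score, c(0.5, 0.7))
})

test_that("import rejects bad files", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines("GeneID\tval", tmp)
  expect_error(import_data(tmp, "GeneID", "L"), "no rows")
  writeLines(character(0), tmp)
  expect_error(import_data(tmp, "GeneID", "L"), "empty")
  write_stats_file(tmp)
  expect_error(import_data(tmp, "missing_col", "L"), "not present")
})

test_that("rows link to nodes directly and through the mapper", {
  map <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_mapping(map)
  store <- load_mapping_table(map)
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_stats_file(tmp)
  tab <- import_data(tmp, id_column = "GeneID", syscode = "SysCode")

  doc <- create_pathway("linked", "Mus musculus")
  direct <- add_data_node(doc, "direct", xref = xref("1001", "L"))
  mapped <- add_data_node(doc, "mapped", xref = xref("ENST0002", "En"))
  bare <- add_data_node(doc, "bare")
  lost <- add_data_node(doc, "lost", xref = xref("999999", "L"))

  lk <- link_to_pathway(tab, doc, store)
  expect_equal(lk$node_rows[[direct]], 1L)
  expect_equal(lk$node_rows[[mapped]], 2L)
  expect_equal(sort(lk$unmapped_nodes), sort(c(bare, lost)))
  expect_equal(lk$row_nodes[[1]], direct)
})

test_that("linking is invariant to row order", {
  map <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_mapping(map)
  store <- load_mapping_table(map)
  df <- data.frame(identifier = c("1001", "1002", "1003"),
                   value = c(1, 2, 3), stringsAsFactors = FALSE)
  doc <- create_pathway("inv", "Mus musculus")
  n1 <- add_data_node(doc, "a", xref = xref("ENST0001", "En"))
  n2 <- add_data_node(doc, "b", xref = xref("ENST0003", "En"))
  t1 <- as_measurement_table(df, id_column = "identifier", syscode = "L")
  t2 <- as_measurement_table(df[3:1, ], id_column = "identifier", syscode = "L")
  l1 <- link_to_pathway(t1, doc, store)
  l2 <- link_to_pathway(t2, doc, store)
  expect_equal(t1$data$identifier[l1$node_rows[[n1]]],
               t2$data$identifier[l2$node_rows[[n1]]])
  expect_equal(t1$data$identifier[l1$node_rows[[n2]]],
               t2$data$identifier[l2$node_rows[[n2]]])
})

test_that("one row can colour several nodes sharing an annotation", {
  df <- data.frame(identifier = "42", value = 1, stringsAsFactors = FALSE)
  tab <- as_measurement_table(df, id_column = "identifier", syscode = "L")
  doc <- create_pathway("multi", "Homo sapiens")
  n1 <- add_data_node(doc, "copy1", xref = xref("42", "L"))
  n2 <- add_data_node(doc, "copy2", xref = xref("42", "L"))
  lk <- link_to_pathway(tab, doc, NULL)
  expect_equal(lk$node_rows[[n1]], 1L)
  expect_equal(lk$node_rows[[n2]], 1L)
  expect_equal(sort(lk$row_nodes[[1]]), sort(c(n1, n2)))
})
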