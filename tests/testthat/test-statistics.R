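test_that("counts on a constructed dataset recover (N, R, n, r) exactly", {
  # 100 genes, 20 meeting the criterion; pathway holds 10 genes, 5 meeting
  df <- data.frame(identifier = sprintf("g%03d", 1:100),
                   P.Value = c(rep(0.01, 20), rep(0.5, 80)),
                   stringsAsFactors = FALSE)
  tab <- as_measurement_table(df, id_column = "identifier", syscode = "L")
  doc <- create_pathway("ten", "Homo sapiens")
  for (g in sprintf("g%03d", c(1:5, 51:55))) add_data_node(doc, g, xref = xref(g, "L"))
  cc <- count_criterion(doc, tab, NULL, "[P.Value] < 0.05")
  expect_equal(unclass(cc)[c("N", "R", "n", "r")],
               list(N = 100L, R = 20L, n = 10L, r = 5L))

  empty <- create_pathway("none", "Homo sapiens")
  cc0 <- count_criterion(empty, tab, NULL, "[P.Value] < 0.05")
  expect_equal(c(cc0$n, cc0$r), c(0L, 0L))
  expect_equal(c(cc0$N, cc0$R), c(100L, 20L))

  all_true <- count_criterion(doc, tab, NULL, "1 = 1")
  expect_equal(all_true$R, all_true$N)
  expect_equal(all_true$r, all_true$n)
})

test_that("duplicate probes unify to one gene and missing cells do not count toward R", {
  df <- data.frame(identifier = c("a", "a", "b", "c"),
                   P.Value = c(0.5, 0.01, NA, 0.01),
                   stringsAsFactors = FALSE)
  tab <- as_measurement_table(df, id_column = "identifier", syscode = "L")
  doc <- create_pathway("d", "Homo sapiens")
  add_data_node(doc, "a", xref = xref("a", "L"))
  cc <- count_criterion(doc, tab, NULL, "[P.Value] < 0.05")
  expect_equal(cc$N, 3L)   # a, b, c
  expect_equal(cc$R, 2L)   # a (any row), c; missing b stays in N only
  expect_equal(cc$n, 1L)
  expect_equal(cc$r, 1L)
})

test_that("rows the store cannot map are excluded from N and reported", {
  map <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_mapping(map)
  store <- load_mapping_table(map)
  df <- data.frame(identifier = c("1001", "1002", "orphan"),
                   P.Value = c(0.01, 0.5, 0.01), stringsAsFactors = FALSE)
  tab <- as_measurement_table(df, id_column = "identifier", syscode = "L")
  doc <- create_pathway("m", "Mus musculus")
  add_data_node(doc, "x", xref = xref("ENST0001", "En"))
  cc <- count_criterion(doc, tab, store, "[P.Value] < 0.05")
  expect_equal(cc$N, 2L)
  expect_equal(cc$excluded, 1L)
  expect_equal(cc$r, 1L)  # 1001 maps onto the En-annotated node
})

test_that("the z score matches the exact hypergeometric oracle and its edge cases", {
  expect_equal(zscore(list(N = 100, R = 50, n = 10, r = 5)), 0)
  o <- hyper_moments(20, 5, 4)
  expect_equal(zscore(list(N = 20, R = 5, n = 4, r = 3)),
               (3 - o$mean) / sqrt(o$var), tolerance = 1e-12)
  expect_true(is.na(zscore(list(N = 100, R = 50, n = 0, r = 0))))
  expect_true(is.na(zscore(list(N = 100, R = 0, n = 10, r = 0))))
  expect_true(is.na(zscore(list(N = 100, R = 100, n = 10, r = 10))))
  expect_true(is.na(zscore(list(N = 10, R = 5, n = 10, r = 5))))
  expect_error(zscore(list(N = 10, R = 5, n = 11, r = 5)), "invalid counts")
  expect_error(zscore(list(N = 10, R = 5, n = 2, r = 3)), "invalid counts")
})

test_that("the sign of z reflects enrichment versus depletion", {
  set.seed(42)
  for (i in 1:200) {
    N <- sample(10:500, 1)
    R <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    r <- sample(max(0, n - (N - R)):min(n, R), 1)
    z <- zscore(list(N = N, R = R, n = n, r = r))
    if (is.na(z)) next
    expect_equal(z > 0, r > n * R / N)
    expect_equal(z < 0, r < n * R / N)
  }
})

test_that("ranking orders by z with names breaking ties and NaN sorting last", {
  df <- data.frame(identifier = sprintf("g%02d", 1:40),
                   P.Value = c(rep(0.01, 10), rep(0.5, 30)),
                   stringsAsFactors = FALSE)
  tab <- as_measurement_table(df, id_column = "identifier", syscode = "L")
  mk <- function(name, genes) {
    d <- create_pathway(name, "Homo sapiens")
    for (g in genes) add_data_node(d, g, xref = xref(g, "L"))
    d
  }
  enriched <- mk("b_enriched", sprintf("g%02d", 1:8))
  depleted <- mk("a_depleted", sprintf("g%02d", 31:38))
  twin1 <- mk("twin_b", sprintf("g%02d", 11:14))
  twin2 <- mk("twin_a", sprintf("g%02d", 15:18))
  undef <- mk("z_undef", character(0))
  ranked <- rank_pathways(list(enriched, depleted, twin1, twin2, undef),
                          tab, NULL, "[P.Value] < 0.05")
  expect_equal(ranked$pathway[[1]], "b_enriched")
  expect_true(ranked$z[[1]] > 0)
  expect_equal(ranked$pathway[[nrow(ranked) - 1L]], "a_depleted")
  expect_true(ranked$z[ranked$pathway == "a_depleted"] < 0)
  expect_true(is.na(ranked$z[[nrow(ranked)]]))
  expect_equal(ranked$pathway[[nrow(ranked)]], "z_undef")
  twins <- ranked[ranked$pathway %in% c("twin_a", "twin_b"), ]
  expect_equal(twins$z[[1]], twins$z[[2]])
  expect_equal(twins$pathway, c("twin_a", "twin_b"))  # name ascending on ties
  expect_error(rank_pathways(list(), tab, NULL, "1 = 1"), "non-empty")
})

test_that("shuffling table rows never changes a z score", {
  set.seed(8)
  fx <- make_fixture(fixture_spec(seed = 31, n_genes = 120, n_pathways = 3,
                                  genes_per_pathway = 15))
  r1 <- rank_pathways(fx$docs, fx$table, fx$store, "[P.Value] < 0.05")
  shuf <- fx$table
  perm <- sample(nrow(shuf$data))
  shuf$data <- shuf$data[perm, , drop = FALSE]
  rownames(shuf$data) <- NULL
  r2 <- rank_pathways(fx$docs, shuf, fx$store, "[P.Value] < 0.05")
  expect_equal(r1$z, r2$z)
  expect_equal(r1$pathway, r2$pathway)
})

test_that("score tables export with the stable column set and NaN markers", {
  df <- data.frame(identifier = c("a", "b"), P.Value = c(0.01, 0.5),
                   stringsAsFactors = FALSE)
  tab <- as_measurement_table(df, id_column = "identifier", syscode = "L")
  doc <- create_pathway("solo", "Homo sapiens")
  ranked <- rank_pathways(list(doc), tab, NULL, "[P.Value] < 0.05")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_scores(ranked, tmp)
  got <- utils::read.delim(tmp, check.names = FALSE)
  expect_equal(names(got), c("pathway", "file", "n", "r", "N", "R", "z"))
  expect_true(is.nan(got$z[[1]]))
})
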