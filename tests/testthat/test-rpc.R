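# Most RPC behaviour is tested through dispatch(), the same function the
# server loop calls; one test exercises the full HTTP round-trip against a
# server running in a background R process.

test_that("XML-RPC values survive an encode/decode round-trip", {
  roundtrip <- function(x) {
    xml <- xml2::read_xml(pathora:::xmlrpc_response_xml(x))
    pathora:::xmlrpc_decode_value(xml2::xml_find_first(xml, "./params/param/value"))
  }
  expect_identical(roundtrip("text & <markup>"), "text & <markup>")
  expect_identical(roundtrip(42L), 42L)
  expect_identical(roundtrip(3.5), 3.5)
  expect_identical(roundtrip(TRUE), TRUE)
  expect_identical(roundtrip(list("a", 1L)), list("a", 1L))
  expect_identical(roundtrip(list(n = 3L, z = 1.25)), list(n = 3L, z = 1.25))
})

test_that("dispatched pathway editing matches direct library calls", {
  s <- new_rpc_session()
  h <- dispatch("PathVisio.createPathway", list("Glycolysis"), s)
  expect_match(h, "^pw")
  id1 <- dispatch("PathVisio.addDataNode", list(h, "Fos", "GeneProduct", "14281", "L"), s)
  expect_equal(dispatch("PathVisio.getElementCount", list(h), s), 1L)
  id2 <- dispatch("PathVisio.addDataNode", list(h, "Nqo1"), s)
  dispatch("PathVisio.addInteraction", list(h, id1, id2), s)

  direct <- create_pathway("Glycolysis")
  d1 <- add_data_node(direct, "Fos", "GeneProduct", xref("14281", "L"))
  d2 <- add_data_node(direct, "Nqo1")
  add_interaction(direct, d1, d2)
  expect_true(pathway_equal(s$objects[[h]], direct))

  dispatch("PathVisio.removeElement", list(h, id2), s)
  remove_element(direct, d2)
  expect_true(pathway_equal(s$objects[[h]], direct))

  tmp <- withr::local_tempfile(fileext = ".gpml")
  dispatch("PathVisio.savePathway", list(h, tmp), s)
  expect_identical(readLines(tmp), strsplit(write_gpml(direct), "\n")[[1]])
  h2 <- dispatch("PathVisio.openPathway", list(tmp), s)
  expect_true(pathway_equal(s$objects[[h2]], direct))
})

test_that("dispatched analysis operations equal their direct counterparts on the fixture suite", {
  tmp <- withr::local_tempdir()
  fx <- make_fixture(fixture_spec(seed = 23, n_genes = 80, n_pathways = 3,
                                  genes_per_pathway = 10), dir = tmp)
  s <- new_rpc_session()
  tb <- dispatch("PathVisio.importData", list(fx$paths$data, "GeneID", "SysCode"), s)
  mp <- dispatch("PathVisio.loadMappingTable", list(fx$paths$mapping), s)

  some_l <- fx$table$data$identifier[[1]]
  expect_identical(unlist(dispatch("PathVisio.mapIdentifier", list(mp, some_l, "L", "En"), s)),
                   map_identifier(fx$store, some_l, "L", "En"))
  expect_identical(dispatch("PathVisio.isKnown", list(mp, some_l, "L"), s),
                   is_known(fx$store, some_l, "L"))

  got <- dispatch("PathVisio.calculateZScores",
                  list(fx$paths$pathway_dir, tb, mp, "[P.Value] < 0.05"), s)
  want <- rank_pathways(fx$paths$pathway_dir, fx$table, fx$store, "[P.Value] < 0.05")
  expect_equal(length(got), nrow(want))
  for (i in seq_along(got)) {
    expect_equal(got[[i]]$pathway, want$pathway[[i]])
    expect_equal(c(got[[i]]$n, got[[i]]$r, got[[i]]$N, got[[i]]$R),
                 c(want$n[[i]], want$r[[i]], want$N[[i]], want$R[[i]]))
    if (is.na(want$z[[i]])) expect_identical(got[[i]]$z, "NaN")
    else expect_equal(got[[i]]$z, want$z[[i]], tolerance = 1e-12)
  }
})

test_that("unknown methods, bad handles and domain errors come back as faults", {
  s <- new_rpc_session()
  expect_error(dispatch("PathVisio.noSuchMethod", list(), s), class = "rpc_fault")
  expect_error(dispatch("PathVisio.getElementCount", list("pw99"), s), class = "rpc_fault")
  expect_error(dispatch("PathVisio.createPathway", list(""), s), class = "rpc_fault")
  f <- tryCatch(dispatch("PathVisio.noSuchMethod", list(), s), rpc_fault = function(e) e)
  expect_equal(f$code, -32601L)
})

test_that("the server binds its documented default port when none is given", {
  h <- tryCatch(start_server(), error = function(e) e)
  # if something else occupies 7777 the startup error must name that port
  if (inherits(h, "error")) {
    expect_match(conditionMessage(h), "7777")
  } else {
    expect_equal(h$port, 7777L)
    expect_equal(h$state, "running")
    expect_error(start_server(7777), "7777")  # port already taken
    stop_server(h)
    expect_equal(h$state, "stopped")
    expect_error(stop_server(h), "not running")
  }
})

test_that("a live server answers namespaced calls over HTTP and shuts down", {
  port <- 18640 + (Sys.getpid() %% 100L)
  script <- withr::local_tempfile(fileext = ".R")
  writeLines(sprintf(
    "library(pathora); h <- start_server(%d); serve(h, max_requests = 6, timeout = 30); stop_server(h)",
    port), script)
  system2(file.path(R.home("bin"), "Rscript"), shQuote(script), wait = FALSE,
          env = paste0("R_LIBS=", shQuote(paste(.libPaths(), collapse = .Platform$path.sep))))
  up <- FALSE
  h <- NULL
  for (try in 1:40) {
    h <- tryCatch(
      suppressWarnings(rpc_call("PathVisio.createPathway", "Glycolysis", port = port)),
      error = function(e) NULL)
    if (!is.null(h)) { up <- TRUE; break }
    Sys.sleep(0.25)
  }
  expect_true(up)
  id <- rpc_call("PathVisio.addDataNode", h, "Fos", "GeneProduct", "14281", "L",
                 port = port)
  expect_equal(rpc_call("PathVisio.getElementCount", h, port = port), 1L)
  fault <- tryCatch(rpc_call("PathVisio.noSuchMethod", port = port),
                    rpc_fault = function(e) e)
  expect_s3_class(fault, "rpc_fault")
  expect_true(rpc_call("system.shutdown", port = port))
  # session state does not survive the stop: port refuses connections
  Sys.sleep(0.5)
  expect_error(suppressWarnings(rpc_call("PathVisio.getElementCount", h,
                                         port = port, timeout = 2)))
})
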