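# XML-RPC service: namespaced "PathVisio.<op>" methods over HTTP.
#
# The RPC layer exchanges opaque string handles ("pw1", "tb1", "mp1") for
# pathway documents, measurement tables and mapping stores, because
# XML-RPC can only pass scalars, arrays and structs; handles live in a
# per-server session store and expire when the server stops.  The server
# is a single-threaded accept loop on a base-R server socket; domain
# errors travel back as XML-RPC faults.

DEFAULT_RPC_PORT <- 7777L

rpc_fault <- function(code, message) {
  structure(class = c("rpc_fault", "error", "condition"),
            list(message = message, call = NULL, code = code))
}

# ---- value marshalling ----

xmlrpc_encode_value <- function(x) {
  if (is.null(x)) return("<value><array><data></data></array></value>")
  if (is.list(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x)))) {
      members <- vapply(names(x), function(nm) {
        sprintf("<member><name>%s</name>%s</member>",
                xml_escape(nm), xmlrpc_encode_value(x[[nm]]))
      }, "")
      return(sprintf("<value><struct>%s</struct></value>", paste(members, collapse = "")))
    }
    items <- vapply(x, xmlrpc_encode_value, "")
    return(sprintf("<value><array><data>%s</data></array></value>",
                   paste(items, collapse = "")))
  }
  if (length(x) != 1L) return(xmlrpc_encode_value(as.list(x)))
  if (is.logical(x)) return(sprintf("<value><boolean>%d</boolean></value>", as.integer(x)))
  if (is.integer(x)) return(sprintf("<value><i4>%d</i4></value>", x))
  if (is.numeric(x)) return(sprintf("<value><double>%s</double></value>", fmt_num(x)))
  sprintf("<value><string>%s</string></value>", xml_escape(as.character(x)))
}

xmlrpc_decode_value <- function(node) {
  kids <- xml2::xml_children(node)
  if (length(kids) == 0L) return(xml2::xml_text(node))
  t <- kids[[1L]]
  tn <- xml2::xml_name(t)
  switch(tn,
    string = xml2::xml_text(t),
    i4 = , int = as.integer(xml2::xml_text(t)),
    double = as.numeric(xml2::xml_text(t)),
    boolean = xml2::xml_text(t) %in% c("1", "true"),
    array = {
      vals <- xml2::xml_find_all(t, "./data/value")
      lapply(vals, xmlrpc_decode_value)
    },
    struct = {
      members <- xml2::xml_find_all(t, "./member")
      out <- lapply(members, function(m) {
        xmlrpc_decode_value(xml2::xml_find_first(m, "./value"))
      })
      names(out) <- vapply(members, function(m) {
        xml2::xml_text(xml2::xml_find_first(m, "./name"))
      }, "")
      out
    },
    xml2::xml_text(t))
}

xmlrpc_request_xml <- function(method, params) {
  paste0('<?xml version="1.0"?><methodCall><methodName>', xml_escape(method),
         '</methodName><params>',
         paste(vapply(params, function(p) sprintf("<param>%s</param>", xmlrpc_encode_value(p)), ""),
               collapse = ""),
         '</params></methodCall>')
}

xmlrpc_response_xml <- function(value) {
  paste0('<?xml version="1.0"?><methodResponse><params><param>',
         xmlrpc_encode_value(value), '</param></params></methodResponse>')
}

xmlrpc_fault_xml <- function(code, message) {
  paste0('<?xml version="1.0"?><methodResponse><fault>',
         xmlrpc_encode_value(list(faultCode = as.integer(code),
                                  faultString = message)),
         '</fault></methodResponse>')
}

# ---- session store & method registry ----

#' Create a fresh RPC session store
#'
#' Holds the objects behind the opaque string handles the RPC surface
#' exchanges.
#' @return An empty session environment.
#' @export
new_rpc_session <- function() {
  s <- new.env(parent = emptyenv())
  s$objects <- list()
  s$counter <- c(pw = 0L, tb = 0L, mp = 0L)
  s
}

session_put <- function(session, prefix, obj) {
  session$counter[[prefix]] <- session$counter[[prefix]] + 1L
  h <- sprintf("%s%d", prefix, session$counter[[prefix]])
  session$objects[[h]] <- obj
  h
}

session_get <- function(session, handle, class) {
  obj <- session$objects[[as.character(handle)]]
  if (is.null(obj) || !inherits(obj, class)) {
    stop(rpc_fault(2L, sprintf("unknown %s handle: %s", class, as.character(handle))))
  }
  obj
}

opt_arg <- function(params, i, default) {
  if (length(params) >= i && nzchar(as.character(params[[i]]))) params[[i]] else default
}

scores_to_structs <- function(ranked) {
  lapply(seq_len(nrow(ranked)), function(i) {
    z <- ranked$z[[i]]
    list(pathway = ranked$pathway[[i]], n = as.integer(ranked$n[[i]]),
         r = as.integer(ranked$r[[i]]), N = as.integer(ranked$N[[i]]),
         R = as.integer(ranked$R[[i]]),
         z = if (is.na(z)) "NaN" else as.numeric(z))
  })
}

rpc_methods <- function() {
  list(
    "PathVisio.createPathway" = function(s, p) {
      session_put(s, "pw", create_pathway(as.character(p[[1L]]),
                                          as.character(opt_arg(p, 2L, "Homo sapiens"))))
    },
    "PathVisio.openPathway" = function(s, p) {
      session_put(s, "pw", read_gpml(as.character(p[[1L]])))
    },
    "PathVisio.savePathway" = function(s, p) {
      doc <- session_get(s, p[[1L]], "PathwayDoc")
      write_gpml(doc, as.character(p[[2L]]))
      as.character(p[[2L]])
    },
    "PathVisio.addDataNode" = function(s, p) {
      doc <- session_get(s, p[[1L]], "PathwayDoc")
      xr <- NULL
      id <- as.character(opt_arg(p, 4L, ""))
      code <- as.character(opt_arg(p, 5L, ""))
      if (nzchar(id) && nzchar(code)) xr <- xref(id, code)
      add_data_node(doc, as.character(p[[2L]]),
                    node_type = as.character(opt_arg(p, 3L, "GeneProduct")), xref = xr)
    },
    "PathVisio.addInteraction" = function(s, p) {
      doc <- session_get(s, p[[1L]], "PathwayDoc")
      add_interaction(doc, as.character(p[[2L]]), as.character(p[[3L]]),
                      interaction_type = as.character(opt_arg(p, 4L, "arrow")))
    },
    "PathVisio.removeElement" = function(s, p) {
      doc <- session_get(s, p[[1L]], "PathwayDoc")
      remove_element(doc, as.character(p[[2L]]))
      TRUE
    },
    "PathVisio.getElementCount" = function(s, p) {
      doc <- session_get(s, p[[1L]], "PathwayDoc")
      element_count(doc)
    },
    "PathVisio.importData" = function(s, p) {
      session_put(s, "tb", import_data(as.character(p[[1L]]),
                                       id_column = as.character(p[[2L]]),
                                       syscode = as.character(p[[3L]])))
    },
    "PathVisio.loadMappingTable" = function(s, p) {
      session_put(s, "mp", load_mapping_table(as.character(p[[1L]])))
    },
    "PathVisio.mapIdentifier" = function(s, p) {
      store <- session_get(s, p[[1L]], "MappingStore")
      as.list(map_identifier(store, as.character(p[[2L]]),
                             as.character(p[[3L]]), as.character(p[[4L]])))
    },
    "PathVisio.isKnown" = function(s, p) {
      store <- session_get(s, p[[1L]], "MappingStore")
      is_known(store, as.character(p[[2L]]), as.character(p[[3L]]))
    },
    "PathVisio.calculateZScores" = function(s, p) {
      table <- session_get(s, p[[2L]], "MeasurementTable")
      mp <- as.character(opt_arg(p, 3L, ""))
      store <- if (nzchar(mp)) session_get(s, mp, "MappingStore") else NULL
      ranked <- rank_pathways(as.character(p[[1L]]), table, store,
                              as.character(p[[4L]]))
      scores_to_structs(ranked)
    },
    "PathVisio.exportPathwayHtml" = function(s, p) {
      doc <- session_get(s, p[[1L]], "PathwayDoc")
      out_dir <- as.character(p[[2L]])
      rendered <- render_pathway(doc)
      export_pathway_html(doc, rendered, NULL, out_dir)
      out_dir
    },
    "PathVisio.visualizeData" = function(s, p) {
      doc <- session_get(s, p[[1L]], "PathwayDoc")
      table <- session_get(s, p[[2L]], "MeasurementTable")
      mp <- as.character(opt_arg(p, 3L, ""))
      store <- if (nzchar(mp)) session_get(s, mp, "MappingStore") else NULL
      spec <- build_spec(as.character(unlist(p[[4L]])), as.character(unlist(p[[5L]])))
      out_dir <- as.character(p[[6L]])
      lk <- link_to_pathway(table, doc, store)
      rendered <- render_pathway(doc, lk, table, spec)
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_image(rendered, file.path(out_dir, "pathway.png"))
      write_image(rendered, file.path(out_dir, "pathway.svg"))
      export_pathway_html(doc, rendered, table, out_dir)
      out_dir
    },
    "system.listMethods" = function(s, p) as.list(names(rpc_methods()))
  )
}

#' Dispatch one RPC method call
#'
#' Maps a namespaced method name (`"PathVisio.<op>"`) plus marshalled
#' parameters onto the corresponding library operation.  Documents,
#' tables and mapping stores travel as opaque string handles stored in
#' `session`.  This is exactly the function the server loop calls, so
#' direct dispatch and a call over the wire produce identical results.
#'
#' @param method Namespaced method name.
#' @param params List of parameters (XML-RPC scalars/arrays/structs).
#' @param session Session store from [new_rpc_session()] (one is created
#'   on the fly if omitted, useful for single calls).
#' @return The operation result (scalar, list, or list of structs).
#'   Unknown methods and domain errors raise conditions of class
#'   `rpc_fault`.
#' @export
dispatch <- function(method, params = list(), session = new_rpc_session()) {
  fns <- rpc_methods()
  fn <- fns[[method]]
  if (is.null(fn)) stop(rpc_fault(-32601L, sprintf("unknown method: %s", method)))
  tryCatch(
    fn(session, params),
    rpc_fault = function(e) stop(e),
    error = function(e) stop(rpc_fault(1L, conditionMessage(e)))
  )
}

# ---- HTTP server ----

#' Start the XML-RPC server
#'
#' Binds a listening socket on `port` (default 7777) and returns a handle
#' with a fresh session store.  The handle must then be passed to
#' [serve()], which blocks processing requests, or to [stop_server()].
#'
#' @param port TCP port; the port must be free.
#' @return A `ServerHandle`.
#' @export
start_server <- function(port = DEFAULT_RPC_PORT) {
  sock <- tryCatch(
    serverSocket(as.integer(port)),
    error = function(e) stop(sprintf("cannot start server on port %d: %s",
                                     as.integer(port), conditionMessage(e)),
                             call. = FALSE)
  )
  h <- new.env(parent = emptyenv())
  h$socket <- sock
  h$port <- as.integer(port)
  h$state <- "running"
  h$session <- new_rpc_session()
  class(h) <- "ServerHandle"
  h
}

#' @export
print.ServerHandle <- function(x, ...) {
  cat(sprintf("<ServerHandle: port %d, %s>\n", x$port, x$state))
  invisible(x)
}

#' Stop the XML-RPC server
#'
#' Releases the port and discards the session store (handles do not
#' survive a stop/start cycle).
#'
#' @param handle A running `ServerHandle`.
#' @return Invisibly `NULL`.
#' @export
stop_server <- function(handle) {
  stopifnot(inherits(handle, "ServerHandle"))
  if (handle$state != "running") stop("server is not running", call. = FALSE)
  close(handle$socket)
  handle$state <- "stopped"
  handle$session <- NULL
  invisible(NULL)
}

read_http_request <- function(con) {
  request_line <- readLines(con, n = 1L)
  if (length(request_line) == 0L) return(NULL)
  len <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !nzchar(line)) break
    if (grepl("^content-length:", line, ignore.case = TRUE)) {
      len <- as.integer(trimws(sub("^[^:]*:", "", line)))
    }
  }
  if (len <= 0L) return("")
  rawToChar(readBin(con, "raw", n = len))
}

http_response <- function(body, status = "200 OK") {
  paste0("HTTP/1.1 ", status, "\r\n",
         "Content-Type: text/xml\r\n",
         "Content-Length: ", nchar(body, type = "bytes"), "\r\n",
         "Connection: close\r\n\r\n", body)
}

#' Serve RPC requests (blocking)
#'
#' Accepts connections one at a time, decodes each XML-RPC call, runs it
#' through [dispatch()] against the handle's session store, and returns
#' the result (or an XML-RPC fault).  The loop ends after `max_requests`
#' calls or when a client invokes the `system.shutdown` method.
#'
#' @param handle A running `ServerHandle`.
#' @param max_requests Stop after this many requests (`Inf` to run until
#'   shutdown).
#' @param timeout Per-accept timeout in seconds.
#' @return Number of requests served, invisibly.
#' @export
serve <- function(handle, max_requests = Inf, timeout = 60) {
  stopifnot(inherits(handle, "ServerHandle"))
  if (handle$state != "running") stop("server is not running", call. = FALSE)
  served <- 0L
  while (served < max_requests) {
    con <- tryCatch(
      socketAccept(handle$socket, blocking = TRUE, open = "r+b", timeout = timeout),
      error = function(e) NULL
    )
    if (is.null(con)) break
    shutdown <- FALSE
    body <- tryCatch(read_http_request(con), error = function(e) NULL)
    if (!is.null(body) && nzchar(body)) {
      resp <- tryCatch({
        req <- xml2::read_xml(body)
        method <- xml2::xml_text(xml2::xml_find_first(req, "./methodName"))
        params <- lapply(xml2::xml_find_all(req, "./params/param/value"),
                         xmlrpc_decode_value)
        if (method == "system.shutdown") {
          shutdown <- TRUE
          xmlrpc_response_xml(TRUE)
        } else {
          xmlrpc_response_xml(dispatch(method, params, handle$session))
        }
      },
      rpc_fault = function(e) xmlrpc_fault_xml(e$code, conditionMessage(e)),
      error = function(e) xmlrpc_fault_xml(1L, conditionMessage(e)))
      writeBin(charToRaw(http_response(resp)), con)
      served <- served + 1L
    }
    close(con)
    if (shutdown) break
  }
  invisible(served)
}

#' Call a method on a running XML-RPC server
#'
#' Minimal XML-RPC client used by the command line and the test suite.
#'
#' @param method Namespaced method name.
#' @param ... Method parameters.
#' @param host Server host.
#' @param port Server port.
#' @param timeout Connection timeout in seconds.
#' @return The decoded result.  Server faults are re-raised as errors of
#'   class `rpc_fault`.
#' @export
rpc_call <- function(method, ..., host = "127.0.0.1", port = DEFAULT_RPC_PORT,
                     timeout = 10) {
  body <- xmlrpc_request_xml(method, list(...))
  con <- socketConnection(host, port, open = "r+b", blocking = TRUE,
                          timeout = timeout)
  on.exit(close(con))
  req <- paste0("POST /RPC2 HTTP/1.1\r\nHost: ", host,
                "\r\nContent-Type: text/xml\r\nContent-Length: ",
                nchar(body, type = "bytes"), "\r\n\r\n", body)
  writeBin(charToRaw(req), con)
  status <- readLines(con, n = 1L)
  len <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !nzchar(line)) break
    if (grepl("^content-length:", line, ignore.case = TRUE)) {
      len <- as.integer(trimws(sub("^[^:]*:", "", line)))
    }
  }
  resp_body <- rawToChar(readBin(con, "raw", n = len))
  resp <- xml2::read_xml(resp_body)
  fault <- xml2::xml_find_first(resp, "./fault/value")
  if (!inherits(fault, "xml_missing")) {
    f <- xmlrpc_decode_value(fault)
    stop(rpc_fault(f$faultCode, f$faultString))
  }
  xmlrpc_decode_value(xml2::xml_find_first(resp, "./params/param/value"))
}
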