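# Criterion expressions: boolean filters over measurement-table rows,
# written in a bracketed-column dialect, e.g.
#   [P.Value] < 0.05 AND ([logFC] > 1 OR [logFC] < -1)
# Comparators: < <= > >= = <>; connectives AND OR NOT (case-insensitive);
# precedence NOT > comparison > AND > OR; parentheses override.
# Evaluation uses three-valued (Kleene) logic: a comparison touching a
# missing cell yields missing; AND(false, missing) = false,
# OR(true, missing) = true, otherwise missing propagates.

criterion_tokenize <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, pos) tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, pos = pos)
  while (i <= n) {
    rest <- substr(text, i, n)
    if (grepl("^\\s", rest)) { i <- i + 1L; next }
    m <- regmatches(rest, regexpr("^\\[[^]]*\\]", rest))
    if (length(m)) {
      nm <- substr(m, 2L, nchar(m) - 1L)
      if (!nzchar(nm)) stop(sprintf("criterion syntax error at position %d: empty column name", i), call. = FALSE)
      push("col", nm, i); i <- i + nchar(m); next
    }
    m <- regmatches(rest, regexpr("^(<=|>=|<>|<|>|=)", rest))
    if (length(m)) { push("cmp", m, i); i <- i + nchar(m); next }
    if (substr(rest, 1L, 1L) == "(") { push("lpar", "(", i); i <- i + 1L; next }
    if (substr(rest, 1L, 1L) == ")") { push("rpar", ")", i); i <- i + 1L; next }
    m <- regmatches(rest, regexpr("^-?(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?", rest))
    if (length(m)) { push("num", as.numeric(m), i); i <- i + nchar(m); next }
    m <- regmatches(rest, regexpr("^\"[^\"]*\"|^'[^']*'", rest))
    if (length(m)) { push("str", substr(m, 2L, nchar(m) - 1L), i); i <- i + nchar(m); next }
    m <- regmatches(rest, regexpr("^[A-Za-z]+", rest))
    if (length(m)) {
      kw <- toupper(m)
      if (kw %in% c("AND", "OR", "NOT")) { push(tolower(kw), kw, i); i <- i + nchar(m); next }
      stop(sprintf("criterion syntax error at position %d: unknown token %s", i, dQuote(m)), call. = FALSE)
    }
    stop(sprintf("criterion syntax error at position %d: unexpected character %s",
                 i, dQuote(substr(rest, 1L, 1L))), call. = FALSE)
  }
  tokens
}

#' Parse a criterion expression
#'
#' @param text Criterion string; column references are written in square
#'   brackets (`[P.Value] < 0.05`).
#' @return A `CriterionAST` object usable with [evaluate_criterion()].
#' @export
#' @examples
#' parse_criterion("[P.Value] < 0.05")
parse_criterion <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("criterion text must be a non-empty string", call. = FALSE)
  }
  tokens <- criterion_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { tk <- peek(); pos <<- pos + 1L; tk }
  fail <- function(tk, what) {
    at <- if (is.null(tk)) nchar(text) + 1L else tk$pos
    stop(sprintf("criterion syntax error at position %d: expected %s", at, what), call. = FALSE)
  }
  parse_operand <- function() {
    tk <- peek()
    if (is.null(tk) || !tk$type %in% c("col", "num", "str")) fail(tk, "a column reference or literal")
    advance()
    list(op = tk$type, value = tk$value)
  }
  parse_primary <- function() {
    tk <- peek()
    if (!is.null(tk) && tk$type == "lpar") {
      advance()
      node <- parse_or()
      tk2 <- peek()
      if (is.null(tk2) || tk2$type != "rpar") fail(tk2, "')'")
      advance()
      return(node)
    }
    lhs <- parse_operand()
    op <- peek()
    if (is.null(op) || op$type != "cmp") fail(op, "a comparator (< <= > >= = <>)")
    advance()
    rhs <- parse_operand()
    list(op = "cmp", cmp = op$value, lhs = lhs, rhs = rhs)
  }
  parse_not <- function() {
    tk <- peek()
    if (!is.null(tk) && tk$type == "not") {
      advance()
      return(list(op = "not", arg = parse_not()))
    }
    parse_primary()
  }
  parse_and <- function() {
    node <- parse_not()
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      node <- list(op = "and", lhs = node, rhs = parse_not())
    }
    node
  }
  parse_or <- function() {
    node <- parse_and()
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      node <- list(op = "or", lhs = node, rhs = parse_and())
    }
    node
  }
  ast <- parse_or()
  tk <- peek()
  if (!is.null(tk)) fail(tk, "end of expression")
  structure(ast, class = "CriterionAST", text = text)
}

#' @export
print.CriterionAST <- function(x, ...) {
  cat(sprintf("<criterion: %s>\n", attr(x, "text")))
  invisible(x)
}

#' Column names referenced by a criterion
#' @param ast A `CriterionAST`.
#' @return Character vector of column names.
#' @export
criterion_columns <- function(ast) {
  walk <- function(node) {
    switch(node$op,
      col = node$value,
      num = , str = character(0),
      cmp = c(walk(node$lhs), walk(node$rhs)),
      not = walk(node$arg),
      c(walk(node$lhs), walk(node$rhs)))
  }
  unique(walk(ast))
}

resolve_operand <- function(node, row) {
  if (node$op != "col") return(node$value)
  if (!node$value %in% names(row)) {
    stop(sprintf("criterion references unknown column %s", dQuote(node$value)), call. = FALSE)
  }
  v <- row[[node$value]]
  if (length(v) != 1L) v <- v[[1L]]
  v
}

compare_cells <- function(cmp, a, b) {
  missing_val <- function(v) {
    is.null(v) || length(v) == 0L || is.na(v) || (is.character(v) && !nzchar(v))
  }
  if (missing_val(a) || missing_val(b)) return(NA)
  an <- suppressWarnings(as.numeric(a))
  bn <- suppressWarnings(as.numeric(b))
  if (!is.na(an) && !is.na(bn)) { a <- an; b <- bn }
  else { a <- as.character(a); b <- as.character(b) }
  switch(cmp,
    "<"  = a < b,
    "<=" = a <= b,
    ">"  = a > b,
    ">=" = a >= b,
    "="  = a == b,
    "<>" = a != b)
}

#' Evaluate a criterion on one row
#'
#' @param ast A `CriterionAST` from [parse_criterion()].
#' @param row Named list or one-row data frame of cell values; missing
#'   cells are `NA` or the empty string.
#' @return `TRUE`, `FALSE`, or `NA` (missing) under three-valued logic.
#' @export
#' @examples
#' evaluate_criterion(parse_criterion("[P] < 0.05"), list(P = 0.01))
evaluate_criterion <- function(ast, row) {
  eval_node <- function(node) {
    switch(node$op,
      cmp = compare_cells(node$cmp, resolve_operand(node$lhs, row),
                          resolve_operand(node$rhs, row)),
      not = !eval_node(node$arg),
      and = eval_node(node$lhs) & eval_node(node$rhs),
      or  = eval_node(node$lhs) | eval_node(node$rhs),
      stop("malformed criterion AST", call. = FALSE))
  }
  eval_node(ast)
}
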