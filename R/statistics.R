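# Z-score over-representation analysis of a pathway collection.
#
# For each pathway the dataset supplies four counts over DISTINCT unified
# gene identities: N measured genes, R of them meeting the criterion, n of
# them linked to the pathway, r of those meeting the criterion.  The score
# standardises the observed r against the hypergeometric expectation:
#
#   z = (r - n R / N) / sqrt( n (R/N) (1 - R/N) (1 - (n-1)/(N-1)) )
#
# i.e. the expected number of criterion genes in a random draw of n genes
# from the dataset, with finite-population-corrected variance.  A positive
# score means the pathway holds more changed genes than expected.  The
# score is undefined (NA) when the variance is zero (n = 0, n = N, R = 0
# or R = N).
#
# Gene unification: each measurement row resolves to its mapping-store
# equivalence class (or to its own (code, identifier) pair when no store
# is supplied); duplicate probes therefore count once, and a gene meets
# the criterion when ANY of its rows does.  With a mapping store, rows
# whose identifier the store does not know are excluded from N entirely
# (they can never hit a pathway); the excluded count is reported.

#' Criterion counts for one pathway
#'
#' @param doc A `PathwayDoc`.
#' @param table A `MeasurementTable`.
#' @param store A `MappingStore`, or `NULL` for identity matching (every
#'   distinct row identity counts as measured).
#' @param criterion Criterion text or `CriterionAST`.
#' @return A `CriterionCounts` list with fields `N`, `R`, `n`, `r` and
#'   `excluded` (rows dropped because the store does not know their
#'   identifier).
#' @export
count_criterion <- function(doc, table, store, criterion, .summary = NULL) {
  stopifnot(is_pathway_doc(doc), inherits(table, "MeasurementTable"))
  ast <- if (inherits(criterion, "CriterionAST")) criterion else parse_criterion(criterion)
  if (is.null(.summary)) .summary <- criterion_gene_summary(table, store, ast)
  gene_met <- .summary$gene_met
  N <- length(gene_met)
  R <- sum(gene_met)
  # genes linked to the pathway: unified identities of node xrefs that are
  # measured
  node_keys <- character(0)
  for (id in element_ids(doc, "DataNode")) {
    xr <- doc$elements[[id]]$xref
    if (is.null(xr)) next
    node_keys <- c(node_keys, unified_key(store, xr$system_code, xr$identifier))
  }
  in_pathway <- intersect(unique(node_keys), names(gene_met))
  n <- length(in_pathway)
  r <- sum(gene_met[in_pathway])
  structure(list(N = as.integer(N), R = as.integer(R),
                 n = as.integer(n), r = as.integer(r),
                 excluded = .summary$excluded),
            class = "CriterionCounts")
}

# Per-dataset summary shared across pathways: unified gene identities and
# whether each gene meets the criterion.  Rows unknown to the mapping
# store are excluded (they can never hit a pathway); a gene meets the
# criterion when any of its rows does.
criterion_gene_summary <- function(table, store, ast) {
  absent <- setdiff(criterion_columns(ast), names(table$data))
  if (length(absent)) {
    stop(sprintf("criterion references absent column(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  d <- table$data
  nr <- nrow(d)
  if (is.null(store)) {
    keys <- paste0("pair:", mkey(d$system_code, d$identifier))
    keep <- rep(TRUE, nr)
  } else {
    sets <- unname(store$set_of[mkey(d$system_code, d$identifier)])
    keep <- !is.na(sets)
    keys <- paste0("set:", sets)
  }
  met <- logical(nr)
  cols <- as.list(d)  # column access is much cheaper than row slicing
  for (i in which(keep)) {
    met[[i]] <- isTRUE(evaluate_criterion(ast, lapply(cols, `[[`, i)))
  }
  gene_met <- if (any(keep)) {
    vapply(split(met[keep], keys[keep]), any, TRUE)
  } else {
    stats::setNames(logical(0), character(0))
  }
  list(gene_met = gene_met, excluded = as.integer(sum(!keep)))
}

#' @export
print.CriterionCounts <- function(x, ...) {
  cat(sprintf("<CriterionCounts: N=%d R=%d n=%d r=%d (excluded rows: %d)>\n",
              x$N, x$R, x$n, x$r, x$excluded))
  invisible(x)
}

#' Over-representation Z score
#'
#' @param counts A `CriterionCounts`, or a list/vector with elements
#'   `N`, `R`, `n`, `r`.
#' @return The Z score, or `NA` when the hypergeometric variance is zero.
#' @export
#' @examples
#' zscore(list(N = 100, R = 50, n = 10, r = 5))  # observed == expected: 0
zscore <- function(counts) {
  N <- counts[["N"]]; R <- counts[["R"]]; n <- counts[["n"]]; r <- counts[["r"]]
  if (anyNA(c(N, R, n, r)) || N < 0 || R < 0 || n < 0 || r < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (r > n || n > N || r > R || R > N) {
    stop("invalid counts: need 0 <= r <= n <= N and r <= R <= N", call. = FALSE)
  }
  if (n == 0L || N <= 1L) return(NA_real_)
  p <- R / N
  variance <- n * p * (1 - p) * (1 - (n - 1) / (N - 1))
  if (variance <= 0) return(NA_real_)
  (r - n * p) / sqrt(variance)
}

#' Rank a pathway collection by Z score
#'
#' Computes one [count_criterion()] + [zscore()] per pathway and orders
#' the result by descending z; undefined scores sort last; ties break by
#' pathway name ascending.
#'
#' @param collection List of `PathwayDoc` objects (optionally named by
#'   file path), or a directory containing `.gpml` files.
#' @inheritParams count_criterion
#' @return A `RankedResult`: data frame with columns `pathway`, `file`,
#'   `n`, `r`, `N`, `R`, `z`, carrying the criterion text and dataset
#'   provenance as attributes.
#' @export
rank_pathways <- function(collection, table, store, criterion) {
  if (is.character(collection) && length(collection) == 1L) {
    collection <- read_gpml_collection(collection)
  }
  if (!is.list(collection) || length(collection) == 0L ||
      !all(vapply(collection, is_pathway_doc, TRUE))) {
    stop("collection must be a non-empty list of PathwayDoc objects", call. = FALSE)
  }
  ast <- if (inherits(criterion, "CriterionAST")) criterion else parse_criterion(criterion)
  files <- names(collection)
  if (is.null(files)) files <- rep(NA_character_, length(collection))
  summary <- criterion_gene_summary(table, store, ast)
  rows <- lapply(seq_along(collection), function(i) {
    doc <- collection[[i]]
    cc <- count_criterion(doc, table, store, ast, .summary = summary)
    data.frame(pathway = doc$name, file = files[[i]],
               n = cc$n, r = cc$r, N = cc$N, R = cc$R,
               z = zscore(cc), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  ord <- order(is.na(res$z), -ifelse(is.na(res$z), 0, res$z), res$pathway)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "criterion") <- attr(ast, "text")
  attr(res, "dataset") <- if (is.na(table$path)) "<in-memory table>" else table$path
  class(res) <- c("RankedResult", "data.frame")
  res
}

#' @export
print.RankedResult <- function(x, ...) {
  cat(sprintf("Pathway over-representation ranking (criterion: %s)\n",
              attr(x, "criterion")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a ranked result as TSV
#'
#' Stable column set: pathway, file, n, r, N, R, z; undefined scores are
#' written as `NaN`.
#'
#' @param ranked A `RankedResult`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scores <- function(ranked, path) {
  stopifnot(inherits(ranked, "RankedResult"))
  out <- ranked
  z_chr <- ifelse(is.na(out$z), "NaN", vapply(out$z, fmt_num, ""))
  out$z <- z_chr
  lines <- c(paste(c("pathway", "file", "n", "r", "N", "R", "z"), collapse = "\t"),
             vapply(seq_len(nrow(out)), function(i) {
               paste(c(out$pathway[[i]],
                       ifelse(is.na(out$file[[i]]), "", out$file[[i]]),
                       out$n[[i]], out$r[[i]], out$N[[i]], out$R[[i]], out$z[[i]]),
                     collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
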