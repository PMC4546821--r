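# Deterministic generators for toy pathway collections, mapping tables and
# measurement tables with planted statistical structure.
#
# The generator emulates the shape of a differential-expression statistics
# table (one row per gene, logFC and P-value columns) scored against a
# small pathway collection.  Two identifier systems are generated — an
# Entrez-like numeric system ("L") used by the measurement table and an
# Ensembl-like accession system ("En") used by the pathway nodes — joined
# by a known bijection in the mapping TSV, so linking always exercises the
# mapper.  A configurable fraction of measurement rows carries identifiers
# absent from the mapping table (unmappable rows).
#
# Hit structure: each gene's criterion status is drawn Bernoulli — genes
# of the first ("enriched") pathway at `enriched_pathway_rate`, all others
# at `background_hit_rate` — and the P.Value column is then set to 0.01
# (hit) or 0.5 (non-hit), so the criterion "[P.Value] < 0.05" recovers the
# planted truth exactly.  Pathways draw disjoint gene sets.  The truth
# record stores the exact (N, R, n, r) per pathway.

#' Fixture generation settings
#'
#' Defaults describe a mid-sized differential-expression experiment: 1000
#' measured genes, five disjoint pathways of 30 genes, a background
#' criterion hit rate of 0.2 with the first pathway enriched threefold
#' (rate 0.6), 5% unmappable rows, no missing cells.
#'
#' @param seed Integer seed; generation is fully determined by it.
#' @param n_genes Number of mappable measured genes.
#' @param n_pathways Number of pathways (the first is the enriched one).
#' @param genes_per_pathway Genes per pathway; `n_pathways *
#'   genes_per_pathway` must not exceed `n_genes`.
#' @param background_hit_rate Probability that a background gene meets the
#'   criterion.
#' @param enriched_pathway_rate Probability for genes of the enriched
#'   pathway (defaults to three times the background).
#' @param n_value_columns Number of logFC/P column pairs (e.g. time
#'   points); the criterion column is always `P.Value` (the first pair's
#'   P column is named `P.Value`).
#' @param missing_rate Probability that a non-criterion cell is missing.
#' @param unmappable_rate Extra measurement rows (as a fraction of
#'   `n_genes`) whose identifiers the mapping table does not know.
#' @return A `FixtureSpec` list.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 1000L, n_pathways = 5L,
                         genes_per_pathway = 30L,
                         background_hit_rate = 0.2,
                         enriched_pathway_rate = 3 * background_hit_rate,
                         n_value_columns = 1L,
                         missing_rate = 0,
                         unmappable_rate = 0.05) {
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               n_pathways = as.integer(n_pathways),
               genes_per_pathway = as.integer(genes_per_pathway),
               background_hit_rate = background_hit_rate,
               enriched_pathway_rate = enriched_pathway_rate,
               n_value_columns = as.integer(n_value_columns),
               missing_rate = missing_rate,
               unmappable_rate = unmappable_rate)
  probs <- c(spec$background_hit_rate, spec$enriched_pathway_rate,
             spec$missing_rate, spec$unmappable_rate)
  if (any(probs < 0 | probs > 1)) stop("rates must be probabilities in [0, 1]", call. = FALSE)
  if (spec$n_genes < 1L || spec$n_pathways < 1L || spec$genes_per_pathway < 1L) {
    stop("counts must be positive", call. = FALSE)
  }
  if (spec$n_pathways * spec$genes_per_pathway > spec$n_genes) {
    stop("n_pathways * genes_per_pathway must not exceed n_genes", call. = FALSE)
  }
  structure(spec, class = "FixtureSpec")
}

#' Generate a complete analysis fixture
#'
#' Writes a pathway collection (GPML files), an identifier mapping TSV and
#' a measurement TSV under `dir`, and returns them together with in-memory
#' objects and the exact truth record.
#'
#' @param spec A `FixtureSpec`.
#' @param dir Output directory (created); pass `NULL` to skip writing and
#'   return in-memory objects only.
#' @return List with `paths` (pathway_dir, mapping, data), in-memory
#'   `docs`, `store`, `table`, and `truth` — a list with dataset-wide `N`
#'   and `R`, per-pathway `n` and `r` vectors, the `enriched` pathway
#'   index, and the planted per-gene hit status.
#' @export
make_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  l_ids <- as.character(100000L + seq_len(ng))
  en_ids <- sprintf("ENSFIX%08d", seq_len(ng))
  # disjoint pathway membership over a shuffled gene order
  shuffled <- sample.int(ng)
  membership <- rep(0L, ng)
  for (p in seq_len(spec$n_pathways)) {
    take <- shuffled[((p - 1L) * spec$genes_per_pathway + 1L):(p * spec$genes_per_pathway)]
    membership[take] <- p
  }
  hit_prob <- ifelse(membership == 1L, spec$enriched_pathway_rate, spec$background_hit_rate)
  hit <- stats::runif(ng) < hit_prob

  # measurement table: mappable genes (system L) plus unmappable extras
  n_extra <- as.integer(round(spec$unmappable_rate * ng))
  ids <- c(l_ids, as.character(900000L + seq_len(n_extra)))
  hits_all <- c(hit, stats::runif(n_extra) < spec$background_hit_rate)
  tab <- data.frame(GeneID = ids, SysCode = rep("L", length(ids)),
                    stringsAsFactors = FALSE)
  for (k in seq_len(spec$n_value_columns)) {
    lfc <- round(stats::rnorm(length(ids), mean = ifelse(hits_all, 1.2, 0), sd = 0.4), 4)
    pv <- ifelse(hits_all, 0.01, 0.5)
    if (spec$missing_rate > 0) {
      lfc[stats::runif(length(ids)) < spec$missing_rate] <- NA
      if (k > 1L) pv[stats::runif(length(ids)) < spec$missing_rate] <- NA
    }
    lfc_name <- if (spec$n_value_columns == 1L) "logFC" else sprintf("logFC_%d", k)
    p_name <- if (k == 1L) "P.Value" else sprintf("P.Value_%d", k)
    tab[[lfc_name]] <- lfc
    tab[[p_name]] <- pv
  }

  # mapping TSV links every mappable gene's L id to its En partner
  map_df <- data.frame(source_code = "L", source_id = l_ids,
                       target_code = "En", target_id = en_ids,
                       stringsAsFactors = FALSE)

  # pathway documents: nodes carry En xrefs
  docs <- vector("list", spec$n_pathways)
  for (p in seq_len(spec$n_pathways)) {
    nm <- sprintf("pathway_%02d%s", p, if (p == 1L) "_enriched" else "")
    doc <- create_pathway(nm, "Mus musculus")
    for (g in which(membership == p)) {
      add_data_node(doc, label = sprintf("G%04d", g), node_type = "GeneProduct",
                    xref = xref(en_ids[[g]], "En"))
    }
    docs[[p]] <- doc
  }
  names(docs) <- vapply(docs, function(d) d$name, "")

  truth <- list(
    N = ng, R = sum(hit),
    n = rep(spec$genes_per_pathway, spec$n_pathways),
    r = vapply(seq_len(spec$n_pathways), function(p) sum(hit[membership == p]), 0L),
    enriched = 1L,
    gene_hit = hit, membership = membership,
    n_unmappable = n_extra
  )

  paths <- NULL
  store <- NULL
  table <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pw_dir <- file.path(dir, "pathways")
    dir.create(pw_dir, showWarnings = FALSE)
    for (p in seq_len(spec$n_pathways)) {
      write_gpml(docs[[p]], file.path(pw_dir, paste0(docs[[p]]$name, ".gpml")))
    }
    map_path <- file.path(dir, "mapping.tsv")
    writeLines(c(paste(c("source_code", "source_id", "target_code", "target_id"),
                       collapse = "\t"),
                 paste(map_df$source_code, map_df$source_id,
                       map_df$target_code, map_df$target_id, sep = "\t")),
               map_path)
    data_path <- file.path(dir, "measurements.tsv")
    cells <- vapply(seq_len(nrow(tab)), function(i) {
      paste(vapply(names(tab), function(cl) {
        v <- tab[[cl]][[i]]
        if (is.na(v)) "NA" else if (is.numeric(v)) fmt_num(v) else as.character(v)
      }, ""), collapse = "\t")
    }, "")
    writeLines(c(paste(names(tab), collapse = "\t"), cells), data_path)
    paths <- list(pathway_dir = pw_dir, mapping = map_path, data = data_path)
    store <- load_mapping_table(map_path, species = "Mus musculus")
    table <- import_data(data_path, id_column = "GeneID", syscode = "SysCode")
  } else {
    store <- mapping_store_from_df(map_df, species = "Mus musculus")
    table <- as_measurement_table(tab, id_column = "GeneID", syscode = "SysCode")
  }
  list(spec = spec, paths = paths, docs = docs, store = store, table = table,
       truth = truth)
}

# In-memory construction of a MappingStore from a link data frame,
# bypassing the TSV round-trip (same union-find semantics as
# load_mapping_table).
mapping_store_from_df <- function(map_df, species = NA_character_) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(c(paste(c("source_code", "source_id", "target_code", "target_id"),
                     collapse = "\t"),
               if (nrow(map_df)) paste(map_df$source_code, map_df$source_id,
                                       map_df$target_code, map_df$target_id, sep = "\t")),
             tmp)
  load_mapping_table(tmp, species = species)
}
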