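#' Local pathway over-representation analysis
#'
#' Tests a gene set against every pathway of a GMT library with the exact
#' one-sided hypergeometric test (the same core as [set_enrichment()]) over
#' a common background, BH-adjusted within the library.
#'
#' @param gene_set Character vector of query genes (subset of background).
#' @param library Named list of pathway gene sets (from [read_gmt()]).
#' @param background Background gene universe.
#' @return `data.table` PATHWAY, OVERLAP, UNIT_SIZE, CATALOG_SIZE,
#'   BACKGROUND_SIZE, FOLD, P, FDR sorted by p.
#' @export
ora <- function(gene_set, library, background) {
  if (!length(library)) stop_cfg("empty pathway library")
  rows <- lapply(names(library), function(pw) {
    cbind(data.table::data.table(PATHWAY = pw),
          set_enrichment(intersect(gene_set, background), library[[pw]], background))
  })
  res <- data.table::rbindlist(rows)
  res[, FDR := bh_fdr(P)]
  res[order(P, PATHWAY)]
}

#' Rank pathways across module ORA tables by system
#'
#' For each system, summarizes every pathway by the median of its -log10
#' adjusted p across the contributing module tables, and returns the top
#' terms per system.
#'
#' @param ora_tables_by_system Named list: system -> list of ORA tables.
#' @param top_k Rows kept per system.
#' @return `data.table` SYSTEM, PATHWAY, MEDIAN_NEG_LOG10_FDR, N_TABLES.
#' @export
rank_pathways_across_modules <- function(ora_tables_by_system, top_k = 3L) {
  rows <- lapply(names(ora_tables_by_system), function(sys) {
    tabs <- ora_tables_by_system[[sys]]
    if (!length(tabs)) return(NULL)
    all <- data.table::rbindlist(lapply(tabs, function(t) t[, .(PATHWAY, FDR)]))
    med <- all[, .(MEDIAN_NEG_LOG10_FDR = stats::median(neg_log10(FDR)),
                   N_TABLES = .N), by = PATHWAY]
    med[, SYSTEM := sys]
    data.table::setorder(med, -MEDIAN_NEG_LOG10_FDR, PATHWAY)
    utils::head(med, top_k)
  })
  out <- data.table::rbindlist(Filter(Negate(is.null), rows))
  out[, .(SYSTEM, PATHWAY, MEDIAN_NEG_LOG10_FDR, N_TABLES)]
}

#' Partition pathways by the set of systems sharing them
#'
#' Every pathway in the union of the per-system significant sets is assigned
#' to exactly one region keyed by the sorted set of systems containing it
#' (fully shared, partially shared, or unique), so region counts sum to the
#' union size.
#'
#' @param significant_pathways_per_system Named list: system -> pathway ids.
#' @return `data.table` REGION, N_SYSTEMS, PATHWAY.
#' @export
system_sharing <- function(significant_pathways_per_system) {
  systems <- names(significant_pathways_per_system)
  all_pw <- sort(unique(unlist(significant_pathways_per_system, use.names = FALSE)))
  if (!length(all_pw))
    return(data.table::data.table(REGION = character(), N_SYSTEMS = integer(),
                                  PATHWAY = character()))
  rows <- lapply(all_pw, function(pw) {
    members <- systems[vapply(systems, function(s)
      pw %in% significant_pathways_per_system[[s]], logical(1))]
    data.table::data.table(REGION = paste(sort(members), collapse = "&"),
                           N_SYSTEMS = length(members), PATHWAY = pw)
  })
  data.table::rbindlist(rows)
}

#' Export a key-driver subnetwork for Cytoscape-style rendering
#'
#' Produces a node table (gene, KD flag, rare-variant level, common-variant
#' -log10 p; unannotated nodes keep empty fields) and the induced edge table
#' of the subnetwork, both loadable as delimited tables.
#'
#' @param kd Key driver gene id.
#' @param network Edge table or igraph containing the KD.
#' @param depth Neighborhood depth (default 1).
#' @param rare_catalog Optional `data.table` GENE, LEVEL.
#' @param common_scores Optional `data.table` GENE, NEG_LOG10_P (from
#'   [common_variant_genes()]`$scores`).
#' @return List with `nodes` (GENE, IS_KD, RARE_LEVEL, COMMON_NEG_LOG10_P)
#'   and `edges` (SOURCE, TARGET).
#' @export
export_subnetwork <- function(kd, network, depth = 1L, rare_catalog = NULL,
                              common_scores = NULL) {
  g <- as_kda_graph(network)
  if (!(kd %in% igraph::V(g)$name)) stop_cfg("key driver '%s' not in network", kd)
  nodes <- subnetwork(g, kd, depth)
  sub <- igraph::induced_subgraph(g, nodes)
  el <- igraph::as_edgelist(sub)
  edges <- data.table::data.table(SOURCE = el[, 1L], TARGET = el[, 2L])

  node_dt <- data.table::data.table(GENE = nodes, IS_KD = nodes == kd)
  node_dt[, RARE_LEVEL := if (is.null(rare_catalog)) NA_character_ else
    rare_catalog$LEVEL[match(GENE, rare_catalog$GENE)]]
  node_dt[, COMMON_NEG_LOG10_P := if (is.null(common_scores)) NA_real_ else
    common_scores$NEG_LOG10_P[match(GENE, common_scores$GENE)]]
  list(nodes = node_dt[], edges = edges)
}

#' Default tissue-to-system map
#'
#' Assigns the first tissue to the `Brain` system and the remainder to
#' `Peripheral`; real analyses should supply their own TISSUE -> SYSTEM
#' table (a tissue may belong to several systems).
#'
#' @param tissues Character vector of tissue labels.
#' @return `data.table` TISSUE, SYSTEM.
#' @export
default_system_map <- function(tissues) {
  data.table::data.table(TISSUE = tissues,
                         SYSTEM = c("Brain", rep("Peripheral", length(tissues) - 1L)))
}
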