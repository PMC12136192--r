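#' Configuration for key driver analysis
#'
#' @param hub_top_fraction Fraction of nodes (by total degree, ties kept)
#'   considered hub candidates; default 0.25.
#' @param neighborhood_depth Undirected hop count defining a hub's
#'   subnetwork; default 1 (first-degree neighbors).
#' @param n_permutations Reshuffled same-size subnetworks per null.
#' @param seed Integer seed.
#' @param fdr_threshold Significance threshold on BH FDR.
#' @return An object of class `kda_config`.
#' @export
kda_config <- function(hub_top_fraction = 0.25, neighborhood_depth = 1L,
                       n_permutations = 1000L, seed = 1L, fdr_threshold = 0.05) {
  if (hub_top_fraction <= 0 || hub_top_fraction > 1)
    stop_cfg("hub_top_fraction must lie in (0, 1]")
  if (neighborhood_depth < 1L) stop_cfg("neighborhood_depth must be >= 1")
  structure(list(hub_top_fraction = as.numeric(hub_top_fraction),
                 neighborhood_depth = as.integer(neighborhood_depth),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 fdr_threshold = as.numeric(fdr_threshold)),
            class = "kda_config")
}

as_kda_graph <- function(network) {
  if (igraph::is_igraph(network)) return(network)
  dt <- validate_network(network)
  if (!nrow(dt)) stop_cfg("empty network")
  igraph::graph_from_data_frame(dt, directed = TRUE)
}

#' Node degrees of a directed network
#'
#' Degree counts each distinct directed edge once: total degree = in + out.
#'
#' @param network Edge `data.table` (SOURCE, TARGET) or an igraph object.
#' @return Named integer vector gene -> degree.
#' @export
node_degree <- function(network) {
  g <- as_kda_graph(network)
  if (igraph::vcount(g) == 0L) stop_cfg("empty network")
  igraph::degree(g, mode = "all")
}

#' Hub candidates by degree cutoff
#'
#' The cutoff is the degree of the `ceiling(fraction * n)`-th highest-degree
#' node; every node with degree at or above it is a candidate, so boundary
#' ties are kept and the candidate set size is at least `fraction * n`.
#'
#' @param degrees Named degree vector from [node_degree()].
#' @param hub_top_fraction Fraction in (0, 1].
#' @return Character vector of candidate gene ids.
#' @export
hub_candidates <- function(degrees, hub_top_fraction = 0.25) {
  if (hub_top_fraction <= 0 || hub_top_fraction > 1)
    stop_cfg("hub_top_fraction must lie in (0, 1]")
  if (!length(degrees)) stop_cfg("empty degree table")
  cutoff <- sort(degrees, decreasing = TRUE)[ceiling(hub_top_fraction * length(degrees))]
  names(degrees)[degrees >= cutoff]
}

#' Local subnetwork of a hub
#'
#' The hub plus all nodes reachable within `depth` hops, traversing edges
#' regardless of direction.
#'
#' @param network Edge table or igraph object.
#' @param hub Hub gene id.
#' @param depth Hop count (>= 1).
#' @return Character vector of subnetwork gene ids (including the hub).
#' @export
subnetwork <- function(network, hub, depth = 1L) {
  g <- as_kda_graph(network)
  if (!(hub %in% igraph::V(g)$name)) stop_cfg("hub '%s' not in network", hub)
  nodes <- igraph::ego(g, order = depth, nodes = hub, mode = "all")[[1L]]
  nodes$name
}

#' Subnetwork enrichment for disease genes
#'
#' The statistic is the overlap count between the subnetwork and the disease
#' gene set. The null reshuffles the subnetwork: `n_permutations` uniform
#' node sets of the same size are drawn from the network's node universe and
#' their overlaps form the null; `z = (obs - null_mean) / null_sd` and `p`
#' is the Gaussian upper tail. The exact hypergeometric upper-tail
#' probability is reported alongside as a cross-check.
#'
#' @param subnet_nodes Subnetwork gene ids.
#' @param disease_genes Disease gene ids.
#' @param network_nodes All network gene ids.
#' @param n_permutations Null sample size.
#' @param seed Optional seed (set when called standalone).
#' @param null_stats Optional precomputed list(mean, sd) for this subnetwork
#'   size (used by [run_kda()] for caching).
#' @return List with `overlap`, `z`, `p`, `p_hypergeom`, `null_mean`,
#'   `null_sd`, `degenerate`.
#' @export
kd_enrichment <- function(subnet_nodes, disease_genes, network_nodes,
                          n_permutations = 1000L, seed = NULL, null_stats = NULL) {
  disease_in <- intersect(disease_genes, network_nodes)
  if (!length(disease_in)) stop_cfg("disease genes do not intersect the network")
  obs <- length(intersect(subnet_nodes, disease_in))
  s <- length(subnet_nodes)
  N <- length(network_nodes)
  K <- length(disease_in)
  if (is.null(null_stats)) {
    if (!is.null(seed)) set.seed(seed)
    null_stats <- kd_null_stats(s, network_nodes %in% disease_in, n_permutations)
  }
  degenerate <- !is.finite(null_stats$sd) || null_stats$sd == 0
  if (degenerate) {
    z <- 0; p <- 1
  } else {
    z <- (obs - null_stats$mean) / null_stats$sd
    p <- clamp_p(stats::pnorm(z, lower.tail = FALSE))
  }
  p_hyper <- clamp_p(stats::phyper(obs - 1, K, N - K, s, lower.tail = FALSE))
  list(overlap = obs, z = z, p = p, p_hypergeom = p_hyper,
       null_mean = null_stats$mean, null_sd = null_stats$sd, degenerate = degenerate)
}

# permutation null for one subnetwork size; is_disease is a logical vector
# over the network node universe
kd_null_stats <- function(size, is_disease, n_permutations) {
  N <- length(is_disease)
  draws <- vapply(seq_len(n_permutations),
                  function(i) sum(is_disease[sample.int(N, size)]), numeric(1))
  list(mean = mean(draws), sd = stats::sd(draws))
}

#' Run key driver analysis over one or more networks
#'
#' For each network group, the disease gene set is the union of genes in
#' MSEA modules significant at the configured FDR (intersected with the
#' network's nodes), or an explicitly supplied set. Every hub candidate
#' (top `hub_top_fraction` by degree, ties kept) is scored by
#' [kd_enrichment()] with permutation nulls cached per subnetwork size;
#' BH FDR is computed over all (network, hub) tests and results are ranked
#' by p.
#'
#' @param networks Named list (per group) of edge data.tables or igraphs.
#' @param msea Optional `msea_result` used to derive the disease set.
#' @param modules Module gene sets (as passed to [run_msea()]); required with
#'   `msea`.
#' @param disease_sets Optional named list group -> gene ids, or a single
#'   character vector applied to every group; overrides `msea`.
#' @param config A [kda_config()].
#' @return Object of class `kda_result`: list with `results` (data.table KD,
#'   GROUP, DEGREE, SUBNET_SIZE, OVERLAP, NULL_MEAN, NULL_SD, Z, P,
#'   P_HYPERGEOM, FDR), `subnetworks` (per group named list hub -> nodes),
#'   `disease_sets`, `config`.
#' @export
run_kda <- function(networks, msea = NULL, modules = NULL, disease_sets = NULL,
                    config = kda_config()) {
  stopifnot(inherits(config, "kda_config"))
  if (is.null(disease_sets)) {
    if (is.null(msea) || is.null(modules))
      stop_cfg("supply either disease_sets or both msea and modules")
    sig <- msea$results[FDR < msea$config$fdr_threshold]
    disease <- unique(unlist(lapply(seq_len(nrow(sig)), function(i)
      modules[[sig$TISSUE[i]]][[sig$MODULE[i]]]), use.names = FALSE))
    disease_sets <- stats::setNames(rep(list(disease), length(networks)), names(networks))
  } else if (is.character(disease_sets)) {
    disease_sets <- stats::setNames(rep(list(disease_sets), length(networks)), names(networks))
  }

  set.seed(config$seed)
  all_rows <- list()
  subnets_out <- list()
  for (grp in names(networks)) {
    g <- as_kda_graph(networks[[grp]])
    nodes <- igraph::V(g)$name
    disease_in <- intersect(disease_sets[[grp]], nodes)
    if (!length(disease_in)) {
      warning(sprintf("group '%s': disease set does not intersect the network; skipped", grp))
      next
    }
    deg <- node_degree(g)
    hubs <- sort(hub_candidates(deg, config$hub_top_fraction))
    subnets <- igraph::ego(g, order = config$neighborhood_depth,
                           nodes = hubs, mode = "all")
    subnets <- lapply(subnets, function(v) v$name)
    names(subnets) <- hubs
    subnets_out[[grp]] <- subnets

    is_disease <- nodes %in% disease_in
    sizes <- sort(unique(lengths(subnets)))
    null_cache <- lapply(sizes, kd_null_stats, is_disease = is_disease,
                         n_permutations = config$n_permutations)
    names(null_cache) <- as.character(sizes)

    rows <- lapply(hubs, function(h) {
      sn <- subnets[[h]]
      enr <- kd_enrichment(sn, disease_in, nodes,
                           null_stats = null_cache[[as.character(length(sn))]])
      data.table::data.table(KD = h, GROUP = grp, DEGREE = unname(deg[h]),
                             SUBNET_SIZE = length(sn), OVERLAP = enr$overlap,
                             NULL_MEAN = enr$null_mean, NULL_SD = enr$null_sd,
                             Z = enr$z, P = enr$p, P_HYPERGEOM = enr$p_hypergeom)
    })
    all_rows[[grp]] <- data.table::rbindlist(rows)
  }
  if (!length(all_rows)) stop_cfg("no network group could be scored")
  res <- data.table::rbindlist(all_rows)
  res[, FDR := bh_fdr(P)]
  res <- res[order(P, -OVERLAP, KD)]
  structure(list(results = res, subnetworks = subnets_out,
                 disease_sets = disease_sets, config = config),
            class = "kda_result")
}

#' Write KDA outputs
#'
#' Writes `kda.results.tsv` and `kda.subnetworks.tsv` (KD, GROUP, NODE).
#'
#' @param kda A `kda_result`.
#' @param out_dir Output directory.
#' @return The directory, invisibly.
#' @export
write_kda <- function(kda, out_dir) {
  stopifnot(inherits(kda, "kda_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(kda$results, file.path(out_dir, "kda.results.tsv"))
  sn <- data.table::rbindlist(lapply(names(kda$subnetworks), function(grp) {
    data.table::rbindlist(lapply(names(kda$subnetworks[[grp]]), function(h)
      data.table::data.table(KD = h, GROUP = grp, NODE = kda$subnetworks[[grp]][[h]])))
  }))
  write_tsv(sn, file.path(out_dir, "kda.subnetworks.tsv"))
  invisible(out_dir)
}
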