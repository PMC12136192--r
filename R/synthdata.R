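#' Configuration for the synthetic study generator
#'
#' Builds a validated configuration describing one synthetic study: a single
#' synthetic chromosome of evenly spaced markers with block-diagonal LD, a
#' gene universe with many-to-many marker-gene maps per tissue, tissue gene
#' modules of varying size (a configurable number of which carry planted
#' association signal), hub-centric directed regulatory networks with planted
#' disease-gene neighborhoods, and a leveled rare-variant gene catalog that
#' partially overlaps the planted hub neighborhoods.
#'
#' The signal model draws planted markers' p-values from Beta(a, 1) with
#' `a = signal_beta_a < 1`, a monotone stretch toward 0 with one
#' interpretable knob; all other markers are Uniform(0, 1).
#'
#' @param n_markers Number of GWAS markers.
#' @param n_genes Size of the gene universe.
#' @param n_blocks Number of LD blocks.
#' @param block_size Markers per LD block (consecutive markers).
#' @param r2_within r-squared assigned to every within-block pair; cross-block
#'   pairs are omitted (implicit r2 = 0).
#' @param marker_spacing_bp Base pairs between adjacent markers (positions are
#'   1-based and strictly increasing).
#' @param n_tissues Number of tissues (maps and module files are per tissue).
#' @param n_modules_per_tissue Modules per tissue.
#' @param module_size_range Integer `c(min, max)` genes per module; sizes are
#'   drawn uniformly.
#' @param n_planted_modules Modules (in the first tissue) given planted signal.
#' @param signal_fraction Fraction of a planted module's distinct mapped
#'   markers given the signal p-value distribution.
#' @param signal_beta_a Shape `a` of the Beta(a, 1) signal distribution;
#'   `a < 1` enriches small p-values.
#' @param map_window_kb Distance window (kb) used when determining a planted
#'   module's mapped markers (matches the analysis default of 20).
#' @param network_groups Character vector of network group labels; planted
#'   hubs are wired into the first group only.
#' @param network_nodes Nodes per network (must not exceed `n_genes`).
#' @param edges_per_node Out-edges added per node during preferential
#'   attachment growth.
#' @param n_planted_hubs Hubs with engineered disease-gene neighborhoods.
#' @param hub_neighbors First-degree neighbor count of each planted hub.
#' @param hub_disease_fraction Fraction of a planted hub's neighbors drawn
#'   from the disease (planted-module) genes.
#' @param rare_level_sizes Named integer vector of catalog sizes per
#'   confidence level `c(S=, "1"=, "2"=, "3"=)`.
#' @param rare_hub_overlap Fraction of catalog genes drawn from planted-hub
#'   first-degree neighborhoods.
#' @param seed Integer seed; identical configurations and seeds reproduce
#'   byte-identical bundles.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_markers = 20000L,
                         n_genes = 500L,
                         n_blocks = 1000L,
                         block_size = 5L,
                         r2_within = 0.8,
                         marker_spacing_bp = 1000L,
                         n_tissues = 2L,
                         n_modules_per_tissue = 25L,
                         module_size_range = c(20L, 30L),
                         n_planted_modules = 2L,
                         signal_fraction = 0.5,
                         signal_beta_a = 0.2,
                         map_window_kb = 20,
                         network_groups = c("brain", "peripheral"),
                         network_nodes = 500L,
                         edges_per_node = 3L,
                         n_planted_hubs = 2L,
                         hub_neighbors = 40L,
                         hub_disease_fraction = 0.8,
                         rare_level_sizes = c(S = 5L, "1" = 15L, "2" = 20L, "3" = 25L),
                         rare_hub_overlap = 0.5,
                         seed = 1L) {
  cfg <- list(
    n_markers = check_count(n_markers, "n_markers"),
    n_genes = check_count(n_genes, "n_genes"),
    n_blocks = check_count(n_blocks, "n_blocks"),
    block_size = check_count(block_size, "block_size"),
    r2_within = check_fraction(r2_within, "r2_within"),
    marker_spacing_bp = check_count(marker_spacing_bp, "marker_spacing_bp"),
    n_tissues = check_count(n_tissues, "n_tissues"),
    n_modules_per_tissue = check_count(n_modules_per_tissue, "n_modules_per_tissue"),
    module_size_range = as.integer(module_size_range),
    n_planted_modules = as.integer(n_planted_modules),
    signal_fraction = check_fraction(signal_fraction, "signal_fraction"),
    signal_beta_a = as.numeric(signal_beta_a),
    map_window_kb = as.numeric(map_window_kb),
    network_groups = as.character(network_groups),
    network_nodes = check_count(network_nodes, "network_nodes"),
    edges_per_node = check_count(edges_per_node, "edges_per_node"),
    n_planted_hubs = as.integer(n_planted_hubs),
    hub_neighbors = check_count(hub_neighbors, "hub_neighbors"),
    hub_disease_fraction = check_fraction(hub_disease_fraction, "hub_disease_fraction"),
    rare_level_sizes = rare_level_sizes,
    rare_hub_overlap = check_fraction(rare_hub_overlap, "rare_hub_overlap"),
    seed = as.integer(seed)
  )
  if (cfg$signal_beta_a <= 0) stop_cfg("signal_beta_a must be > 0")
  if (length(cfg$module_size_range) != 2L || cfg$module_size_range[1] < 3L ||
      cfg$module_size_range[1] > cfg$module_size_range[2])
    stop_cfg("module_size_range must be c(min, max) with min >= 3")
  if (cfg$module_size_range[2] > cfg$n_genes)
    stop_cfg("module size exceeds the gene universe")
  if (cfg$n_planted_modules < 0 || cfg$n_planted_modules > cfg$n_modules_per_tissue)
    stop_cfg("n_planted_modules must lie in [0, n_modules_per_tissue]")
  if (cfg$n_blocks * cfg$block_size > cfg$n_markers)
    stop_cfg("n_blocks * block_size must not exceed n_markers")
  if (cfg$network_nodes > cfg$n_genes)
    stop_cfg("network_nodes must not exceed n_genes")
  if (cfg$edges_per_node >= cfg$network_nodes)
    stop_cfg("edges_per_node must be smaller than network_nodes")
  if (cfg$n_planted_hubs < 0) stop_cfg("n_planted_hubs must be >= 0")
  if (is.null(names(cfg$rare_level_sizes)) ||
      !setequal(names(cfg$rare_level_sizes), c("S", "1", "2", "3")) ||
      any(cfg$rare_level_sizes < 0))
    stop_cfg("rare_level_sizes must be a named non-negative vector over {S, 1, 2, 3}")
  if (sum(cfg$rare_level_sizes) > cfg$n_genes)
    stop_cfg("rare catalog larger than the gene universe")
  if (length(cfg$network_groups) < 1L) stop_cfg("at least one network group is required")
  structure(cfg, class = "synth_config")
}

marker_ids <- function(n) sprintf("M%05d", seq_len(n))
gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate marker positions and block-diagonal LD
#'
#' Markers sit on a single synthetic chromosome at strictly increasing
#' positions. The first `n_blocks * block_size` markers form consecutive LD
#' blocks; every within-block pair receives `r2_within` and no cross-block
#' pair is emitted (implicit r2 = 0). Deterministic (no randomness).
#'
#' @param config A [synth_config()].
#' @return A list with `markers` (MARKER, CHR, POS, BLOCK) and `ld`
#'   (MARKER_A, MARKER_B, R2) data.tables.
#' @export
simulate_ld <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_markers
  ids <- marker_ids(n)
  block <- rep(NA_integer_, n)
  nb <- config$n_blocks * config$block_size
  block[seq_len(nb)] <- rep(seq_len(config$n_blocks), each = config$block_size)
  markers <- data.table::data.table(
    MARKER = ids, CHR = "chr1",
    POS = (seq_len(n) - 1) * as.numeric(config$marker_spacing_bp) + 1,
    BLOCK = block
  )
  pairs <- if (config$block_size >= 2L) {
    data.table::rbindlist(lapply(seq_len(config$n_blocks), function(b) {
      m <- ids[which(block == b)]
      cmb <- utils::combn(m, 2L)
      data.table::data.table(MARKER_A = cmb[1L, ], MARKER_B = cmb[2L, ], R2 = config$r2_within)
    }))
  } else {
    data.table::data.table(MARKER_A = character(), MARKER_B = character(), R2 = numeric())
  }
  list(markers = markers, ld = pairs)
}

#' Simulate GWAS association p-values
#'
#' Non-signal markers draw p ~ Uniform(0, 1); signal markers draw
#' p ~ Beta(`signal_beta_a`, 1) via the inverse CDF `u^(1/a)`, so `a < 1`
#' stretches p-values toward 0. With `a = 1` the signal distribution is the
#' null.
#'
#' @param config A [synth_config()].
#' @param markers Marker table from [simulate_ld()].
#' @param signal_markers Character vector of marker ids given signal.
#' @return A `data.table` with columns MARKER, CHR, POS, PVALUE.
#' @export
simulate_gwas <- function(config, markers, signal_markers = character()) {
  stopifnot(inherits(config, "synth_config"))
  if (!all(signal_markers %in% markers$MARKER))
    stop_cfg("signal markers must belong to the marker universe")
  n <- nrow(markers)
  p <- stats::runif(n)
  sig <- markers$MARKER %in% signal_markers
  if (any(sig)) p[sig] <- p[sig]^(1 / config$signal_beta_a)
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  data.table::data.table(MARKER = markers$MARKER, CHR = markers$CHR,
                         POS = markers$POS, PVALUE = p)
}

#' Simulate marker-gene maps, gene annotations and tissue modules
#'
#' Genes are laid evenly along the synthetic chromosome (so the +/-20 kb
#' distance window is meaningful); every gene receives 1-3 QTL-mapped markers
#' per tissue (eQTL/sQTL sources). Modules are sampled per tissue with sizes
#' uniform in `module_size_range`; the first `n_planted_modules` modules of
#' the first tissue are planted: their genes are drawn disjointly, each gene
#' receives one dedicated QTL marker (sampled without replacement across the
#' planted genes), and `signal_fraction` of each planted module's distinct
#' mapped markers (QTL plus distance-window markers) is designated as signal.
#'
#' @param config A [synth_config()].
#' @param markers Marker table from [simulate_ld()].
#' @return A list with `genes` (annotation table), `maps` (per-tissue QTL map
#'   data.tables), `modules` (per-tissue named lists of gene sets),
#'   `signal_markers`, `signal_genes`, `planted_module_ids`.
#' @export
simulate_maps_and_modules <- function(config, markers) {
  stopifnot(inherits(config, "synth_config"))
  ng <- config$n_genes
  gids <- gene_ids(ng)
  span <- as.numeric(config$n_markers) * config$marker_spacing_bp
  start <- floor((seq_len(ng) - 1) * (span / ng)) + 1
  genes <- data.table::data.table(GENE = gids, CHR = "chr1",
                                  START = start, END = start + 999)
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))

  # planted module gene sets: disjoint, from the first tissue
  sizes1 <- sample(seq(config$module_size_range[1], config$module_size_range[2]),
                   config$n_modules_per_tissue, replace = TRUE)
  n_pl <- config$n_planted_modules
  planted_genes <- character()
  planted_sets <- list()
  if (n_pl > 0L) {
    need <- sum(sizes1[seq_len(n_pl)])
    if (need > ng) stop_cfg("planted modules exceed the gene universe")
    pool <- sample(gids, need)
    off <- 0L
    for (j in seq_len(n_pl)) {
      planted_sets[[j]] <- pool[(off + 1L):(off + sizes1[j])]
      off <- off + sizes1[j]
    }
    planted_genes <- pool
  }

  maps <- list()
  modules <- list()
  for (ti in seq_along(tissues)) {
    nq <- sample(3L, ng, replace = TRUE)
    map <- data.table::data.table(
      MARKER = sample(markers$MARKER, sum(nq), replace = TRUE),
      GENE = rep(gids, nq),
      TISSUE = tissues[ti],
      SOURCE = sample(c("eqtl", "sqtl"), sum(nq), replace = TRUE)
    )
    if (ti == 1L && n_pl > 0L) {
      dedicated <- sample(markers$MARKER, length(planted_genes))
      map <- rbind(map, data.table::data.table(
        MARKER = dedicated, GENE = planted_genes,
        TISSUE = tissues[ti], SOURCE = "eqtl"))
    }
    map <- unique(map)
    sizes <- if (ti == 1L) sizes1 else
      sample(seq(config$module_size_range[1], config$module_size_range[2]),
             config$n_modules_per_tissue, replace = TRUE)
    sets <- vector("list", config$n_modules_per_tissue)
    for (j in seq_len(config$n_modules_per_tissue)) {
      sets[[j]] <- if (ti == 1L && j <= n_pl) planted_sets[[j]] else sample(gids, sizes[j])
    }
    names(sets) <- sprintf("%s_M%03d", tissues[ti], seq_len(config$n_modules_per_tissue))
    maps[[tissues[ti]]] <- map
    modules[[tissues[ti]]] <- sets
  }

  # designate signal markers over each planted module's distinct mapped markers
  signal_markers <- character()
  if (n_pl > 0L) {
    gwas_like <- data.table::data.table(MARKER = markers$MARKER, CHR = markers$CHR,
                                        POS = markers$POS)
    dist_map <- map_by_distance(gwas_like, genes, window_kb = config$map_window_kb)
    for (j in seq_len(n_pl)) {
      gset <- planted_sets[[j]]
      mapped <- union(maps[[1L]][GENE %in% gset, MARKER],
                      dist_map[GENE %in% gset, MARKER])
      s <- ceiling(config$signal_fraction * length(mapped))
      if (s > 0L) signal_markers <- union(signal_markers, sample(mapped, s))
    }
  }

  list(genes = genes, maps = maps, modules = modules,
       signal_markers = signal_markers, signal_genes = planted_genes,
       planted_module_ids = if (n_pl > 0L) names(modules[[1L]])[seq_len(n_pl)] else character())
}

#' Simulate a directed regulatory network with optional planted hubs
#'
#' The network grows by preferential attachment: each new node sends
#' `edges_per_node` directed edges to existing nodes with probability
#' proportional to current degree, yielding a heavy-tailed degree
#' distribution. When `planted = TRUE`, `n_planted_hubs` dedicated hub nodes
#' are appended afterwards, each wired hub -> neighbor to exactly
#' `hub_neighbors` growth nodes of which `round(hub_neighbors *
#' hub_disease_fraction)` are disease genes, so the planted neighborhood
#' composition holds exactly by construction.
#'
#' @param config A [synth_config()].
#' @param universe Character vector of available gene ids.
#' @param disease_genes Character vector of disease gene ids (needed when
#'   planting hubs).
#' @param group Group label attached to the edge table.
#' @param planted Wire planted hubs into this network?
#' @return A list with `edges` (SOURCE, TARGET data.table, attribute `group`)
#'   and `hub_ids` (planted hub gene ids, empty when `planted = FALSE`).
#' @export
simulate_network <- function(config, universe, disease_genes = character(),
                             group = "network", planted = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  if (config$network_nodes > length(universe))
    stop_cfg("network_nodes exceeds the supplied gene universe")
  n_hubs <- if (planted) config$n_planted_hubs else 0L
  n_pa <- config$network_nodes - n_hubs
  if (n_pa <= config$edges_per_node)
    stop_cfg("edges_per_node must be smaller than the grown network size")

  if (n_hubs > 0L) {
    if (length(disease_genes) == 0L)
      stop_cfg("planted hubs require a non-empty disease gene set")
    hub_pool <- setdiff(universe, disease_genes)
    if (length(hub_pool) < n_hubs)
      stop_cfg("not enough non-disease genes to host planted hubs")
    hub_ids <- sample(hub_pool, n_hubs)
  } else hub_ids <- character()

  pa_pool <- setdiff(universe, hub_ids)
  disease_in <- intersect(disease_genes, pa_pool)
  if (length(disease_in) > n_pa)
    stop_cfg("disease gene set larger than the grown network")
  pa_genes <- sample(c(disease_in, sample(setdiff(pa_pool, disease_in),
                                          n_pa - length(disease_in))))

  g <- igraph::sample_pa(n_pa, power = 1, m = config$edges_per_node,
                         directed = TRUE, algorithm = "psumtree")
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.table::data.table(SOURCE = pa_genes[el[, 1L]], TARGET = pa_genes[el[, 2L]])

  if (n_hubs > 0L) {
    n_dis <- round(config$hub_neighbors * config$hub_disease_fraction)
    if (n_dis > length(disease_in))
      stop_cfg("hub wiring infeasible: %d disease neighbors requested, %d disease genes in network",
               n_dis, length(disease_in))
    non_dis <- setdiff(pa_genes, disease_in)
    if (config$hub_neighbors - n_dis > length(non_dis))
      stop_cfg("hub wiring infeasible: not enough non-disease neighbors")
    hub_edges <- data.table::rbindlist(lapply(hub_ids, function(h) {
      nb <- c(sample(disease_in, n_dis),
              sample(non_dis, config$hub_neighbors - n_dis))
      data.table::data.table(SOURCE = h, TARGET = nb)
    }))
    edges <- rbind(edges, hub_edges)
  }
  edges <- unique(edges[SOURCE != TARGET])
  data.table::setattr(edges, "group", group)
  list(edges = edges, hub_ids = hub_ids)
}

#' Simulate a leveled rare-variant gene catalog
#'
#' Each catalog gene carries exactly one confidence level in `{S, 1, 2, 3}`;
#' `rare_hub_overlap` of the catalog is drawn from the planted hubs'
#' first-degree neighborhoods and the remainder from outside them.
#'
#' @param config A [synth_config()].
#' @param universe Character vector of gene ids.
#' @param hub_neighborhoods Character vector: union of planted-hub
#'   first-degree neighborhoods (may be empty when nothing is planted).
#' @return A `data.table` with columns GENE, LEVEL.
#' @export
simulate_rare_catalog <- function(config, universe, hub_neighborhoods = character()) {
  stopifnot(inherits(config, "synth_config"))
  sizes <- config$rare_level_sizes
  n_cat <- sum(sizes)
  n_in <- round(config$rare_hub_overlap * n_cat)
  pool_in <- intersect(hub_neighborhoods, universe)
  pool_out <- setdiff(universe, pool_in)
  if (n_in > length(pool_in))
    stop_cfg("rare_hub_overlap infeasible: %d genes requested from neighborhoods of size %d",
             n_in, length(pool_in))
  if (n_cat - n_in > length(pool_out))
    stop_cfg("rare catalog infeasible outside hub neighborhoods")
  genes <- sample(c(sample(pool_in, n_in), sample(pool_out, n_cat - n_in)))
  lv <- c("S", "1", "2", "3")
  data.table::data.table(GENE = genes,
                         LEVEL = rep(lv, times = as.integer(sizes[lv])))
}

#' Generate a complete synthetic study bundle
#'
#' Runs every simulator under a single seeded RNG stream and writes the
#' bundle to `out_dir`: `gwas.tsv`, `ld.tsv`, `genes.tsv`,
#' `map.<tissue>.tsv`, `modules.<tissue>.gmt`,
#' `network.<group>.edges.tsv`, `rare_catalog.tsv` and `truth.json`
#' (planted module/hub/gene ids plus a config echo). Re-running with the same
#' configuration reproduces byte-identical files.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `truth`, `dir` and the in-memory bundle
#'   pieces.
#' @export
generate_study <- function(config = synth_config(), out_dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  ld <- simulate_ld(config)
  mm <- simulate_maps_and_modules(config, ld$markers)
  gwas <- simulate_gwas(config, ld$markers, mm$signal_markers)

  if (config$n_planted_hubs > 0L && length(mm$signal_genes) == 0L)
    stop_cfg("planted hubs require planted modules (disease genes); set n_planted_modules > 0")

  networks <- list()
  hub_ids <- character()
  for (gi in seq_along(config$network_groups)) {
    grp <- config$network_groups[gi]
    net <- simulate_network(config, universe = mm$genes$GENE,
                            disease_genes = mm$signal_genes,
                            group = grp, planted = (gi == 1L))
    networks[[grp]] <- net$edges
    if (gi == 1L) hub_ids <- net$hub_ids
  }

  neighborhoods <- character()
  if (length(hub_ids)) {
    e1 <- networks[[1L]]
    neighborhoods <- setdiff(
      unique(c(e1[SOURCE %in% hub_ids, TARGET], e1[TARGET %in% hub_ids, SOURCE])),
      hub_ids)
  }
  rare <- simulate_rare_catalog(config, mm$genes$GENE, neighborhoods)

  write_tsv(gwas, file.path(out_dir, "gwas.tsv"))
  write_tsv(ld$ld, file.path(out_dir, "ld.tsv"))
  write_tsv(mm$genes, file.path(out_dir, "genes.tsv"))
  for (tis in names(mm$maps))
    write_tsv(mm$maps[[tis]][, .(MARKER, GENE, SOURCE)],
              file.path(out_dir, sprintf("map.%s.tsv", tis)))
  for (tis in names(mm$modules))
    write_gmt(mm$modules[[tis]], file.path(out_dir, sprintf("modules.%s.gmt", tis)),
              descriptions = rep("synthetic coexpression module", length(mm$modules[[tis]])))
  for (grp in names(networks))
    write_tsv(networks[[grp]], file.path(out_dir, sprintf("network.%s.edges.tsv", grp)))
  write_tsv(rare, file.path(out_dir, "rare_catalog.tsv"))

  truth <- list(
    planted_module_ids = as.list(mm$planted_module_ids),
    planted_hub_ids = as.list(hub_ids),
    signal_gene_ids = as.list(mm$signal_genes),
    disease_gene_ids = as.list(mm$signal_genes),
    signal_marker_ids = as.list(sort(mm$signal_markers)),
    config_echo = unclass(config)
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(truth = truth, dir = out_dir, gwas = gwas, ld = ld$ld,
                 markers = ld$markers, genes = mm$genes, maps = mm$maps,
                 modules = mm$modules, networks = networks, rare_catalog = rare))
}
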