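#' Run the full genetics-to-network pipeline on a synthetic study
#'
#' Generates (or reads) a study bundle and runs every stage in sequence:
#' marker dependency filtering, marker set enrichment analysis, key driver
#' analysis, rare/common variant convergence, and reporting (pathway ORA of
#' the top KD subnetwork against the bundle's module sets, system-sharing
#' partition, Cytoscape-style export of the top KD subnetwork). All result
#' tables plus a `manifest.json` recording the effective parameters are
#' written under `out_dir`; runs with identical configuration and seed
#' produce byte-identical outputs.
#'
#' @param config A [synth_config()] describing the study.
#' @param out_dir Output directory; the bundle is written to
#'   `<out_dir>/bundle` and results to `<out_dir>/results`.
#' @param mdf_cfg,msea_cfg,kda_cfg Stage configurations; seeds for the
#'   permutation stages default to the study seed.
#' @param common_p_threshold Common-variant gene rule for convergence.
#' @param fdr_threshold Significance threshold used by convergence
#'   classification and reporting.
#' @return Invisibly, a list with every stage result (`bundle`, `mdf`,
#'   `msea`, `kda`, `convergence`, `ora_tables`, `sharing`, `export`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = synth_config(), out_dir,
                         mdf_cfg = mdf_config(),
                         msea_cfg = msea_config(seed = config$seed),
                         kda_cfg = kda_config(seed = config$seed),
                         common_p_threshold = 1e-4,
                         fdr_threshold = 0.05) {
  bundle_dir <- file.path(out_dir, "bundle")
  res_dir <- file.path(out_dir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)

  generate_study(config, bundle_dir)
  bundle <- read_study(bundle_dir)

  mdf <- run_mdf(bundle$gwas, bundle$maps, bundle$genes, bundle$ld, mdf_cfg)
  write_mdf(mdf, res_dir)

  msea <- run_msea(mdf, bundle$modules, msea_cfg)
  write_msea(msea, res_dir)

  kda <- run_kda(bundle$networks, msea = msea, modules = bundle$modules,
                 config = kda_cfg)
  write_kda(kda, res_dir)

  conv <- run_convergence(kda, bundle$rare_catalog, mdf, bundle$networks,
                          common_p_threshold = common_p_threshold,
                          fdr_threshold = fdr_threshold)
  write_convergence(conv, res_dir)

  # report stage: annotate each group's top KD subnetwork against the
  # bundle's own module gene sets, grouped into systems for sharing
  libraries <- lapply(bundle$modules, identity)
  sysmap <- default_system_map(names(bundle$modules))
  ora_tables_by_system <- list()
  sig_by_system <- list()
  top_kds <- kda$results[, utils::head(.SD, 1L), by = GROUP]
  for (i in seq_len(nrow(top_kds))) {
    grp <- top_kds$GROUP[i]; h <- top_kds$KD[i]
    sn <- kda$subnetworks[[grp]][[h]]
    bg <- igraph::V(as_kda_graph(bundle$networks[[grp]]))$name
    for (tis in names(libraries)) {
      tab <- ora(sn, libraries[[tis]], bg)
      write_tsv(tab, file.path(res_dir, sprintf("ora.%s_%s.%s.tsv", grp, h, tis)))
      sys <- sysmap[TISSUE == tis, SYSTEM]
      for (s in sys) {
        ora_tables_by_system[[s]] <- c(ora_tables_by_system[[s]], list(tab))
        sig_by_system[[s]] <- sort(union(sig_by_system[[s]] %||% character(),
                                         tab[FDR < fdr_threshold, PATHWAY]))
      }
    }
  }
  ranking <- rank_pathways_across_modules(ora_tables_by_system, top_k = 3L)
  write_tsv(ranking, file.path(res_dir, "pathway_ranking.tsv"))
  sharing <- system_sharing(sig_by_system)
  write_tsv(sharing, file.path(res_dir, "system_sharing.tsv"))

  export <- NULL
  if (nrow(top_kds)) {
    grp <- top_kds$GROUP[1L]; h <- top_kds$KD[1L]
    export <- export_subnetwork(h, bundle$networks[[grp]],
                                depth = kda_cfg$neighborhood_depth,
                                rare_catalog = bundle$rare_catalog,
                                common_scores = conv$common$scores)
    write_tsv(export$nodes, file.path(res_dir, sprintf("subnet.%s.nodes.tsv", h)))
    write_tsv(export$edges, file.path(res_dir, sprintf("subnet.%s.edges.tsv", h)))
  }

  manifest <- list(
    package = "convergene",
    parameters = list(
      r2_threshold = mdf_cfg$r2_threshold,
      window_kb = mdf_cfg$window_kb,
      mapping_sources = mdf_cfg$mapping_sources,
      n_quantile_points = msea_cfg$n_quantile_points,
      quantile_start = 0.5,
      kappa = msea_cfg$kappa,
      msea_permutations = msea_cfg$n_permutations,
      min_module_size = msea_cfg$min_module_size,
      hub_top_fraction = kda_cfg$hub_top_fraction,
      neighborhood_depth = kda_cfg$neighborhood_depth,
      kda_permutations = kda_cfg$n_permutations,
      common_p_threshold = common_p_threshold,
      fdr_threshold = fdr_threshold,
      seed = config$seed
    ),
    study = unclass(config),
    files = sort(list.files(res_dir))
  )
  jsonlite::write_json(manifest, file.path(res_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(bundle = bundle, mdf = mdf, msea = msea, kda = kda,
                 convergence = conv, sharing = sharing, export = export,
                 manifest = manifest, out_dir = out_dir))
}
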