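#' Raw and size-normalized variant counts in a network
#'
#' Counts, per variant class, the network genes present in the class and
#' normalizes by the network's gene count. Classes are the rare catalog as a
#' collective (`rare_all`), each confidence level (`rare_S`, `rare_1`,
#' `rare_2`, `rare_3`) and the common-variant gene set (`common`).
#'
#' @param network_nodes Character vector of network gene ids.
#' @param rare_catalog `data.table` GENE, LEVEL (or NULL to skip rare classes).
#' @param common_set Character vector of common-variant genes (or NULL).
#' @return `data.table` with CLASS, RAW, NORMALIZED.
#' @export
variant_counts <- function(network_nodes, rare_catalog = NULL, common_set = NULL) {
  if (!length(network_nodes)) stop_cfg("empty network")
  n <- length(unique(network_nodes))
  classes <- variant_class_sets(rare_catalog, common_set)
  data.table::rbindlist(lapply(names(classes), function(cl) {
    raw <- length(intersect(network_nodes, classes[[cl]]))
    data.table::data.table(CLASS = cl, RAW = raw, NORMALIZED = raw / n)
  }))
}

variant_class_sets <- function(rare_catalog = NULL, common_set = NULL) {
  classes <- list()
  if (!is.null(rare_catalog)) {
    classes$rare_all <- rare_catalog$GENE
    for (lv in c("S", "1", "2", "3"))
      classes[[paste0("rare_", lv)]] <- rare_catalog[LEVEL == lv, GENE]
  }
  if (!is.null(common_set)) classes$common <- common_set
  if (!length(classes)) stop_cfg("no variant class supplied")
  classes
}

#' Percentage of key drivers carrying a variant annotation
#'
#' @param key_drivers Character vector of KD gene ids (non-empty).
#' @param variant_set Character vector of annotated genes.
#' @return Percentage in [0, 100].
#' @export
kd_variant_percentage <- function(key_drivers, variant_set) {
  if (!length(key_drivers)) stop_cfg("empty key driver list")
  100 * length(intersect(key_drivers, variant_set)) / length(unique(key_drivers))
}

#' Exact over-representation of a catalog within a gene unit
#'
#' One-sided enrichment probability from the 2x2 table
#' (in unit vs not) x (in catalog vs not) over the background: the
#' hypergeometric upper tail, identical to a one-sided Fisher exact test.
#' Fold enrichment is `(overlap/unit)/(catalog/background)` (0 when the
#' overlap is 0).
#'
#' @param unit_genes Genes of the tested unit (must lie in the background).
#' @param catalog_genes Catalog genes (intersected with the background).
#' @param background_genes Background gene universe.
#' @return One-row `data.table`: OVERLAP, UNIT_SIZE, CATALOG_SIZE,
#'   BACKGROUND_SIZE, FOLD, P.
#' @export
set_enrichment <- function(unit_genes, catalog_genes, background_genes) {
  background <- unique(background_genes)
  if (!length(background)) stop_cfg("empty background")
  unit <- unique(unit_genes)
  if (!all(unit %in% background)) stop_cfg("unit genes must be a subset of the background")
  catalog <- intersect(unique(catalog_genes), background)
  ov <- length(intersect(unit, catalog))
  n <- length(unit); K <- length(catalog); N <- length(background)
  fold <- if (ov == 0 || n == 0 || K == 0) {
    if (ov == 0) 0 else NA_real_
  } else (ov / n) / (K / N)
  p <- clamp_p(stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE))
  data.table::data.table(OVERLAP = ov, UNIT_SIZE = n, CATALOG_SIZE = K,
                         BACKGROUND_SIZE = N, FOLD = fold, P = p)
}

#' Common-variant gene set from MDF output
#'
#' A gene is a common-variant gene when its best retained mapped marker has
#' p below `p_threshold`; the continuous best -log10 p per gene is returned
#' for annotation regardless of the cutoff.
#'
#' @param mdf An `mdf_result`.
#' @param p_threshold Association p-value cutoff (default 1e-4).
#' @return List with `scores` (data.table GENE, BEST_P, NEG_LOG10_P) and
#'   `genes` (character vector passing the cutoff).
#' @export
common_variant_genes <- function(mdf, p_threshold = 1e-4) {
  stopifnot(inherits(mdf, "mdf_result"))
  joined <- merge(mdf$map[, .(MARKER, GENE)], mdf$retained[, .(MARKER, PVALUE)],
                  by = "MARKER", allow.cartesian = TRUE)
  scores <- joined[, .(BEST_P = min(PVALUE)), by = GENE]
  scores[, NEG_LOG10_P := neg_log10(BEST_P)]
  data.table::setorder(scores, GENE)
  list(scores = scores[], genes = scores[BEST_P < p_threshold, GENE])
}

#' Group comparison with normality check
#'
#' Reports a Shapiro-Wilk normality p-value for the pooled data (skipped
#' with a flag when the pooled values are constant or outside the test's
#' supported size) and a rank-sum (Mann-Whitney / Wilcoxon) test with the
#' configured alternative, plus medians and group sizes.
#'
#' @param values_a,values_b Numeric vectors (>= 3 values each).
#' @param alternative One of "two.sided", "greater", "less" (a vs b).
#' @return List with `shapiro_p`, `normality_skipped`, `wilcox_p`,
#'   `median_a`, `median_b`, `n_a`, `n_b`, `alternative`.
#' @export
compare_groups <- function(values_a, values_b, alternative = "two.sided") {
  if (length(values_a) < 3L || length(values_b) < 3L)
    stop_cfg("each group needs at least 3 values")
  pooled <- c(values_a, values_b)
  skipped <- FALSE
  shapiro_p <- NA_real_
  if (stats::sd(pooled) == 0 || length(pooled) < 3L || length(pooled) > 5000L) {
    skipped <- TRUE
  } else {
    shapiro_p <- stats::shapiro.test(pooled)$p.value
  }
  w <- suppressWarnings(stats::wilcox.test(values_a, values_b, alternative = alternative))
  list(shapiro_p = shapiro_p, normality_skipped = skipped, wilcox_p = w$p.value,
       median_a = stats::median(values_a), median_b = stats::median(values_b),
       n_a = length(values_a), n_b = length(values_b), alternative = alternative)
}

#' Classify rare/common convergence of key-driver subnetworks
#'
#' Labels each KD `both` / `rare_only` / `common_only` / `neither` from the
#' FDR of its `rare_all` and `common` enrichment, and tabulates the partition
#' per network group.
#'
#' @param overlap_results `data.table` with UNIT, GROUP, CLASS, FDR covering
#'   classes `rare_all` and `common` for every KD.
#' @param fdr_threshold Significance threshold.
#' @return List with `classes` (UNIT, GROUP, CONVERGENCE) and `counts`
#'   (GROUP x CONVERGENCE partition sizes).
#' @export
classify_convergence <- function(overlap_results, fdr_threshold = 0.05) {
  dt <- data.table::as.data.table(overlap_results)
  need <- c("rare_all", "common")
  wide <- data.table::dcast(dt[CLASS %in% need], UNIT + GROUP ~ CLASS, value.var = "FDR")
  if (!all(need %in% names(wide))) stop_cfg("both 'rare_all' and 'common' classes are required")
  if (anyNA(wide$rare_all) || anyNA(wide$common))
    stop_cfg("every key driver needs both a rare_all and a common result")
  wide[, CONVERGENCE := data.table::fcase(
    rare_all < fdr_threshold & common < fdr_threshold, "both",
    rare_all < fdr_threshold, "rare_only",
    common < fdr_threshold, "common_only",
    default = "neither")]
  counts <- wide[, .(N = .N), by = .(GROUP, CONVERGENCE)]
  list(classes = wide[, .(UNIT, GROUP, CONVERGENCE)], counts = counts)
}

#' Rank key drivers by variant-class enrichment
#'
#' Sorts by p ascending (ties: higher fold enrichment, then KD id) within
#' one variant class and returns the top k.
#'
#' @param overlap_results `data.table` with UNIT, CLASS, P, FOLD.
#' @param variant_class Class to rank (e.g. "rare_all", "common").
#' @param k Number of rows to keep (> 0).
#' @return The top-k `data.table`.
#' @export
rank_kd_by_variant_enrichment <- function(overlap_results, variant_class, k = 15L) {
  if (k <= 0) stop_cfg("k must be > 0")
  dt <- data.table::as.data.table(overlap_results)[CLASS == variant_class]
  dt <- dt[order(P, -FOLD, UNIT)]
  utils::head(dt, k)
}

#' Quantify rare/common variant convergence of KD subnetworks
#'
#' Scores every KD subnetwork against each variant class (`rare_all`, the
#' four rare levels, `common`) with the exact hypergeometric test over the
#' network's gene universe (or an explicit per-group background), applies
#' BH FDR within each variant class, classifies convergence, and compares
#' the first network group against the rest (enrichment -log10 p per class,
#' two-sided rank-sum).
#'
#' @param kda A `kda_result`.
#' @param rare_catalog `data.table` GENE, LEVEL.
#' @param mdf An `mdf_result` (for the common-variant gene rule).
#' @param networks Named list of edge tables/igraphs matching the KDA groups.
#' @param common_p_threshold Common-variant gene p-value rule.
#' @param fdr_threshold Significance threshold for classification.
#' @param backgrounds Optional named list group -> background gene vector
#'   (defaults to each network's node universe).
#' @return Object of class `convergence_result`: list with `results` (UNIT,
#'   GROUP, CLASS, OVERLAP, UNIT_SIZE, CATALOG_SIZE, BACKGROUND_SIZE, FOLD,
#'   P, FDR), `classes`, `class_counts`, `group_stats`, `common` (the scored
#'   common-variant gene table), `network_counts`.
#' @export
run_convergence <- function(kda, rare_catalog, mdf, networks,
                            common_p_threshold = 1e-4, fdr_threshold = 0.05,
                            backgrounds = NULL) {
  stopifnot(inherits(kda, "kda_result"), inherits(mdf, "mdf_result"))
  common <- common_variant_genes(mdf, common_p_threshold)
  class_sets <- variant_class_sets(rare_catalog, common$genes)

  rows <- list()
  net_counts <- list()
  for (grp in names(kda$subnetworks)) {
    nodes <- igraph::V(as_kda_graph(networks[[grp]]))$name
    bg <- unique(backgrounds[[grp]] %||% nodes)
    net_counts[[grp]] <- cbind(GROUP = grp,
                               variant_counts(nodes, rare_catalog, common$genes))
    for (h in names(kda$subnetworks[[grp]])) {
      sn <- intersect(kda$subnetworks[[grp]][[h]], bg)
      for (cl in names(class_sets)) {
        enr <- set_enrichment(sn, class_sets[[cl]], bg)
        rows[[length(rows) + 1L]] <- cbind(
          data.table::data.table(UNIT = h, GROUP = grp, CLASS = cl), enr)
      }
    }
  }
  res <- data.table::rbindlist(rows)
  res[, FDR := bh_fdr(P), by = CLASS]

  cls <- classify_convergence(res, fdr_threshold)

  # first group vs the rest, per class, on -log10 enrichment p
  group_stats <- NULL
  groups <- unique(res$GROUP)
  if (length(groups) >= 2L) {
    first <- groups[1L]
    gs <- lapply(unique(res$CLASS), function(cl) {
      a <- res[CLASS == cl & GROUP == first, neg_log10(P)]
      b <- res[CLASS == cl & GROUP != first, neg_log10(P)]
      if (length(a) < 3L || length(b) < 3L) return(NULL)
      cmp <- compare_groups(a, b, alternative = "two.sided")
      data.table::data.table(CLASS = cl, GROUP_A = first, GROUP_B = "rest",
                             N_A = cmp$n_a, N_B = cmp$n_b,
                             MEDIAN_A = cmp$median_a, MEDIAN_B = cmp$median_b,
                             SHAPIRO_P = cmp$shapiro_p, WILCOX_P = cmp$wilcox_p)
    })
    group_stats <- data.table::rbindlist(Filter(Negate(is.null), gs))
  }

  structure(list(results = res, classes = cls$classes, class_counts = cls$counts,
                 group_stats = group_stats, common = common,
                 network_counts = data.table::rbindlist(net_counts)),
            class = "convergence_result")
}

#' Write convergence outputs
#'
#' Writes `convergence.results.tsv`, `convergence.classes.tsv`,
#' `convergence.groupstats.tsv` and `convergence.network_counts.tsv`.
#'
#' @param conv A `convergence_result`.
#' @param out_dir Output directory.
#' @return The directory, invisibly.
#' @export
write_convergence <- function(conv, out_dir) {
  stopifnot(inherits(conv, "convergence_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(conv$results, file.path(out_dir, "convergence.results.tsv"))
  write_tsv(conv$classes, file.path(out_dir, "convergence.classes.tsv"))
  if (!is.null(conv$group_stats) && nrow(conv$group_stats))
    write_tsv(conv$group_stats, file.path(out_dir, "convergence.groupstats.tsv"))
  write_tsv(conv$network_counts, file.path(out_dir, "convergence.network_counts.tsv"))
  invisible(out_dir)
}
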