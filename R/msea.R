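#' Configuration for marker set enrichment analysis
#'
#' Defaults mirror the method's standard settings: 10 rank-based quantile
#' points starting at 0.5, stability parameter kappa = 1, a random-gene-set
#' permutation null of 1000 draws, and module significance at BH FDR < 0.05.
#'
#' @param n_quantile_points Number of quantile cutpoints (>= 2).
#' @param kappa Stability constant added to the expected count (>= 0).
#' @param n_permutations Random gene sets per null distribution (>= 100).
#' @param seed Integer seed for the permutation null.
#' @param min_module_size Minimum module gene count after intersection with
#'   genes carrying retained markers.
#' @param max_module_size Optional maximum gene count (NULL = no cap).
#' @param fdr_threshold Significance threshold on BH FDR.
#' @param fdr_family `"global"` (one family across tissues, the default) or
#'   `"tissue"` (BH within tissue).
#' @return An object of class `msea_config`.
#' @export
msea_config <- function(n_quantile_points = 10L, kappa = 1, n_permutations = 1000L,
                        seed = 1L, min_module_size = 10L, max_module_size = NULL,
                        fdr_threshold = 0.05, fdr_family = c("global", "tissue")) {
  if (n_quantile_points < 2L) stop_cfg("n_quantile_points must be >= 2")
  if (kappa < 0) stop_cfg("kappa must be >= 0")
  if (n_permutations < 100L) stop_cfg("n_permutations must be >= 100")
  structure(list(n_quantile_points = as.integer(n_quantile_points),
                 kappa = as.numeric(kappa),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 min_module_size = as.integer(min_module_size),
                 max_module_size = if (is.null(max_module_size)) NULL else as.integer(max_module_size),
                 fdr_threshold = as.numeric(fdr_threshold),
                 fdr_family = match.arg(fdr_family)),
            class = "msea_config")
}

#' Quantile cutpoints adjusted by the median module size
#'
#' Returns `n_points` equally spaced quantiles from 0.5 to
#' `q_upper = 1 - 1/mu` inclusive, where `mu` is the median marker-set size
#' over all tested modules in the run. The upper limit lets the quantile grid
#' adapt to module size.
#'
#' @param median_module_size `mu`, the median marker-set size (> 2).
#' @param n_points Number of cutpoints.
#' @return Numeric vector of strictly increasing quantiles.
#' @export
quantile_cutpoints <- function(median_module_size, n_points = 10L) {
  q_upper <- 1 - 1 / median_module_size
  if (!is.finite(q_upper) || q_upper <= 0.5)
    stop_cfg("degenerate quantile range: q_upper = %s <= 0.5 (median size %s)",
             format(q_upper), format(median_module_size))
  seq(0.5, q_upper, length.out = n_points)
}

#' Rank all retained markers by association strength
#'
#' Sorts markers by descending -log10 p, ties broken lexicographically by
#' marker id, and returns the table with a `rank_` column (1 = strongest).
#'
#' @param retained Retained association table with MARKER and NEG_LOG10_P.
#' @return A ranked `data.table`.
#' @export
rank_markers <- function(retained) {
  dt <- data.table::as.data.table(retained)
  dt <- dt[order(-NEG_LOG10_P, MARKER)]
  dt[, rank_ := .I]
  dt[]
}

#' Observed and expected positive-association counts at quantile cutpoints
#'
#' A marker is "positive" at quantile `q` iff its global rank is at most
#' `k_q = floor((1 - q) * M)` where `M` is the retained marker count. For a
#' module with `m` distinct markers, `O` is the count of module markers among
#' the top `k_q` and `E = m * k_q / M`, the module's share of the global
#' positive fraction.
#'
#' @param module_markers Character vector of the module's distinct markers.
#' @param ranking Ranked marker table from [rank_markers()].
#' @param cutpoints Quantile cutpoints.
#' @return A list with `cutpoints`, `k`, `observed`, `expected`.
#' @export
positive_counts <- function(module_markers, ranking, cutpoints) {
  ranks <- ranking$rank_[match(module_markers, ranking$MARKER)]
  if (anyNA(ranks)) stop_cfg("module marker absent from the global retained set")
  profile_from_ranks(unique(ranks), nrow(ranking), cutpoints)
}

# fast path: module marker ranks already resolved
profile_from_ranks <- function(ranks, M, cutpoints) {
  # epsilon guard: (1 - q) * M is meant as exact rational arithmetic, but
  # e.g. (1 - 0.9) * 100 = 9.999... in floating point and would floor to 9
  k <- floor((1 - cutpoints) * M + 1e-9)
  sr <- sort(ranks)
  O <- findInterval(k, sr)
  E <- length(ranks) * k / M
  list(cutpoints = cutpoints, k = k, observed = O, expected = E)
}

#' The quantile chi-like enrichment statistic
#'
#' `chi = sum_i (O_i - E_i) / sqrt(E_i + kappa)`: a signed sum over quantile
#' cutpoints, so deficits subtract; kappa stabilizes terms with very small
#' expected counts.
#'
#' @param observed Integer vector of observed positive counts.
#' @param expected Numeric vector of expected positive counts.
#' @param kappa Stability constant (default 1).
#' @return The chi statistic (scalar).
#' @export
chi_statistic <- function(observed, expected, kappa = 1) {
  if (length(observed) != length(expected))
    stop_cfg("observed and expected must have equal length")
  sum((observed - expected) / sqrt(expected + kappa))
}

#' Permutation null distribution for a module size
#'
#' Samples `n_permutations` random gene sets of `n_genes` genes (uniformly,
#' without replacement) from the eligible universe, forms each set's distinct
#' marker union and computes its chi statistic. Under the null, random sets
#' carry an equal proportion of positive associations, so the null mean of
#' chi is approximately 0.
#'
#' @param n_genes Gene count to match.
#' @param gene_ranks Named list: eligible gene -> integer vector of global
#'   marker ranks.
#' @param M Total retained marker count.
#' @param cutpoints Quantile cutpoints.
#' @param kappa Stability constant.
#' @param n_permutations Number of random gene sets.
#' @param seed Optional seed (set when called standalone; `run_msea` manages
#'   the stream itself).
#' @return A list with `mean`, `sd` ((n-1)-denominator), `sample` and a
#'   `degenerate` flag (TRUE when sd is 0).
#' @export
null_distribution <- function(n_genes, gene_ranks, M, cutpoints, kappa = 1,
                              n_permutations = 1000L, seed = NULL) {
  U <- length(gene_ranks)
  if (n_genes > U) stop_cfg("module gene count exceeds the eligible universe")
  if (!is.null(seed)) set.seed(seed)
  chis <- vapply(seq_len(n_permutations), function(i) {
    idx <- sample.int(U, n_genes)
    ranks <- unique(unlist(gene_ranks[idx], use.names = FALSE))
    pr <- profile_from_ranks(ranks, M, cutpoints)
    chi_statistic(pr$observed, pr$expected, kappa)
  }, numeric(1))
  s <- stats::sd(chis)
  list(mean = mean(chis), sd = s, sample = chis,
       degenerate = !is.finite(s) || s == 0)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement, equal to
#' `q_(i) = min_{j >= i} (p_(j) * m / j)` capped at 1.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Run marker set enrichment analysis
#'
#' Scores every tissue module for enrichment of strong GWAS association
#' among its mapped, LD-filtered markers. For each module the distinct
#' retained marker set is intersected with the global ranking, the chi
#' statistic is computed over the shared quantile grid (with
#' `q_upper = 1 - 1/mu`, `mu` the run-wide median marker-set size), and
#' standardized against a permutation null of size-matched random gene sets
#' (cached per tissue and gene count). Z scores are converted to one-sided
#' Gaussian upper-tail p-values and BH-adjusted over the configured family.
#'
#' @param mdf An `mdf_result` from [run_mdf()].
#' @param modules Named list (per tissue) of named lists of gene id vectors,
#'   as returned by [read_gmt()] per tissue.
#' @param config An [msea_config()].
#' @return An object of class `msea_result`: list with `results` (data.table
#'   MODULE, TISSUE, N_GENES, N_MARKERS, CHI, NULL_MEAN, NULL_SD, Z, P, FDR,
#'   sorted by p ascending), `skipped`, `tissue_counts`, `mu`, `cutpoints`,
#'   `config`.
#' @export
run_msea <- function(mdf, modules, config = msea_config()) {
  stopifnot(inherits(mdf, "mdf_result"), inherits(config, "msea_config"))
  ranking <- rank_markers(mdf$retained)
  M <- nrow(ranking)
  rank_of <- stats::setNames(ranking$rank_, ranking$MARKER)

  tissues <- intersect(names(modules), names(mdf$gene_markers))
  if (!length(tissues)) stop_cfg("no tissue shared between modules and MDF output")

  prep <- list()
  skipped <- list()
  universes <- list()
  for (tis in tissues) {
    gm <- mdf$gene_markers[[tis]]
    gene_ranks <- lapply(gm, function(mk) unname(rank_of[mk]))
    universes[[tis]] <- gene_ranks
    for (mod in names(modules[[tis]])) {
      genes <- intersect(modules[[tis]][[mod]], names(gene_ranks))
      ng <- length(genes)
      if (ng < config$min_module_size ||
          (!is.null(config$max_module_size) && ng > config$max_module_size)) {
        skipped[[length(skipped) + 1L]] <- data.table::data.table(
          MODULE = mod, TISSUE = tis, N_GENES = ng, REASON = "size filter")
        next
      }
      ranks <- unique(unlist(gene_ranks[genes], use.names = FALSE))
      prep[[length(prep) + 1L]] <- list(module = mod, tissue = tis,
                                        n_genes = ng, ranks = ranks)
    }
  }
  if (!length(prep)) stop_cfg("no module passes the size filters")

  mu <- stats::median(vapply(prep, function(x) length(x$ranks), numeric(1)))
  cutpoints <- quantile_cutpoints(mu, config$n_quantile_points)

  # permutation nulls cached per (tissue, gene count), deterministic order
  set.seed(config$seed)
  nulls <- list()
  need <- unique(data.table::data.table(
    tissue = vapply(prep, `[[`, "", "tissue"),
    n = vapply(prep, `[[`, 0L, "n_genes")))
  data.table::setorder(need, tissue, n)
  for (i in seq_len(nrow(need))) {
    tis <- need$tissue[i]; n <- need$n[i]
    nulls[[paste(tis, n)]] <- null_distribution(
      n, universes[[tis]], M, cutpoints, config$kappa, config$n_permutations)
  }

  rows <- lapply(prep, function(x) {
    pr <- profile_from_ranks(x$ranks, M, cutpoints)
    chi <- chi_statistic(pr$observed, pr$expected, config$kappa)
    nd <- nulls[[paste(x$tissue, x$n_genes)]]
    if (nd$degenerate) {
      warning(sprintf("degenerate null (sd = 0) for module %s; p set to 1", x$module))
      z <- 0; p <- 1
    } else {
      z <- (chi - nd$mean) / nd$sd
      p <- clamp_p(stats::pnorm(z, lower.tail = FALSE))
    }
    data.table::data.table(MODULE = x$module, TISSUE = x$tissue,
                           N_GENES = x$n_genes, N_MARKERS = length(x$ranks),
                           CHI = chi, NULL_MEAN = nd$mean, NULL_SD = nd$sd,
                           Z = z, P = p)
  })
  res <- data.table::rbindlist(rows)
  if (config$fdr_family == "global") {
    res[, FDR := bh_fdr(P)]
  } else {
    res[, FDR := bh_fdr(P), by = TISSUE]
  }
  res <- res[order(P)]  # stable: ties keep module order

  counts <- res[, .(N_MODULES = .N, N_SIGNIFICANT = sum(FDR < config$fdr_threshold)),
                by = TISSUE]
  structure(list(results = res,
                 skipped = if (length(skipped)) data.table::rbindlist(skipped)
                           else data.table::data.table(MODULE = character(),
                                                       TISSUE = character(),
                                                       N_GENES = integer(),
                                                       REASON = character()),
                 tissue_counts = counts, mu = mu, cutpoints = cutpoints,
                 config = config),
            class = "msea_result")
}

#' Write MSEA outputs
#'
#' Writes `msea.results.tsv` and `msea.tissue_counts.tsv`.
#'
#' @param msea An `msea_result`.
#' @param out_dir Output directory.
#' @return The directory, invisibly.
#' @export
write_msea <- function(msea, out_dir) {
  stopifnot(inherits(msea, "msea_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(msea$results, file.path(out_dir, "msea.results.tsv"))
  write_tsv(msea$tissue_counts, file.path(out_dir, "msea.tissue_counts.tsv"))
  invisible(out_dir)
}
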