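#' Configuration for marker dependency filtering
#'
#' Defaults follow standard practice for GWAS-network integration: markers in
#' LD at r-squared above 0.5 are collapsed to the strongest association, and
#' distance-based mapping uses a symmetric +/-20 kb window around the gene
#' body.
#'
#' @param r2_threshold LD r-squared above which two markers are considered
#'   dependent (strictly greater-than).
#' @param window_kb Symmetric distance window in kilobases.
#' @param mapping_sources Subset of `c("eqtl", "sqtl", "distance")`.
#' @return An object of class `mdf_config`.
#' @export
mdf_config <- function(r2_threshold = 0.5, window_kb = 20,
                       mapping_sources = c("eqtl", "sqtl", "distance")) {
  if (r2_threshold < 0 || r2_threshold > 1) stop_cfg("r2_threshold must lie in [0, 1]")
  if (window_kb < 0) stop_cfg("window_kb must be >= 0")
  if (!all(mapping_sources %in% c("eqtl", "sqtl", "distance")) || !length(mapping_sources))
    stop_cfg("mapping_sources must be a non-empty subset of {eqtl, sqtl, distance}")
  structure(list(r2_threshold = as.numeric(r2_threshold),
                 window_kb = as.numeric(window_kb),
                 mapping_sources = mapping_sources),
            class = "mdf_config")
}

#' Map markers to genes by genomic distance
#'
#' A marker maps to a gene iff they share a chromosome label and the marker
#' position falls in `[START - W, END + W]` with `W = window_kb * 1000`
#' (1-based inclusive coordinates, boundary inclusive).
#'
#' @param associations Marker table with MARKER, CHR, POS.
#' @param gene_annotations Gene table with GENE, CHR, START, END.
#' @param window_kb Window in kilobases (must be >= 0).
#' @return A `data.table` with columns MARKER, GENE, SOURCE ("distance").
#' @export
map_by_distance <- function(associations, gene_annotations, window_kb = 20) {
  if (window_kb < 0) stop_cfg("window_kb must be >= 0")
  assoc <- data.table::as.data.table(associations)
  genes <- data.table::as.data.table(gene_annotations)
  w <- window_kb * 1000
  shared <- intersect(unique(assoc$CHR), unique(genes$CHR))
  if (!length(shared)) {
    warning("no shared chromosome labels between markers and genes; zero mappings")
    return(data.table::data.table(MARKER = character(), GENE = character(),
                                  SOURCE = character()))
  }
  out <- lapply(shared, function(ch) {
    a <- assoc[CHR == ch]
    g <- genes[CHR == ch]
    pos <- sort(a$POS)
    ids <- a$MARKER[order(a$POS)]
    # per gene, the contiguous run of sorted marker positions inside the window
    lo <- findInterval(g$START - w - 0.5, pos) + 1L
    hi <- findInterval(g$END + w + 0.5, pos)
    keep <- which(hi >= lo)
    if (!length(keep)) return(NULL)
    data.table::data.table(
      MARKER = unlist(lapply(keep, function(i) ids[lo[i]:hi[i]]), use.names = FALSE),
      GENE = rep(g$GENE[keep], times = (hi - lo + 1L)[keep]),
      SOURCE = "distance")
  })
  res <- data.table::rbindlist(out)
  if (!nrow(res)) return(data.table::data.table(MARKER = character(),
                                                GENE = character(), SOURCE = character()))
  unique(res)
}

#' Merge QTL and distance maps, restricted to enabled sources
#'
#' Returns the union of records from both maps keeping only the enabled
#' evidence sources; exact duplicates are collapsed, while a (marker, gene,
#' tissue) pair supported by several sources keeps one record per source.
#'
#' @param qtl_map data.table with MARKER, GENE, TISSUE, SOURCE.
#' @param distance_map data.table with MARKER, GENE, SOURCE (TISSUE optional).
#' @param mapping_sources Enabled sources.
#' @param tissue Tissue label applied to distance records lacking one.
#' @return The merged `data.table` (MARKER, GENE, TISSUE, SOURCE).
#' @export
merge_maps <- function(qtl_map, distance_map,
                       mapping_sources = c("eqtl", "sqtl", "distance"),
                       tissue = NULL) {
  qtl <- data.table::as.data.table(qtl_map)
  dst <- data.table::as.data.table(distance_map)
  if (nrow(dst) && !("TISSUE" %in% names(dst))) {
    if (is.null(tissue)) stop_cfg("distance map lacks TISSUE and no tissue label supplied")
    dst[, TISSUE := tissue]
  }
  cols <- c("MARKER", "GENE", "TISSUE", "SOURCE")
  both <- data.table::rbindlist(list(
    if (nrow(qtl)) qtl[, cols, with = FALSE] else NULL,
    if (nrow(dst)) dst[, cols, with = FALSE] else NULL))
  if (!nrow(both)) stop_cfg("no mappings after merging and source filtering")
  both <- unique(both[SOURCE %in% mapping_sources])
  if (!nrow(both)) stop_cfg("no mappings after merging and source filtering")
  both[]
}

#' Greedy LD clumping of GWAS markers
#'
#' Markers are processed in order of ascending p-value (ties broken
#' lexicographically by marker id). The best unclaimed marker is retained and
#' every unclaimed marker linked to it by a pair with r-squared strictly
#' above `r2_threshold` is discarded; the pass repeats until all markers are
#' claimed. Markers never named in a supra-threshold pair are always
#' retained. Output preserves the input row order restricted to the retained
#' set. LD pairs naming markers absent from the association table are dropped
#' with a message.
#'
#' @param associations Association table with MARKER and PVALUE.
#' @param ld_pairs LD table with MARKER_A, MARKER_B, R2.
#' @param r2_threshold Dependence cutoff (strict `>`).
#' @return The retained subset of `associations` (same columns, same order).
#' @export
ld_clump <- function(associations, ld_pairs, r2_threshold = 0.5) {
  assoc <- data.table::as.data.table(associations)
  ld <- data.table::as.data.table(ld_pairs)
  if (nrow(ld) && any(ld$R2 < 0 | ld$R2 > 1)) stop_cfg("r2 values must lie in [0, 1]")
  n <- nrow(assoc)
  idx <- seq_len(n)
  names(idx) <- assoc$MARKER

  ld <- ld[R2 > r2_threshold]
  unresolved <- !(ld$MARKER_A %in% assoc$MARKER) | !(ld$MARKER_B %in% assoc$MARKER)
  if (any(unresolved)) {
    message(sprintf("dropped %d LD pairs with markers absent from the association table",
                    sum(unresolved)))
    ld <- ld[!unresolved]
  }

  adj <- vector("list", n)
  if (nrow(ld)) {
    ia <- idx[ld$MARKER_A]; ib <- idx[ld$MARKER_B]
    sp_a <- split(ib, ia); sp_b <- split(ia, ib)
    for (k in names(sp_a)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], sp_a[[k]])
    for (k in names(sp_b)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], sp_b[[k]])
  }

  ord <- order(assoc$PVALUE, assoc$MARKER)
  status <- integer(n)  # 0 unclaimed, 1 retained, -1 discarded
  for (i in ord) {
    if (status[i] != 0L) next
    status[i] <- 1L
    nb <- adj[[i]]
    if (length(nb)) status[nb[status[nb] == 0L]] <- -1L
  }
  assoc[status == 1L]
}

#' Run marker dependency filtering
#'
#' Executes the full MDF stage: validate associations, clump markers by LD,
#' build the per-tissue merged marker-gene map (QTL sources plus the distance
#' window), restrict it to retained markers, and index each gene's distinct
#' retained marker set. Genes with zero retained markers are dropped. No
#' GWAS p-value cutoff is applied, so the full association spectrum feeds the
#' downstream null estimation.
#'
#' @param associations GWAS table (MARKER, CHR, POS, PVALUE).
#' @param qtl_maps Named list (per tissue) of QTL map data.tables
#'   (MARKER, GENE, TISSUE, SOURCE).
#' @param gene_annotations Gene annotation table (needed when "distance" is an
#'   enabled source); may be `NULL` otherwise.
#' @param ld_pairs LD pair table.
#' @param config An [mdf_config()].
#' @return An object of class `mdf_result`: list with `retained` (association
#'   table with NEG_LOG10_P), `map` (merged retained map), `gene_markers`
#'   (per-tissue named list gene -> retained marker ids) and `config`.
#' @export
run_mdf <- function(associations, qtl_maps, gene_annotations = NULL,
                    ld_pairs = NULL, config = mdf_config()) {
  stopifnot(inherits(config, "mdf_config"))
  assoc <- validate_associations(associations)
  ld <- if (is.null(ld_pairs)) {
    data.table::data.table(MARKER_A = character(), MARKER_B = character(), R2 = numeric())
  } else validate_ld(ld_pairs)

  retained <- ld_clump(assoc, ld, config$r2_threshold)
  if (!nrow(retained)) stop_cfg("no markers retained after LD clumping")

  dist_map <- NULL
  if ("distance" %in% config$mapping_sources) {
    if (is.null(gene_annotations))
      stop_cfg("distance mapping enabled but no gene annotations supplied")
    dist_map <- map_by_distance(assoc, gene_annotations, config$window_kb)
  }

  tissues <- names(qtl_maps)
  if (is.null(tissues) || !length(tissues)) stop_cfg("qtl_maps must be a named per-tissue list")
  retained_set <- retained$MARKER
  maps <- list()
  gene_markers <- list()
  for (tis in tissues) {
    merged <- merge_maps(qtl_maps[[tis]],
                         dist_map %||% data.table::data.table(MARKER = character(),
                                                              GENE = character(),
                                                              SOURCE = character()),
                         mapping_sources = config$mapping_sources, tissue = tis)
    merged <- merged[MARKER %in% retained_set]
    maps[[tis]] <- merged
    gm <- merged[, .(markers = list(sort(unique(MARKER)))), by = GENE]
    gene_markers[[tis]] <- stats::setNames(gm$markers, gm$GENE)
  }

  structure(list(retained = retained, map = data.table::rbindlist(maps),
                 gene_markers = gene_markers, config = config),
            class = "mdf_result")
}

#' Write MDF outputs
#'
#' Writes `mdf.retained.tsv` and one `mdf.<tissue>.genes.tsv` per tissue
#' (GENE, MARKERS semicolon-joined).
#'
#' @param mdf An `mdf_result`.
#' @param out_dir Output directory.
#' @return The directory, invisibly.
#' @export
write_mdf <- function(mdf, out_dir) {
  stopifnot(inherits(mdf, "mdf_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(mdf$retained, file.path(out_dir, "mdf.retained.tsv"))
  for (tis in names(mdf$gene_markers)) {
    gm <- mdf$gene_markers[[tis]]
    dt <- data.table::data.table(
      GENE = names(gm),
      MARKERS = vapply(gm, paste, "", collapse = ";"))
    data.table::setorder(dt, GENE)
    write_tsv(dt, file.path(out_dir, sprintf("mdf.%s.genes.tsv", tis)))
  }
  invisible(out_dir)
}
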