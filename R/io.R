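#' Read GWAS summary statistics
#'
#' Expects a tab-delimited file with columns `MARKER`, `CHR`, `POS`, `PVALUE`.
#' P-values must lie in (0, 1]; a `NEG_LOG10_P` column is added.
#'
#' @param path Path to a `gwas.tsv`-style file.
#' @return A `data.table` with one row per marker.
#' @export
read_gwas <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("MARKER", "CHR", "POS", "PVALUE")
  if (!all(need %in% names(dt)))
    stop_cfg("GWAS file '%s' must have columns %s", path, paste(need, collapse = ", "))
  validate_associations(dt)
}

validate_associations <- function(dt) {
  dt <- data.table::as.data.table(dt)
  if (anyDuplicated(dt$MARKER)) stop_cfg("duplicate marker ids in association table")
  if (any(dt$PVALUE <= 0 | dt$PVALUE > 1)) stop_cfg("association p-values must lie in (0, 1]")
  dt[, NEG_LOG10_P := neg_log10(PVALUE)]
  dt[]
}

#' Read an LD pair table
#'
#' Tab-delimited `MARKER_A`, `MARKER_B`, `R2`. Pairs are interpreted
#' symmetrically; self-pairs are rejected.
#'
#' @param path Path to an `ld.tsv`-style file.
#' @return A `data.table` of marker pairs.
#' @export
read_ld <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("MARKER_A", "MARKER_B", "R2")
  if (!all(need %in% names(dt)))
    stop_cfg("LD file '%s' must have columns %s", path, paste(need, collapse = ", "))
  validate_ld(dt)
}

validate_ld <- function(dt) {
  dt <- data.table::as.data.table(dt)
  if (nrow(dt) && any(dt$R2 < 0 | dt$R2 > 1)) stop_cfg("r2 values must lie in [0, 1]")
  if (nrow(dt) && any(dt$MARKER_A == dt$MARKER_B)) stop_cfg("self-pairs are not allowed in the LD table")
  dt[]
}

#' Read gene annotations
#'
#' Tab-delimited `GENE`, `CHR`, `START`, `END` with 1-based inclusive
#' coordinates and `START <= END`.
#'
#' @param path Path to a `genes.tsv`-style file.
#' @return A `data.table` of gene intervals.
#' @export
read_gene_annotations <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("GENE", "CHR", "START", "END")
  if (!all(need %in% names(dt)))
    stop_cfg("gene annotation file '%s' must have columns %s", path, paste(need, collapse = ", "))
  if (any(dt$START > dt$END)) stop_cfg("gene annotations must satisfy START <= END")
  dt
}

#' Read a marker-to-gene map
#'
#' Tab-delimited `MARKER`, `GENE`, `SOURCE` with sources in
#' `{eqtl, sqtl, distance}`; the tissue label is supplied by the caller
#' (conventionally taken from the `map.<tissue>.tsv` filename).
#'
#' @param path Path to a map file.
#' @param tissue Tissue label attached to every record.
#' @return A `data.table` with columns `MARKER`, `GENE`, `TISSUE`, `SOURCE`.
#' @export
read_marker_gene_map <- function(path, tissue) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("MARKER", "GENE", "SOURCE")
  if (!all(need %in% names(dt)))
    stop_cfg("map file '%s' must have columns %s", path, paste(need, collapse = ", "))
  dt[, TISSUE := tissue]
  unique(dt[, .(MARKER, GENE, TISSUE, SOURCE)])
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop_cfg("GMT line with fewer than 3 fields in '%s'", path)
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(ln) strsplit(ln, "\t", fixed = TRUE)[[1L]][1L], "")
  if (anyDuplicated(names(out))) stop_cfg("duplicate set ids in '%s'", path)
  out
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a directed regulatory network edge list
#'
#' Tab-delimited `SOURCE`, `TARGET`. Self-loops and duplicate directed edges
#' are dropped (with a message) to satisfy the network invariants.
#'
#' @param path Path to a `network.<group>.edges.tsv`-style file.
#' @param group Network group label.
#' @return A `data.table` of edges with attribute `group`.
#' @export
read_network <- function(path, group = NA_character_) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("SOURCE", "TARGET")
  if (!all(need %in% names(dt)))
    stop_cfg("network file '%s' must have columns %s", path, paste(need, collapse = ", "))
  validate_network(dt[, .(SOURCE, TARGET)], group = group)
}

validate_network <- function(dt, group = NA_character_) {
  dt <- data.table::as.data.table(dt)
  n0 <- nrow(dt)
  dt <- dt[SOURCE != TARGET]
  dt <- unique(dt)
  if (nrow(dt) < n0)
    message(sprintf("dropped %d self-loop/duplicate edges", n0 - nrow(dt)))
  data.table::setattr(dt, "group", group)
  dt[]
}

#' Read a rare-variant gene catalog
#'
#' Tab-delimited `GENE`, `LEVEL` with levels in `{S, 1, 2, 3}` (mirroring the
#' SFARI confidence stratification: Syndromic, high confidence, strong
#' candidate, suggestive evidence) and one level per gene.
#'
#' @param path Path to a `rare_catalog.tsv`-style file.
#' @return A `data.table` with columns `GENE`, `LEVEL`.
#' @export
read_rare_catalog <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(character = c("GENE", "LEVEL")))
  need <- c("GENE", "LEVEL")
  if (!all(need %in% names(dt)))
    stop_cfg("rare catalog '%s' must have columns %s", path, paste(need, collapse = ", "))
  if (!all(dt$LEVEL %in% c("S", "1", "2", "3")))
    stop_cfg("rare catalog levels must be in {S, 1, 2, 3}")
  if (anyDuplicated(dt$GENE)) stop_cfg("rare catalog must carry one level per gene")
  dt
}

#' Read a complete synthetic study bundle
#'
#' Loads every file written by [generate_study()] into memory.
#'
#' @param dir Bundle directory.
#' @return A list with elements `gwas`, `ld`, `genes`, `maps` (per tissue),
#'   `modules` (per tissue), `networks` (per group), `rare_catalog`, `truth`.
#' @export
read_study <- function(dir) {
  tissue_of <- function(f, prefix, suffix) sub(suffix, "", sub(prefix, "", basename(f)))
  map_files <- sort(list.files(dir, "^map\\..*\\.tsv$", full.names = TRUE))
  mod_files <- sort(list.files(dir, "^modules\\..*\\.gmt$", full.names = TRUE))
  net_files <- sort(list.files(dir, "^network\\..*\\.edges\\.tsv$", full.names = TRUE))
  maps <- lapply(map_files, function(f) read_marker_gene_map(f, tissue_of(f, "map\\.", "\\.tsv$")))
  names(maps) <- vapply(map_files, tissue_of, "", prefix = "map\\.", suffix = "\\.tsv$")
  modules <- lapply(mod_files, read_gmt)
  names(modules) <- vapply(mod_files, tissue_of, "", prefix = "modules\\.", suffix = "\\.gmt$")
  networks <- lapply(net_files, function(f)
    read_network(f, tissue_of(f, "network\\.", "\\.edges\\.tsv$")))
  names(networks) <- vapply(net_files, tissue_of, "", prefix = "network\\.", suffix = "\\.edges\\.tsv$")
  truth_path <- file.path(dir, "truth.json")
  list(
    gwas = read_gwas(file.path(dir, "gwas.tsv")),
    ld = read_ld(file.path(dir, "ld.tsv")),
    genes = read_gene_annotations(file.path(dir, "genes.tsv")),
    maps = maps,
    modules = modules,
    networks = networks,
    rare_catalog = read_rare_catalog(file.path(dir, "rare_catalog.tsv")),
    truth = if (file.exists(truth_path)) jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  )
}

write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
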