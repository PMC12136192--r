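# Small in-code fixtures shared across test files.

tiny_assoc <- function(p, ids = sprintf("M%02d", seq_along(p))) {
  data.table::data.table(MARKER = ids, CHR = "chr1",
                         POS = seq_along(p) * 1000, PVALUE = p,
                         NEG_LOG10_P = -log10(p))
}

tiny_ld <- function(a, b, r2) {
  data.table::data.table(MARKER_A = a, MARKER_B = b, R2 = r2)
}

# a small fast study configuration for integration-style tests;
# any synth_config argument can be overridden through ...
small_config <- function(seed = 1L, ...) {
  args <- list(n_markers = 4000L, n_genes = 200L, n_blocks = 200L, block_size = 5L,
               n_tissues = 2L, n_modules_per_tissue = 12L,
               network_nodes = 200L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

gene_ids <- function(n) sprintf("G%04d", seq_len(n))

# one-group star network: hub -> n leaves
star_network <- function(hub = "H", n = 5L) {
  data.table::data.table(SOURCE = hub, TARGET = sprintf("L%02d", seq_len(n)))
}
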