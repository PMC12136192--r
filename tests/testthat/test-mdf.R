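test_that("distance mapping respects the inclusive window boundary", {
  genes <- data.table::data.table(GENE = "G1", CHR = "chr1", START = 110000, END = 120000)
  mk <- function(pos) data.table::data.table(MARKER = "M1", CHR = "chr1", POS = pos)
  expect_equal(nrow(map_by_distance(mk(90000), genes, 20)), 1L)   # exactly on boundary
  expect_equal(nrow(map_by_distance(mk(89999), genes, 20)), 0L)   # one bp outside
  expect_equal(nrow(map_by_distance(mk(140000), genes, 20)), 1L)  # upper boundary
  expect_equal(nrow(map_by_distance(mk(140001), genes, 20)), 0L)
  expect_error(map_by_distance(mk(1), genes, -1), "window_kb")
  expect_warning(
    map_by_distance(data.table::data.table(MARKER = "M1", CHR = "chrX", POS = 1),
                    genes, 20),
    "no shared chromosome")
})

test_that("distance mapping matches a brute-force interval scan", {
  set.seed(21)
  for (rep in 1:20) {
    n_m <- sample(5:40, 1)
    n_g <- sample(2:10, 1)
    assoc <- data.table::data.table(
      MARKER = sprintf("M%02d", seq_len(n_m)), CHR = "chr1",
      POS = sample.int(500000, n_m))
    start <- sample.int(400000, n_g)
    genes <- data.table::data.table(GENE = sprintf("G%02d", seq_len(n_g)),
                                    CHR = "chr1", START = start,
                                    END = start + sample.int(50000, n_g))
    got <- map_by_distance(assoc, genes, 20)
    want <- list()
    for (i in seq_len(n_m)) for (j in seq_len(n_g)) {
      if (assoc$POS[i] >= genes$START[j] - 20000 && assoc$POS[i] <= genes$END[j] + 20000)
        want[[length(want) + 1L]] <- paste(assoc$MARKER[i], genes$GENE[j])
    }
    expect_setequal(got[, paste(MARKER, GENE)], unlist(want))
  }
})

test_that("map merging respects sources and collapses duplicates", {
  qtl <- data.table::data.table(MARKER = sprintf("M%d", 1:5), GENE = sprintf("G%d", 1:5),
                                TISSUE = "t1", SOURCE = "eqtl")
  dst <- data.table::data.table(MARKER = sprintf("M%d", 6:10), GENE = sprintf("G%d", 1:5),
                                SOURCE = "distance")
  expect_equal(nrow(merge_maps(qtl, dst, tissue = "t1")), 10L)
  # identical (marker, gene, tissue) from two sources keeps one record per source
  dst2 <- data.table::copy(qtl)[, SOURCE := "distance"]
  expect_equal(nrow(merge_maps(qtl, dst2, tissue = "t1")), 10L)
  # restricting sources drops the other records
  out <- merge_maps(qtl, dst, mapping_sources = "eqtl", tissue = "t1")
  expect_true(all(out$SOURCE == "eqtl"))
  expect_error(merge_maps(qtl[0], dst[0], tissue = "t1"), "no mappings")
})

test_that("clumping applies the strict r2 rule and keeps the strongest marker", {
  assoc <- tiny_assoc(c(1e-8, 1e-3), ids = c("A", "B"))
  expect_equal(ld_clump(assoc, tiny_ld("A", "B", 0.6), 0.5)$MARKER, "A")
  expect_equal(ld_clump(assoc, tiny_ld("A", "B", 0.4), 0.5)$MARKER, c("A", "B"))
  # chain A-B, B-C supra-threshold; A-C weak: greedy retains {A, C}
  assoc3 <- tiny_assoc(c(1e-8, 1e-5, 1e-3), ids = c("A", "B", "C"))
  ld3 <- tiny_ld(c("A", "B", "A"), c("B", "C", "C"), c(0.6, 0.6, 0.2))
  expect_equal(ld_clump(assoc3, ld3, 0.5)$MARKER, c("A", "C"))
  expect_error(ld_clump(assoc, tiny_ld("A", "B", 1.2), 0.5), "r2")
  # unresolvable pairs are dropped with a message
  expect_message(ld_clump(assoc, tiny_ld("A", "ZZZ", 0.9), 0.5), "dropped 1 LD pairs")
})

test_that("clumping equals the exhaustive greedy oracle on random graphs", {
  set.seed(33)
  for (rep in 1:300) {
    n <- sample(2:12, 1)
    ids <- sprintf("S%02d", sample(n))  # shuffled input order
    assoc <- data.table::data.table(MARKER = ids, CHR = "chr1",
                                    POS = seq_len(n), PVALUE = stats::runif(n))
    n_pairs <- sample(0:min(12, n * (n - 1) / 2), 1)
    ld <- if (n_pairs > 0) {
      pr <- t(replicate(n_pairs, sample(ids, 2)))
      tiny_ld(pr[, 1], pr[, 2], stats::runif(n_pairs))
    } else tiny_ld(character(), character(), numeric())
    got <- ld_clump(assoc, ld, 0.5)
    expect_identical(got$MARKER, oracle_clump(as.data.frame(assoc), as.data.frame(ld), 0.5))
    # global best-p marker always retained
    best <- assoc$MARKER[order(assoc$PVALUE, assoc$MARKER)][1]
    expect_true(best %in% got$MARKER)
    # idempotence
    expect_identical(ld_clump(got, ld, 0.5)$MARKER, got$MARKER)
  }
})

test_that("the retained set is a maximal independent set of the LD graph", {
  # independence: no two retained markers linked above threshold; maximality:
  # every discarded marker is linked to some retained one, so adding it back
  # would violate independence
  set.seed(44)
  for (rep in 1:50) {
    n <- sample(5:30, 1)
    ids <- sprintf("S%02d", 1:n)
    assoc <- data.table::data.table(MARKER = ids, CHR = "chr1", POS = 1:n,
                                    PVALUE = stats::runif(n))
    pr <- t(replicate(40, sample(ids, 2)))
    ld <- tiny_ld(pr[, 1], pr[, 2], stats::runif(40))
    kept <- ld_clump(assoc, ld, 0.5)$MARKER
    strong <- ld[R2 > 0.5]
    expect_false(any(strong$MARKER_A %in% kept & strong$MARKER_B %in% kept))
    for (m in setdiff(ids, kept)) {
      partners <- c(strong[MARKER_A == m, MARKER_B], strong[MARKER_B == m, MARKER_A])
      expect_true(any(partners %in% kept))
    }
  }
})

test_that("run_mdf indexes genes by their retained markers and drops empty genes", {
  assoc <- tiny_assoc(c(1e-6, 1e-4, 0.5, 0.9), ids = c("A", "B", "C", "D"))
  qtl <- data.table::data.table(
    MARKER = c("A", "B", "C", "A", "D"),
    GENE = c("G1", "G1", "G1", "G2", "G3"),
    TISSUE = "t1", SOURCE = "eqtl")
  ld <- tiny_ld("A", "B", 0.9)  # B removed (A stronger)
  mdf <- run_mdf(assoc, list(t1 = qtl), gene_annotations = NULL, ld_pairs = ld,
                 config = mdf_config(mapping_sources = "eqtl"))
  expect_setequal(mdf$retained$MARKER, c("A", "C", "D"))
  expect_setequal(mdf$gene_markers$t1[["G1"]], c("A", "C"))
  expect_setequal(mdf$gene_markers$t1[["G2"]], "A")  # shared marker in both genes
  expect_setequal(mdf$gene_markers$t1[["G3"]], "D")
  expect_true(all(lengths(mdf$gene_markers$t1) >= 1))
  expect_equal(mdf$retained$NEG_LOG10_P, -log10(mdf$retained$PVALUE), tolerance = 1e-12)
})
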