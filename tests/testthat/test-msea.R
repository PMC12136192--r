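test_that("quantile cutpoints follow the median-size rule", {
  cp <- quantile_cutpoints(100, 10)
  expect_equal(cp[1], 0.5)
  expect_equal(cp[10], 0.99)
  expect_equal(diff(cp), rep((0.99 - 0.5) / 9, 9))
  expect_equal(quantile_cutpoints(10, 2), c(0.5, 0.9))
  expect_error(quantile_cutpoints(2, 10), "degenerate quantile range")
})

test_that("positive counts follow the rank rule and saturate correctly", {
  # 100 markers ranked by construction: M001 strongest ... M100 weakest
  p <- seq(1e-10, 0.99, length.out = 100)
  ranking <- rank_markers(tiny_assoc(p, sprintf("M%03d", 1:100)))
  # q = 0.9 -> k = 10; module of 20 markers with 5 in the top 10
  module <- c(sprintf("M%03d", 1:5), sprintf("M%03d", 50:64))
  pr <- positive_counts(module, ranking, 0.9)
  expect_equal(pr$observed, 5L)
  expect_equal(pr$expected, 2.0)
  # module = whole universe saturates O = E = k at every cutpoint
  pr_all <- positive_counts(sprintf("M%03d", 1:100), ranking, c(0.5, 0.7, 0.9))
  expect_equal(pr_all$observed, pr_all$k)
  expect_equal(pr_all$expected, as.numeric(pr_all$k))
  expect_error(positive_counts("NOPE", ranking, 0.9), "absent from the global")
})

test_that("mean observed count matches the hypergeometric expectation", {
  set.seed(55)
  p <- stats::runif(200)
  ranking <- rank_markers(tiny_assoc(p, sprintf("M%03d", 1:200)))
  cp <- 0.9  # k = 20
  draws <- vapply(1:1000, function(i) {
    positive_counts(sample(ranking$MARKER, 30), ranking, cp)$observed
  }, numeric(1))
  E <- 30 * 20 / 200
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - E), 3 * se)
})

test_that("chi statistic identities hold", {
  expect_identical(chi_statistic(c(3L, 7L), c(3, 7), 1), 0)
  expect_equal(chi_statistic(5L, 3, 1), 1.0)
  expect_error(chi_statistic(1:3, 1:2, 1), "equal length")
  # strictly increasing in any O_i with E fixed
  base <- chi_statistic(c(2L, 4L), c(2, 4), 1)
  expect_gt(chi_statistic(c(3L, 4L), c(2, 4), 1), base)
})

test_that("null distribution is seeded, centered and flags degeneracy", {
  set.seed(66)
  p <- stats::runif(300)
  ranking <- rank_markers(tiny_assoc(p, sprintf("M%03d", 1:300)))
  gene_ranks <- split(sample(ranking$rank_, 300), rep(1:100, 3))
  names(gene_ranks) <- sprintf("G%03d", 1:100)
  cp <- quantile_cutpoints(9, 10)
  n1 <- null_distribution(10, gene_ranks, 300, cp, 1, 500, seed = 9)
  n2 <- null_distribution(10, gene_ranks, 300, cp, 1, 500, seed = 9)
  expect_identical(n1$mean, n2$mean)
  expect_identical(n1$sd, n2$sd)
  # E[O] = E by construction, so the null mean of chi is ~0
  expect_lt(abs(n1$mean), 3 * n1$sd / sqrt(500))
  expect_false(n1$degenerate)
  # constant p-values make every permutation chi identical
  pc <- rep(0.5, 50)
  rank_c <- rank_markers(tiny_assoc(pc, sprintf("M%03d", 1:50)))
  gr_c <- split(1:50, rep(1:25, each = 2))
  names(gr_c) <- sprintf("G%03d", 1:25)
  nc <- null_distribution(25, gr_c, 50, quantile_cutpoints(4, 5), 1, 200, seed = 1)
  expect_true(nc$degenerate)
})

test_that("bh_fdr matches hand-computed step-up values", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
})

test_that("run_msea recovers planted modules and orders by p", {
  cfg <- small_config(seed = 2L, n_tissues = 1L, n_planted_modules = 2L,
                      n_planted_hubs = 0L, rare_hub_overlap = 0)
  d <- withr::local_tempdir()
  b <- generate_study(cfg, d)
  mdf <- run_mdf(b$gwas, b$maps, b$genes, b$ld)
  ms <- run_msea(mdf, b$modules, msea_config(seed = 2, n_permutations = 500))
  expect_false(is.unsorted(ms$results$P))
  planted <- unlist(b$truth$planted_module_ids)
  expect_setequal(ms$results$MODULE[1:2], planted)
  expect_true(all(ms$results[MODULE %in% planted, FDR] < 0.05))
  # audit fields are consistent
  expect_equal(ms$results[, Z], ms$results[, (CHI - NULL_MEAN) / NULL_SD])
  expect_true(all(ms$results$P > 0 & ms$results$P <= 1))
  # modules below the size floor are reported as skipped, not dropped silently
  mods <- b$modules
  mods$tissue01$too_small <- mods$tissue01[[1]][1:4]
  ms2 <- run_msea(mdf, mods, msea_config(seed = 2, n_permutations = 500))
  expect_true("too_small" %in% ms2$skipped$MODULE)
})

test_that("doubling permutations changes null z-scores only slightly", {
  cfg <- small_config(seed = 9L, n_tissues = 1L, n_planted_modules = 0L,
                      n_planted_hubs = 0L, rare_hub_overlap = 0)
  d <- withr::local_tempdir()
  b <- generate_study(cfg, d)
  mdf <- run_mdf(b$gwas, b$maps, b$genes, b$ld)
  z1 <- run_msea(mdf, b$modules, msea_config(seed = 3, n_permutations = 1000))$results
  z2 <- run_msea(mdf, b$modules, msea_config(seed = 4, n_permutations = 2000))$results
  m <- merge(z1[, .(MODULE, Z1 = Z)], z2[, .(MODULE, Z2 = Z)], by = "MODULE")
  expect_gte(mean(abs(m$Z1 - m$Z2) < 0.2), 0.95)
})
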