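test_that("configuration invariants are enforced", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(n_markers = 0), "n_markers")
  expect_error(synth_config(signal_beta_a = 0), "signal_beta_a")
  expect_error(synth_config(n_blocks = 100, block_size = 50, n_markers = 2000),
               "must not exceed n_markers")
  expect_error(synth_config(module_size_range = c(2, 10)), "min >= 3")
  expect_error(synth_config(n_planted_modules = 30, n_modules_per_tissue = 25),
               "n_planted_modules")
  expect_error(synth_config(edges_per_node = 600, network_nodes = 500, n_genes = 500),
               "edges_per_node")
})

test_that("LD blocks emit exactly the within-block pairs", {
  cfg <- synth_config(n_markers = 10L, n_blocks = 2L, block_size = 3L,
                      r2_within = 0.8, n_genes = 10L, network_nodes = 5L,
                      edges_per_node = 1L, module_size_range = c(3, 3),
                      n_planted_modules = 0L, n_planted_hubs = 0L,
                      rare_level_sizes = c(S = 1L, "1" = 1L, "2" = 1L, "3" = 1L),
                      rare_hub_overlap = 0)
  sim <- simulate_ld(cfg)
  expect_equal(nrow(sim$ld), 2 * choose(3, 2))
  expect_true(all(sim$ld$R2 == 0.8))
  expect_true(all(diff(sim$markers$POS) > 0))
  expect_false(anyDuplicated(sim$markers$MARKER) > 0)
  # block_size 1 emits no pairs
  cfg1 <- synth_config(n_markers = 10L, n_blocks = 3L, block_size = 1L,
                       n_genes = 10L, network_nodes = 5L, edges_per_node = 1L,
                       module_size_range = c(3, 3), n_planted_modules = 0L,
                       n_planted_hubs = 0L,
                       rare_level_sizes = c(S = 1L, "1" = 1L, "2" = 1L, "3" = 1L),
                       rare_hub_overlap = 0)
  expect_equal(nrow(simulate_ld(cfg1)$ld), 0L)
})

test_that("signal p-values follow Beta(a, 1) and a = 1 is the null", {
  cfg <- small_config()
  sim <- simulate_ld(cfg)
  set.seed(11)
  gw <- simulate_gwas(cfg, sim$markers, signal_markers = sim$markers$MARKER)
  # P(p < 0.05) = 0.05^a for Beta(a, 1); a = 0.2 -> ~0.549
  expect_equal(mean(gw$PVALUE < 0.05), 0.05^0.2, tolerance = 0.05)
  cfg1 <- small_config(signal_beta_a = 1)
  set.seed(11)
  gw1 <- simulate_gwas(cfg1, sim$markers, signal_markers = sim$markers$MARKER)
  set.seed(11)
  gw0 <- simulate_gwas(cfg1, sim$markers, signal_markers = character())
  expect_equal(gw1$PVALUE, gw0$PVALUE)  # Beta(1,1) == Uniform, same draws
  expect_true(all(gw$PVALUE > 0 & gw$PVALUE <= 1))
})

test_that("bundles are deterministic and parse back with construction guarantees", {
  cfg <- small_config(seed = 5L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_study(cfg, d1)
  generate_study(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  }
  b <- read_study(d1)
  expect_named(b$maps, c("tissue01", "tissue02"))
  expect_named(b$networks, c("brain", "peripheral"))

  # every gene mapped; planted module markers carry designated signal
  expect_setequal(unique(b$maps$tissue01$GENE), b$genes$GENE)
  truth <- b$truth
  planted <- unlist(truth$planted_module_ids)
  expect_length(planted, cfg$n_planted_modules)
  dist_map <- map_by_distance(b$gwas, b$genes, cfg$map_window_kb)
  for (mod in planted) {
    gset <- b$modules$tissue01[[mod]]
    mapped <- union(b$maps$tissue01[GENE %in% gset, MARKER],
                    dist_map[GENE %in% gset, MARKER])
    n_sig <- length(intersect(mapped, unlist(truth$signal_marker_ids)))
    expect_gte(n_sig, ceiling(cfg$signal_fraction * length(gset)))
  }

  # planted hubs have exactly the requested neighborhood composition
  hubs <- unlist(truth$planted_hub_ids)
  expect_length(hubs, cfg$n_planted_hubs)
  e <- b$networks$brain
  disease <- unlist(truth$disease_gene_ids)
  for (h in hubs) {
    nb <- setdiff(unique(c(e[SOURCE == h, TARGET], e[TARGET == h, SOURCE])), h)
    expect_length(nb, cfg$hub_neighbors)
    expect_equal(sum(nb %in% disease),
                 round(cfg$hub_neighbors * cfg$hub_disease_fraction))
  }

  # rare catalog: level sizes and hub overlap fraction hold exactly
  expect_equal(nrow(b$rare_catalog), sum(cfg$rare_level_sizes))
  lv_counts <- table(b$rare_catalog$LEVEL)[c("S", "1", "2", "3")]
  expect_equal(as.vector(lv_counts),
               as.vector(cfg$rare_level_sizes[c("S", "1", "2", "3")]))
  neigh <- setdiff(unique(c(e[SOURCE %in% hubs, TARGET], e[TARGET %in% hubs, SOURCE])), hubs)
  expect_equal(sum(b$rare_catalog$GENE %in% neigh),
               round(cfg$rare_hub_overlap * sum(cfg$rare_level_sizes)))

  # GMT lines parse back with at least min module size genes
  expect_true(all(lengths(b$modules$tissue01) >= cfg$module_size_range[1]))

  # different seeds differ
  d3 <- withr::local_tempdir()
  generate_study(small_config(seed = 6L), d3)
  expect_false(identical(read_gwas(file.path(d1, "gwas.tsv"))$PVALUE,
                         read_gwas(file.path(d3, "gwas.tsv"))$PVALUE))
})

test_that("null bundles carry no systematic signal", {
  # with nothing planted, GWAS p-values are uniform: K-S non-significant at
  # alpha = 0.01 in at least 95% of seeds
  cfg0 <- small_config(n_planted_modules = 0L, n_planted_hubs = 0L, rare_hub_overlap = 0)
  sim <- simulate_ld(cfg0)
  ks_p <- vapply(1:100, function(seed) {
    set.seed(seed)
    gw <- simulate_gwas(cfg0, sim$markers, character())
    suppressWarnings(stats::ks.test(gw$PVALUE, "punif")$p.value)
  }, numeric(1))
  expect_gte(mean(ks_p > 0.01), 0.95)
})

test_that("rare catalog overlap edge cases behave by construction", {
  cfg <- small_config(rare_hub_overlap = 0, n_planted_hubs = 0L)
  set.seed(3)
  cat0 <- simulate_rare_catalog(cfg, gene_ids(200), character())
  expect_equal(nrow(cat0), sum(cfg$rare_level_sizes))
  # full overlap with a feasible neighborhood pool
  cfg1 <- small_config(rare_hub_overlap = 1)
  pool <- gene_ids(200)[1:80]
  set.seed(3)
  cat1 <- simulate_rare_catalog(cfg1, gene_ids(200), pool)
  expect_true(all(cat1$GENE %in% pool))
  # infeasible overlap errors
  expect_error(simulate_rare_catalog(cfg1, gene_ids(200), pool[1:10]), "infeasible")
})

test_that("preferential attachment yields heavy-tailed degrees", {
  cfg <- synth_config(n_genes = 2000L, network_nodes = 2000L, edges_per_node = 3L,
                      n_planted_hubs = 0L)
  ratios <- vapply(1:10, function(seed) {
    set.seed(seed)
    net <- simulate_network(cfg, gene_ids(2000), character(), planted = FALSE)
    deg <- node_degree(net$edges)
    max(deg) / stats::median(deg)
  }, numeric(1))
  expect_true(all(ratios >= 5))
})
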