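test_that("seed-screen generator plants the advertised correlation", {
  # degenerate r = 1, noise enters only through the shared latent factor
  ds <- generate_seed_screen_dataset(n_null = 2L, n_pos = 3L, n_neg = 2L,
                                     n_samples = 10L, planted_r = 1,
                                     rng_seed = 3L)
  v <- unclass(ds$matrix)
  seedp <- v[ds$truth$seed_gene_id, ]
  for (g in ds$truth$pos_module) {
    expect_equal(stats::cor(v[g, ], seedp), 1)
  }
  for (g in ds$truth$neg_module) {
    expect_equal(stats::cor(v[g, ], seedp), -1)
  }

  # Monte-Carlo check of the population value at large n
  big <- generate_seed_screen_dataset(n_null = 0L, n_pos = 30L,
                                      n_neg = 30L, n_samples = 1000L,
                                      planted_r = 0.8, rng_seed = 9L)
  vb <- unclass(big$matrix)
  sp <- vb[big$truth$seed_gene_id, ]
  r_pos <- vapply(big$truth$pos_module,
                  function(g) stats::cor(vb[g, ], sp), numeric(1L))
  r_neg <- vapply(big$truth$neg_module,
                  function(g) stats::cor(vb[g, ], sp), numeric(1L))
  expect_lt(abs(mean(r_pos) - 0.8), 0.05)
  expect_lt(abs(mean(r_neg) + 0.8), 0.05)

  expect_error(generate_seed_screen_dataset(1, 1, 1, 10, planted_r = 1.2),
               "planted_r")
  expect_error(generate_seed_screen_dataset(1, 1, 1, 3), "4 samples")
})

test_that("generators are bit-reproducible and truth is consistent", {
  a <- generate_seed_screen_dataset(50L, 5L, 5L, 12L, rng_seed = 77L)
  b <- generate_seed_screen_dataset(50L, 5L, 5L, 12L, rng_seed = 77L)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  modules <- c(a$truth$pos_module, a$truth$neg_module, a$truth$null_genes)
  expect_false(anyDuplicated(modules) > 0)
  expect_setequal(c(a$truth$seed_gene_id, modules), rownames(a$matrix))

  d1 <- generate_dose_response_dataset(rng_seed = 5L)
  d2 <- generate_dose_response_dataset(rng_seed = 5L)
  expect_identical(unclass(d1$matrix), unclass(d2$matrix))
})

test_that("contrast generator shifts only the affected genes", {
  # planted effect recovered within 3 standard errors
  ds <- generate_contrast_dataset(n_genes = 20L, n_per_group = 4L,
                                  affected_genes = "G0001",
                                  effect_log2 = -1, noise_sd = 1,
                                  rng_seed = 11L)
  v <- unclass(ds$matrix)
  grp2 <- ds$metadata$sample_id[ds$metadata$group == "disease"]
  grp1 <- setdiff(ds$metadata$sample_id, grp2)
  diff <- mean(v["G0001", grp2]) - mean(v["G0001", grp1])
  se <- sqrt(1 / 4 + 1 / 4)
  expect_lt(abs(diff - (-1)), 3 * se)

  expect_error(generate_contrast_dataset(10L, 1L), "2 samples")
  expect_error(generate_contrast_dataset(10L, 4L,
                                         affected_genes = "G9999"),
               "G9999")
})

test_that("dose-response generator follows the titration design", {
  ds <- generate_dose_response_dataset(rng_seed = 2L)
  expect_equal(ds$truth$doses, c(0.1, 1, 10, 100, 1000))
  expect_equal(nrow(ds$metadata), 15L)  # 5 doses x 3 replicates

  # noise-free limit: strictly decreasing means, rho exactly -1
  nf <- generate_dose_response_dataset(responsive_genes = "G0001",
                                       dose_slope = -0.5, noise_sd = 1e-9,
                                       n_genes = 3L, rng_seed = 4L)
  means <- tapply(unclass(nf$matrix)["G0001", ], nf$metadata$dose, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) < 0))
  # per-sample Spearman is capped by replicate-tied dose ranks; the
  # per-dose means attain rho = -1 exactly
  expect_equal(stats::cor(unname(means)[order(as.numeric(names(means)))],
                          log10(c(0.1, 1, 10, 100, 1000)),
                          method = "spearman"), -1)

  expect_error(generate_dose_response_dataset(doses = c(0, 1, 10)),
               "positive")
  expect_error(generate_dose_response_dataset(n_reps = 1L), "replicates")
})

test_that("planted catalog and planted network match their construction", {
  ds <- generate_seed_screen_dataset(100L, 10L, 20L, 12L, rng_seed = 8L)
  catalog <- generate_catalog_with_planted_enrichment(
    ds$truth, n_terms = 5L, planted_term_overlap = 10L,
    background = rownames(ds$matrix), rng_seed = 8L)
  expect_true(all(c("PLANTED_SIG", "PLANTED_SIG_DUP") %in%
                    names(catalog$sets)))
  expect_identical(catalog$sets$PLANTED_SIG, catalog$sets$PLANTED_SIG_DUP)
  expect_true(all(catalog$sets$PLANTED_SIG %in% ds$truth$neg_module))
  expect_error(generate_catalog_with_planted_enrichment(
    ds$truth, planted_term_overlap = 50L, background = rownames(ds$matrix)),
    "overlap")

  # cliques (5, 4), no background: C(5,2) + C(4,2) edges, components = cliques
  net <- generate_planted_network(c(5L, 4L), n_background_nodes = 0L,
                                  rng_seed = 1L)
  expect_equal(igraph::ecount(net$graph), choose(5, 2) + choose(4, 2))
  comp <- igraph::components(net$graph)
  expect_equal(comp$no, 2L)
  expect_setequal(
    split(igraph::V(net$graph)$name, comp$membership)[[1L]],
    net$truth$planted_complex_nodes[[1L]])
  expect_error(generate_planted_network(c(2L)), ">= 3")
})
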