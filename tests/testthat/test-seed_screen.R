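test_that("centered cosine matches its worked examples and Pearson", {
  expect_equal(centered_cosine(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(centered_cosine(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(centered_cosine(c(2, 4, 4, 6), c(1, 1, 3, 3)), 1 / sqrt(2))
  expect_equal(centered_cosine(c(1, 1, 1), c(1, 2, 3)), 0)  # zero norm

  expect_error(centered_cosine(1:3, 1:4), "equal length")
  expect_error(centered_cosine(1:2, 2:1), "3 samples")

  # equivalence with Pearson on random pairs
  set.seed(101)
  max_diff <- max(vapply(1:1000, function(i) {
    n <- sample(4:30, 1L)
    x <- rnorm(n); y <- rnorm(n)
    abs(centered_cosine(x, y) - stats::cor(x, y))
  }, numeric(1L)))
  expect_lt(max_diff, 1e-12)

  # un-centered flag preserves the literal cosine
  x <- c(2, 4, 6); y <- c(1, 2, 3)
  expect_equal(centered_cosine(x, y, center = FALSE),
               sum(x * y) / sqrt(sum(x^2) * sum(y^2)))
})

test_that("bh_adjust matches the step-up oracle and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(1, 5L)), rep(1, 5L))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")

  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1L))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q[order(p)] == cummax(q[order(p)])))  # monotone
  }
})

test_that("permutation p-values follow the add-one floor and conventions", {
  ds <- generate_seed_screen_dataset(n_null = 20L, n_pos = 3L,
                                     n_neg = 0L, n_samples = 30L,
                                     planted_r = 1, rng_seed = 5L)
  cfg <- screen_config("SEED", rng_seed = 2L, exhaustive = FALSE)
  pv <- permutation_pvalues(ds$matrix, cfg)
  # planted r = 1 genes: no permutation can beat |T| = 1 except ties
  expect_true(all(pv$p[ds$truth$pos_module] <= 2 / 1001))
  expect_true(all(pv$p >= 1 / 1001))

  # zero-variance gene: T = 0, p = 1
  v <- unclass(ds$matrix)
  v["NULL0001", ] <- 5
  flat <- expression_matrix(v, rownames(ds$matrix), colnames(ds$matrix))
  pv2 <- permutation_pvalues(flat, cfg)
  expect_equal(unname(pv2$similarity["NULL0001"]), 0)
  expect_equal(unname(pv2$p["NULL0001"]), 1)

  expect_error(
    permutation_pvalues(ds$matrix, screen_config("MISSING", rng_seed = 1L)),
    "MISSING")
})

test_that("Monte-Carlo p agrees with the exhaustive oracle at n = 5", {
  ds <- generate_seed_screen_dataset(n_null = 12L, n_pos = 2L,
                                     n_neg = 2L, n_samples = 5L,
                                     planted_r = 0.9, rng_seed = 21L)
  v <- unclass(ds$matrix)
  seedp <- v["SEED", ]
  mc <- permutation_pvalues(
    ds$matrix, screen_config("SEED", rng_seed = 31L, exhaustive = FALSE))
  ex <- permutation_pvalues(
    ds$matrix, screen_config("SEED", rng_seed = 31L, exhaustive = TRUE))
  for (g in setdiff(rownames(v), "SEED")) {
    p_oracle <- oracle_exhaustive_p(v[g, ], seedp)
    expect_equal(unname(ex$p[g]), p_oracle, tolerance = 1e-12)
    se <- sqrt(p_oracle * (1 - p_oracle) / 1000)
    c_mc <- unname(mc$p[g]) * 1001 - 1          # raw exceedance count
    expect_lt(abs(c_mc / 1000 - p_oracle), 3 * se + 1e-9)
  }
})

test_that("p-values are invariant to a common re-ordering of samples", {
  # exact relabelling symmetry holds in exhaustive mode (6! = 720 orderings);
  # Monte-Carlo mode agrees only up to sampling noise, checked separately
  ds <- generate_seed_screen_dataset(n_null = 30L, n_pos = 5L,
                                     n_neg = 5L, n_samples = 6L,
                                     rng_seed = 6L)
  cfg <- screen_config("SEED", rng_seed = 9L, exhaustive = TRUE)
  p1 <- permutation_pvalues(ds$matrix, cfg)$p
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  shuffled <- expression_matrix(unclass(ds$matrix)[, perm],
                                rownames(ds$matrix),
                                colnames(ds$matrix)[perm])
  p2 <- permutation_pvalues(shuffled, cfg)$p
  expect_equal(p1, p2)

  big <- generate_seed_screen_dataset(n_null = 30L, n_pos = 5L,
                                      n_neg = 5L, n_samples = 12L,
                                      rng_seed = 6L)
  cfg_mc <- screen_config("SEED", rng_seed = 9L)
  q1 <- permutation_pvalues(big$matrix, cfg_mc)$p
  perm12 <- c(4L, 1L, 10L, 2L, 8L, 3L, 12L, 6L, 9L, 11L, 5L, 7L)
  shuffled12 <- expression_matrix(unclass(big$matrix)[, perm12],
                                  rownames(big$matrix),
                                  colnames(big$matrix)[perm12])
  q2 <- permutation_pvalues(shuffled12, cfg_mc)$p
  se <- sqrt(pmax(q1 * (1 - q1), 0.25e-3) / 1000)
  expect_true(all(abs(q1 - q2) <= 4 * se + 2 / 1001))
})

test_that("run_seed_screen recovers planted modules with correct signs", {
  ds <- generate_seed_screen_dataset(n_null = 1000L, n_pos = 50L,
                                     n_neg = 50L, n_samples = 20L,
                                     planted_r = 0.9, rng_seed = 40L)
  res <- run_seed_screen(ds$matrix, screen_config("SEED", rng_seed = 41L))
  expect_false("SEED" %in% res$gene_id)
  pos <- res$gene_id[res$sign == "positive"]
  neg <- res$gene_id[res$sign == "negative"]
  expect_true(all(intersect(pos, c(ds$truth$pos_module,
                                   ds$truth$neg_module)) %in%
                    ds$truth$pos_module))
  expect_true(all(intersect(neg, c(ds$truth$pos_module,
                                   ds$truth$neg_module)) %in%
                    ds$truth$neg_module))
  expect_gt(length(intersect(pos, ds$truth$pos_module)), 40L)
  expect_gt(length(intersect(neg, ds$truth$neg_module)), 40L)
  # labels consistent with similarity sign and threshold
  expect_true(all(res$similarity[res$sign == "positive"] > 0))
  expect_true(all(res$similarity[res$sign == "negative"] < 0))
  expect_true(all(res$q[res$sign != "nonsignificant"] < 0.1))
  # sorted by q then |T| descending
  expect_true(!is.unsorted(res$q))
})

test_that("median |T| of planted genes grows with planted_r", {
  med_t <- vapply(c(0.2, 0.5, 0.8), function(r) {
    ds <- generate_seed_screen_dataset(n_null = 0L, n_pos = 40L,
                                       n_neg = 0L, n_samples = 20L,
                                       planted_r = r, rng_seed = 50L)
    v <- unclass(ds$matrix)
    stats::median(abs(vapply(ds$truth$pos_module, function(g) {
      stats::cor(v[g, ], v["SEED", ])
    }, numeric(1L))))
  }, numeric(1L))
  expect_true(all(diff(med_t) > 0))
})

test_that("screen_config validates its fields", {
  expect_error(screen_config("S", n_permutations = 10L), ">= 100")
  expect_error(screen_config("S", fdr_threshold = 0), "\\(0, 1\\)")
  expect_error(screen_config(c("a", "b")), "single string")
})
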