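test_that("expression TSV round-trips byte-identically and rejects bad input", {
  x <- expression_matrix(
    matrix(c(1.5, 2.25, 3, 4.125, 5, 6.75), 3L, 2L),
    c("TSPAN32", "CD37", "CD81"), c("S1", "S2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(x, path)
  y <- read_expression_tsv(path)
  expect_equal(unclass(y), unclass(x))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(y, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS1\tS2", "TSPAN32\t1\t2", "TSPAN32\t3\t4"), dup)
  expect_error(read_expression_tsv(dup), "TSPAN32")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_expression_tsv(empty), "no data rows")

  ragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS1\tS2", "A\t1\t2", "B\t3"), ragged)
  expect_error(read_expression_tsv(ragged), "line 3")

  nonnum <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS1\tS2", "A\t1\tNA"), nonnum)
  expect_error(read_expression_tsv(nonnum), "non-numeric")
})

test_that("GMT reader enforces format and dedups members with a warning", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines("IFN_SIG\tdesc\tA\tB\tC", gmt)
  cat1 <- read_gmt(gmt)
  expect_length(cat1$sets, 1L)
  expect_equal(cat1$sets$IFN_SIG, c("A", "B", "C"))

  writeLines("T1\tdesc\tA\tA", gmt)
  expect_warning(cat2 <- read_gmt(gmt), "duplicate member")
  expect_equal(cat2$sets$T1, "A")

  writeLines(c("T1\tdesc\tA", "T1\tdesc\tB"), gmt)
  expect_error(read_gmt(gmt), "duplicate term")

  writeLines("T1\tdesc", gmt)
  expect_error(read_gmt(gmt), "line 1")
})

test_that("edge-list reader yields a simple graph with warnings", {
  el <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "C\tC"), el)
  expect_warning(expect_warning(g <- read_edge_list(el), "self-loop"),
                 "duplicate edge")
  expect_equal(igraph::ecount(g), 1L)

  writeLines(character(0), el)
  g0 <- read_edge_list(el)
  expect_equal(igraph::vcount(g0), 0L)

  k4 <- t(utils::combn(c("a", "b", "c", "d"), 2L))
  writeLines(paste(k4[, 1L], k4[, 2L], sep = "\t"), el)
  g4 <- read_edge_list(el)
  expect_equal(igraph::vcount(g4), 4L)
  expect_equal(igraph::ecount(g4), 6L)

  writeLines("A\tB\tC", el)
  expect_error(read_edge_list(el), "line 1")
})

test_that("log2_transform follows the documented conventions", {
  x <- expression_matrix(matrix(c(1, 0, 3, 7), 2L, 2L),
                         c("g1", "g2"), c("s1", "s2"),
                         log_scale = FALSE)
  y <- log2_transform(x, offset = 1)
  expect_equal(unclass(y)[1L, 1L], 1)   # log2(1 + 1)
  expect_equal(unclass(y)[2L, 1L], 0)   # log2(0 + 1)
  expect_true(attr(y, "log_scale"))
  expect_error(log2_transform(y), "already")
  neg <- expression_matrix(matrix(-1, 1L, 1L), "g", "s",
                           log_scale = FALSE)
  expect_error(log2_transform(neg), "negative")
})

test_that("quantile normalization matches its definition", {
  # identical samples are a fixed point
  x <- expression_matrix(cbind(s1 = c(3, 1, 2), s2 = c(3, 1, 2)),
                         sprintf("g%d", 1:3), c("s1", "s2"))
  expect_equal(unclass(quantile_normalize(x)), unclass(x))

  # hand-computed example
  y <- expression_matrix(cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6)),
                         sprintf("g%d", 1:3), c("s1", "s2"))
  qn <- quantile_normalize(y)
  expect_equal(unname(unclass(qn)),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)),
               ignore_attr = TRUE)

  # definitional invariant + idempotence + rank preservation
  set.seed(7)
  z <- expression_matrix(matrix(rnorm(200), 40L, 5L),
                         sprintf("g%02d", 1:40), sprintf("s%d", 1:5))
  qz <- quantile_normalize(z)
  sorted <- apply(unclass(qz), 2L, sort)
  expect_lt(max(abs(sorted - sorted[, 1L])), 1e-12)
  qz2 <- quantile_normalize(qz)
  expect_lt(max(abs(unclass(qz2) - unclass(qz))), 1e-12)
  for (j in 1:5) {
    expect_equal(order(unclass(qz)[, j]), order(unclass(z)[, j]))
  }

  # ties get the mean of the spanned target values
  tied <- expression_matrix(cbind(s1 = c(1, 1, 1, 5), s2 = c(1, 2, 3, 4)),
                            sprintf("g%d", 1:4), c("s1", "s2"))
  qt <- quantile_normalize(tied)
  target <- rowMeans(cbind(sort(c(1, 1, 1, 5)), sort(c(1, 2, 3, 4))))
  expect_equal(unname(unclass(qt)[1:3, 1L]),
               rep(mean(target[1:3]), 3L))

  single <- expression_matrix(matrix(1, 2L, 1L), c("a", "b"), "s")
  expect_error(quantile_normalize(single), "2 samples")
})

test_that("expression_matrix enforces its invariants", {
  m <- matrix(1, 2L, 2L)
  expect_error(expression_matrix(m, c("a", "a"), c("s1", "s2")),
               "duplicate gene")
  expect_error(expression_matrix(m, c("a", "b"), c("s", "s")),
               "duplicate sample")
  m[1L, 1L] <- NA
  expect_error(expression_matrix(m, c("a", "b"), c("s1", "s2")),
               "finite")
})
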