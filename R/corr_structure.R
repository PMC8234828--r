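#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of average-fractional ranks; ties receive average
#' ranks. A zero-variance vector yields rho = 0 by convention, with a
#' warning, so similarity matrices stay well-formed.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\].
#' @export
#' @examples
#' spearman_rho(c(1, 1, 2), c(1, 2, 3))  # sqrt(3)/2
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    warning("zero-variance vector: rho set to 0 by convention",
            call. = FALSE)
    return(0)
  }
  stats::cor(rx, ry, method = "pearson")
}

#' Gene-gene Spearman similarity matrix
#'
#' Pairwise Spearman rho over samples for a requested gene panel (for
#' example a gene family), with unit diagonal for non-degenerate genes.
#' Zero-variance genes get rho 0 against everything (and on their own
#' diagonal), with one warning.
#'
#' @param x an `ExpressionMatrix`.
#' @param gene_subset character vector of gene ids (default: all genes).
#' @return a `SimilarityMatrix`: symmetric numeric matrix with gene-id
#'   dimnames.
#' @export
similarity_matrix <- function(x, gene_subset = rownames(x)) {
  missing <- setdiff(gene_subset, rownames(x))
  if (length(missing)) {
    stopf("unknown gene id(s): %s", paste(missing, collapse = ", "))
  }
  v <- unclass(x)[gene_subset, , drop = FALSE]
  ranks <- t(apply(v, 1L, rank, ties.method = "average"))
  degenerate <- apply(ranks, 1L, function(r) stats::var(r) == 0)
  if (any(degenerate)) {
    warnf("%d zero-variance gene(s): rho set to 0 by convention",
          sum(degenerate))
  }
  rho <- suppressWarnings(stats::cor(t(ranks), method = "pearson"))
  rho[degenerate, ] <- 0
  rho[, degenerate] <- 0
  diag(rho)[!degenerate] <- 1
  rho <- (rho + t(rho)) / 2  # enforce exact symmetry
  dimnames(rho) <- list(gene_subset, gene_subset)
  structure(rho, class = c("SimilarityMatrix", "matrix", "array"))
}

#' Hierarchical clustering of a similarity matrix
#'
#' Agglomerative clustering on the dissimilarity `d = 1 - rho` (signed:
#' anti-correlated genes are maximally distant) with average linkage
#' (UPGMA). The merge order is deterministic for a given input order;
#' exact distance ties are resolved by `hclust`'s stable ordering of the
#' (lexicographically ordered) gene ids.
#'
#' @param sim a `SimilarityMatrix`.
#' @param k number of flat clusters to cut, 1 <= k <= genes.
#' @param linkage linkage method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return a `ClusterTree`: list with the `hclust` object (`tree`), the
#'   leaf order (`leaf_order`, gene ids), and the flat `labels` (named
#'   integer vector) at the requested `k`.
#' @export
hierarchical_clusters <- function(sim, k, linkage = "average") {
  n <- nrow(sim)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > n) {
    stopf("`k` must lie in [1, %d]", n)
  }
  ord <- order(rownames(sim))
  sim_o <- sim[ord, ord, drop = FALSE]
  d <- stats::as.dist(1 - sim_o)
  if (n == 1L) {
    return(structure(list(tree = NULL,
                          leaf_order = rownames(sim),
                          labels = stats::setNames(1L, rownames(sim)),
                          k = 1L),
                     class = "ClusterTree"))
  }
  tree <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(tree, k = as.integer(k))
  structure(list(tree = tree,
                 leaf_order = tree$labels[tree$order],
                 labels = labels,
                 k = as.integer(k)),
            class = "ClusterTree")
}

#' @export
print.ClusterTree <- function(x, ...) {
  cat(sprintf("ClusterTree: %d leaves cut into %d cluster(s)\n",
              length(x$labels), x$k))
  print(split(names(x$labels), x$labels))
  invisible(x)
}
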