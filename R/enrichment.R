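#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` members of a size-`K` set when sampling `n` genes without
#' replacement from a background of `N`. Computed through
#' [stats::phyper()], which works on log scale internally for stability.
#'
#' @param k observed overlap (integer >= 0).
#' @param n query size.
#' @param K gene-set size.
#' @param N background size.
#' @return p in (0, 1].
#' @export
#' @examples
#' hypergeom_tail(5, 5, 5, 20)  # 1 / choose(20, 5)
hypergeom_tail <- function(k, n, K, N) {
  vals <- c(k, n, K, N)
  if (any(vals != round(vals)) || any(vals < 0)) {
    stop("k, n, K, N must be nonnegative integers", call. = FALSE)
  }
  if (k > min(n, K) || n > N || K > N) {
    stopf("inconsistent counts: need 0 <= k <= min(n, K) <= N (k=%d n=%d K=%d N=%d)",
          k, n, K, N)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' One-sided (upper-tail) hypergeometric test of each catalog term against
#' a query gene list, with Benjamini-Hochberg correction across the tested
#' terms. Term members are intersected with the background before testing;
#' terms with zero overlap with the query are excluded from the table.
#' `log10p` is reported as a negative value (e.g. -13.1 means
#' p = 10^-13.1).
#'
#' @param query_genes character vector, must be a subset of `background`.
#' @param catalog a `GeneSetCatalog`.
#' @param background character vector of all genes eligible for the query
#'   (typically the genes present on the analyzed matrix).
#' @return an `EnrichmentResult`: data.frame with one row per term with
#'   k >= 1, columns `term_id`, `term_name`, `k`, `n`, `K`, `N`, `p`, `q`,
#'   `log10p`, `overlap_genes`; sorted by p ascending, ties by term id.
#' @export
enrich_gene_sets <- function(query_genes, catalog, background) {
  query_genes <- unique(as.character(query_genes))
  background <- unique(as.character(background))
  if (!length(query_genes)) stop("empty query", call. = FALSE)
  if (!length(background)) stop("empty background", call. = FALSE)
  stray <- setdiff(query_genes, background)
  if (length(stray)) {
    stopf("query gene(s) not in background: %s",
          paste(utils::head(stray, 5L), collapse = ", "))
  }
  N <- length(background)
  n <- length(query_genes)
  rows <- lapply(names(catalog$sets), function(id) {
    members <- intersect(catalog$sets[[id]], background)
    K <- length(members)
    if (K == 0L) return(NULL)
    overlap <- intersect(members, query_genes)
    k <- length(overlap)
    if (k == 0L) return(NULL)
    data.frame(term_id = id,
               term_name = catalog$descriptions[[id]] %||% id,
               k = k, n = n, K = K, N = N,
               p = hypergeom_tail(k, n, K, N),
               overlap_genes = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    res <- data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      log10p = numeric(0), overlap_genes = character(0),
                      stringsAsFactors = FALSE)
    return(structure(res, class = c("EnrichmentResult", "data.frame")))
  }
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res$log10p <- log10(res$p)
  res <- res[order(res$p, res$term_id),
             c("term_id", "term_name", "k", "n", "K", "N", "p", "q",
               "log10p", "overlap_genes")]
  rownames(res) <- NULL
  structure(res, class = c("EnrichmentResult", "data.frame"))
}

#' Cohen's kappa similarity of two gene sets
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` of the two membership
#' indicator vectors over a common background; identical sets give 1,
#' complementary sets covering the background give -1, unrelated sets
#' give roughly 0.
#'
#' @param setA,setB character vectors of gene ids.
#' @param background_size size of the common background,
#'   >= `|setA U setB|`.
#' @return kappa <= 1.
#' @export
kappa_similarity <- function(setA, setB, background_size) {
  setA <- unique(setA); setB <- unique(setB)
  union_size <- length(union(setA, setB))
  if (background_size < union_size) {
    stop("background smaller than the union of the sets", call. = FALSE)
  }
  N <- background_size
  a <- length(intersect(setA, setB))          # in both
  b <- length(setdiff(setA, setB))            # A only
  c <- length(setdiff(setB, setA))            # B only
  d <- N - a - b - c                          # neither
  po <- (a + d) / N
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / N^2
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Cluster redundant enrichment terms by kappa similarity
#'
#' Greedy merging of overlapping terms: seed with the most significant
#' unclustered term, absorb every unclustered term whose kappa with the
#' seed's member set meets the threshold, repeat until all terms are
#' assigned. The representative of each cluster is its seed — the member
#' with minimal p (ties broken by term id) — so representatives' p-values
#' are non-increasing in discovery order.
#'
#' @param results an `EnrichmentResult`.
#' @param catalog the `GeneSetCatalog` the results were computed from.
#' @param background character vector used as background in the test.
#' @param kappa_threshold minimum kappa to absorb a term (default 0.3,
#'   the usual redundancy-filter convention).
#' @return list of `TermCluster`s: each a list with `representative`,
#'   `members` (term ids), `p` (representative p), and `kappa` (named
#'   vector of members' kappa to the representative).
#' @export
cluster_terms <- function(results, catalog, background,
                          kappa_threshold = 0.3) {
  if (!nrow(results)) stop("no enriched terms to cluster", call. = FALSE)
  if (kappa_threshold <= 0 || kappa_threshold >= 1) {
    stop("`kappa_threshold` must lie in (0, 1)", call. = FALSE)
  }
  N <- length(unique(background))
  sets <- lapply(results$term_id, function(id) {
    intersect(catalog$sets[[id]], background)
  })
  names(sets) <- results$term_id
  remaining <- results[order(results$p, results$term_id), ]
  clusters <- list()
  while (nrow(remaining)) {
    rep_id <- remaining$term_id[1L]
    kap <- vapply(remaining$term_id, function(id) {
      kappa_similarity(sets[[rep_id]], sets[[id]], N)
    }, numeric(1L))
    absorb <- remaining$term_id[kap >= kappa_threshold |
                                  remaining$term_id == rep_id]
    clusters[[length(clusters) + 1L]] <-
      structure(list(representative = rep_id,
                     members = absorb,
                     p = remaining$p[1L],
                     kappa = kap[absorb]),
                class = "TermCluster")
    remaining <- remaining[!remaining$term_id %in% absorb, , drop = FALSE]
  }
  clusters
}

#' @export
print.TermCluster <- function(x, ...) {
  cat(sprintf("TermCluster: %s (p = %.3g), %d member(s)\n",
              x$representative, x$p, length(x$members)))
  invisible(x)
}
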