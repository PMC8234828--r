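# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: permutations are generated by Heap's
# algorithm, tail probabilities by direct summation of binomial
# coefficients, BH by the literal step-up definition, and complex scores
# by exhaustive subset enumeration.

# Heap's algorithm: all n! orderings of 1..n, one per row.
oracle_all_perms <- function(n) {
  out <- vector("list", factorial(n))
  idx <- 0L
  a <- seq_len(n)
  heap <- function(k) {
    if (k == 1L) {
      idx <<- idx + 1L
      out[[idx]] <<- a
      return(invisible())
    }
    for (i in seq_len(k)) {
      heap(k - 1L)
      if (k %% 2L == 0L) {
        tmp <- a[i]; a[i] <<- a[k]; a[k] <<- tmp
      } else {
        tmp <- a[1L]; a[1L] <<- a[k]; a[k] <<- tmp
      }
    }
  }
  heap(n)
  do.call(rbind, out)
}

# Exact two-sided permutation p for one gene vs a seed profile, by
# exhaustive enumeration with stats::cor.
oracle_exhaustive_p <- function(gene, seed_profile) {
  perms <- oracle_all_perms(length(seed_profile))
  t_obs <- abs(stats::cor(gene, seed_profile))
  t_null <- apply(perms, 1L, function(pi) {
    abs(stats::cor(gene, seed_profile[pi]))
  })
  mean(t_null >= t_obs - 1e-12)
}

# Literal BH step-up: q_(i) = min over j >= i of min(1, p_(j) m / j).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(pmin(1, p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Upper-tail hypergeometric by direct summation over the support.
oracle_hyper_tail <- function(k, n, K, N) {
  ks <- max(0L, n - (N - K)):min(n, K)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= k])
}

# Maximum density*size over all connected vertex subsets (|V| <= ~12).
oracle_best_subgraph <- function(graph) {
  nodes <- igraph::V(graph)$name
  best <- list(score = -Inf, nodes = character(0))
  for (mask in seq_len(2^length(nodes) - 1L)) {
    sel <- nodes[bitwAnd(mask, 2^(seq_along(nodes) - 1L)) > 0]
    if (length(sel) < 2L) next
    sub <- igraph::induced_subgraph(graph, sel)
    if (!igraph::is_connected(sub)) next
    v <- igraph::vcount(sub)
    s <- 2 * igraph::ecount(sub) / (v * (v - 1)) * v
    if (s > best$score) best <- list(score = s, nodes = sort(sel))
  }
  best
}

# Small deterministic matrix fixture.
toy_matrix <- function(n_genes = 3L, n_samples = 4L, seed = 42L) {
  set.seed(seed)
  expression_matrix(
    matrix(round(stats::rnorm(n_genes * n_samples, 8, 1), 3L),
           n_genes, n_samples),
    sprintf("g%02d", seq_len(n_genes)),
    sprintf("s%02d", seq_len(n_samples)))
}
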