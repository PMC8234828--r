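#' Per-gene Welch two-group contrast
#'
#' A documented stand-in for moderated linear-model tests: per-gene Welch
#' t on log2 values with the Welch-Satterthwaite degrees of freedom,
#' two-sided p, and Benjamini-Hochberg q across genes. The log2 fold
#' change is `mean(group2) - mean(group1)`. Zero-variance degenerate
#' genes (both groups constant) get t = 0 and p = 1 and are flagged; with
#' only n = 4 per group, empirical-Bayes variance moderation would be
#' preferable on real data — this function makes no such claim.
#'
#' @param x an `ExpressionMatrix` (log2 scale).
#' @param metadata data.frame with `sample_id` and `group` columns.
#' @param group_pair length-2 character vector `(group1, group2)`; the
#'   contrast is group2 minus group1.
#' @return a `ContrastResult` data.frame: `gene_id`, `lfc`, `t`, `df`,
#'   `p`, `q`, `degenerate`.
#' @export
welch_contrast <- function(x, metadata, group_pair) {
  if (length(group_pair) != 2L) {
    stop("`group_pair` must name exactly two groups", call. = FALSE)
  }
  md <- check_metadata(x, metadata)
  unknown <- setdiff(group_pair, unique(md$group))
  if (length(unknown)) {
    stopf("unknown group label(s): %s", paste(unknown, collapse = ", "))
  }
  s1 <- md$sample_id[md$group == group_pair[1L]]
  s2 <- md$sample_id[md$group == group_pair[2L]]
  if (length(s1) < 2L || length(s2) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  v <- unclass(x)
  v1 <- v[, s1, drop = FALSE]
  v2 <- v[, s2, drop = FALSE]
  n1 <- length(s1); n2 <- length(s2)
  m1 <- rowMeans(v1); m2 <- rowMeans(v2)
  var1 <- rowSums((v1 - m1)^2) / (n1 - 1)
  var2 <- rowSums((v2 - m2)^2) / (n2 - 1)
  se2 <- var1 / n1 + var2 / n2
  lfc <- m2 - m1
  degenerate <- se2 == 0
  tt <- ifelse(degenerate, 0, lfc / sqrt(se2))
  df <- ifelse(degenerate, NA_real_,
               se2^2 / ((var1 / n1)^2 / (n1 - 1) +
                          (var2 / n2)^2 / (n2 - 1)))
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tt), df))
  p <- pmin(1, pmax(p, .Machine$double.xmin))
  res <- data.frame(gene_id = rownames(x), lfc = unname(lfc),
                    t = unname(tt), df = unname(df), p = unname(p),
                    q = bh_adjust(unname(p)),
                    degenerate = unname(degenerate),
                    stringsAsFactors = FALSE)
  res <- res[order(res$p, res$gene_id), ]
  rownames(res) <- NULL
  structure(res, group_pair = group_pair,
            class = c("ContrastResult", "data.frame"))
}

#' Dose-response trend test
#'
#' Per-gene Spearman rho between expression and log10(dose), with
#' significance from a permutation null that reshuffles the
#' sample-to-dose assignment (two-sided, add-one rule, default B = 1000;
#' exact enumeration of all orderings is auto-enabled for small designs).
#' Rank-based, so the test is invariant to any monotone re-labelling of
#' the doses. Significant genes (p below `alpha`) are labelled by the
#' sign of rho; degenerate zero-variance genes get rho 0, p 1.
#'
#' @param x an `ExpressionMatrix`.
#' @param metadata data.frame with `sample_id` and positive `dose`
#'   columns; at least 3 distinct doses.
#' @param n_permutations B (default 1000).
#' @param rng_seed RNG seed for the permutation stream.
#' @param alpha significance level used for the direction label
#'   (default 0.05, the conventional adjusted-p threshold).
#' @param exhaustive `TRUE`/`FALSE` to force exact enumeration, `NA` to
#'   auto-enable when `n_samples! <= 5000`.
#' @return a `DoseTrendResult` data.frame: `gene_id`, `rho`, `p`, `q`,
#'   `direction` (`down`, `up`, or `none`).
#' @export
dose_trend <- function(x, metadata, n_permutations = 1000L, rng_seed = 1L,
                       alpha = 0.05, exhaustive = NA) {
  md <- check_metadata(x, metadata)
  if (is.null(md$dose)) stop("metadata lacks a dose column", call. = FALSE)
  dose <- as.numeric(md$dose)
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    stop("all doses must be positive", call. = FALSE)
  }
  if (length(unique(dose)) < 3L) {
    stop("need at least 3 distinct dose levels", call. = FALSE)
  }
  n <- length(dose)
  ld_rank <- rank(log10(dose), ties.method = "average")
  v <- unclass(x)
  expr_ranks <- t(apply(v, 1L, rank, ties.method = "average"))
  degenerate <- apply(expr_ranks, 1L, function(r) stats::var(r) == 0)
  # Spearman rho = Pearson on ranks; precompute centered/scaled ranks
  er_c <- expr_ranks - rowMeans(expr_ranks)
  er_n <- sqrt(rowSums(er_c^2)); er_n[er_n == 0] <- Inf
  er_u <- er_c / er_n
  dr_c <- ld_rank - mean(ld_rank)
  dr_u <- dr_c / sqrt(sum(dr_c^2))
  rho <- as.vector(er_u %*% dr_u)
  rho[degenerate] <- 0

  nfact <- factorial(n)
  use_exhaustive <- if (is.na(exhaustive)) nfact <= 5000 else {
    isTRUE(exhaustive)
  }
  perms <- if (use_exhaustive) all_permutations(n) else {
    with_seed(rng_seed, t(replicate(n_permutations, sample.int(n))))
  }
  perm_dr <- matrix(dr_u[t(perms)], ncol = n, byrow = TRUE)
  rho_null <- perm_dr %*% t(er_u)               # B x genes
  eps <- 1e-12
  counts <- colSums(abs(rho_null) >= rep(abs(rho), each = nrow(perms)) - eps)
  p <- if (use_exhaustive) counts / nrow(perms) else {
    (1 + counts) / (1 + nrow(perms))
  }
  p[degenerate] <- 1
  q <- bh_adjust(p)
  direction <- rep("none", nrow(v))
  direction[p < alpha & rho > 0] <- "up"
  direction[p < alpha & rho < 0] <- "down"
  res <- data.frame(gene_id = rownames(x), rho = rho, p = p, q = q,
                    direction = direction, stringsAsFactors = FALSE)
  res <- res[order(res$p, res$gene_id), ]
  rownames(res) <- NULL
  structure(res, exhaustive = use_exhaustive,
            class = c("DoseTrendResult", "data.frame"))
}
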