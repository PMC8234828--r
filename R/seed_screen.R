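#' Screen configuration
#'
#' Settings for the seed-gene co-expression screen: the seed gene, the
#' number of random permutations B used to build the null (default 1000),
#' the FDR threshold used to call positive/negative correlates (default
#' 0.1), whether genes are mean-centered before the cosine (default TRUE,
#' making the statistic identical to Pearson correlation — the only
#' reading under which negative correlates can exist on non-negative log2
#' intensities), sidedness, and the RNG seed.
#'
#' When the number of samples is small enough that all `n!` orderings can
#' be enumerated (`n! <= exhaustive_limit`, default 5000, i.e. n <= 7) and
#' `exhaustive` is `NA`, the permutation null is computed exactly instead
#' of by Monte-Carlo sampling.
#'
#' @param seed_gene_id gene identifier of the seed.
#' @param n_permutations integer B >= 100.
#' @param fdr_threshold FDR cutoff in (0, 1).
#' @param center_genes mean-center vectors before the cosine?
#' @param two_sided two-sided test on |T|?
#' @param rng_seed integer seed for the permutation stream.
#' @param exhaustive `TRUE`/`FALSE` to force, `NA` to auto-enable when
#'   feasible.
#' @param exhaustive_limit max `n!` for auto-enabling exhaustive mode.
#' @return a `ScreenConfig` list.
#' @export
screen_config <- function(seed_gene_id, n_permutations = 1000L,
                          fdr_threshold = 0.1, center_genes = TRUE,
                          two_sided = TRUE, rng_seed = 1L,
                          exhaustive = NA, exhaustive_limit = 5000L) {
  if (!is.character(seed_gene_id) || length(seed_gene_id) != 1L) {
    stop("`seed_gene_id` must be a single string", call. = FALSE)
  }
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 100L) {
    stop("`n_permutations` must be an integer >= 100", call. = FALSE)
  }
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("`fdr_threshold` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(seed_gene_id = seed_gene_id,
                 n_permutations = n_permutations,
                 fdr_threshold = fdr_threshold,
                 center_genes = isTRUE(center_genes),
                 two_sided = isTRUE(two_sided),
                 rng_seed = as.integer(rng_seed),
                 exhaustive = exhaustive,
                 exhaustive_limit = as.integer(exhaustive_limit)),
            class = "ScreenConfig")
}

#' Centered cosine similarity of two sample vectors
#'
#' Both vectors are mean-centered, then the cosine
#' `dot(x, y) / (|x| |y|)` is taken, which equals the Pearson correlation
#' of the raw vectors. If either centered vector has zero norm
#' (zero-variance gene) the similarity is 0 by convention. With
#' `center = FALSE` the literal un-centered cosine is returned.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param center mean-center before the cosine (default TRUE).
#' @return a number in \[-1, 1\].
#' @export
#' @examples
#' centered_cosine(c(1, 2, 3), c(3, 2, 1))   # -1
#' centered_cosine(c(2, 4, 4, 6), c(1, 1, 3, 3))  # 1/sqrt(2)
centered_cosine <- function(x, y, center = TRUE) {
  if (length(x) != length(y)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("values must be finite", call. = FALSE)
  }
  if (center) {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  max(-1, min(1, sum(x * y) / (nx * ny)))
}

# Rows of `v` centered (optionally) and scaled to unit norm; zero-norm
# rows become all-zero so their similarity is 0 against anything.
unit_rows <- function(v, center = TRUE) {
  if (center) v <- v - rowMeans(v)
  nrm <- sqrt(rowSums(v^2))
  nrm[nrm == 0] <- Inf
  v / nrm
}

# All similarities of matrix rows against one profile, vectorized.
cosine_against <- function(v, seed_profile, center = TRUE) {
  u <- unit_rows(v, center)
  s <- seed_profile
  if (center) s <- s - mean(s)
  ns <- sqrt(sum(s^2))
  if (ns == 0) return(stats::setNames(rep(0, nrow(v)), rownames(v)))
  stats::setNames(pmin(1, pmax(-1, as.vector(u %*% (s / ns)))),
                  rownames(v))
}

# Permutation matrix for the null: rows are sample orderings. Exhaustive
# mode enumerates all n! orderings (identity included); Monte-Carlo mode
# samples B orderings with replacement under the config's RNG seed.
null_permutations <- function(n, config) {
  nfact <- factorial(n)
  use_exhaustive <- if (is.na(config$exhaustive)) {
    nfact <= config$exhaustive_limit
  } else {
    isTRUE(config$exhaustive)
  }
  if (use_exhaustive) {
    perms <- all_permutations(n)
    list(perms = perms, exhaustive = TRUE)
  } else {
    perms <- with_seed(config$rng_seed, {
      t(replicate(config$n_permutations, sample.int(n)))
    })
    list(perms = perms, exhaustive = FALSE)
  }
}

# All permutations of 1..n, rows of an (n! x n) matrix, lexicographic.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Permutation p-values for similarity to a seed gene
#'
#' The null is built by permuting the sample order of the seed gene's
#' profile: one shared permutation per iteration, scored against all genes
#' at once, preserving the inter-gene correlation structure of the matrix.
#' Two-sided p-values use the add-one rule
#' `p = (1 + #\{b : |T_b| >= |T_obs|\}) / (1 + B)`; in exhaustive mode the
#' p-value is the exact proportion `#\{pi : |T_pi| >= |T_obs|\} / n!`
#' (the identity ordering guarantees p >= 1/n!). Zero-variance genes get
#' T = 0 and p = 1.
#'
#' @param x an `ExpressionMatrix` containing the seed gene, >= 4 samples.
#' @param config a [screen_config()].
#' @return list with `similarity` (named vector T), `p` (named vector),
#'   and `exhaustive` (logical).
#' @export
permutation_pvalues <- function(x, config) {
  if (!config$seed_gene_id %in% rownames(x)) {
    stopf("seed gene %s not found in the matrix", config$seed_gene_id)
  }
  n <- ncol(x)
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  v <- unclass(x)
  seed_profile <- v[config$seed_gene_id, ]
  t_obs <- cosine_against(v, seed_profile, config$center_genes)

  nil <- null_permutations(n, config)
  u <- unit_rows(v, config$center_genes)
  s <- seed_profile
  if (config$center_genes) s <- s - mean(s)
  ns <- sqrt(sum(s^2))
  if (ns == 0) {
    # degenerate seed: similarity identically 0, null flat
    p <- stats::setNames(rep(1, nrow(v)), rownames(v))
    return(list(similarity = t_obs, p = p, exhaustive = nil$exhaustive))
  }
  s_unit <- s / ns
  perm_profiles <- matrix(s_unit[t(nil$perms)], ncol = n, byrow = TRUE)
  t_null <- perm_profiles %*% t(u)              # B x genes
  obs <- if (config$two_sided) abs(t_obs) else t_obs
  nul <- if (config$two_sided) abs(t_null) else t_null
  eps <- 1e-12                                  # guard FP noise at |T|=1
  counts <- colSums(nul >= rep(obs, each = nrow(nul)) - eps)
  p <- if (nil$exhaustive) counts / nrow(nil$perms) else {
    (1 + counts) / (1 + nrow(nil$perms))
  }
  zero_var <- t_obs == 0 & rowSums((v - rowMeans(v))^2) == 0
  p[zero_var] <- 1
  names(p) <- rownames(v)
  list(similarity = t_obs, p = p, exhaustive = nil$exhaustive)
}

#' Run the seed-gene co-expression screen
#'
#' Scores every gene against the seed by (centered) cosine similarity,
#' assigns permutation p-values, applies Benjamini-Hochberg FDR control,
#' and labels genes with `q < fdr_threshold` as `positive` or `negative`
#' correlates by the sign of T; all others are `nonsignificant`. The seed
#' gene is excluded from its own result table. Rows are sorted by q, then
#' |T| descending, ties broken lexicographically by gene id.
#'
#' @param x an `ExpressionMatrix`.
#' @param config a [screen_config()].
#' @return a `ScreenResult`: data.frame with columns `gene_id`,
#'   `similarity`, `p`, `q`, `sign`, plus attributes `n_positive`,
#'   `n_negative`, `config`.
#' @export
run_seed_screen <- function(x, config) {
  pv <- permutation_pvalues(x, config)
  keep <- setdiff(rownames(x), config$seed_gene_id)
  t_obs <- pv$similarity[keep]
  p <- pv$p[keep]
  q <- bh_adjust(p)
  sign_label <- rep("nonsignificant", length(keep))
  sign_label[q < config$fdr_threshold & t_obs > 0] <- "positive"
  sign_label[q < config$fdr_threshold & t_obs < 0] <- "negative"
  res <- data.frame(gene_id = keep, similarity = unname(t_obs),
                    p = unname(p), q = unname(q), sign = sign_label,
                    stringsAsFactors = FALSE)
  res <- res[order(res$q, -abs(res$similarity), res$gene_id), ]
  rownames(res) <- NULL
  structure(res,
            n_positive = sum(sign_label == "positive"),
            n_negative = sum(sign_label == "negative"),
            exhaustive = pv$exhaustive,
            config = config,
            class = c("ScreenResult", "data.frame"))
}

#' Significant correlate gene lists from a screen result
#' @param result a `ScreenResult`.
#' @param sign `"positive"`, `"negative"`, or `"both"`.
#' @return character vector of gene ids.
#' @export
screen_correlates <- function(result, sign = c("both", "positive",
                                               "negative")) {
  sign <- match.arg(sign)
  if (sign == "both") {
    result$gene_id[result$sign != "nonsignificant"]
  } else {
    result$gene_id[result$sign == sign]
  }
}

#' @export
print.ScreenResult <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Seed-gene screen: seed %s, %d genes tested, FDR < %g\n",
    cfg$seed_gene_id, nrow(x), cfg$fdr_threshold))
  cat(sprintf("  %d positive, %d negative correlates (%s null)\n",
              attr(x, "n_positive"), attr(x, "n_negative"),
              if (attr(x, "exhaustive")) "exhaustive" else "Monte-Carlo"))
  print(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
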