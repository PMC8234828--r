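#' Synthetic seed-screen dataset with planted correlated modules
#'
#' Latent-factor construction: the seed gene's profile is a standard
#' normal `z` over samples; each positive-module gene is
#' `r * z + sqrt(1 - r^2) * eps` (population Pearson correlation exactly
#' `r` with the seed), negative-module genes use `-z`, and null genes are
#' independent noise. All profiles are scaled by `noise_sd` and shifted
#' to a common baseline so values resemble log2 microarray intensities.
#' Fully reproducible from `rng_seed`; the planted truth is recorded.
#'
#' @param n_null,n_pos,n_neg numbers of null / positively correlated /
#'   negatively correlated genes.
#' @param n_samples number of samples (>= 4).
#' @param planted_r population correlation of planted genes with the
#'   seed, in (0, 1].
#' @param noise_sd scale of the profiles in log2 units (default 1).
#' @param baseline additive log2 baseline (default 8, a typical
#'   microarray log-intensity).
#' @param rng_seed integer seed.
#' @param seed_gene_id identifier given to the seed gene.
#' @return list with `matrix` (an `ExpressionMatrix`) and `truth` (a
#'   `SyntheticTruth` list recording `seed_gene_id`, `pos_module`,
#'   `neg_module`, `null_genes`, `planted_r`, `rng_seed`).
#' @export
generate_seed_screen_dataset <- function(n_null, n_pos, n_neg,
                                         n_samples, planted_r = 0.8,
                                         noise_sd = 1, baseline = 8,
                                         rng_seed = 1L,
                                         seed_gene_id = "SEED") {
  if (any(c(n_null, n_pos, n_neg) < 0)) {
    stop("gene counts must be nonnegative", call. = FALSE)
  }
  if (n_samples < 4L) stop("need at least 4 samples", call. = FALSE)
  if (!is.numeric(planted_r) || planted_r <= 0 || planted_r > 1) {
    stop("`planted_r` must lie in (0, 1]", call. = FALSE)
  }
  pos_ids <- if (n_pos) sprintf("POS%04d", seq_len(n_pos)) else character(0)
  neg_ids <- if (n_neg) sprintf("NEG%04d", seq_len(n_neg)) else character(0)
  null_ids <- if (n_null) sprintf("NULL%04d", seq_len(n_null)) else character(0)
  gene_ids <- c(seed_gene_id, pos_ids, neg_ids, null_ids)
  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  resid <- sqrt(1 - planted_r^2)
  v <- with_seed(rng_seed, {
    z <- stats::rnorm(n_samples)
    rows <- list(z)
    for (i in seq_len(n_pos)) {
      rows[[length(rows) + 1L]] <-
        planted_r * z + resid * stats::rnorm(n_samples)
    }
    for (i in seq_len(n_neg)) {
      rows[[length(rows) + 1L]] <-
        planted_r * (-z) + resid * stats::rnorm(n_samples)
    }
    for (i in seq_len(n_null)) {
      rows[[length(rows) + 1L]] <- stats::rnorm(n_samples)
    }
    do.call(rbind, rows)
  })
  v <- baseline + noise_sd * v
  mat <- expression_matrix(v, gene_ids, sample_ids, log_scale = TRUE)
  truth <- structure(list(seed_gene_id = seed_gene_id,
                          pos_module = pos_ids, neg_module = neg_ids,
                          null_genes = null_ids, planted_r = planted_r,
                          rng_seed = as.integer(rng_seed)),
                     class = "SyntheticTruth")
  list(matrix = mat, truth = truth)
}

#' Synthetic two-group contrast dataset
#'
#' Emulates a case-control design with donors in two groups (default 4 vs
#' 4, the typical small cohort) across cell subsets: gene profiles are
#' i.i.d. normal around a baseline; `affected_genes` are shifted by
#' `effect_log2` in the second group.
#'
#' @param n_genes number of genes.
#' @param n_per_group donors per group (>= 2).
#' @param affected_genes character vector of gene ids (must exist among
#'   the generated `G0001..` ids) receiving the shift.
#' @param effect_log2 shift, log2 units, applied in group 2.
#' @param groups length-2 character vector of group labels.
#' @param subsets character vector of cell-subset labels cycled over
#'   donors (metadata only; the effect is applied uniformly).
#' @param noise_sd residual SD in log2 units.
#' @param baseline additive baseline.
#' @param rng_seed integer seed.
#' @return list with `matrix`, `metadata` (sample_id, group, subset,
#'   replicate), and `truth`.
#' @export
generate_contrast_dataset <- function(n_genes, n_per_group,
                                      affected_genes = character(0),
                                      effect_log2 = 0,
                                      groups = c("healthy", "disease"),
                                      subsets = c("naive", "memory",
                                                  "plasmablast"),
                                      noise_sd = 1, baseline = 8,
                                      rng_seed = 1L) {
  if (n_per_group < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  stray <- setdiff(affected_genes, gene_ids)
  if (length(stray)) {
    stopf("affected gene(s) outside the generated range: %s",
          paste(stray, collapse = ", "))
  }
  n_samples <- 2L * n_per_group
  sample_ids <- sprintf("%s_%02d", rep(groups, each = n_per_group),
                        rep(seq_len(n_per_group), 2L))
  group <- rep(groups, each = n_per_group)
  md <- data.frame(sample_id = sample_ids, group = group,
                   subset = rep_len(subsets, n_samples),
                   replicate = rep(seq_len(n_per_group), 2L),
                   stringsAsFactors = FALSE)
  v <- with_seed(rng_seed, {
    matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
           n_genes, n_samples)
  }) + baseline
  v[match(affected_genes, gene_ids), group == groups[2L]] <-
    v[match(affected_genes, gene_ids), group == groups[2L]] + effect_log2
  mat <- expression_matrix(v, gene_ids, sample_ids, log_scale = TRUE)
  truth <- structure(list(affected_genes = affected_genes,
                          effect_log2 = effect_log2, groups = groups,
                          rng_seed = as.integer(rng_seed)),
                     class = "SyntheticTruth")
  list(matrix = mat, metadata = md, truth = truth)
}

#' Synthetic dose-response titration dataset
#'
#' Emulates a cytokine titration: the default grid is five ten-fold
#' concentrations spanning 0.1 to 1000 U/mL with 2-3 biological
#' replicates each. Responsive genes have mean
#' `baseline + dose_slope * log10(dose)`; all other genes are dose-flat.
#'
#' @param doses strictly increasing positive dose grid (default
#'   `c(0.1, 1, 10, 100, 1000)`).
#' @param n_reps biological replicates per dose (>= 2, default 3).
#' @param n_genes total number of genes.
#' @param responsive_genes gene ids (within `G0001..`) given the slope.
#' @param dose_slope log2 units per log10 dose.
#' @param noise_sd residual SD in log2 units.
#' @param baseline additive baseline.
#' @param rng_seed integer seed.
#' @return list with `matrix`, `metadata` (sample_id, dose, replicate),
#'   and `truth`.
#' @export
generate_dose_response_dataset <- function(doses = c(0.1, 1, 10, 100, 1000),
                                           n_reps = 3L, n_genes = 50L,
                                           responsive_genes = character(0),
                                           dose_slope = -0.5,
                                           noise_sd = 0.3, baseline = 8,
                                           rng_seed = 1L) {
  if (any(doses <= 0)) stop("all doses must be positive", call. = FALSE)
  if (is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be strictly increasing", call. = FALSE)
  }
  if (n_reps < 2L) stop("need at least 2 replicates", call. = FALSE)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  stray <- setdiff(responsive_genes, gene_ids)
  if (length(stray)) {
    stopf("responsive gene(s) outside the generated range: %s",
          paste(stray, collapse = ", "))
  }
  dose_vec <- rep(doses, each = n_reps)
  n_samples <- length(dose_vec)
  sample_ids <- sprintf("D%g_R%d", dose_vec,
                        rep(seq_len(n_reps), length(doses)))
  md <- data.frame(sample_id = sample_ids, dose = dose_vec,
                   replicate = rep(seq_len(n_reps), length(doses)),
                   stringsAsFactors = FALSE)
  mean_mat <- matrix(baseline, n_genes, n_samples)
  idx <- match(responsive_genes, gene_ids)
  if (length(idx)) {
    mean_mat[idx, ] <- baseline +
      dose_slope * rep(log10(dose_vec), each = length(idx))
  }
  noise <- with_seed(rng_seed, {
    matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
           n_genes, n_samples)
  })
  mat <- expression_matrix(mean_mat + noise, gene_ids, sample_ids,
                           log_scale = TRUE)
  truth <- structure(list(responsive_genes = responsive_genes,
                          dose_slope = dose_slope, doses = doses,
                          rng_seed = as.integer(rng_seed)),
                     class = "SyntheticTruth")
  list(matrix = mat, metadata = md, truth = truth)
}

#' Synthetic gene-set catalog with one planted enriched term
#'
#' Builds a catalog in which one term (`IFN_SIG`-like) draws
#' `planted_term_overlap` of its members from the screen truth's negative
#' module and the remainder at random, plus one exact duplicate of that
#' term (to exercise redundancy clustering at kappa = 1), plus random
#' background terms.
#'
#' @param screen_truth a `SyntheticTruth` from
#'   [generate_seed_screen_dataset()].
#' @param n_terms number of random background terms.
#' @param planted_term_overlap members drawn from the negative module
#'   (<= its size).
#' @param planted_term_size total size of the planted term (>= overlap;
#'   default equals the overlap).
#' @param background character vector of all eligible gene ids.
#' @param term_size size of each random background term.
#' @param rng_seed integer seed.
#' @return a `GeneSetCatalog`; the planted term is `PLANTED_SIG`, its
#'   duplicate `PLANTED_SIG_DUP`.
#' @export
generate_catalog_with_planted_enrichment <- function(screen_truth,
                                                     n_terms = 20L,
                                                     planted_term_overlap = 15L,
                                                     planted_term_size = planted_term_overlap,
                                                     background,
                                                     term_size = 20L,
                                                     rng_seed = 1L) {
  neg <- screen_truth$neg_module
  if (planted_term_overlap > length(neg)) {
    stop("overlap exceeds the negative module size", call. = FALSE)
  }
  if (planted_term_size < planted_term_overlap) {
    stop("planted term smaller than its overlap", call. = FALSE)
  }
  with_seed(rng_seed, {
    planted <- if (planted_term_overlap > 0) {
      sample(neg, planted_term_overlap)
    } else character(0)
    extra_pool <- setdiff(background, neg)
    extra <- planted_term_size - planted_term_overlap
    planted <- c(planted, if (extra > 0) sample(extra_pool, extra))
    sets <- list(PLANTED_SIG = planted, PLANTED_SIG_DUP = planted)
    for (i in seq_len(n_terms)) {
      sets[[sprintf("RANDOM_%03d", i)]] <- sample(background, term_size)
    }
    gene_set_catalog(sets,
                     background_size = length(unique(background)))
  })
}

#' Synthetic network with planted cliques
#'
#' Disjoint cliques wired into a sparse Erdos-Renyi background by
#' explicit bridge edges; the truth records the clique node sets so
#' complex-recovery can be scored.
#'
#' @param clique_sizes integer vector, each >= 3.
#' @param n_background_nodes number of background nodes.
#' @param background_edge_prob edge probability among background nodes
#'   (default 0.05).
#' @param n_bridge_edges number of random clique-to-background bridges
#'   (default 1 per clique when background nodes exist).
#' @param rng_seed integer seed.
#' @return list with `graph` (igraph) and `truth` (clique node sets).
#' @export
generate_planted_network <- function(clique_sizes,
                                     n_background_nodes = 0L,
                                     background_edge_prob = 0.05,
                                     n_bridge_edges = NULL,
                                     rng_seed = 1L) {
  if (any(clique_sizes < 3L)) {
    stop("clique sizes must be >= 3", call. = FALSE)
  }
  cliques <- lapply(seq_along(clique_sizes), function(i) {
    sprintf("C%d_%02d", i, seq_len(clique_sizes[i]))
  })
  bg_nodes <- if (n_background_nodes > 0) {
    sprintf("B%03d", seq_len(n_background_nodes))
  } else character(0)
  edges <- do.call(rbind, lapply(cliques, function(nodes) {
    t(utils::combn(nodes, 2L))
  }))
  n_bridge_edges <- n_bridge_edges %||%
    (if (length(bg_nodes)) length(cliques) else 0L)
  extra <- with_seed(rng_seed, {
    bg_edges <- NULL
    if (length(bg_nodes) >= 2L && background_edge_prob > 0) {
      pairs <- t(utils::combn(bg_nodes, 2L))
      keep <- stats::runif(nrow(pairs)) < background_edge_prob
      bg_edges <- pairs[keep, , drop = FALSE]
    }
    bridges <- NULL
    if (n_bridge_edges > 0 && length(bg_nodes)) {
      bridges <- cbind(
        vapply(seq_len(n_bridge_edges), function(i) {
          cl <- cliques[[((i - 1L) %% length(cliques)) + 1L]]
          sample(cl, 1L)
        }, character(1L)),
        sample(bg_nodes, n_bridge_edges, replace = TRUE))
    }
    rbind(bg_edges, bridges)
  })
  all_edges <- rbind(edges, extra)
  g <- igraph::graph_from_edgelist(all_edges, directed = FALSE)
  g <- igraph::add_vertices(
    g, length(setdiff(c(unlist(cliques), bg_nodes),
                      igraph::V(g)$name)),
    name = setdiff(c(unlist(cliques), bg_nodes), igraph::V(g)$name))
  g <- igraph::simplify(g)
  truth <- structure(list(planted_complex_nodes = cliques,
                          background_nodes = bg_nodes,
                          rng_seed = as.integer(rng_seed)),
                     class = "SyntheticTruth")
  list(graph = g, truth = truth)
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat("SyntheticTruth:\n")
  utils::str(unclass(x), max.level = 1L, give.attr = FALSE)
  invisible(x)
}
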