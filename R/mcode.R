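#' MCODE parameters
#'
#' Defaults follow the original Molecular Complex Detection algorithm:
#' vertex weight percentage (vwp) 0.2, haircut on, fluff off with density
#' threshold 0.2, minimum complex size 3.
#'
#' @param vwp vertex weight percentage in \[0, 1): a neighbor joins a
#'   complex if its weight >= seed_weight * (1 - vwp).
#' @param haircut iteratively remove complex members of within-complex
#'   degree <= 1?
#' @param fluff add boundary nodes whose neighborhood density exceeds
#'   `fluff_density_threshold`? Fluffed nodes may appear in several
#'   complexes.
#' @param fluff_density_threshold density cutoff for fluff in \[0, 1\].
#' @param min_complex_size complexes smaller than this are dropped.
#' @return an `MCODEParams` list.
#' @export
mcode_params <- function(vwp = 0.2, haircut = TRUE, fluff = FALSE,
                         fluff_density_threshold = 0.2,
                         min_complex_size = 3L) {
  if (!is.numeric(vwp) || vwp < 0 || vwp >= 1) {
    stop("`vwp` must lie in [0, 1)", call. = FALSE)
  }
  if (fluff_density_threshold < 0 || fluff_density_threshold > 1) {
    stop("`fluff_density_threshold` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(vwp = vwp, haircut = isTRUE(haircut),
                 fluff = isTRUE(fluff),
                 fluff_density_threshold = fluff_density_threshold,
                 min_complex_size = as.integer(min_complex_size)),
            class = "MCODEParams")
}

# Loopless undirected density 2E / (V (V - 1)); singleton -> 0.
graph_density <- function(graph) {
  v <- igraph::vcount(graph)
  if (v < 2L) return(0)
  2 * igraph::ecount(graph) / (v * (v - 1))
}

#' MCODE vertex weights
#'
#' For each node v, take the subgraph induced by its closed neighborhood,
#' find the highest k-core of that subgraph, and set
#' `weight(v) = k_max * density(highest k-core)`. Isolated nodes weigh 0.
#'
#' @param graph a simple undirected igraph with named vertices.
#' @return named numeric vector of weights.
#' @export
vertex_weights <- function(graph) {
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) {
    nodes <- as.character(seq_len(igraph::vcount(graph)))
    igraph::V(graph)$name <- nodes
  }
  w <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in nodes) {
    nb <- igraph::neighbors(graph, v)$name
    if (!length(nb)) next
    gv <- igraph::induced_subgraph(graph, c(v, nb))
    core <- igraph::coreness(gv)
    k_max <- max(core)
    core_graph <- igraph::induced_subgraph(gv, names(core)[core >= k_max])
    w[v] <- k_max * graph_density(core_graph)
  }
  w
}

#' Score of a node set: density times size
#'
#' MCODE's ranking criterion for a complex: the loopless undirected
#' density of the induced subgraph multiplied by the number of nodes;
#' singletons score 0.
#'
#' @param graph a simple undirected igraph.
#' @param node_set character vector of vertex names.
#' @return nonnegative score.
#' @export
score_complex <- function(graph, node_set) {
  if (!length(node_set)) stop("empty node set", call. = FALSE)
  missing <- setdiff(node_set, igraph::V(graph)$name)
  if (length(missing)) {
    stopf("node(s) not in graph: %s", paste(missing, collapse = ", "))
  }
  sub <- igraph::induced_subgraph(graph, node_set)
  graph_density(sub) * igraph::vcount(sub)
}

# Iteratively strip nodes of within-complex degree <= 1.
apply_haircut <- function(graph, nodes) {
  repeat {
    if (length(nodes) < 2L) return(character(0L))
    sub <- igraph::induced_subgraph(graph, nodes)
    deg <- igraph::degree(sub)
    drop <- names(deg)[deg <= 1L]
    if (!length(drop)) return(nodes)
    nodes <- setdiff(nodes, drop)
  }
}

# Fluff: append boundary neighbors whose closed-neighborhood density in
# the full graph exceeds the threshold (fluffed nodes are not claimed).
apply_fluff <- function(graph, nodes, threshold) {
  boundary <- setdiff(
    unique(unlist(lapply(nodes, function(v) {
      igraph::neighbors(graph, v)$name
    }))), nodes)
  keep <- vapply(boundary, function(v) {
    nb <- c(v, igraph::neighbors(graph, v)$name)
    graph_density(igraph::induced_subgraph(graph, nb)) > threshold
  }, logical(1L))
  c(nodes, sort(boundary[keep]))
}

#' Predict dense complexes (MCODE stage 2)
#'
#' Seeds are taken from the highest-weight unassigned node (ties broken
#' lexicographically by node id); a complex grows breadth-first over
#' unassigned neighbors whose weight is at least
#' `seed_weight * (1 - vwp)`, each node visited once per expansion. Nodes
#' joining a complex are excluded from later complexes; nodes merely
#' rejected remain eligible as later seeds. Haircut then removes
#' singly-connected members; fluff optionally adds dense boundary nodes.
#' Complexes below `min_complex_size` are dropped; the rest are ranked by
#' score descending, ties by size then seed id.
#'
#' @param graph a simple undirected igraph with named vertices.
#' @param params an [mcode_params()].
#' @return list of `MCODEComplex`es: each a list with `nodes`, `seed`,
#'   `score`, `rank`.
#' @export
predict_complexes <- function(graph, params = mcode_params()) {
  if (igraph::vcount(graph) == 0L) return(list())
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  w <- vertex_weights(graph)
  assigned <- character(0L)
  seed_order <- names(sort(w, decreasing = TRUE))
  # stable lexicographic tie-break within equal weights
  seed_order <- seed_order[order(-w[seed_order], seed_order)]
  raw <- list()
  for (seed in seed_order) {
    if (seed %in% assigned) next
    threshold <- w[seed] * (1 - params$vwp)
    members <- seed
    frontier <- seed
    visited <- seed
    while (length(frontier)) {
      nxt <- character(0L)
      for (v in frontier) {
        for (u in igraph::neighbors(graph, v)$name) {
          if (u %in% visited || u %in% assigned) next
          visited <- c(visited, u)
          if (w[u] >= threshold) {
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    if (length(members) < 2L) next
    assigned <- c(assigned, members)
    raw[[length(raw) + 1L]] <- list(seed = seed, members = members)
  }
  complexes <- list()
  for (cx in raw) {
    nodes <- cx$members
    if (params$haircut) nodes <- apply_haircut(graph, nodes)
    if (length(nodes) && params$fluff) {
      nodes <- apply_fluff(graph, nodes, params$fluff_density_threshold)
    }
    if (length(nodes) < params$min_complex_size) next
    complexes[[length(complexes) + 1L]] <-
      list(nodes = sort(nodes), seed = cx$seed,
           score = score_complex(graph, nodes))
  }
  if (!length(complexes)) return(list())
  scores <- vapply(complexes, `[[`, numeric(1L), "score")
  sizes <- vapply(complexes, function(c) length(c$nodes), integer(1L))
  seeds <- vapply(complexes, `[[`, character(1L), "seed")
  ord <- order(-scores, -sizes, seeds)
  complexes <- complexes[ord]
  for (i in seq_along(complexes)) {
    complexes[[i]]$rank <- i
    class(complexes[[i]]) <- "MCODEComplex"
  }
  complexes
}

#' @export
print.MCODEComplex <- function(x, ...) {
  cat(sprintf("MCODEComplex rank %d: %d nodes, score %.3f, seed %s\n",
              x$rank, length(x$nodes), x$score, x$seed))
  invisible(x)
}
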