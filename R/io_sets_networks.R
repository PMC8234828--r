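#' Read a GMT gene-set catalog
#'
#' Standard GMT: one set per line, tab-separated `term_id`, description,
#' then member gene identifiers. Duplicate members within a line are
#' dropped with a warning; a line with fewer than three fields or a
#' repeated term id is a hard error.
#'
#' @param path file path.
#' @return a `GeneSetCatalog`: list with `sets` (named list of character
#'   vectors), `descriptions` (named character), and `background_size`
#'   (`NA` until a background is chosen at test time).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stopf("GMT line %d has %d field(s); need term, description, >=1 member",
          short[1L], lengths(fields)[short[1L]])
  }
  term_ids <- vapply(fields, `[[`, character(1L), 1L)
  dup <- unique(term_ids[duplicated(term_ids)])
  if (length(dup)) {
    stopf("duplicate term id(s): %s", paste(dup, collapse = ", "))
  }
  descriptions <- vapply(fields, `[[`, character(1L), 2L)
  sets <- lapply(seq_along(fields), function(i) {
    members <- fields[[i]][-(1:2)]
    u <- unique(members)
    if (length(u) < length(members)) {
      warnf("term %s: %d duplicate member(s) removed",
            term_ids[i], length(members) - length(u))
    }
    u
  })
  names(sets) <- term_ids
  names(descriptions) <- term_ids
  gene_set_catalog(sets, descriptions)
}

gene_set_catalog <- function(sets, descriptions = NULL,
                             background_size = NA_integer_) {
  if (!length(sets) || any(lengths(sets) == 0L)) {
    stop("catalog must contain only non-empty sets", call. = FALSE)
  }
  structure(list(sets = sets,
                 descriptions = descriptions %||%
                   stats::setNames(names(sets), names(sets)),
                 background_size = background_size),
            class = "GeneSetCatalog")
}

#' @export
print.GeneSetCatalog <- function(x, ...) {
  cat(sprintf("GeneSetCatalog: %d sets, sizes %d-%d\n", length(x$sets),
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Write a GMT gene-set catalog
#' @param catalog a `GeneSetCatalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog$sets), function(id) {
    paste(c(id, catalog$descriptions[[id]], catalog$sets[[id]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected gene network from a two-column edge list
#'
#' Tab-separated pairs of gene identifiers. Self-loops are dropped and
#' duplicate edges (in either orientation) collapsed, each with a warning,
#' so the result is always a simple undirected graph.
#'
#' @param path file path.
#' @return an [igraph::graph] (undirected, simple, named vertices).
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stopf("malformed edge at line %d: expected 2 tab-separated fields",
          bad[1L])
  }
  a <- vapply(fields, `[[`, character(1L), 1L)
  b <- vapply(fields, `[[`, character(1L), 2L)
  loops <- a == b
  if (any(loops)) {
    warnf("%d self-loop(s) dropped", sum(loops))
    a <- a[!loops]; b <- b[!loops]
  }
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  n_before <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::ecount(g) < n_before) {
    warnf("%d duplicate edge(s) collapsed", n_before - igraph::ecount(g))
  }
  g
}

#' Write a network as a two-column edge list
#' @param graph an undirected igraph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  if (nrow(el)) {
    writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
  } else {
    writeLines(character(0L), path)
  }
  invisible(path)
}
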