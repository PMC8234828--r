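#' ExpressionMatrix: a validated log2 gene-by-sample matrix
#'
#' The substrate of every analysis stage: a numeric matrix with genes in
#' rows and samples in columns, unique identifiers on both dimensions, all
#' values finite, and a flag recording whether values are on the log2
#' scale. Gene identifiers are opaque, case-sensitive strings; no
#' probe-to-symbol mapping is attempted.
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids character vector of unique row identifiers
#'   (defaults to `rownames(values)`).
#' @param sample_ids character vector of unique column identifiers
#'   (defaults to `colnames(values)`).
#' @param log_scale logical; `TRUE` if values are log2 intensities.
#' @return an object of class `ExpressionMatrix` (a numeric matrix with
#'   dimnames and a `log_scale` attribute).
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              log_scale = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stopf("%d gene ids for %d rows", length(gene_ids), nrow(values))
  }
  if (length(sample_ids) != ncol(values)) {
    stopf("%d sample ids for %d columns", length(sample_ids), ncol(values))
  }
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    stopf("duplicate gene id(s): %s", paste(unique(dup), collapse = ", "))
  }
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) {
    stopf("duplicate sample id(s): %s", paste(unique(dup), collapse = ", "))
  }
  if (!all(is.finite(values))) {
    stop("all expression values must be finite; missing values are not supported",
         call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(values, log_scale = isTRUE(log_scale),
            class = c("ExpressionMatrix", "matrix", "array"))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "log_scale"))) "log2" else "linear"))
  n <- min(5L, nrow(x)); m <- min(6L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE], ...)
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

is_log_scale <- function(x) isTRUE(attr(x, "log_scale"))

# Subset keeping class/attributes; used by pipeline sample filters.
subset_expression <- function(x, genes = NULL, samples = NULL) {
  g <- genes %||% rownames(x)
  s <- samples %||% colnames(x)
  missing_g <- setdiff(g, rownames(x))
  if (length(missing_g)) {
    stopf("unknown gene id(s): %s", paste(missing_g, collapse = ", "))
  }
  missing_s <- setdiff(s, colnames(x))
  if (length(missing_s)) {
    stopf("unknown sample id(s): %s", paste(missing_s, collapse = ", "))
  }
  expression_matrix(unclass(x)[g, s, drop = FALSE], g, s,
                    log_scale = is_log_scale(x))
}

#' Read an expression matrix from TSV
#'
#' Expected dialect: UTF-8, tab-separated, `.` decimal; header row of
#' sample identifiers; first column gene identifiers; genes in rows. Rows
#' containing any non-numeric cell are rejected with a hard error, as are
#' duplicate gene identifiers and ragged rows.
#'
#' @param path file path.
#' @param log_scale logical flag recording the scale of the stored values
#'   (the reader does not transform them).
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, log_scale = TRUE) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 2L) stop("no data rows", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header)
  sample_ids <- header[-1L]
  body <- fields[-1L]
  widths <- lengths(body)
  bad <- which(widths != n_col)
  if (length(bad)) {
    stopf("ragged row at line %d: %d fields, expected %d",
          bad[1L] + 1L, widths[bad[1L]], n_col)
  }
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stopf("duplicate gene id(s): %s", paste(dup, collapse = ", "))
  }
  vals <- vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1L]))
    v
  }, numeric(n_col - 1L))
  vals <- if (n_col == 2L) matrix(vals, ncol = 1L) else t(vals)
  nn <- which(apply(vals, 1L, function(r) any(is.na(r))))
  if (length(nn)) {
    stopf("non-numeric value in row for gene %s (line %d)",
          gene_ids[nn[1L]], nn[1L] + 1L)
  }
  expression_matrix(vals, gene_ids, sample_ids, log_scale = log_scale)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_tsv()]: round-trips byte-identically for
#' matrices whose values print exactly (R's default 15-significant-digit
#' formatting is used).
#'
#' @param x an `ExpressionMatrix`.
#' @param path output file path.
#' @param header_comment optional character vector written as leading
#'   `#`-prefixed lines (provenance metadata).
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, header_comment = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  emit <- function(s) writeLines(s, con, sep = "\n", useBytes = TRUE)
  if (length(header_comment)) emit(paste0("# ", header_comment))
  emit(paste(c("gene_id", colnames(x)), collapse = "\t"))
  body <- apply(unclass(x), 1L, function(r) {
    paste(format(r, trim = TRUE, digits = 15L, scientific = FALSE),
          collapse = "\t")
  })
  emit(paste(rownames(x), body, sep = "\t"))
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `group`, `subset`, `dose`, `replicate`;
#' `dose` and `subset` may be absent for designs that lack them. Every
#' `sample_id` must be unique.
#'
#' @param path file path.
#' @return a data.frame with one row per sample.
#' @export
read_metadata_tsv <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"sample_id" %in% names(md)) {
    stop("metadata must contain a sample_id column", call. = FALSE)
  }
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  md
}

#' Write a sample metadata table
#' @param md data.frame as returned by [read_metadata_tsv()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata_tsv <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Checks metadata against a matrix: every sample accounted for.
check_metadata <- function(x, md) {
  missing <- setdiff(colnames(x), md$sample_id)
  if (length(missing)) {
    stopf("sample(s) missing from metadata: %s",
          paste(missing, collapse = ", "))
  }
  md[match(colnames(x), md$sample_id), , drop = FALSE]
}
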