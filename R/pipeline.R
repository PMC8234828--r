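# Known configuration schema: top-level keys and per-section keys.
# validate_config() reports every violation at once and suggests the
# nearest known key for typos.
config_schema <- list(
  top = c("matrix", "metadata", "seed_gene", "output_dir", "rng_seed",
          "normalize", "sample_subset", "screen", "contrast",
          "simmatrix", "enrichment", "mcode", "dosetrend", "simulate",
          "stages"),
  screen = c("permutations", "fdr", "center", "two_sided"),
  normalize = c("quantile"),
  sample_subset = c("column", "value"),
  contrast = c("groups"),
  simmatrix = c("genes", "k", "linkage"),
  enrichment = c("gmt", "kappa_threshold"),
  mcode = c("edges", "vwp", "haircut", "fluff", "min_size"),
  dosetrend = c("enabled", "alpha", "permutations"),
  simulate = c("n_null", "n_pos", "n_neg", "n_samples", "planted_r",
               "noise_sd"),
  stages = c("normalize", "contrast", "screen", "simmatrix",
             "enrichment", "mcode", "dosetrend")
)

check_keys <- function(keys, allowed, where) {
  unknown <- setdiff(keys, allowed)
  vapply(unknown, function(k) {
    hit <- agrep(k, allowed, max.distance = 2L, value = TRUE)
    if (length(hit)) {
      sprintf("unknown key '%s' in %s; did you mean '%s'?",
              k, where, hit[1L])
    } else {
      sprintf("unknown key '%s' in %s", k, where)
    }
  }, character(1L))
}

#' Validate and resolve a pipeline configuration
#'
#' Reads a YAML or JSON configuration file, rejects unknown keys (with a
#' nearest-match suggestion), checks that referenced files exist, and
#' applies the documented defaults: 1000 permutations, FDR threshold 0.1,
#' MCODE vwp 0.2, kappa threshold 0.3. All violations are reported in one
#' error message.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` config file.
#' @return a resolved `PipelineConfig` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  problems <- character(0L)
  problems <- c(problems, check_keys(names(raw), config_schema$top,
                                     "config"))
  for (sec in intersect(names(raw), setdiff(names(config_schema), "top"))) {
    if (is.list(raw[[sec]])) {
      problems <- c(problems,
                    check_keys(names(raw[[sec]]), config_schema[[sec]],
                               sprintf("section '%s'", sec)))
    }
  }
  if (is.null(raw$simulate) && is.null(raw$matrix)) {
    problems <- c(problems, "either 'matrix' or 'simulate' is required")
  }
  if (is.null(raw$seed_gene) && is.null(raw$simulate)) {
    problems <- c(problems, "missing required key 'seed_gene'")
  }
  for (f in c(raw$matrix, raw$metadata, raw$enrichment$gmt,
              raw$mcode$edges)) {
    if (!is.null(f) && !file.exists(f)) {
      problems <- c(problems, sprintf("referenced file not found: %s", f))
    }
  }
  if (length(problems)) {
    stop(paste(c("invalid configuration:",
                 paste0("  - ", problems)), collapse = "\n"),
         call. = FALSE)
  }
  cfg <- list(
    matrix = raw$matrix,
    metadata = raw$metadata,
    seed_gene = raw$seed_gene %||% "SEED",
    output_dir = raw$output_dir %||% "coexscreen_out",
    rng_seed = as.integer(raw$rng_seed %||% 1L),
    normalize = list(quantile = isTRUE(raw$normalize$quantile)),
    sample_subset = raw$sample_subset,
    screen = list(
      permutations = as.integer(raw$screen$permutations %||% 1000L),
      fdr = as.numeric(raw$screen$fdr %||% 0.1),
      center = raw$screen$center %||% TRUE,
      two_sided = raw$screen$two_sided %||% TRUE),
    contrast = raw$contrast,
    simmatrix = raw$simmatrix,
    enrichment = if (!is.null(raw$enrichment)) {
      list(gmt = raw$enrichment$gmt,
           kappa_threshold = as.numeric(raw$enrichment$kappa_threshold %||%
                                          0.3))
    },
    mcode = if (!is.null(raw$mcode)) {
      list(edges = raw$mcode$edges,
           vwp = as.numeric(raw$mcode$vwp %||% 0.2),
           haircut = raw$mcode$haircut %||% TRUE,
           fluff = isTRUE(raw$mcode$fluff),
           min_size = as.integer(raw$mcode$min_size %||% 3L))
    },
    dosetrend = raw$dosetrend,
    simulate = raw$simulate,
    stages = raw$stages
  )
  class(cfg) <- "PipelineConfig"
  cfg
}

# FNV-1a hash of the serialized config, for provenance headers. The
# output directory is excluded: the hash identifies the analysis, not
# where its results land.
config_hash <- function(cfg) {
  keep <- setdiff(names(cfg), "output_dir")
  s <- jsonlite::toJSON(unclass(cfg)[keep], auto_unbox = TRUE,
                        null = "null")
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619 %% 2^31
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stage_enabled <- function(cfg, stage, default = TRUE) {
  v <- cfg$stages[[stage]]
  if (is.null(v)) default else isTRUE(v)
}

provenance <- function(cfg) {
  c(sprintf("coexscreen %s",
            as.character(utils::packageVersion("coexscreen"))),
    sprintf("config_hash=%s", config_hash(cfg)),
    sprintf("rng_seed=%d", cfg$rng_seed))
}

write_result_tsv <- function(df, path, cfg) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("# ", provenance(cfg)), con, useBytes = TRUE)
  writeLines(paste(names(df), collapse = "\t"), con, useBytes = TRUE)
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col)) {
        format(col, trim = TRUE, digits = 15L, scientific = FALSE)
      } else as.character(col)
    }), sep = "\t"))
    writeLines(body, con, useBytes = TRUE)
  }
  invisible(path)
}

log_msg <- function(level, fmt, ...) {
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in fixed dependency order — simulate/load,
#' normalize, group contrast, seed screen, similarity clustering,
#' enrichment with term clustering, MCODE, dose trend — writing one TSV
#' per stage (with provenance header comments) plus a JSON report to the
#' output directory. Optional stages whose inputs are missing (no GMT, no
#' edge list, no dose column) are skipped with a warning and noted in the
#' report; identical config and seed give byte-identical outputs.
#'
#' @param cfg a `PipelineConfig` from [validate_config()], or a path to a
#'   config file.
#' @return the `PipelineReport` list, invisibly (also written as
#'   `report.json`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- validate_config(cfg)
  t_start <- proc.time()[["elapsed"]]
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(version = as.character(utils::packageVersion("coexscreen")),
                 rng_seed = cfg$rng_seed,
                 config_hash = config_hash(cfg),
                 stages = list())
  timing <- function(t0) round(proc.time()[["elapsed"]] - t0, 3L)

  # --- load or simulate -------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  md <- NULL
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    ds <- generate_seed_screen_dataset(
      n_null = sim$n_null %||% 1000L, n_pos = sim$n_pos %||% 50L,
      n_neg = sim$n_neg %||% 50L, n_samples = sim$n_samples %||% 24L,
      planted_r = sim$planted_r %||% 0.8,
      noise_sd = sim$noise_sd %||% 1,
      rng_seed = derive_seed(cfg$rng_seed, 11L),
      seed_gene_id = cfg$seed_gene)
    x <- ds$matrix
    truth <- ds$truth
    write_expression_tsv(x, file.path(cfg$output_dir, "simulated_matrix.tsv"),
                         header_comment = provenance(cfg))
    # two balanced groups x cycled cell subsets, so the contrast stage can
    # run on simulated data (a null contrast unless effects are planted)
    n <- ncol(x)
    md <- data.frame(
      sample_id = colnames(x),
      group = rep(c("groupA", "groupB"), each = ceiling(n / 2))[seq_len(n)],
      subset = rep_len(c("naive", "memory", "plasmablast"), n),
      replicate = seq_len(n),
      stringsAsFactors = FALSE)
    con <- file(file.path(cfg$output_dir, "simulated_metadata.tsv"),
                open = "wb")
    writeLines(paste0("# ", provenance(cfg)), con, useBytes = TRUE)
    utils::write.table(md, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  } else {
    x <- read_expression_tsv(cfg$matrix)
  }
  if (!is.null(cfg$metadata)) md <- read_metadata_tsv(cfg$metadata)
  if (!is.null(cfg$sample_subset) && !is.null(md)) {
    keep <- md$sample_id[md[[cfg$sample_subset$column]] ==
                           cfg$sample_subset$value]
    x <- subset_expression(x, samples = intersect(colnames(x), keep))
    log_msg("INFO", "sample subset %s=%s: %d samples retained",
            cfg$sample_subset$column, cfg$sample_subset$value, ncol(x))
  }
  report$stages$load <- list(n_genes = nrow(x), n_samples = ncol(x),
                             simulated = !is.null(cfg$simulate),
                             seconds = timing(t0))

  # --- normalize --------------------------------------------------------
  if (stage_enabled(cfg, "normalize") && isTRUE(cfg$normalize$quantile)) {
    t0 <- proc.time()[["elapsed"]]
    x <- quantile_normalize(x)
    report$stages$normalize <- list(method = "quantile",
                                    seconds = timing(t0))
  }

  # --- group contrast ---------------------------------------------------
  if (stage_enabled(cfg, "contrast") && !is.null(cfg$contrast) &&
      !is.null(md)) {
    t0 <- proc.time()[["elapsed"]]
    ct <- welch_contrast(x, md, cfg$contrast$groups)
    write_result_tsv(as.data.frame(ct),
                     file.path(cfg$output_dir, "contrast.tsv"), cfg)
    report$stages$contrast <- list(
      groups = cfg$contrast$groups,
      n_significant_q05 = sum(ct$q < 0.05),
      seconds = timing(t0))
  }

  # --- seed screen ------------------------------------------------------
  screen_res <- NULL
  if (stage_enabled(cfg, "screen")) {
    t0 <- proc.time()[["elapsed"]]
    sc <- screen_config(cfg$seed_gene,
                        n_permutations = cfg$screen$permutations,
                        fdr_threshold = cfg$screen$fdr,
                        center_genes = cfg$screen$center,
                        two_sided = cfg$screen$two_sided,
                        rng_seed = derive_seed(cfg$rng_seed, 23L))
    screen_res <- run_seed_screen(x, sc)
    write_result_tsv(as.data.frame(screen_res),
                     file.path(cfg$output_dir, "screen.tsv"), cfg)
    report$stages$screen <- list(
      seed_gene = cfg$seed_gene,
      n_positive = attr(screen_res, "n_positive"),
      n_negative = attr(screen_res, "n_negative"),
      fdr_threshold = cfg$screen$fdr,
      seconds = timing(t0))
  }

  # --- similarity clustering -------------------------------------------
  if (stage_enabled(cfg, "simmatrix") && !is.null(cfg$simmatrix)) {
    t0 <- proc.time()[["elapsed"]]
    genes <- intersect(unlist(cfg$simmatrix$genes), rownames(x))
    if (length(genes) >= 2L) {
      sm <- similarity_matrix(x, genes)
      k <- min(as.integer(cfg$simmatrix$k %||% 2L), length(genes))
      tree <- hierarchical_clusters(sm, k,
                                    linkage = cfg$simmatrix$linkage %||%
                                      "average")
      smd <- as.data.frame(as.table(unclass(sm)),
                           stringsAsFactors = FALSE)
      names(smd) <- c("gene_a", "gene_b", "rho")
      write_result_tsv(smd, file.path(cfg$output_dir, "simmatrix.tsv"),
                       cfg)
      write_result_tsv(
        data.frame(gene_id = names(tree$labels),
                   cluster = unname(tree$labels),
                   stringsAsFactors = FALSE),
        file.path(cfg$output_dir, "clusters.tsv"), cfg)
      report$stages$simmatrix <- list(n_genes = length(genes), k = k,
                                      seconds = timing(t0))
    } else {
      log_msg("WARN", "simmatrix skipped: fewer than 2 requested genes present")
      report$stages$simmatrix <- list(skipped = "fewer than 2 genes present")
    }
  }

  # --- enrichment -------------------------------------------------------
  if (stage_enabled(cfg, "enrichment") && !is.null(screen_res)) {
    t0 <- proc.time()[["elapsed"]]
    catalog <- if (!is.null(cfg$enrichment$gmt)) {
      read_gmt(cfg$enrichment$gmt)
    } else if (!is.null(truth) && length(truth$neg_module) >= 5L) {
      generate_catalog_with_planted_enrichment(
        truth, background = rownames(x),
        planted_term_overlap = min(15L, length(truth$neg_module)),
        rng_seed = derive_seed(cfg$rng_seed, 31L))
    }
    if (is.null(catalog)) {
      log_msg("WARN", "enrichment skipped: no gene-set catalog supplied")
      report$stages$enrichment <- list(skipped = "no catalog")
    } else {
      background <- rownames(x)
      for (dir in c("negative", "positive")) {
        query <- screen_correlates(screen_res, dir)
        if (!length(query)) next
        er <- enrich_gene_sets(query, catalog, background)
        write_result_tsv(as.data.frame(er),
                         file.path(cfg$output_dir,
                                   sprintf("enrichment_%s.tsv", dir)),
                         cfg)
        clusters <- if (nrow(er)) {
          cluster_terms(er, catalog, background,
                        cfg$enrichment$kappa_threshold %||% 0.3)
        } else list()
        jsonlite::write_json(
          lapply(clusters, function(cl) {
            list(representative = cl$representative,
                 members = cl$members, p = cl$p)
          }),
          file.path(cfg$output_dir,
                    sprintf("term_clusters_%s.json", dir)),
          auto_unbox = TRUE, digits = NA, pretty = TRUE)
        report$stages$enrichment[[dir]] <-
          list(n_terms = nrow(er), n_clusters = length(clusters),
               top_term = if (nrow(er)) er$term_id[1L] else NA)
      }
      report$stages$enrichment$seconds <- timing(t0)
    }
  }

  # --- MCODE ------------------------------------------------------------
  if (stage_enabled(cfg, "mcode") && !is.null(cfg$mcode)) {
    t0 <- proc.time()[["elapsed"]]
    if (is.null(cfg$mcode$edges)) {
      log_msg("WARN", "mcode skipped: no edge list supplied")
      report$stages$mcode <- list(skipped = "no edge list")
    } else {
      g <- read_edge_list(cfg$mcode$edges)
      params <- mcode_params(vwp = cfg$mcode$vwp,
                             haircut = cfg$mcode$haircut,
                             fluff = cfg$mcode$fluff,
                             min_complex_size = cfg$mcode$min_size)
      cx <- predict_complexes(g, params)
      memb <- if (length(cx)) {
        do.call(rbind, lapply(cx, function(c) {
          data.frame(complex_rank = c$rank, gene_id = c$nodes,
                     score = c$score, seed = c$seed,
                     stringsAsFactors = FALSE)
        }))
      } else {
        data.frame(complex_rank = integer(0), gene_id = character(0),
                   score = numeric(0), seed = character(0))
      }
      write_result_tsv(memb, file.path(cfg$output_dir, "mcode.tsv"), cfg)
      jsonlite::write_json(
        lapply(cx, function(c) {
          list(rank = c$rank, seed = c$seed, score = c$score,
               size = length(c$nodes))
        }),
        file.path(cfg$output_dir, "mcode.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      report$stages$mcode <- list(n_complexes = length(cx),
                                  top_score = if (length(cx)) {
                                    cx[[1L]]$score
                                  } else NA,
                                  seconds = timing(t0))
    }
  }

  # --- dose trend -------------------------------------------------------
  if (stage_enabled(cfg, "dosetrend") && !is.null(cfg$dosetrend)) {
    t0 <- proc.time()[["elapsed"]]
    if (is.null(md) || is.null(md$dose)) {
      log_msg("WARN", "dosetrend skipped: no dose column in metadata")
      report$stages$dosetrend <- list(skipped = "no dose metadata")
    } else {
      dt <- dose_trend(x, md,
                       n_permutations = as.integer(
                         cfg$dosetrend$permutations %||% 1000L),
                       rng_seed = derive_seed(cfg$rng_seed, 41L),
                       alpha = as.numeric(cfg$dosetrend$alpha %||% 0.05))
      write_result_tsv(as.data.frame(dt),
                       file.path(cfg$output_dir, "dosetrend.tsv"), cfg)
      report$stages$dosetrend <- list(
        n_down = sum(dt$direction == "down"),
        n_up = sum(dt$direction == "up"),
        seconds = timing(t0))
    }
  }

  report$total_seconds <- round(proc.time()[["elapsed"]] - t_start, 3L)
  jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
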