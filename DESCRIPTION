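Package: coexscreen
Title: Seed-Gene Co-Expression Screening with Permutation FDR, Enrichment
    and Dense-Module Detection
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A config-driven pipeline for screening all genes of an
    expression matrix against a single seed gene by centered cosine
    similarity with a permutation null and Benjamini-Hochberg false
    discovery rate control; Spearman similarity matrices and hierarchical
    clustering over gene panels; hypergeometric gene-set
    over-representation with kappa-based clustering of redundant terms;
    MCODE-style dense-complex detection on gene networks; Welch two-group
    contrasts and monotone dose-response trend tests; and a synthetic-data
    generator that plants correlated modules, group effects, dose slopes,
    enriched terms and dense cliques with a recorded ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
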