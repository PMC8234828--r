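---
title: "Methods: seed-gene co-expression screening and downstream analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-gene co-expression screening and downstream analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexscreen)
```

## The problem

A recurring question in transcriptomics is: given one gene of interest —
a *seed* gene, for instance a tetraspanin-family membrane protein whose
expression collapses in autoimmune B cells — which other genes move with
it, which move against it, and what biology do those co-moving sets
encode? `coexscreen` implements that workflow end to end on log2
expression matrices: a similarity screen with a permutation null,
multiple-testing control, correlation-structure inspection of a gene
panel, gene-set over-representation with redundancy collapsing, dense
network-module detection, and supporting two-group and dose–response
stages. A synthetic-data module plants every kind of structure the
pipeline is supposed to find, so the whole chain is testable against
recorded ground truth without any external download.

## The screen statistic

For sample vectors $x, y \in \mathbb{R}^n$ the screen uses the cosine
similarity of the *mean-centered* vectors,

$$T(x, y) \;=\; \frac{\langle x - \bar x,\; y - \bar y\rangle}
{\lVert x - \bar x\rVert\,\lVert y - \bar y\rVert},$$

which is exactly the Pearson correlation of $x$ and $y$. Centering is
the default for a structural reason: log2 intensities are non-negative,
so the *un*-centered cosine of two expression profiles is always
$\ge 0$ and no gene could ever be "negatively correlated" to the seed.
Since the screen is explicitly meant to separate positive from negative
correlates, the centered statistic is the only consistent reading. The
literal un-centered cosine remains available via
`screen_config(center_genes = FALSE)` for users who want it. A
zero-variance gene has no direction; its similarity is 0 by convention
and its p-value 1.

## The permutation null

Significance comes from re-ordering the seed gene's samples: for each
of $B$ iterations (default $B = 1000$) one random permutation is
applied to the seed profile and $T$ is recomputed against **all** genes
at once. Sharing one permutation per iteration preserves the inter-gene
correlation structure of the matrix and costs a single matrix product
per screen. The two-sided p-value uses the add-one rule

$$p_g = \frac{1 + \#\{b : |T_{b,g}| \ge |T_{\mathrm{obs},g}|\}}{1 + B},$$

so $p \ge 1/(B+1)$ and $p = 0$ is impossible. Permutations are sampled
with replacement from the $n!$ orderings; when $n! \le 5000$ (i.e.
$n \le 7$ samples) the implementation automatically switches to exact
enumeration of all orderings, where $p_g = \#\{\pi\}/n!$ with the
identity included. Exact relabelling symmetry (invariance of $p$ under
a common re-ordering of all samples) holds in exhaustive mode;
Monte-Carlo mode obeys it up to binomial sampling noise, and both facts
are tested as such.

Benjamini–Hochberg step-up adjustment is applied across genes, and
genes with $q$ below the FDR threshold (default 0.1, the conventional
choice for this kind of exploratory correlate screen) are labelled
`positive` or `negative` by the sign of $T$. The seed gene is excluded
from its own table. Output order is $q$, then $|T|$ descending, then
gene id — fully deterministic.

### Which samples enter the screen

Published seed screens often leave unstated whether the correlation was
computed within one cell population or across a pooled case–control
design, and the two choices answer different questions. The package
takes no position: the screen runs on whatever matrix it is handed, and
the pipeline exposes a `sample_subset` filter (`column` + `value`
against the metadata) so the choice is explicit in the config.

## Correlation structure of a gene panel

`similarity_matrix()` computes pairwise Spearman rank correlation
(average ranks for ties) over samples and `hierarchical_clusters()`
performs agglomerative clustering on the dissimilarity $d = 1 - \rho$
with average linkage (UPGMA). Two open choices were fixed as follows:

* **Linkage**: average, the common default for correlation-based
  expression clustering and deterministic; configurable.
* **Distance transform**: $1 - \rho$, *not* $1 - |\rho|$ — a signed
  similarity display should keep anti-correlated genes maximally
  distant rather than merging them.

Genes are sorted lexicographically before the merge so exact-tie
resolution does not depend on input order. Zero-variance genes get
$\rho = 0$ against everything (with a warning) instead of `NaN`.

## Over-representation and term redundancy

For a query list of $n$ genes from a background of $N$, a term with $K$
background members and $k$ query members is scored with the upper
hypergeometric tail $P(X \ge k)$ (via `phyper`, log-space internally),
one-sided because only over-representation is asked. Terms are
intersected with the background first; zero-overlap terms are dropped;
BH runs across the tested terms. The background defaults to the genes
present on the analyzed matrix — the standard choice for array-style
data, where the measured universe, not the genome, is what the query
was drawn from.

Ontology catalogs are heavily redundant, so enriched terms are merged
by Cohen's kappa of their membership indicators over the background:
seed with the most significant unclustered term, absorb every term with
$\kappa \ge$ threshold (default 0.3, the usual redundancy-filter
convention), repeat. Representatives therefore appear in order of
increasing p. Kappa of identical sets is 1, of complementary sets
covering the background $-1$, and near 0 for unrelated sets in a large
background.

## Dense-module detection (MCODE)

The network stage re-implements the Molecular Complex Detection
algorithm. Stage 1 weighs each vertex by the density of the densest
k-core of its closed neighborhood: $w(v) = k_{\max} \cdot
\mathrm{density}(\text{highest k-core of } G_v)$. Stage 2 grows
complexes from the highest-weight unassigned seed, admitting neighbors
with $w \ge w_{\mathrm{seed}}(1 - \mathrm{vwp})$, each node visited
once per expansion; nodes that *join* a complex are excluded from later
complexes, while nodes merely rejected stay eligible as later seeds.
Post-processing: haircut (iteratively strip members of within-complex
degree $\le 1$; on by default) and optional fluff. Complexes below the
minimum size (3) are dropped and the rest ranked by score = density
$\times$ size, ties by size then seed id. Parameter defaults (vwp 0.2,
haircut on, fluff off) follow the algorithm's original publication,
since sources that merely *name* MCODE rarely state them.

## Group contrasts and dose trends

The two-group stage is a deliberately plain per-gene Welch t-test on
log2 values with BH adjustment — a documented stand-in for moderated
linear models, not a re-implementation of them. With cohorts of four
donors per group, empirical-Bayes variance moderation would genuinely
help on real data; the stand-in keeps the pipeline self-contained and
its null behavior testable (type-I error at $\alpha = 0.05$ is checked
to be nominal). Degenerate zero-variance genes get $t = 0$, $p = 1$,
and a flag.

The dose–response stage tests monotone trend as the Spearman
correlation of expression with $\log_{10}(\mathrm{dose})$, with
significance from permuting the sample-to-dose assignment (add-one,
two-sided, $B = 1000$, exact enumeration for small designs).
Rank-based, so any monotone re-labelling of the doses gives identical
results. Jonckheere–Terpstra would be the classical alternative; the
Spearman-vs-log-dose permutation test was chosen because it yields a
signed effect size ($\rho$) in the same family as the screen statistic.
**Tie behavior worth knowing:** with replicates, dose ranks are tied,
and the average-rank $\rho$ of a perfectly monotone gene tops out below
1 in magnitude — for 5 doses $\times$ 3 replicates at
$\max|\rho| = 0.982$. The tests assert that exact tie-adjusted limit;
$|\rho| = 1$ is attainable only in replicate-free designs (or on the
per-dose means).

## The synthetic world

The generator module states one fixed world per design and the tests
never tune it:

* **Seed screen**: latent factor $z \sim \mathcal{N}(0, I_n)$ as the
  seed profile; planted gene $= r z + \sqrt{1 - r^2}\,\varepsilon$
  (population correlation exactly $r$); negative module uses $-z$;
  nulls independent. Baseline 8.0 log2 units and scale 1.0 — typical
  microarray log-intensity ranges, so normalization and centering
  operate on realistic numbers.
* **Contrast**: two groups (default 4 vs 4 donors, the small-cohort
  case-control design) across three cycled cell-subset labels; affected
  genes shifted by a stated log2 effect in group 2.
* **Titration**: five ten-fold doses spanning 0.1–1000 U/mL, 2–3
  replicates; responsive-gene mean $= \mathrm{baseline} +
  \mathrm{slope}\cdot\log_{10}(\mathrm{dose})$, default slope $-0.5$
  log2 per decade with residual SD 0.3 — a strong but not trivial
  signal for an $n = 15$ design.
* **Catalog**: one term drawn from the planted negative module plus an
  exact duplicate of it (to exercise $\kappa = 1$ merging) among random
  background terms.
* **Network**: planted cliques wired to a sparse Erdős–Rényi background
  ($p = 0.05$) by explicit bridge edges.

What the generator does **not** emulate: probe-level effects, batch
effects, count-based RNA-seq noise, or dependence among null genes. A
green recovery test therefore establishes that the algorithms do what
they claim on data matching their assumptions — it does not certify
performance on any particular real dataset.

## Numerical and determinism choices

* All randomness flows from explicit integer seeds; generators use one
  local RNG scope each (Mersenne-Twister, never the global state), and
  the pipeline derives per-stage seeds from the single top-level
  `rng_seed` by fixed offsets.
* Quantile normalization implements the mean-of-spanned-values tie rule
  directly (ties receive the mean of the target values their ranks
  span); this makes the map idempotent and rank-preserving and differs
  from interpolation-based implementations only on ties spanning more
  than two ranks.
* Exceedance counts in permutation tests use a $10^{-12}$ guard so that
  floating-point noise at $|T| = 1$ cannot drop exact ties.
* Ties in every ranking (screen output, complex ranking, term order)
  break lexicographically, so reruns are byte-identical; the pipeline
  test verifies this end to end.
* TSV numerics are written with 15 significant digits, enough for exact
  round-trips of the values the package produces.

## Known limitations

* The Welch stand-in is underpowered relative to moderated statistics
  at very small $n$; it is calibrated, not optimal.
* Missing values are a hard error by design; impute or filter upstream.
* The permutation screen's Monte-Carlo p-values have granularity
  $1/(B+1)$; with $B = 1000$, q-values near a 0.1 threshold can move
  between reruns with different permutation seeds. Raise
  `n_permutations` when ranking near the threshold matters.
* MCODE numbering of complexes is this package's deterministic ranking;
  it will not match the numbering of other tools.
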