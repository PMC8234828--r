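#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment. A thin, input-validated wrapper
#' around [stats::p.adjust()] with `method = "BH"`: the adjusted value is
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)` over the sorted p-values, so
#' the adjustment is order-preserving (`p_i <= p_j` implies `q_i <= q_j`).
#'
#' @param p numeric vector of p-values, all in (0, 1].
#' @return numeric vector of adjusted values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p) {
  if (!is.numeric(p) || length(p) == 0L) {
    stop("`p` must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("all p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# Deterministic RNG scope: runs `expr` under a local RNG seeded with `seed`
# (Mersenne-Twister / Inversion / Rejection), restoring global state after.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`rng_seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Derive a per-stage seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 2000000000L) + as.integer(offset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
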