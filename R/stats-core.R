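#' 1-Wasserstein distance between two empirical distributions
#'
#' Computes the first Wasserstein (earth-mover) distance between the
#' empirical distributions of two samples, each point carrying equal mass
#' within its sample. For distributions on the line this equals the
#' integral over the real line of `|F_A(x) - F_B(x)|`, where `F_A`, `F_B`
#' are the empirical CDFs; sample sizes need not match. Units are the
#' units of the input values (nucleotides throughout this package).
#'
#' @param a,b Numeric vectors of observations (non-empty, finite). Order
#'   is irrelevant.
#' @return A non-negative scalar; zero iff the two empirical distributions
#'   are identical as distributions.
#' @examples
#' wasserstein_1d(5, 12)            # point masses: |5 - 12| = 7
#' wasserstein_1d(c(0, 4), c(1, 3)) # 1
#' @export
wasserstein_1d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L)
    stop("wasserstein_1d: both samples must be non-empty")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("wasserstein_1d: all values must be finite")
  wasserstein1d_cpp(a, b)
}

#' Permutation test for a distributional difference between two samples
#'
#' Tests whether two samples come from the same distribution using the
#' 1-Wasserstein distance as the statistic. The pooled values are randomly
#' re-partitioned without replacement into groups of the original sizes
#' `n_perm` times; the p-value uses the add-one estimator
#' `p = (1 + #\{permuted >= observed\}) / (n_perm + 1)`, so the smallest
#' attainable p is `1/(n_perm + 1)` and ties between permuted and observed
#' distances count as exceedances (conservative). Fully reproducible given
#' `seed`.
#'
#' @param a,b Numeric vectors (non-empty, finite).
#' @param n_perm Number of permutations; default 999.
#' @param seed Integer seed; required so every call is reproducible. The
#'   RNG state of the session is restored on exit.
#' @return A list of class `"permutation_result"` with elements
#'   `observed_distance`, `p_value`, `n_perm`, `seed`, and
#'   `max_perm_distance` (largest distance seen across permutations, kept
#'   for diagnostics).
#' @examples
#' permutation_test(c(1, 2, 3), c(1, 2, 3), n_perm = 99, seed = 1)$p_value # 1
#' @export
permutation_test <- function(a, b, n_perm = 999L, seed) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L)
    stop("permutation_test: both samples must be non-empty")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("permutation_test: all values must be finite")
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L)
    stop("permutation_test: n_perm must be a positive integer")
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("permutation_test: an integer seed is required")
  seed <- as.integer(seed)

  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(seed)
  res <- perm_test_cpp(a, b, n_perm)

  structure(
    list(
      observed_distance = res$observed,
      p_value = (1 + res$n_exceed) / (n_perm + 1),
      n_perm = n_perm,
      seed = seed,
      max_perm_distance = res$max_perm
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Wasserstein permutation test: D = %.4g, p = %.4g (%d permutations, seed %d)\n",
    x$observed_distance, x$p_value, x$n_perm, x$seed
  ))
  invisible(x)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Deterministic per-gene sub-seed
#'
#' Derives a reproducible seed for one gene from the master seed and the
#' gene identifier, so per-gene permutation results do not depend on the
#' order in which genes are scanned. Uses a 31-ary polynomial hash of the
#' identifier modulo 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param gene_id Gene identifier (string).
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
gene_seed <- function(seed, gene_id) {
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(as.character(gene_id))) {
    h <- (h * 31 + code) %% m
  }
  as.integer((as.numeric(seed) %% m + h) %% m)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment across a family of tests.
#' Thin validating wrapper around [stats::p.adjust()] with `method = "BH"`;
#' inputs must be valid p-values in `(0, 1]` (permutation p-values from this
#' package are never 0 by construction).
#'
#' @param p Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values, same length and order as `p`; each adjusted
#'   value is `>=` its raw value.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("bh_fdr: p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fisher exact test for a 2x2 contingency table
#'
#' Two-sided Fisher exact test (hypergeometric: sums the probabilities of
#' all tables with the observed margins that are at most as probable as the
#' observed table), reported together with the sample odds ratio
#' `(a*d)/(b*c)`. With the convention used throughout this package, rows are
#' in-category / not-in-category and columns are m6A-modified / not.
#'
#' @param tab A 2x2 matrix of non-negative counts, or the four counts
#'   `c(a, b, c, d)` in row-major order.
#' @return A list with `odds_ratio` (sample OR; `Inf` when `b*c == 0` and
#'   `a*d > 0`, `NaN` for 0/0), `p_value`, and `table`.
#' @examples
#' fisher_2x2(matrix(c(10, 10, 10, 10), 2, byrow = TRUE)) # OR 1, p 1
#' @export
fisher_2x2 <- function(tab) {
  if (is.matrix(tab)) {
    if (!all(dim(tab) == c(2L, 2L))) stop("fisher_2x2: table must be 2x2")
    m <- tab
  } else {
    tab <- as.numeric(tab)
    if (length(tab) != 4L) stop("fisher_2x2: supply a 2x2 matrix or 4 counts")
    m <- matrix(tab, nrow = 2, byrow = TRUE)
  }
  if (anyNA(m) || any(m < 0) || any(m != round(m)))
    stop("fisher_2x2: cells must be non-negative integers")
  if (sum(m) == 0) stop("fisher_2x2: table total must be positive")
  storage.mode(m) <- "double"

  num <- m[1, 1] * m[2, 2]
  den <- m[1, 2] * m[2, 1]
  or <- if (den == 0 && num == 0) NaN else if (den == 0) Inf else num / den
  p <- stats::fisher.test(m)$p.value
  list(odds_ratio = or, p_value = p, table = m)
}
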