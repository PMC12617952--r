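# Independent oracles used to cross-check the implementation. Each takes a
# route through the problem different from the package's CDF-walk /
# p.adjust / fisher.test code paths.

# 1-Wasserstein via the quantile-function representation:
# W1 = integral_0^1 |Q_A(u) - Q_B(u)| du, evaluated exactly by splitting
# [0, 1] at every i/n_A and j/n_B breakpoint (the quantile functions are
# constant inside each piece).
oracle_w1_quantile <- function(a, b) {
  a <- sort(a); b <- sort(b)
  na <- length(a); nb <- length(b)
  u <- sort(unique(c(seq_len(na) / na, seq_len(nb) / nb)))
  lo <- c(0, u[-length(u)])
  mid <- (lo + u) / 2
  qa <- a[ceiling(mid * na)]
  qb <- b[ceiling(mid * nb)]
  sum((u - lo) * abs(qa - qb))
}

# Brute-force Benjamini-Hochberg step-up from its definition:
# adjusted_(i) = min_{k >= i} min(1, m * p_(k) / k) in sorted order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, m * ps / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-sided Fisher exact p by exhaustive enumeration of all 2x2 tables
# with the observed margins, summing hypergeometric probabilities of
# tables at most as probable as the observed one (with the customary
# 1 + 1e-7 relative tolerance for "at most as probable").
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c_          # column-1 margin
  n <- b + d           # column-2 margin
  k <- a + b           # row-1 margin
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# LP transport oracle: shells out to scipy.optimize.linprog via the
# bundled python script. `instances` is a list of list(a =, b =).
oracle_lp_transport <- function(instances) {
  script <- system.file("oracle", "lp_transport.py", package = "polyAdiff")
  stopifnot(nzchar(script))
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile), add = TRUE)
  jsonlite::write_json(
    lapply(instances, function(x) list(a = x$a, b = x$b)),
    infile, digits = NA)
  out <- system2("python", c(script, infile), stdout = TRUE)
  as.numeric(jsonlite::fromJSON(paste(out, collapse = "")))
}
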