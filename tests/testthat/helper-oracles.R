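# Independent brute-force oracles used to check the package implementations.
# These are written from definitions, not by calling the code under test.

# literal position-by-position running-sum ssGSEA score for one sample
ssgsea_oracle <- function(x, sig, alpha = 0.25) {
  G <- length(x)
  ord <- order(-x, names(x))
  rnk <- rank(x, ties.method = "average")
  w <- rnk^alpha
  inset <- names(x) %in% sig
  win <- sum(w[inset])
  K <- sum(inset)
  p_in <- 0; p_out <- 0; es <- 0
  for (pos in seq_len(G)) {
    g <- ord[pos]
    if (inset[g]) p_in <- p_in + w[g] / win else p_out <- p_out + 1 / (G - K)
    es <- es + (p_in - p_out)
  }
  as.numeric(es)
}

# spreadsheet-style O/E/V tabulation of the two-group log-rank statistic
logrank_oracle_2g <- function(time, event, grp) {
  lv <- sort(unique(grp))
  stopifnot(length(lv) == 2)
  ut <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    atr <- time >= t
    n <- sum(atr); n1 <- sum(atr & grp == lv[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == lv[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n - d) / (n - 1) * (n1 / n) * (1 - n1 / n)
  }
  (O - E)^2 / V
}

# Fisher exact p by full enumeration over all tables with the observed
# margins (two-sided: probability ordering with the customary relative
# tolerance)
fisher_enum_oracle <- function(a, b, c, d, alternative = "two.sided") {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (n == 0) return(1)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(xs, r1, n - r1, c1)
  pobs <- stats::dhyper(a, r1, n - r1, c1)
  p <- switch(alternative,
              two.sided = sum(probs[probs <= pobs * (1 + 1e-7)]),
              greater = sum(probs[xs >= a]),
              less = sum(probs[xs <= a]))
  min(p, 1)
}

# upper-tail hypergeometric ORA p by direct summation
ora_enum_oracle <- function(k, set_size, universe_size, query_size) {
  xs <- k:min(set_size, query_size)
  sum(stats::dhyper(xs, set_size, universe_size - set_size, query_size))
}

# hand step-up BH
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n); out[o] <- q
  out
}

# small random labelled expression matrix
random_expr <- function(n_genes, n_samples, seed, space = "log_normalized") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  if (space == "raw_counts") m <- matrix(rpois(n_genes * n_samples, 20),
                                         n_genes, n_samples,
                                         dimnames = dimnames(m)) * 1.0
  expression_matrix(m, space)
}
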