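# Brute-force statistical oracles, independent of the package implementation.

# Probability of a 2x2 table [a, r1-a; c1-a, ...] under the hypergeometric
# null with fixed margins, via explicit binomial coefficients.
table_prob <- function(a, r1, r2, c1) {
  choose(r1, a) * choose(r2, c1 - a) / choose(r1 + r2, c1)
}

# Fisher exact p by full enumeration of tables with the observed margins.
oracle_fisher_p <- function(a, b, c, d,
                            alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, table_prob, numeric(1), r1 = r1, r2 = r2, c1 = c1)
  obs <- table_prob(a, r1, r2, c1)
  switch(alternative,
         two_sided = sum(probs[probs <= obs * (1 + 1e-7)]),
         greater = sum(probs[support >= a]),
         less = sum(probs[support <= a]))
}

# Benjamini-Hochberg step-up by hand.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Closed-form tail probability of a product of k independent uniforms:
# P(prod U_i <= q) = q * sum_{j=0}^{k-1} (-log q)^j / j!  -- the null
# distribution of Fisher's combination statistic.
oracle_uniform_product_tail <- function(p_values) {
  q <- prod(p_values)
  k <- length(p_values)
  q * sum(vapply(0:(k - 1), function(j) (-log(q))^j / factorial(j),
                 numeric(1)))
}

# Exact two-sided signed-rank p by exhaustive sign-flip enumeration
# (distinct non-zero |d| assumed; n <= ~14).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# All (possibly overlapping) occurrences of a pattern by position-wise scan.
oracle_substring_positions <- function(pat, s) {
  L <- nchar(pat)
  hits <- integer(0)
  for (i in seq_len(nchar(s) - L + 1)) {
    if (substr(s, i, i + L - 1) == pat) hits <- c(hits, i)
  }
  hits
}

# Largest single-repeat intersection of an exon with a repeat set.
oracle_best_overlap <- function(exon, repeats) {
  if (nrow(repeats) == 0) return(0L)
  ov <- pmax(0L, pmin(exon[2], repeats$end) - pmax(exon[1], repeats$start))
  max(ov)
}
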