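# Independent brute-force oracles used to validate the exact tests. These
# enumerate the relevant discrete null distributions directly and are kept
# deliberately separate from the package implementations.

# Two-sided binomial p by direct enumeration of Binomial(n, p0):
# sum of P(X = j) over all j whose probability does not exceed P(X = k),
# with the same relative tolerance stats::binom.test applies to ties.
oracle_binom_two_sided <- function(k, n, p0) {
  pr <- dbinom(0:n, n, p0)
  min(1, sum(pr[pr <= pr[k + 1] * (1 + 1e-7)]))
}

# Two-sided Fisher p for a 2x2 table by full enumeration over margin-fixed
# tables (hypergeometric probabilities).
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + c          # first-column total
  nn <- b + d         # second-column total
  r1 <- a + b         # first-row total
  lo <- max(0, r1 - nn)
  hi <- min(r1, m)
  pr <- dhyper(lo:hi, m, nn, r1)
  obs <- dhyper(a, m, nn, r1)
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Conditional two-group Poisson-limit oracle: given group totals (a, b) from
# nA and nB equal-size libraries, A | A+B = s is Binomial(s, nA/(nA+nB)).
oracle_poisson_exact <- function(a, b, nA, nB) {
  oracle_binom_two_sided(a, a + b, nA / (nA + nB))
}

# Exact two-sided rank-sum p by exhaustive enumeration of all assignments of
# the pooled values to the two groups (ties allowed): doubled smaller tail
# of the rank-sum statistic, capped at 1.
oracle_ranksum_two_sided <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(m)])
  all_w <- combn(n, m, function(idx) sum(r[idx]))
  p <- 2 * min(mean(all_w <= obs), mean(all_w >= obs))
  min(1, p)
}
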