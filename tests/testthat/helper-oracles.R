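# Independent oracles: brute-force implementations used only to check the
# package's statistics, never sharing code with them.

# two-sided rank-sum p by exhaustive enumeration of all group assignments
enum_ranksum_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  r <- rank(pool)
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pool), n1)
  ws <- apply(combs, 2, function(ix) sum(r[ix]))
  min(1, 2 * min(sum(ws <= obs), sum(ws >= obs)) / ncol(combs))
}

# step-up BH by direct definition: adj for the i-th smallest p is
# min over j >= i of m * p_(j) / j, capped at 1
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- vapply(seq_len(m), function(i) min(1, min(m * sorted[i:m] / (i:m))),
                numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# upper hypergeometric tail P(X >= k) by direct summation of choose() terms
brute_hyper_tail <- function(k, K, N, n) {
  i <- seq(from = k, to = min(K, n))
  if (k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
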