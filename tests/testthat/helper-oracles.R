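# Brute-force definitional oracles, independent of the package's code paths.

holm_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE else break
  }
  reject
}

bh_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i * alpha / m) k <- i
  reject <- logical(m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  reject
}

# exhaustive two-sided permutation p-value for the rank-sum U statistic
mw_permutation_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu))
}
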