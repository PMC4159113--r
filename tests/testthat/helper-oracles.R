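# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive computation kept separate from the
# package's implementation path.

# build a small ExpressionMatrix from a plain matrix (auto ids if missing)
toy_expr <- function(values, metadata = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  expression_matrix(values, metadata)
}

# hypergeometric upper tail as a plain ratio of binomial coefficients
hyper_tail_choose <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# hypergeometric upper tail by enumerating every n-subset of the universe
# (only feasible for tiny N)
hyper_tail_enum <- function(k, K, n, N) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# midranks from first principles (count-below plus half the tie block)
midrank_oracle <- function(x)
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))

# textbook Pearson correlation
pearson_oracle <- function(a, b) {
  da <- a - mean(a); db <- b - mean(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# log-rank O, E, V accumulated time-by-time from first principles
logrank_oracle <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  o <- e <- v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    r <- sum(at_risk); r_a <- sum(at_risk & grp_a)
    d <- sum(event & time == t)
    d_a <- sum(event & time == t & grp_a)
    o <- o + d_a
    e <- e + d * r_a / r
    if (r > 1)
      v <- v + d * (r_a / r) * (1 - r_a / r) * (r - d) / (r - 1)
  }
  chisq <- (o - e)^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# product-limit estimate at a time point, naive loop
km_oracle_at <- function(time, event, t0) {
  s <- 1
  for (t in sort(unique(time[event & time <= t0]))) {
    r <- sum(time >= t)
    d <- sum(event & time == t)
    s <- s * (1 - d / r)
  }
  s
}
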