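# Independently coded textbook statistical oracles (deliberately naive
# implementations, used to check the package's implementations).

oracle_paired_t <- function(x, y, tail = "greater") {
  d <- x - y; n <- length(d)
  t <- mean(d) / sqrt(sum((d - mean(d))^2) / (n - 1) / n)
  p <- switch(tail, greater = 1 - pt(t, n - 1), less = pt(t, n - 1),
              two.sided = 2 * (1 - pt(abs(t), n - 1)))
  list(t = t, p = p)
}

oracle_yuen_paired <- function(x, y, trim = 0.2, tail = "greater") {
  n <- length(x); g <- floor(trim * n); h <- n - 2 * g
  wins <- function(v) {
    s <- sort(v)
    v[v < s[g + 1]] <- s[g + 1]; v[v > s[n - g]] <- s[n - g]; v
  }
  tm <- function(v) mean(sort(v)[(g + 1):(n - g)])
  wx <- wins(x); wy <- wins(y)
  q1 <- (n - 1) * var(wx); q2 <- (n - 1) * var(wy); q3 <- (n - 1) * cov(wx, wy)
  se <- sqrt((q1 + q2 - 2 * q3) / (h * (h - 1)))
  t <- (tm(x) - tm(y)) / se
  p <- switch(tail, greater = 1 - pt(t, h - 1), less = pt(t, h - 1),
              two.sided = 2 * (1 - pt(abs(t), h - 1)))
  list(t = t, p = p)
}

oracle_holm <- function(p, alpha) {
  m <- length(p); o <- order(p); reject <- rep(FALSE, m)
  for (i in seq_len(m)) {
    if (p[o[i]] <= alpha / (m - i + 1)) reject[o[i]] <- TRUE else break
  }
  reject
}

oracle_bh <- function(p, alpha) {
  m <- length(p); o <- order(p)
  ks <- which(p[o] <= alpha * seq_len(m) / m)
  reject <- rep(FALSE, m)
  if (length(ks)) reject[o[seq_len(max(ks))]] <- TRUE
  reject
}
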