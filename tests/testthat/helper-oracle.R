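# Independent brute-force re-statement of the three sudden-gain criteria.
# Written as a direct, loop-based translation of the rule text, on purpose
# kept free of any package internals so it can serve as an oracle.

oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracle_detect <- function(values, rci = 12, rel = 0.25,
                          m_full = 2.78, m_five = 3.18) {
  T_ <- length(values)
  hits <- integer(0)
  n_eval <- 0L
  for (n in seq_len(T_ - 1)) {
    if (n == 1 || n == T_ - 1) next
    x_n <- values[n]; x_n1 <- values[n + 1]
    if (is.na(x_n) || is.na(x_n1)) next
    pre <- c()
    for (i in (n - 2):n) if (i >= 1 && !is.na(values[i])) pre <- c(pre, values[i])
    post <- c()
    for (i in (n + 1):(n + 3)) {
      if (i <= T_ && !is.na(values[i])) post <- c(post, values[i])
    }
    if (length(pre) < 2 || length(post) < 2 || length(pre) + length(post) < 5) next
    n_eval <- n_eval + 1L
    drop <- x_n - x_n1
    c1 <- drop >= rci
    c2 <- drop >= rel * x_n
    s1 <- oracle_sd(pre); s2 <- oracle_sd(post)
    n1 <- length(pre); n2 <- length(post)
    psd <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
    mult <- if (n1 + n2 == 6) m_full else m_five
    c3 <- (sum(pre) / n1 - sum(post) / n2) > mult * psd
    if (c1 && c2 && c3) hits <- c(hits, n)
  }
  list(hits = hits, n_evaluable = n_eval)
}

# random short trajectory with optional missingness and occasional big drops
random_series <- function(T_ = sample(6:16, 1), miss = 0.1) {
  base <- runif(1, 40, 120)
  x <- base + cumsum(c(0, rnorm(T_ - 1, -1.5, 6)))
  if (runif(1) < 0.5) {
    n <- sample(2:(T_ - 2), 1)
    x <- gainstudy::inject_gain(x, n, runif(1, 5, 40))
  }
  x <- pmin(pmax(x, 0), 144)
  x[runif(T_) < miss] <- NA
  x
}
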