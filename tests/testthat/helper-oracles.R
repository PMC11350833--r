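# Brute-force reference implementations, independent of the package code
# paths they check. All are written as plain loops over definitions.

oracle_alpha <- function(x) {
  # x: one count vector
  s <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  chao1 <- s + f1 * (f1 - 1) / (2 * (f2 + 1))
  p <- x[x > 0] / sum(x)
  h <- -sum(p * log(p))
  j <- if (s > 1) h / log(s) else NA_real_
  list(s_obs = s, chao1 = chao1, shannon = h, pielou = j)
}

oracle_welch <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  va <- sum((a - ma)^2) / (length(a) - 1)
  vb <- sum((b - mb)^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                 (vb / length(b))^2 / (length(b) - 1))
  p <- 2 * pt(-abs(tt), df)
  list(statistic = tt, df = df, p = p)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  zx <- (x - mean(x)) / sd(x)
  zy <- (y - mean(y)) / sd(y)
  r <- sum(zx * zy) / (n - 1)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, statistic = tt, df = n - 2, p = 2 * pt(-abs(tt), n - 2))
}

oracle_yates_chisq <- function(m) {
  # m: 2x2 table of observed counts; the correction never overshoots |O - E|
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum(pmax(abs(m - e) - 0.5, 0)^2 / e)
}

oracle_gof_chisq <- function(obs, prop) {
  e <- sum(obs) * prop / sum(prop)
  sum((obs - e)^2 / e)
}

oracle_kappa <- function(pred, obs) {
  po <- mean(pred == obs)
  cls <- union(unique(pred), unique(obs))
  pe <- 0
  for (cl in cls) pe <- pe + mean(pred == cl) * mean(obs == cl)
  (po - pe) / (1 - pe)
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_ranksum_exact <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  rk <- rank(c(a, b))
  w_obs <- sum(rk[seq_len(n1)])
  combos <- combn(n, n1)
  w_all <- apply(combos, 2, function(idx) sum(rk[idx]))
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

oracle_garson <- function(w1, w2) {
  h <- nrow(w1); k <- ncol(w1)
  imp <- numeric(k)
  for (j in seq_len(k)) {
    for (m in seq_len(h)) {
      imp[j] <- imp[j] + abs(w1[m, j]) / sum(abs(w1[m, ])) * abs(w2[m])
    }
  }
  imp / sum(imp)
}

# hypergeometric expectation of rarefied counts
oracle_rarefy_expectation <- function(x, depth) depth * x / sum(x)

# independent loop-based re-computation of the tie- and continuity-corrected
# normal-approximation rank-sum p-value (no rank(), explicit averaging)
oracle_ranksum_normal <- function(a, b) {
  v <- c(a, b)
  n <- length(v); n1 <- length(a); n2 <- length(b)
  rk <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(v < v[i])
    eq <- sum(v == v[i])
    rk[i] <- less + (eq + 1) / 2
  }
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie_term <- 0
  for (val in unique(v)) {
    tcount <- sum(v == val)
    tie_term <- tie_term + (tcount^3 - tcount)
  }
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- u - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  2 * pnorm(-abs(z))
}
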