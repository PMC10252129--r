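# Independent oracles used across the suite. Each recomputes the quantity
# under test from first principles (enumeration, closed form or brute force),
# deliberately avoiding the package's own code paths.

# Benjamini-Hochberg by explicit step-down enumeration.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, p[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# DerSimonian-Laird pooling, every formula evaluated step by step.
oracle_dl <- function(y, v) {
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  k <- length(y)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / C) else 0
  ws <- 1 / (v + tau2)
  pooled <- sum(ws * y) / sum(ws)
  se <- sqrt(1 / sum(ws))
  list(pooled = pooled, se = se, tau2 = tau2, Q = Q,
       p = 2 * pnorm(-abs(pooled / se)))
}

# TMM factor for one sample against a reference, by explicit sorting-based
# double trim and weighted mean (brute force, no rank-window shortcut).
oracle_tmm_factor <- function(obs, ref, trim_m = 0.30, trim_a = 0.05) {
  nO <- sum(obs); nR <- sum(ref)
  keep <- obs > 0 & ref > 0
  o <- obs[keep]; r <- ref[keep]
  M <- log2((o / nO) / (r / nR))
  A <- (log2(o / nO) + log2(r / nR)) / 2
  w <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
  n <- length(M)
  n_trim_m <- floor(n * trim_m)
  n_trim_a <- floor(n * trim_a)
  keep_m <- order(M)[seq(n_trim_m + 1, n - n_trim_m)]
  keep_a <- order(A)[seq(n_trim_a + 1, n - n_trim_a)]
  sel <- intersect(keep_m, keep_a)
  2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
}

# Hypergeometric upper tail P(X >= k) by direct combinatorial summation.
oracle_hyper_tail <- function(N, K, n, k) {
  i <- seq(k, min(K, n))
  if (length(i) == 0 || k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Kaplan-Meier product-limit estimate evaluated by hand at each distinct time.
oracle_km <- function(time, event) {
  ts <- sort(unique(time))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_i <- sum(time >= ts[i])
    d_i <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  data.frame(time = ts, survival = surv)
}

# Log-rank statistic by explicit 2x2 risk-table enumeration at event times.
oracle_logrank <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O - E)^2 / V
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Permutation reference p-value for the log-rank test (label shuffles).
oracle_logrank_permutation <- function(time, event, group, B = 10000,
                                       seed = 42) {
  obs <- oracle_logrank(time, event, group)$statistic
  set.seed(seed)
  hits <- 0
  for (b in seq_len(B)) {
    if (oracle_logrank(time, event, sample(group))$statistic >= obs) {
      hits <- hits + 1
    }
  }
  hits / B
}

# Jaccard similarity of binary rows by explicit set arithmetic.
oracle_jaccard <- function(a, b) {
  ia <- which(a == 1); ib <- which(b == 1)
  u <- union(ia, ib)
  if (length(u) == 0) return(0)
  length(intersect(ia, ib)) / length(u)
}
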