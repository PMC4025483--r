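# Independent oracles, kept free of the code paths they check.

# Welch statistic, Welch-Satterthwaite df and two-sided p from the textbook
# formulas (no call into stats::t.test or the package).
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x) / n1
  v2 <- var(y) / n2
  t_stat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# Brute-force hypergeometric upper tail by direct summation with choose().
# For M <= 30 every binomial coefficient and partial product is below 2^53,
# so the sum is exact up to a final rounding.
hyper_tail_brute <- function(M, K, m, k) {
  i <- k:min(K, m)
  i <- i[m - i <= M - K & m - i >= 0]
  if (length(i) == 0) return(0)
  sum(choose(K, i) * choose(M - K, m - i)) / choose(M, m)
}

# Eigenvalues of a small symmetric matrix via the characteristic polynomial
# (Faddeev-LeVerrier coefficients + polyroot), independent of LAPACK
# svd()/eigen(). Returns them in decreasing order.
eigvals_charpoly <- function(a) {
  n <- nrow(a)
  m <- matrix(0, n, n)
  cf <- numeric(n + 1) # coefficients of lambda^n, lambda^(n-1), ..., lambda^0
  cf[1] <- 1
  for (k in seq_len(n)) {
    m <- a %*% m + cf[k] * diag(n)
    cf[k + 1] <- -sum(diag(a %*% m)) / k
  }
  roots <- polyroot(rev(cf))
  sort(Re(roots), decreasing = TRUE)
}

# Singular values of a matrix from the characteristic polynomial of D'D.
singvals_oracle <- function(d) {
  ev <- eigvals_charpoly(t(d) %*% d)
  sqrt(pmax(ev, 0))
}
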