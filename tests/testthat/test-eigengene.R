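test_that("a single-nonzero-row matrix is rank one: degenerate fractions, zero entropy", {
  mat <- matrix(0, nrow = 5, ncol = 3)
  mat[2, ] <- c(4, 1, 2)
  fit <- eigen_decompose(expr_table(mat))
  expect_equal(sum(fit$singular_values > 1e-10), 1L)
  expect_equal(fit$fractions, c(1, 0, 0))
  expect_equal(fit$entropy, 0)
})

test_that("a full-rank synthetic series with 12 stages yields exactly 12 eigengenes", {
  sim <- simulate_expression(n_genes = 1000, n_timepoints = 12, seed = 4)
  fit <- eigen_decompose(sim$expression)
  expect_equal(nrow(fit$eigengenes), 12L)
  expect_equal(length(fit$singular_values), 12L)
  expect_equal(length(fit$fractions), 12L)
})

test_that("planted orthogonal factors are recovered to 1e-8 without noise", {
  # construct a strictly nonnegative rank-2 matrix whose SVD factors are
  # known: orthonormal v's, orthonormal nonneg-dominant u's, plus weights
  n <- 40; t <- 4
  v1 <- rep(1, t) / sqrt(t)
  v2 <- c(-3, -1, 1, 3) / sqrt(20)
  set.seed(7)
  u1 <- abs(rnorm(n)) + 1; u1 <- u1 / sqrt(sum(u1^2)) # bounded away from 0
  u2 <- abs(rnorm(n)); u2 <- u2 - sum(u2 * u1) * u1; u2 <- u2 / sqrt(sum(u2^2))
  d <- 50 * outer(u1, v1) + 5 * outer(u2, v2)
  expect_true(all(d >= 0)) # dominant constant component keeps it nonnegative
  fit <- eigen_decompose(expr_table(d))
  expect_equal(sum(fit$singular_values > 1e-8), 2L)
  expect_equal(fit$singular_values[1:2], c(50, 5), tolerance = 1e-10)
  for (p in 1:2) {
    planted <- list(v1, v2)[[p]]
    rec <- fit$eigengenes[p, ]
    dev <- min(max(abs(rec - planted)), max(abs(rec + planted)))
    expect_lt(dev, 1e-8)
  }
})

test_that("eigenexpression fractions follow the printed arithmetic", {
  expect_equal(eigenexpression_fractions(c(5, 0, 0)), c(1, 0, 0))
  expect_equal(eigenexpression_fractions(rep(2, 12)), rep(1 / 12, 12))
  expect_equal(eigenexpression_fractions(c(3, 2, 1)), c(1 / 2, 1 / 3, 1 / 6))
  expect_error(eigenexpression_fractions(c(0, 0)), "all be zero")
  expect_error(eigenexpression_fractions(c(1, -1)), "nonnegative")
  expect_error(eigenexpression_fractions(c(1, 2)), "nonincreasing")
})

test_that("entropy endpoints are exact and bad inputs are rejected", {
  expect_identical(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_identical(shannon_entropy(rep(1 / 12, 12)), 1)
  expect_identical(shannon_entropy(rep(1 / 5, 5)), 1)
  # intermediate value bracketed
  d <- shannon_entropy(c(0.7, 0.2, 0.1))
  expect_gt(d, 0); expect_lt(d, 1)
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
  expect_error(shannon_entropy(c(1)), "length >= 2")
})

test_that("cumulative fraction sums the largest shares", {
  expect_equal(cumulative_fraction(c(0.5, 0.3, 0.2), 2), 0.8)
  expect_equal(cumulative_fraction(c(0.2, 0.5, 0.3), 2), 0.8) # order-free
  expect_equal(cumulative_fraction(rep(0.25, 4), 4), 1)
  expect_error(cumulative_fraction(c(0.5, 0.5), 3), "exceeds")
  expect_error(cumulative_fraction(c(0.5, 0.5), 0), "integer >= 1")
})

test_that("decomposition satisfies orthonormality and reconstruction", {
  for (seed in c(1, 2, 3)) {
    sim <- simulate_expression(n_genes = 150, n_timepoints = 8, seed = seed)
    fit <- eigen_decompose(sim$expression)
    u <- fit$loadings
    vt <- fit$eigengenes
    r <- length(fit$singular_values)
    expect_lt(max(abs(crossprod(u) - diag(r))), 1e-8)
    expect_lt(max(abs(vt %*% t(vt) - diag(r))), 1e-8)
    d <- as.matrix(sim$expression[, -1])
    recon <- u %*% (fit$singular_values * vt)
    expect_lt(norm(recon - d, "F") / norm(d, "F"), 1e-8)
    expect_equal(sum(fit$fractions), 1, tolerance = 1e-12)
    expect_false(is.unsorted(rev(fit$fractions)))
    expect_true(all(fit$orientation_signs %in% c(-1, 1)))
  }
})

test_that("singular values match a characteristic-polynomial oracle on small matrices", {
  set.seed(11)
  for (rep in 1:20) {
    nr <- sample(4:6, 1)
    nc <- sample(2:4, 1)
    d <- matrix(abs(rnorm(nr * nc, mean = 2)), nr, nc)
    fit <- eigen_decompose(expr_table(d))
    expect_equal(fit$singular_values, singvals_oracle(d), tolerance = 1e-8)
  }
})

test_that("invalid expression input is rejected with explicit messages", {
  wide <- matrix(1, nrow = 2, ncol = 4)
  expect_error(eigen_decompose(expr_table(wide)), "fewer genes")
  bad <- expr_table(matrix(c(1, 2, NA, 4, 5, 6), 2, 3))
  expect_error(eigen_decompose(bad), "finite")
  neg <- expr_table(matrix(c(1, -2, 3, 4, 5, 6), 2, 3))
  expect_error(eigen_decompose(neg), "nonnegative")
  dup <- expr_table(matrix(1:6, 2, 3), gene_ids = c("a", "a"))
  expect_error(eigen_decompose(dup), "Duplicate")
})

test_that("centering removes the constant program; log1p compresses scale", {
  sim <- simulate_expression(n_genes = 200, n_timepoints = 6, seed = 9)
  plain <- eigen_decompose(sim$expression)
  centered <- eigen_decompose(sim$expression, center = TRUE)
  # uncentered leading eigengene is near-constant; centered one is not
  cv <- function(v) sd(v) / abs(mean(v))
  expect_lt(cv(plain$eigengenes[1, ]), 0.1)
  expect_gt(sd(centered$eigengenes[1, ]), sd(plain$eigengenes[1, ]))
  logged <- eigen_decompose(sim$expression, transform = "log1p")
  expect_lt(logged$singular_values[1], plain$singular_values[1])
})

test_that("gene ranking is loading-ordered, tie-broken by ID, and sized", {
  # single indicator gene
  mat <- matrix(0, 6, 3)
  mat[4, ] <- c(0, 0, 9)
  fit <- eigen_decompose(expr_table(mat))
  expect_equal(rank_genes(fit, 1, 1)$gene_id, "g04")

  # planted order, no noise: recovered ranking equals planted order
  n <- 40; t <- 4
  v1 <- rep(1, t) / sqrt(t)
  set.seed(3)
  u1 <- abs(rnorm(n)); u1 <- u1 / sqrt(sum(u1^2))
  fit <- eigen_decompose(expr_table(10 * outer(u1, v1)))
  planted_order <- sprintf("g%02d", order(-u1, sprintf("g%02d", 1:n)))
  expect_equal(rank_genes(fit, 1, n)$gene_id, planted_order)

  # exact ties (duplicate rows) break lexicographically by gene ID
  mat <- rbind(c(2, 2, 2), c(2, 2, 2), c(1, 1, 1))
  fit <- eigen_decompose(expr_table(mat, gene_ids = c("gB", "gA", "gC")))
  expect_equal(rank_genes(fit, 1, 3)$gene_id, c("gA", "gB", "gC"))

  # default size is 500
  sim <- simulate_expression(n_genes = 600, n_timepoints = 6, seed = 2)
  fit <- eigen_decompose(sim$expression)
  expect_equal(nrow(rank_genes(fit, 2)), 500L)

  expect_error(rank_genes(fit, 7), "exceeds the number of patterns")
  expect_error(rank_genes(fit, 1, 601), "exceeds the gene count")
})

test_that("tidy and glance expose the decomposition in tabular form", {
  sim <- simulate_expression(n_genes = 50, n_timepoints = 5, seed = 1)
  fit <- eigen_decompose(sim$expression)
  fr <- tidy(fit, "fractions")
  expect_equal(nrow(fr), 5L)
  expect_equal(fr$cumulative[5], 1, tolerance = 1e-12)
  eg <- tidy(fit, "eigengenes")
  expect_equal(nrow(eg), 25L)
  ld <- tidy(fit, "loadings")
  expect_equal(nrow(ld), 250L)
  g <- glance(fit)
  expect_equal(g$n_genes, 50L)
  expect_equal(g$entropy, fit$entropy)
})
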