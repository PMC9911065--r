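test_that("eigen summaries reconstruct the matrix and fix eigenvector signs", {
  expect_equal(eigen_summary(diag(6))$values, rep(1, 6))
  es <- eigen_summary(diag(c(3, 2, 1, 1, 1, 1)))
  expect_equal(es$values[1], 3)
  expect_equal(abs(es$mmax), c(1, 0, 0, 0, 0, 0))

  set.seed(301)
  for (i in 1:5) {
    M <- random_psd(6)
    es <- eigen_summary(M)
    # descending order and orthonormality
    expect_true(all(diff(es$values) <= 1e-12))
    expect_equal(crossprod(es$vectors), diag(6), ignore_attr = TRUE,
                 tolerance = 1e-10)
    # rank-one rebuild oracle
    rebuild <- Reduce(`+`, lapply(1:6, function(k)
      es$values[k] * tcrossprod(es$vectors[, k])))
    expect_equal(rebuild, M, tolerance = 1e-8, ignore_attr = TRUE)
    # sign convention: largest-magnitude coordinate positive
    expect_true(all(apply(es$vectors, 2, function(v) v[which.max(abs(v))]) > 0))
  }
  expect_error(eigen_summary(matrix(1:36, 6)), "symmetric")
})

test_that("folded angles live in [0, 90] and respect symmetry and scale", {
  v <- c(1, 2, -1, 0, 3, 1)
  expect_equal(vector_angle(v, v), 0)
  expect_equal(vector_angle(v, -v), 0)
  expect_equal(vector_angle(c(1, 0), c(0, 1)), 90)
  expect_error(vector_angle(v, rep(0, 6)), "zero vector")

  set.seed(302)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6); c <- runif(1, 0.1, 10)
    th <- vector_angle(a, b)
    expect_true(th >= 0 && th <= 90)
    expect_equal(vector_angle(b, a), th, tolerance = 1e-10)
    expect_equal(vector_angle(a, c * b), th, tolerance = 1e-10)
  }
})

test_that("the random-vector null angle has mean 45 degrees in dimension two", {
  set.seed(303)
  nul <- null_angle_samples(2, 40000)
  expect_true(all(nul$samples >= 0 & nul$samples <= 90))
  expect_lt(abs(nul$mean - 45), 3 * nul$se)
  # higher dimension pushes the null mean above 45
  nul6 <- null_angle_samples(6, 20000)
  expect_gt(nul6$mean, 45)
  expect_lt(nul6$mean, 90)
  expect_error(null_angle_samples(1, 10), "dim")
})

test_that("projected variance is a Rayleigh quotient with its bounds", {
  set.seed(304)
  M <- random_psd(6)
  es <- eigen_summary(M)
  # eigenvector projection returns the eigenvalue
  for (k in c(1, 3, 6))
    expect_equal(project_variance(M, es$vectors[, k]), es$values[k],
                 tolerance = 1e-10)
  expect_equal(project_variance(diag(6), rnorm(6)), 1, tolerance = 1e-10)
  for (i in 1:20) {
    v <- rnorm(6)
    e <- project_variance(M, v)
    expect_gte(e, min(es$values) - 1e-10)
    expect_lte(e, max(es$values) + 1e-10)
  }
  expect_error(project_variance(M, rep(0, 6)), "zero vector")
})

test_that("Pi and its null expectation behave as ratios of eigenvalues", {
  M <- diag(c(3, 2, 1, 1, 1, 1))
  es <- eigen_summary(M)
  expect_equal(pi_statistic(M, es$mmax), 1, tolerance = 1e-12)
  expect_equal(pi_statistic(M, c(0, 1, 0, 0, 0, 0)), 2 / 3, tolerance = 1e-12)
  expect_equal(pi_statistic(diag(6), rnorm(6)), 1, tolerance = 1e-10)
  expect_equal(pi_null(diag(6)), 1)
  expect_equal(pi_null(diag(c(6, 0, 0, 0, 0, 0))), 1 / 6)
  expect_error(pi_null(matrix(0, 6, 6)), "degenerate")

  set.seed(305)
  for (i in 1:10) {
    Mx <- random_psd(6)
    v <- rnorm(6)
    es <- eigen_summary(Mx)
    p <- pi_statistic(Mx, v)
    expect_gte(p, min(es$values) / max(es$values) - 1e-10)
    expect_lte(p, 1 + 1e-10)
    p0 <- pi_null(Mx)
    expect_true(p0 > 0 && p0 <= 1 + 1e-12)
  }
})

test_that("posterior Pi intervals match an order-statistics oracle", {
  set.seed(306)
  # posterior draws: random PSD perturbations around a base matrix
  base <- diag(c(3, 2, 1, 1, 1, 1))
  draws <- array(NA_real_, c(6, 6, 50))
  for (s in 1:50) draws[, , s] <- base + random_psd(6) * 0.3
  v <- rnorm(6)
  pp <- pi_posterior(draws, v, levels = c(0.83, 0.95))
  expect_equal(length(pp$pi), 50)
  # oracle: quantiles of the sorted sample at 0.085 / 0.915
  expect_equal(unname(pp$intervals$pi["83%", ]),
               unname(quantile(pp$pi, c(0.085, 0.915), names = FALSE)),
               tolerance = 1e-12)

  # degenerate posterior: zero-width intervals
  dg <- array(rep(base, 5), c(6, 6, 5))
  ppd <- pi_posterior(dg, v)
  expect_equal(ppd$intervals$pi["95%", 1], ppd$intervals$pi["95%", 2])

  # matrices built with strong leading variance along y_mmax separate Pi from Pi0
  aligned <- array(NA_real_, c(6, 6, 40))
  u <- v / sqrt(sum(v^2))
  for (s in 1:40)
    aligned[, , s] <- 5 * tcrossprod(u) + diag(runif(6, 0.05, 0.15))
  ppa <- pi_posterior(aligned, v)
  expect_gt(ppa$intervals$pi["95%", 1], ppa$intervals$pi0["95%", 2])
})

test_that("rotating null matrices onto observed eigentraits gives per-axis nulls", {
  set.seed(307)
  M <- random_psd(6)
  es <- eigen_summary(M)
  # null set containing only the observed matrix returns its eigenvalues
  rot <- rotate_null_eigenvalues(list(M), es)
  expect_equal(drop(rot$samples), es$values, ignore_attr = TRUE,
               tolerance = 1e-10)
  # zero matrices give zero null values
  rot0 <- rotate_null_eigenvalues(list(matrix(0, 6, 6), matrix(0, 6, 6)), es)
  expect_true(all(rot0$samples == 0))
  expect_error(rotate_null_eigenvalues(list(diag(3)), es), "dimension mismatch")
})

test_that("the credible-interval overlap rule is conservative for identical distributions", {
  x <- rnorm(100)
  expect_false(ci_compare(x, x, 0.83)$different)
  expect_true(ci_compare(runif(50, 0, 1), runif(50, 10, 11), 0.83)$different)
  expect_error(ci_compare(x, x, 0.5), "level")
  expect_error(ci_compare(1, x, 0.83), "at least 2")

  set.seed(308)
  hits <- vapply(seq_len(300), function(i) {
    a <- rnorm(200); b <- rnorm(200)
    ci_compare(a, b, 0.83)$different
  }, logical(1))
  # same-distribution false-positive rate stays well below 1 - 0.83
  expect_lt(mean(hits), 0.17)
})
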