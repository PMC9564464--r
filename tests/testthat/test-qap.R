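test_that("difference and proximity matrices follow their definitions", {
  m <- difference_matrix(c(A = 1, B = 3, C = 6))
  expect_equal(m["A", "B"], 2)
  expect_equal(m["A", "C"], 5)
  expect_equal(m["B", "C"], 3)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(difference_matrix(rep(2, 4)) == 0))
  expect_equal(difference_matrix(c(1, 3) * 10), 10 * difference_matrix(c(1, 3)))
  expect_error(difference_matrix(c(1, NA)), "missing")

  d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(proximity_matrix(d)["A", "B"], 0.5)
  expect_error(proximity_matrix(d, mode = "border_adjacency"), "border_pairs")
  bm <- proximity_matrix(d, mode = "border_adjacency",
                         border_pairs = cbind("A", "B"))
  expect_equal(bm["B", "A"], 1)
  expect_true(all(proximity_matrix(d, mode = "border_adjacency",
                                   border_pairs = matrix(character(0), 0, 2)) == 0))
})

test_that("network adjacency round-trips into the dyadic role", {
  net <- generate_block_network(c(4, 4), p_in = 0.8, p_out = 0.1, seed = 1)
  m <- binary_network_as_dyads(net)
  expect_equal(unname(m), unname(net$a + 0))
  expect_equal(length(m[row(m) != col(m)]), 8 * 7)
  empty <- directed_network(matrix(0, 4, 4))
  expect_true(all(binary_network_as_dyads(empty) == 0))
})

test_that("QAP correlation handles identical and mirrored matrices", {
  set.seed(2)
  a <- matrix(rnorm(64), 8, 8); diag(a) <- 0
  r <- qap_correlation(a, a, n_perm = 200, seed = 1)
  expect_equal(r$coefficient, 1)
  expect_lte(r$p_ge, 0.05)
  rneg <- qap_correlation(a, -a, n_perm = 200, seed = 1)
  expect_equal(rneg$coefficient, -1)
  expect_error(qap_correlation(a, matrix(1, 8, 8), n_perm = 10),
               "zero variance")
})

test_that("QAP permutation distributions are reproducible and label-invariant", {
  set.seed(3)
  a <- matrix(rnorm(100), 10, 10); diag(a) <- 0
  b <- matrix(rnorm(100), 10, 10); diag(b) <- 0
  r1 <- qap_correlation(a, b, n_perm = 500, seed = 42)
  r2 <- qap_correlation(a, b, n_perm = 500, seed = 42)
  expect_identical(r1, r2)
  expect_equal(r1$p_ge + r1$p_le >= 1, TRUE)
  expect_equal(r1$sig, min(r1$p_ge, r1$p_le))
  # same relabeling of both matrices leaves the observed r unchanged
  p <- sample(10)
  r3 <- qap_correlation(a[p, p], b[p, p], n_perm = 10, seed = 1)
  expect_equal(r3$coefficient, r1$coefficient)
})

test_that("for symmetric matrices QAP r equals the unordered-pair correlation", {
  set.seed(4)
  v1 <- rnorm(9); v2 <- rnorm(9)
  a <- difference_matrix(v1); b <- difference_matrix(v2)
  r <- qap_correlation(a, b, n_perm = 10, seed = 1)
  lower <- lower.tri(a)
  expect_equal(r$coefficient, cor(a[lower], b[lower]))
})

test_that("QAP correlation agrees with an independent Mantel implementation", {
  skip_if_not_installed("vegan")
  set.seed(5)
  a <- difference_matrix(rnorm(12))
  b <- difference_matrix(rnorm(12))
  r <- qap_correlation(a, b, n_perm = 999, seed = 9)
  mv <- vegan::mantel(as.dist(a), as.dist(b), permutations = 999)
  expect_equal(r$coefficient, unname(mv$statistic))
  expect_lt(abs(r$p_ge - mv$signif), 0.06)   # both permutation p of same null
})

test_that("MRQAP recovers an exact linear map and rejects collinearity", {
  set.seed(6)
  x1 <- difference_matrix(rnorm(10))
  fit <- qap_regression(2 * x1, list(x1 = x1), n_perm = 100, seed = 1)
  expect_equal(unname(coef(fit)), c(0, 2), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_error(qap_regression(2 * x1, list(a = x1, b = 2 * x1), n_perm = 10),
               "collinear")
})

test_that("MRQAP estimates match lm on the off-diagonal vectorization", {
  d <- generate_dyadic_design(12, betas = c(1.5, -0.5), noise_sd = 1, seed = 7)
  fit <- qap_regression(d$y, d$xs, n_perm = 50, seed = 1)
  off <- row(d$y) != col(d$y)
  ref <- lm(d$y[off] ~ d$xs[[1]][off] + d$xs[[2]][off])
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(fit$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
  expect_equal(fit$adj_r_squared, summary(ref)$adj.r.squared, tolerance = 1e-10)
  # standardized coefficients
  sdy <- sd(d$y[off])
  expect_equal(fit$coefficients$std_estimate[2],
               unname(coef(ref)[2]) * sd(d$xs[[1]][off]) / sdy)
  # deterministic given seed
  fit2 <- qap_regression(d$y, d$xs, n_perm = 50, seed = 1)
  expect_identical(fit$coefficients, fit2$coefficients)
})

test_that("MRQAP detects a planted effect and passes over a null covariate", {
  d <- generate_dyadic_design(25, betas = c(2, 0), noise_sd = 0.5, seed = 11)
  fit <- qap_regression(d$y, list(x1 = d$xs[[1]], x2 = d$xs[[2]]),
                        n_perm = 1000, seed = 3)
  sig <- fit$coefficients$sig[match(c("x1", "x2"), fit$coefficients$term)]
  expect_lt(sig[1], 0.05)
  expect_gt(sig[2], 0.05)
})
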