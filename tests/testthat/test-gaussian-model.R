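test_that("weighted moments reduce to plain moments under uniform weights", {
  set.seed(2)
  X <- matrix(rnorm(8 * 6), 8, 6)
  mc_null <- weighted_mean_cov(X, NULL)
  mc_unif <- weighted_mean_cov(X, rep(0.37, 8))  # any constant weight
  expect_equal(mc_null$xbar, colMeans(X))
  expect_equal(mc_unif$xbar, mc_null$xbar)
  expect_equal(mc_unif$cbar, mc_null$cbar)
  # population covariance, not sample
  expect_equal(mc_null$cbar, crossprod(sweep(X, 2, colMeans(X))) / 8)
})

test_that("degenerate and tiny alignments give the closed-form moments", {
  expect_equal(weighted_mean_cov(matrix(c(3, 1, 4), 1, 3))$cbar,
               matrix(0, 3, 3))
  # two sequences A, C under 1-D encoding A -> 1, C -> -1
  vals <- stats::setNames(rep(0, 20), aa_alphabet())
  vals["A"] <- 1; vals["C"] <- -1
  em <- encode_msa(msa(c("A", "C")), property_encoding(vals))
  mc <- weighted_mean_cov(em)
  expect_equal(mc$xbar, 0)
  expect_equal(mc$cbar, matrix(1, 1, 1))
})

test_that("uniform-composition prior has exact closed forms", {
  pr <- build_prior(binary20_encoding(), L = 3)
  expect_equal(pr$rbar, rep(0.05, 20), ignore_attr = TRUE)
  expect_equal(diag(pr$Cr), rep(0.0475, 20), ignore_attr = TRUE)
  offdiag <- pr$Cr[upper.tri(pr$Cr)]
  expect_equal(offdiag, rep(-0.0025, length(offdiag)))
  # block-diagonal whole-alignment prior
  expect_equal(pr$mu, rep(rep(0.05, 20), 3), ignore_attr = TRUE)
  expect_equal(pr$CP[1:20, 21:40], matrix(0, 20, 20))

  # 1-D: prior mean/variance are the population moments of the scale
  v <- stats::setNames(seq(-2, 1.8, by = 0.2), aa_alphabet())
  pr1 <- build_prior(property_encoding(v), L = 2)
  expect_equal(unname(pr1$rbar), mean(v))
  expect_equal(pr1$Cr[1, 1], mean((v - mean(v)) ^ 2))
})

test_that("corrected covariance matches the blend formula", {
  # scalar case: CP = 0.25, Cbar = 1, Xbar = 0, muP = 0, lambda = 0.5
  vals <- stats::setNames(rep(c(0.5, -0.5), 10), aa_alphabet())  # Cr = 0.25
  pr <- build_prior(property_encoding(vals), L = 1)
  expect_equal(pr$Cr[1, 1], 0.25)
  expect_equal(unname(pr$rbar), 0)
  CM <- corrected_covariance(0, matrix(1, 1, 1), pr, lambda = 0.5)
  expect_equal(CM[1, 1], 0.625)
  expect_error(corrected_covariance(0, matrix(1, 1, 1), pr, lambda = 1.5))
})

test_that("lambda endpoints are exact and the rank-one term scales", {
  pr <- build_prior(binary20_encoding(), L = 2)
  cbar <- diag(0.25, 40)  # rational inputs so endpoint equality is bitwise
  xbar <- rep(c(0.125, 0), 20)
  expect_identical(corrected_covariance(xbar, cbar, pr, 0), cbar)
  expect_identical(corrected_covariance(xbar, cbar, pr, 1), pr$CP)
  # interior lambda includes the rank-one mean-shift term
  d <- xbar - pr$mu
  CM <- corrected_covariance(xbar, cbar, pr, 0.5)
  expect_equal(CM, 0.5 * pr$CP + 0.5 * cbar + 0.25 * tcrossprod(d))
})

test_that("coupling matrix inverts CM, ridging only when singular", {
  d <- c(2, 0.5, 4, 1)
  cp <- coupling_matrix(diag(d))
  expect_equal(cp$epsilon, 0)
  expect_equal(cp$J, diag(1 / d))

  set.seed(4)
  A <- matrix(rnorm(100), 10, 10)
  CM <- crossprod(A) / 10 + diag(0.5, 10)
  cp <- coupling_matrix(CM)
  expect_lt(max(abs(cp$J %*% CM - diag(10))), 1e-10)

  # exactly singular: ridge ladder engages; with ridge = "none" it fails
  sing <- diag(c(1, 1, 0))
  expect_error(coupling_matrix(sing, ridge = "none"), "singular")
  cp2 <- coupling_matrix(sing)
  expect_gt(cp2$epsilon, 0)
})

test_that("gap-free binary encoding is singular at lambda < 1 without ridge", {
  set.seed(6)
  x <- generate_msa(synthetic_spec(L = 5, N = 30, gap_rate = 0, seed = 6))$msa
  em <- encode_msa(x, binary20_encoding())
  mc <- weighted_mean_cov(em)
  pr <- build_prior(binary20_encoding(), x$L)
  CM <- corrected_covariance(mc$xbar, mc$cbar, pr, lambda = 0.8)
  # each position block annihilates the all-ones direction exactly
  v <- c(rep(1, 20), rep(0, 80))
  expect_equal(max(abs(CM %*% v)), 0, tolerance = 1e-12)
  expect_lt(qr(CM)$rank, 100)
  expect_error(coupling_matrix(CM, ridge = "none"), "singular")
})

test_that("null-prior model has exactly zero inter-position couplings", {
  x <- generate_msa(synthetic_spec(L = 4, N = 20, gap_rate = 0.1,
                                   seed = 8))$msa
  em <- encode_msa(x, binary20_encoding())
  model <- gaussian_model(em, weights = uniform_weights(x), lambda = 1)
  s <- em$s
  for (i in 1:3) for (j in (i + 1):4) {
    block <- model$J[(i - 1) * s + 1:s, (j - 1) * s + 1:s]
    expect_equal(max(abs(block)), 0)
  }
})

test_that("log-likelihood has its closed form and MLE at the moments", {
  d <- 6
  mu <- rnorm(d)
  X <- matrix(mu, 1, d)
  expect_equal(gaussian_log_likelihood(X, mu, diag(d)),
               -d / 2 * log(2 * pi))
  # doubling the sequences doubles the log-likelihood
  set.seed(12)
  X2 <- matrix(rnorm(5 * d), 5, d)
  ll <- gaussian_log_likelihood(X2, mu, diag(d) * 2)
  expect_equal(gaussian_log_likelihood(rbind(X2, X2), mu, diag(d) * 2),
               2 * ll)
  expect_error(gaussian_log_likelihood(X2, mu, diag(c(1, 1, 1, 1, 1, -1))),
               "positive definite")

  # unweighted MLE sits at (xbar, cbar): perturbations do not improve it
  set.seed(13)
  v <- stats::setNames(rnorm(20), aa_alphabet())
  x <- generate_msa(synthetic_spec(L = 3, N = 12, seed = 13))$msa
  em <- encode_msa(x, property_encoding(v))
  mc <- weighted_mean_cov(em)
  ll_hat <- gaussian_log_likelihood(em, mc$xbar, mc$cbar)
  for (k in 1:5) {
    ll_pert <- gaussian_log_likelihood(em, mc$xbar + rnorm(3, sd = 0.05),
                                       mc$cbar * (1 + runif(1, -0.2, 0.2)))
    expect_lte(ll_pert, ll_hat)
  }
})
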