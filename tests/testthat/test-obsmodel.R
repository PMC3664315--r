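test_that("polynomial and Legendre bases satisfy their contracts", {
  expect_equal(polynomial_basis(c(0.2, 0.7), 0.2, 0),
               matrix(1, 2, 1))
  expect_equal(polynomial_basis(c(0, 0.5, 1), 0, 1),
               cbind(1, c(0, 0.5, 1)))
  ## order-7 monomial basis on 25 points has a finite (large) condition
  ## number; the orthonormal basis is well-conditioned
  u <- seq(0, 1, length.out = 25)
  cm <- kappa(crossprod(polynomial_basis(u, 0, 7)), exact = TRUE)
  cl <- kappa(crossprod(legendre_basis(u, 0, 7)), exact = TRUE)
  expect_true(is.finite(cm))
  expect_lt(cl, 1e3)
  expect_lt(cl, cm / 1e6)
  ## legendre_basis is orthonormal in the continuum limit
  uu <- seq(0, 1, length.out = 20001)
  G <- crossprod(legendre_basis(uu, 0, 5)) / length(uu)
  expect_equal(G, diag(6), tolerance = 1e-3)
  ## coefficient matrix reproduces the recurrence evaluation
  Cm <- bbseg:::legendre_coef_matrix(5)
  expect_equal(polynomial_basis(u, 0, 5) %*% t(Cm),
               legendre_basis(u, 0, 5), tolerance = 1e-10)
})

test_that("empty segments leave the prior untouched with zero evidence", {
  pr <- obs_prior(2, 3)
  post <- posterior_update(pr, matrix(0, 0, 3), matrix(0, 0, 3))
  expect_equal(post$log_evidence, 0)
  expect_equal(post$coeff_bias, pr$coeff_bias)
  expect_equal(post$wishart_dof, pr$wishart_dof)
})

test_that("evidence matches brute-force quadrature for L = 1 across a grid", {
  x2 <- c(0.1, -0.2)
  times2 <- c(0.25, 0.75)
  for (b in c(0.5, 1, 2)) for (V in c(0.5, 1, 2)) for (nu in c(1, 3)) {
    pr <- obs_prior(0, 1, coeff_concentration = matrix(b, 1, 1),
                    wishart_dof = nu, wishart_scale = matrix(V, 1, 1))
    lev <- segment_log_evidence(times2, matrix(x2), pr,
                                t_start = 0, t_end = 1)
    q <- quadrature_evidence_1d(x2, legendre_basis(times2, 0, 0, 1),
                                b, nu, V)
    expect_equal(lev, log(q), tolerance = 1e-5)
  }
  ## order 1 (3D quadrature), n = 3
  x3 <- c(0.3, -0.1, 0.4)
  times3 <- c(0.1, 0.5, 0.9)
  pr1 <- obs_prior(1, 1, coeff_concentration = diag(2),
                   wishart_dof = 2, wishart_scale = matrix(1, 1, 1))
  lev1 <- segment_log_evidence(times3, matrix(x3), pr1,
                               t_start = 0, t_end = 1)
  q1 <- quadrature_evidence_1d(x3, legendre_basis(times3, 0, 1, 1),
                               1, 2, 1)
  expect_equal(lev1, log(q1), tolerance = 1e-5)
})

test_that("single-sample evidence equals the Student-t predictive density", {
  ## for L = 1, S = 0: marginal of one observation is a location-scale t
  ## with 2*(nu/2) = nu degrees of freedom, location a0, and squared scale
  ## V^-1 (1 + 1/b) / nu  (rate of the Gamma over the precision, inflated
  ## by the coefficient prior)
  for (b in c(0.5, 2)) for (V in c(0.5, 1.5)) for (nu in c(1, 4)) {
    pr <- obs_prior(0, 1, coeff_concentration = matrix(b, 1, 1),
                    wishart_dof = nu, wishart_scale = matrix(V, 1, 1))
    x <- 0.37
    lev <- segment_log_evidence(0.5, matrix(x), pr, t_start = 0, t_end = 1)
    s2 <- (1 / V) * (1 + 1 / b) / nu
    lt <- dt(x / sqrt(s2), df = nu, log = TRUE) - 0.5 * log(s2)
    expect_equal(lev, lt, tolerance = 1e-10)
  }
})

test_that("evidence obeys the probability chain rule and sample-order invariance", {
  set.seed(21)
  tt <- seq(0, 1, length.out = 12)
  X <- cbind(rnorm(12), rnorm(12), rnorm(12))
  pr <- obs_prior(2, 3, wishart_scale = diag(3))
  full <- segment_posterior(tt, X, pr, 0, 1)
  ## chain rule: evidence(all) = evidence(first k) + predictive of the rest
  k <- 5
  headp <- segment_posterior(tt[1:k], X[1:k, ], pr, 0, 1)
  ## predictive of the remainder under the k-sample posterior: same basis
  ## anchoring, so reuse the posterior as a prior
  mid <- obs_prior(2, 3, coeff_bias = headp$coeff_bias,
                   coeff_concentration = headp$coeff_concentration,
                   wishart_dof = headp$wishart_dof,
                   wishart_scale = headp$wishart_scale)
  tailev <- segment_log_evidence(tt[(k + 1):12], X[(k + 1):12, ], mid,
                                 t_start = 0, t_end = 1)
  expect_equal(full$log_evidence, headp$log_evidence + tailev,
               tolerance = 1e-8)
  ## permutation invariance
  perm <- sample(12)
  shuf <- segment_log_evidence(tt[perm], X[perm, ], pr, 0, 1)
  expect_equal(shuf, full$log_evidence, tolerance = 1e-10)
  ## monotone degrees of freedom
  expect_equal(full$wishart_dof, pr$wishart_dof + 12)
  expect_gt(full$wishart_dof, headp$wishart_dof)
})

test_that("higher-order evidence wins decisively on matching polynomial data", {
  set.seed(8)
  tt <- seq(0, 1, by = 1 / 240)
  u <- tt
  X <- cbind(1 + 2 * u - 8 * u^2 + 6 * u^3,
             -2 + 5 * u + 3 * u^2 - 4 * u^3,
             0.5 - 3 * u + 6 * u^2 - 2 * u^3) +
    matrix(rnorm(3 * length(u), 0, 0.05), ncol = 3)
  Xc <- sweep(X, 2, colMeans(X))
  ev <- vapply(c(0, 3), function(S)
    segment_log_evidence(tt, Xc, default_obs_prior(Xc, S), 0, 1), numeric(1))
  expect_gt(ev[2] - ev[1], 10)
})

test_that("posterior mean recovers noise-free lines and obeys conjugate limits", {
  tt <- seq(0, 1, length.out = 50)
  X <- cbind(1 + 2 * tt, -3 + tt, 0.5 - 2 * tt)
  broad <- obs_prior(1, 3, coeff_concentration = 1e-8 * diag(2),
                     wishart_scale = diag(3))
  post <- segment_posterior(tt, X, broad, 0, 1)
  expect_equal(posterior_mean_trajectory(post, tt), X, tolerance = 1e-6,
               ignore_attr = TRUE)
  ## order 0: constant at the posterior mean
  p0 <- segment_posterior(tt, X, obs_prior(0, 3), 0, 1)
  pred0 <- posterior_mean_trajectory(p0, tt)
  expect_equal(pred0, matrix(rep(pred0[1, ], each = 50), 50, 3),
               tolerance = 1e-12)
  ## huge concentration pins the fit at the coefficient bias (zero)
  tight <- obs_prior(1, 3, coeff_concentration = 1e10 * diag(2),
                     wishart_scale = diag(3))
  pt <- segment_posterior(tt, X, tight, 0, 1)
  expect_lt(max(abs(posterior_mean_trajectory(pt, tt))), 1e-5)
})

test_that("0th-order posterior covariance matches sample PCA on large segments", {
  set.seed(15)
  n <- 4000
  A <- matrix(c(2, 0.5, 0.1, 0.5, 1, -0.3, 0.1, -0.3, 0.5), 3, 3)
  X <- matrix(rnorm(3 * n), n, 3) %*% A
  X <- sweep(X, 2, colMeans(X))
  post <- segment_posterior(rep(0.5, n), X, default_obs_prior(X, 0), 0, 1)
  ## posterior expected covariance: inverse scale / (dof - L - 1)
  Sig <- post$wishart_inv_scale / (post$wishart_dof - 3 - 1)
  e_model <- eigen(Sig, symmetric = TRUE)$vectors
  e_pca <- eigen(crossprod(X) / n, symmetric = TRUE)$vectors
  for (j in 1:3)
    expect_gt(abs(sum(e_model[, j] * e_pca[, j])), 0.99)
})

test_that("hyperparameters round-trip through JSON", {
  pr <- obs_prior(2, 3, coeff_bias = matrix(1:9 / 10, 3, 3),
                  wishart_dof = 6.5,
                  wishart_scale = diag(c(1, 2, 3)))
  f <- tempfile(fileext = ".json")
  obs_prior_to_json(pr, f)
  pr2 <- obs_prior_from_json(f)
  expect_equal(pr2$coeff_bias, pr$coeff_bias)
  expect_equal(pr2$wishart_scale, pr$wishart_scale)
  expect_equal(pr2$wishart_dof, pr$wishart_dof)
  unlink(f)
})
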