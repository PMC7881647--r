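test_that("ar1_precision matches the inverse correlation matrix", {
  # rho = 0 -> identity
  expect_equal(as.matrix(ar1_precision(4, 0)), diag(4), ignore_attr = TRUE)
  # T = 2, rho = 0.5: inverse of [[1, .5], [.5, 1]] (derived by hand)
  Q <- as.matrix(ar1_precision(2, 0.5))
  expect_equal(Q, matrix(c(4 / 3, -2 / 3, -2 / 3, 4 / 3), 2), ignore_attr = TRUE)
  # product with its correlation matrix is the identity, random (T, rho)
  set.seed(1)
  for (k in 1:5) {
    T <- sample(2:6, 1); rho <- runif(1, -0.9, 0.9)
    R <- outer(1:T, 1:T, function(i, j) rho^abs(i - j))
    expect_equal(as.matrix(ar1_precision(T, rho)) %*% R, diag(T),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # innovation scale: marginal variance 1/(1 - rho^2)
  Qi <- as.matrix(ar1_precision(3, 0.6, scale = "innovation"))
  expect_equal(solve(Qi)[1, 1], 1 / (1 - 0.36), tolerance = 1e-10)
  expect_error(ar1_precision(3, 1), "rho")
})

test_that("spacetime_precision has Kronecker structure (dense oracles)", {
  m <- tiny_mesh(max_edge = 0.6)   # small G
  Qs <- spde_precision(m, spde_params(2, 1))
  G <- nrow(Qs)
  # Qt identity -> block diagonal with T copies of Qs
  Q1 <- spacetime_precision(Qs, Matrix::Diagonal(3))
  expect_equal(as.matrix(Q1[1:G, 1:G]), as.matrix(Qs), ignore_attr = TRUE)
  expect_equal(as.matrix(Q1[1:G, G + 1:G]), matrix(0, G, G), ignore_attr = TRUE)
  # eigenvalues = pairwise products; determinant identity (G small)
  Qs_small <- as.matrix(Qs)[1:6, 1:6]  # any SPD submatrix works for the identity
  Qs_small <- Qs_small + diag(6) * 0.1
  Qt <- as.matrix(ar1_precision(3, 0.4))
  Q <- spacetime_precision(Matrix::Matrix(Qs_small, sparse = TRUE),
                           Matrix::Matrix(Qt, sparse = TRUE))
  ev <- sort(eigen(as.matrix(Q), only.values = TRUE)$values)
  ev_oracle <- sort(as.vector(outer(eigen(Qs_small, only.values = TRUE)$values,
                                    eigen(Qt, only.values = TRUE)$values)))
  expect_equal(ev, ev_oracle, tolerance = 1e-8)
  expect_equal(determinant(as.matrix(Q))$modulus[1],
               3 * determinant(Qs_small)$modulus[1] +
                 6 * determinant(Qt)$modulus[1], tolerance = 1e-8)
  expect_error(spacetime_precision(Qs, matrix(1, 2, 3)), "square")
})

test_that("temporal_projection is linear-interpolation B-spline weights", {
  knots <- c(2007, 2010.5, 2014)
  expect_equal(temporal_projection(2007, knots)[1, ], c(1, 0, 0))
  expect_equal(temporal_projection(2014, knots)[1, ], c(0, 0, 1))
  # survey year 2011: derived as ((2014-2011)/3.5, (2011-2010.5)/3.5)
  expect_equal(temporal_projection(2011, knots)[1, ], c(0, 6 / 7, 1 / 7),
               tolerance = 1e-12)
  # always a convex combination
  yrs <- seq(2007, 2014, by = 0.25)
  W <- temporal_projection(yrs, knots)
  expect_true(all(W >= 0))
  expect_equal(rowSums(W), rep(1, length(yrs)))
  expect_error(temporal_projection(2015, knots), "outside")
  expect_error(temporal_projection(2006.9, knots), "outside")
})

test_that("loglik_binomial matches a direct summation oracle", {
  expect_equal(loglik_binomial(1, 1, 0), log(0.5))
  # y = 0 with strongly negative predictor: loglik -> 0
  expect_gt(loglik_binomial(rep(0, 5), rep(10, 5), rep(-30, 5)), -1e-8)
  set.seed(2)
  for (k in 1:5) {
    n <- sample(5:40, 20, replace = TRUE)
    y <- rbinom(20, n, 0.3)
    eta <- rnorm(20)
    oracle <- sum(sapply(seq_len(20), function(i) {
      p <- 1 / (1 + exp(-eta[i]))
      lchoose(n[i], y[i]) + y[i] * log(p) + (n[i] - y[i]) * log(1 - p)
    }))
    expect_equal(loglik_binomial(y, n, eta), oracle, tolerance = 1e-10)
    # invariant under reordering of clusters
    o <- sample(20)
    expect_equal(loglik_binomial(y[o], n[o], eta[o]),
                 loglik_binomial(y, n, eta), tolerance = 1e-12)
  }
  expect_error(loglik_binomial(5, 3, 0), "0 <= y <= n")
})

test_that("log_prior equals the sum of independent per-term oracles", {
  pr <- prior_spec()
  # beta term at 0 is the normal log-density mode
  expect_equal(log_prior(list(beta0 = 0), pr), dnorm(0, 0, sqrt(1000), log = TRUE))
  # gamma(1, 0.00005) on the precision is exponential: closed form
  s2 <- 0.06
  expect_equal(log_prior(list(sigma2_nonsp = s2), pr),
               log(0.00005) - 0.00005 / s2, tolerance = 1e-10)
  # total = sum of component oracles on random points
  set.seed(3)
  for (k in 1:5) {
    par <- list(beta0 = rnorm(1), beta = rnorm(3), kappa = exp(rnorm(1)),
                tau = exp(rnorm(1)), rho = runif(1, -0.9, 0.9),
                sigma2_nonsp = exp(rnorm(1)))
    oracle <- dnorm(par$beta0, 0, sqrt(1000), log = TRUE) +
      sum(dnorm(par$beta, 0, sqrt(1000), log = TRUE)) +
      dnorm(log(par$tau), 0.378, sqrt(10), log = TRUE) +
      dnorm(log(par$kappa), -1.64, sqrt(10), log = TRUE) +
      dnorm(log((1 + par$rho) / (1 - par$rho)), 0, sqrt(1 / 0.15), log = TRUE) +
      dgamma(1 / par$sigma2_nonsp, 1, rate = 0.00005, log = TRUE)
    expect_equal(log_prior(par, pr), oracle, tolerance = 1e-10)
  }
  # out of support
  expect_identical(log_prior(list(sigma2_nonsp = -1), pr), -Inf)
  expect_identical(log_prior(list(rho = 1.2), pr), -Inf)
  # variance convention for the rho transform is switchable
  prv <- prior_spec(rho_convention = "variance")
  expect_equal(log_prior(list(rho = 0.3), prv),
               dnorm(log(1.3 / 0.7), 0, sqrt(0.15), log = TRUE))
})

test_that("constraints: projection identity, idempotence, satisfaction", {
  set.seed(4)
  G <- 12; T <- 2; L <- 5
  cs <- constraint_set(G = G, T = T, n_lambda = L)
  N <- L + G * T
  # random SPD precision for conditioning
  A <- matrix(rnorm(N * N), N)
  Q <- Matrix::Matrix(crossprod(A) + diag(N), sparse = TRUE)
  x <- rnorm(N)
  xc <- apply_constraints(x, cs, Q = Q)
  expect_lt(max(abs(cs$B %*% xc)), 1e-8)
  # idempotent
  expect_equal(apply_constraints(xc, cs, Q = Q), xc, tolerance = 1e-8)
  # a conforming draw is unchanged
  expect_equal(apply_constraints(xc, cs, Q = Q), xc, tolerance = 1e-8)
  # Euclidean version too
  xe <- apply_constraints(x, cs)
  expect_lt(max(abs(cs$B %*% xe)), 1e-8)
  # rank-deficient constraints error
  Bbad <- rbind(cs$B, cs$B[1, ])
  expect_error(apply_constraints(x, Bbad), "rank deficient")
})

test_that("constraint_set includes design-orthogonality rows from the QR", {
  set.seed(5)
  n <- 30; G <- 10; T <- 1
  X <- cbind(1, rnorm(n))
  A_st <- projection_matrix(tiny_mesh(max_edge = 0.45),
                            cbind(runif(n), runif(n)))
  G <- ncol(A_st)
  cs <- constraint_set(X = X, A_st = A_st, G = G, T = T, n_lambda = 0)
  # applying the constraints makes the projected field orthogonal to X
  xi <- rnorm(G)
  xic <- apply_constraints(xi, cs)
  expect_lt(max(abs(crossprod(X, as.vector(A_st %*% xic)))), 1e-6)
})
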