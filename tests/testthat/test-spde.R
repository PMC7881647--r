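test_that("build_mesh honors its contracts", {
  # minimal mesh from 3 non-collinear points contains them as vertices
  p3 <- cbind(c(0, 1, 0), c(0, 0, 1))
  m3 <- build_mesh(p3, max_edge = 10, extension = 1)
  for (i in 1:3)
    expect_true(any(abs(m3$loc[, 1] - p3[i, 1]) + abs(m3$loc[, 2] - p3[i, 2]) < 1e-9))
  # halving max_edge increases the vertex count
  set.seed(1)
  pts <- cbind(runif(15), runif(15))
  v1 <- nrow(build_mesh(pts, max_edge = 0.4, extension = 0.3)$loc)
  v2 <- nrow(build_mesh(pts, max_edge = 0.2, extension = 0.3)$loc)
  expect_gt(v2, v1)
  # duplicate points within cutoff merge to one vertex
  dup <- rbind(pts, pts[1, ] + 1e-5)
  md <- build_mesh(dup, max_edge = 0.4, cutoff = 1e-3, extension = 0.3)
  expect_equal(md$n_data, 15)
  expect_equal(md$point_map[16], md$point_map[1])
  # collinear input errors
  expect_error(build_mesh(cbind(1:5, 2 * (1:5)), max_edge = 1), "collinear")
  # no degenerate triangles, every data vertex referenced
  tri <- md$tri
  a <- md$loc[tri[, 1], ]; b <- md$loc[tri[, 2], ]; cc <- md$loc[tri[, 3], ]
  areas <- 0.5 * abs((b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
                     (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1]))
  expect_true(all(areas > 1e-12))
  expect_true(all(seq_len(md$n_data) %in% as.vector(tri)))
})

test_that("mesh serialization round-trips", {
  m <- tiny_mesh()
  path <- withr::local_tempfile(fileext = ".txt")
  write_mesh(m, path)
  m2 <- read_mesh(path)
  expect_equal(m2$loc, m$loc)
  expect_equal(m2$tri, m$tri)
})

test_that("projection_matrix yields barycentric convex weights", {
  m <- tiny_mesh()
  # a point at a vertex -> single weight 1
  A <- projection_matrix(m, m$loc[4, , drop = FALSE])
  expect_equal(max(A), 1)
  expect_equal(Matrix::rowSums(A)[1], 1)
  expect_equal(sum(A != 0), 1)
  # centroid of a triangle -> weights (1/3, 1/3, 1/3)
  t1 <- m$tri[1, ]
  centroid <- colMeans(m$loc[t1, ])
  Ac <- projection_matrix(m, rbind(centroid))
  expect_equal(sort(as.numeric(Ac[1, t1])), rep(1 / 3, 3), tolerance = 1e-9)
  # convexity: projected value within corner range, rows sum to one
  set.seed(2)
  pts <- cbind(runif(50), runif(50))
  Ap <- projection_matrix(m, pts)
  expect_equal(as.numeric(Matrix::rowSums(Ap)), rep(1, 50), tolerance = 1e-9)
  f <- rnorm(nrow(m$loc))
  proj <- as.numeric(Ap %*% f)
  for (i in seq_len(50)) {
    sup <- which(Ap[i, ] != 0)
    expect_gte(proj[i], min(f[sup]) - 1e-9)
    expect_lte(proj[i], max(f[sup]) + 1e-9)
  }
  expect_error(projection_matrix(m, cbind(99, 99)), "outside")
})

test_that("matern_correlation has the right limits, shape and R-value", {
  p <- spde_params(kappa = 2, tau = 1, nu = 1)
  expect_equal(matern_correlation(0, p), 1)
  expect_lt(matern_correlation(1e4, p), 1e-10)
  d <- seq(0, 5, by = 0.05)
  expect_true(all(diff(matern_correlation(d, p)) < 0))
  # value at the range: (sqrt(8) K_1(sqrt(8))) for nu = 1, about 0.139;
  # frozen from a high-precision Bessel evaluation
  R <- spatial_range(p)
  expect_equal(matern_correlation(R, p), 0.139667474015293, tolerance = 1e-10)
  # scale invariance: correlation at R does not depend on kappa
  for (k in c(0.05, 0.5, 5))
    expect_equal(matern_correlation(spatial_range(spde_params(k, 1)),
                                    spde_params(k, 1)),
                 matern_correlation(R, p), tolerance = 1e-12)
  expect_error(matern_correlation(-1, p), ">= 0")
})

test_that("spatial_range and spatial_variance match their closed forms", {
  expect_equal(spatial_range(spde_params(sqrt(8), 1)), 1, tolerance = 1e-12)
  # the study's posterior-median range: nu = 1, kappa = 0.05368 -> ~52.69 km
  expect_equal(spatial_range(spde_params(0.05368, 1)), sqrt(8) / 0.05368,
               tolerance = 1e-12)
  expect_equal(round(spatial_range(spde_params(0.05368, 1)), 2), 52.69)
  expect_equal(spatial_variance(spde_params(1, 1 / sqrt(4 * pi))), 1,
               tolerance = 1e-12)
  p <- spde_params(0.3, 2.5)
  expect_equal(spatial_variance(p), 1 / (4 * pi * 0.3^2 * 2.5^2), tolerance = 1e-12)
  # inverse mapping round-trips
  p2 <- spde_params_from_range(52.69, 0.15)
  expect_equal(spatial_range(p2), 52.69, tolerance = 1e-10)
  expect_equal(spatial_variance(p2), 0.15, tolerance = 1e-10)
  expect_error(spde_params(-1, 1), "kappa")
})

test_that("spde_precision is symmetric positive definite and obeys the tau scaling law", {
  m <- tiny_mesh()
  for (kappa in c(1, 4)) {
    Q <- spde_precision(m, spde_params(kappa, 1.3))
    expect_true(Matrix::isSymmetric(Q))
    expect_silent(Matrix::Cholesky(Q))   # PD iff Cholesky succeeds
  }
  # doubling tau divides the implied marginal variance by 4
  Q1 <- spde_precision(m, spde_params(3, 1))
  Q2 <- spde_precision(m, spde_params(3, 2))
  v1 <- Matrix::diag(Matrix::solve(Q1))
  v2 <- Matrix::diag(Matrix::solve(Q2))
  expect_equal(as.numeric(v1 / v2), rep(4, nrow(Q1)), tolerance = 1e-9)
  expect_error(spde_precision(m, list(kappa = -1, tau = 1, nu = 1)))
})

test_that("GMRF samples reproduce the analytic Matern covariance (dense oracle)", {
  # small mesh (< 200 vertices), moderate kappa; Monte-Carlo against the
  # closed-form covariance sigma2 * C(d)
  m <- tiny_mesh(max_edge = 0.28, extension = 0.7)
  expect_lt(nrow(m$loc), 200)
  p <- spde_params(4, 1)
  Q <- spde_precision(m, p)
  set.seed(42)
  draws <- sample_gmrf(Q, 4000)
  interior <- which(m$loc[, 1] > 0.1 & m$loc[, 1] < 0.9 &
                    m$loc[, 2] > 0.1 & m$loc[, 2] < 0.9)
  i <- interior[1]
  dists <- sqrt((m$loc[interior, 1] - m$loc[i, 1])^2 +
                (m$loc[interior, 2] - m$loc[i, 2])^2)
  j <- interior[which.min(abs(dists - 0.4))]
  emp <- cov(draws[i, ], draws[j, ])
  d <- sqrt(sum((m$loc[i, ] - m$loc[j, ])^2))
  expected <- spatial_variance(p) * matern_correlation(d, p)
  se <- sd(draws[i, ] * draws[j, ]) / sqrt(4000)
  expect_lt(abs(emp - expected), 4 * se + 0.02 * spatial_variance(p))
})

test_that("nu = 0.5 precision implies the exponential-family variance", {
  m <- tiny_mesh(max_edge = 0.3, extension = 0.8)
  p <- spde_params(4, 1, nu = 0.5)
  Q <- spde_precision(m, p)
  expect_true(Matrix::isSymmetric(Q))
  S <- solve(as.matrix(Q))
  interior <- which(m$loc[, 1] > 0 & m$loc[, 1] < 1 & m$loc[, 2] > 0 & m$loc[, 2] < 1)
  ratio <- mean(diag(S)[interior]) / spatial_variance(p)
  expect_lt(abs(ratio - 1), 0.15)
})

test_that("grid_raster text serialization round-trips including nodata", {
  v <- matrix(rnorm(20), 4, 5)
  v[2, 3] <- NA
  r <- grid_raster(v, xmin = -3, ymin = 2, res = 2.5)
  path <- withr::local_tempfile(fileext = ".asc")
  write_grid_raster(r, path)
  r2 <- read_grid_raster(path)
  expect_equal(r2$values, r$values)
  expect_equal(r2$xmin, r$xmin)
  expect_equal(r2$res, r$res)
})
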