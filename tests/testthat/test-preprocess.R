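test_that("aggregate_to_clusters counts, averages and drops missing coordinates", {
  set.seed(1)
  rows <- data.frame(
    cluster_id = rep(c("a", "b"), c(30, 10)),
    year = 2010,
    x_km = rep(c(1, 2), c(30, 10)),
    y_km = rep(c(1, 2), c(30, 10)),
    outcome = c(rep(c(1, 0), c(4, 26)), rep(1, 10)),
    edu = c(rep(2, 30), rep(5, 10)))
  rows$x_km[40] <- NA   # one individual lacks coordinates
  out <- suppressMessages(aggregate_to_clusters(rows))
  expect_equal(nrow(out), 2)
  a <- out[out$cluster_id == "a", ]
  expect_equal(a$n, 30)
  expect_equal(a$y, 4)
  expect_equal(a$edu, 2)
  b <- out[out$cluster_id == "b", ]
  expect_equal(b$y, b$n)           # all positive -> y = n
  expect_equal(attr(out, "n_dropped"), 1L)
  expect_warning(aggregate_to_clusters(rows[0, ]), "empty")
})

test_that("standardize is exact on [1,2,3], errors on constants, round-trips", {
  s <- standardize(c(1, 2, 3))
  expect_equal(s$values, c(-1, 0, 1))
  expect_error(standardize(rep(2, 5), name = "wealth"), "wealth")
  x <- rnorm(50, 7, 3)
  s2 <- standardize(x)
  expect_equal(mean(s2$values), 0, tolerance = 1e-12)
  expect_equal(sd(s2$values), 1, tolerance = 1e-12)
  expect_equal(unstandardize(s2$values, s2), x)
  # idempotent on already standardized data (mean 0, sd 1 preserved)
  s3 <- standardize(s2$values)
  expect_equal(s3$values, s2$values, tolerance = 1e-12)
})

test_that("prune_collinear drops the lower-priority member of each conflicted pair", {
  set.seed(2)
  women <- rnorm(200)
  husbands <- 0.92 * women + sqrt(1 - 0.92^2) * rnorm(200)  # r ~ 0.92
  other <- rnorm(200)
  tab <- data.frame(edu_women = women, edu_husbands = husbands, other = other)
  out <- prune_collinear(tab, threshold = 0.8,
                         priority = c("edu_women", "other", "edu_husbands"))
  expect_true("edu_women" %in% out$kept)
  expect_identical(out$dropped, "edu_husbands")
  expect_gt(abs(out$report$r), 0.8)
  # no conflicted pair survives
  R <- cor(tab[out$kept])
  expect_true(all(abs(R[upper.tri(R)]) <= 0.8))
  # nothing above threshold -> all retained
  tab2 <- data.frame(a = rnorm(100), b = rnorm(100))
  expect_equal(prune_collinear(tab2)$kept, c("a", "b"))
  expect_error(prune_collinear(tab, threshold = 0.8, priority = "edu_women"),
               "priority")
})

test_that("prune_collinear on three mutually correlated columns keeps exactly one,
          matching brute force", {
  set.seed(3)
  base <- rnorm(300)
  tab <- data.frame(p1 = base + 0.1 * rnorm(300),
                    p2 = base + 0.1 * rnorm(300),
                    p3 = base + 0.1 * rnorm(300))
  # brute-force oracle: greedily visit pairs by best priority, drop losers
  oracle <- function(tab, priority) {
    R <- cor(tab); cols <- names(tab)
    dropped <- character(0)
    prs <- which(abs(R) > 0.8 & upper.tri(R), arr.ind = TRUE)
    ord <- order(pmin(match(cols[prs[, 1]], priority), match(cols[prs[, 2]], priority)))
    for (k in ord) {
      a <- cols[prs[k, 1]]; b <- cols[prs[k, 2]]
      if (a %in% dropped || b %in% dropped) next
      dropped <- c(dropped,
                   if (match(a, priority) <= match(b, priority)) b else a)
    }
    setdiff(cols, dropped)
  }
  for (pri in list(c("p1", "p2", "p3"), c("p3", "p1", "p2"), c("p2", "p3", "p1"))) {
    got <- prune_collinear(tab, priority = pri)$kept
    expect_identical(got, oracle(tab, pri))
    expect_length(got, 1)
    expect_identical(got, pri[1])
  }
})

test_that("extract_at_points is nearest-pixel with deterministic tie-break", {
  r <- grid_raster(matrix(1:12, 3, 4), xmin = 0, ymin = 0, res = 1)
  # pixel centers at (0.5, 0.5) etc; value layout: column-major 3x4
  expect_equal(extract_at_points(r, cbind(0.5, 0.5))[1], 1)
  expect_equal(extract_at_points(r, cbind(3.5, 2.5))[1], 12)
  # boundary between pixels (x = 1): lower column index wins
  expect_equal(extract_at_points(r, cbind(1, 0.5))[1], 1)
  expect_equal(extract_at_points(r, cbind(1.0000001, 0.5))[1], 4)
  # outside extent -> clamped to edge pixel, counted
  v <- extract_at_points(r, cbind(-5, 0.5))
  expect_equal(v[1], 1)
  expect_equal(attr(v, "n_outside"), 1L)
  # constant raster: displacement never changes the value
  rc <- grid_raster(matrix(7, 5, 5), res = 2)
  pts <- cbind(runif(20, 0, 10), runif(20, 0, 10))
  expect_true(all(extract_at_points(rc, pts) == 7))
})

test_that("distance_to_water matches geometry and a brute-force oracle", {
  # point inside a polygon -> 0
  sq <- square_feature("w1", 0, 10, 0, 10)
  expect_equal(distance_to_water(cbind(5, 5), list(sq)), 0)
  # point 5 km from a straight segment
  seg <- list(list(id = 1, type = "LineString",
                   rings = list(cbind(c(0, 10), c(0, 0)))))
  expect_equal(distance_to_water(cbind(5, 5), seg), 5)
  expect_error(distance_to_water(cbind(0, 0), list()), "empty")
  # multiple features: min over features equals pairwise brute force
  set.seed(4)
  feats <- lapply(1:5, function(i) {
    list(id = i, type = "LineString",
         rings = list(cbind(runif(4, 0, 50), runif(4, 0, 50))))
  })
  pts <- cbind(runif(10, 0, 50), runif(10, 0, 50))
  got <- distance_to_water(pts, feats)
  for (i in seq_len(nrow(pts))) {
    dmin <- Inf
    for (f in feats) {
      ring <- f$rings[[1]]
      for (s in seq_len(nrow(ring) - 1)) {
        # dense sampling along the segment as an independent oracle
        tt <- seq(0, 1, length.out = 2001)
        sx <- ring[s, 1] + tt * (ring[s + 1, 1] - ring[s, 1])
        sy <- ring[s, 2] + tt * (ring[s + 1, 2] - ring[s, 2])
        dmin <- min(dmin, sqrt((pts[i, 1] - sx)^2 + (pts[i, 2] - sy)^2))
      }
    }
    expect_equal(got[i], dmin, tolerance = 2e-3)
  }
})

test_that("annual_mean averages within-year slices and flags empty years", {
  r <- function(v) grid_raster(matrix(v, 2, 2), res = 1)
  slices <- list(r(10), r(20), r(5))
  times <- c(2010.1, 2010.5, 2011.2)
  m <- annual_mean(slices, times, 2010)
  expect_equal(m$values, matrix(15, 2, 2))
  # 12 identical monthly values -> that value
  s12 <- replicate(12, r(3), simplify = FALSE)
  expect_equal(annual_mean(s12, 2010 + (0:11) / 12, 2010)$values, matrix(3, 2, 2))
  # one missing month among 12 -> mean of the 11 others (per pixel)
  s12[[4]]$values[1, 1] <- NA
  s12[[5]] <- r(14)
  mm <- annual_mean(s12, 2010 + (0:11) / 12, 2010)
  expect_equal(mm$values[1, 1], (3 * 10 + 14) / 11)
  expect_warning(annual_mean(slices, times, 1999), "no observations")
})

test_that("categorize3 builds tertile indicators and rejects degenerate cuts", {
  x <- 1:30
  c3 <- categorize3(x)
  expect_equal(levels(c3$factor), c("low", "mid", "high"))
  expect_equal(colSums(c3$design), c(mid = 10, high = 10))
  expect_error(categorize3(rep(c(0, 1), 15), name = "v"), "v")
})

test_that("sar_smoothness separates white noise, smooth fields and checkerboards", {
  # white noise: coefficient near 0 (Monte-Carlo over 20 seeds)
  coefs <- vapply(1:20, function(s) {
    set.seed(s)
    sar_smoothness(matrix(rnorm(144), 12, 12))
  }, numeric(1))
  expect_lt(abs(mean(coefs)), 0.1)
  # strongly smoothed field: > 0.9 (the regime reported for real surfaces)
  set.seed(7)
  z <- matrix(rnorm(16), 4, 4)
  big <- matrix(NA, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    # bilinear upsampling = very smooth surface
    fi <- (i - 1) / 5 + 1; fj <- (j - 1) / 5 + 1
    i0 <- floor(fi); j0 <- floor(fj)
    wi <- fi - i0; wj <- fj - j0
    i1 <- min(i0 + 1, 4); j1 <- min(j0 + 1, 4)
    big[i, j] <- (1 - wi) * (1 - wj) * z[i0, j0] + wi * (1 - wj) * z[i1, j0] +
      (1 - wi) * wj * z[i0, j1] + wi * wj * z[i1, j1]
  }
  expect_gt(sar_smoothness(big), 0.9)
  # checkerboard: negative autocorrelation
  cb <- outer(1:8, 1:8, function(i, j) (-1)^(i + j))
  expect_lt(sar_smoothness(cb), 0)
  # affine invariance
  set.seed(8)
  w <- matrix(rnorm(100), 10, 10)
  expect_equal(sar_smoothness(w), sar_smoothness(5 * w - 3), tolerance = 1e-5)
  expect_error(sar_smoothness(matrix(1, 5, 5)), "constant")
  expect_error(sar_smoothness(matrix(rnorm(4), 2, 2)), "3 x 3")
})
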