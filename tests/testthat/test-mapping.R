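test_that("prediction_grid standardizes with training parameters and masks nothing by default", {
  r <- grid_raster(matrix(1:100, 10, 10), xmin = 0, ymin = 0, res = 10)
  std <- list(v = list(mean = 50, sd = 10))
  g <- prediction_grid(c(0, 100, 0, 100), res = 10, surfaces = list(v = r), std = std)
  expect_equal(nrow(g$points), 100)
  expect_equal(g$X[, "v"], (extract_at_points(r, g$points) - 50) / 10,
               ignore_attr = TRUE)
  expect_true(all(g$pop == 1))
})

test_that("as_raster round-trips pixel order", {
  g <- prediction_grid(c(0, 40, 0, 20), res = 10)
  vals <- seq_len(nrow(g$points))
  r <- as_raster(g, vals)
  expect_equal(extract_at_points(r, g$points), vals, ignore_attr = TRUE)
})

# one small shared fit for the prediction tests
local({
  sim <- simulate_survey(small_config(seed = 51, n_clusters = 50))
  fit <- do.call(fit_geostat,
                 c(list(data = sim$clusters, covariates = c("cov1", "cov2"),
                        temporal = temporal_spec(2010, "exchangeable")),
                   fast_fit_args(iter = 200, warmup = 150)))
  grid <- prediction_grid(c(0, 200, 0, 200), res = 25,
                          surfaces = list(cov1 = sim$surfaces$cov1,
                                          cov2 = sim$surfaces$cov2),
                          pop = sim$surfaces$pop)

  test_that("predict_grid produces coherent summaries and honors masking", {
    pg <- predict_grid(fit, grid, 2010)
    s <- pg$summary
    expect_true(all(s$lower <= s$median & s$median <= s$upper))
    expect_true(all(s$median > 0 & s$median < 1))
    # masked pixel: poison one covariate
    g2 <- grid; g2$X[3, 1] <- NA
    pg2 <- suppressMessages(predict_grid(fit, g2, 2010))
    expect_equal(pg2$n_masked, 1)
    expect_true(is.na(pg2$summary$median[3]))
  })

  test_that("covariate monotonicity propagates through the link", {
    # raise a covariate with known-sign coefficient at one pixel
    bsign <- sign(median(fit$draws[, "beta_cov1"]))
    g3 <- grid
    g3$X[7, "cov1"] <- g3$X[7, "cov1"] + 2 * bsign
    pg <- predict_grid(fit, grid, 2010)
    pg3 <- predict_grid(fit, g3, 2010)
    expect_gt(pg3$summary$median[7], pg$summary$median[7])
  })

  test_that("infected_counts multiplies draws by population", {
    pg <- predict_grid(fit, grid, 2010)
    ic <- infected_counts(pg)
    expect_equal(ic$draws[5, ], pg$draws[5, ] * grid$pop[5])
    # zero population -> zero count
    pop0 <- rep(0, nrow(grid$points))
    ic0 <- infected_counts(pg, pop0)
    expect_true(all(ic0$summary$median == 0))
    expect_error(infected_counts(pg, -pop0 - 1), "negative")
    # p = 0.134 with pop 1000 -> 134
    pd <- matrix(0.134, 1, 50)
    expect_equal(infected_counts(pd, 1000)$summary$median, 134)
  })

  test_that("aggregate_admin reproduces exact identities", {
    pg <- predict_grid(fit, grid, 2010)
    whole <- square_feature("all", 0, 200, 0, 200)
    left <- square_feature("L", 0, 100, 0, 200)
    right <- square_feature("R", 100, 200, 0, 200)
    # uniform prevalence over a unit returns that prevalence exactly
    pg_u <- pg
    pg_u$draws[] <- 0.234
    agg_u <- aggregate_admin(pg_u, list(whole))
    expect_equal(agg_u$prev_median, 0.234, tolerance = 1e-12)
    # one-unit partition equals the whole-domain population-weighted mean per draw
    agg <- aggregate_admin(pg, list(whole))
    draw_means <- colSums(pg$draws * grid$pop) / sum(grid$pop)
    expect_equal(agg$prev_median, median(draw_means), tolerance = 1e-12)
    expect_equal(agg$count_median, median(colSums(pg$draws * grid$pop)),
                 tolerance = 1e-9)
    # two-pixel hand check: p = (.1, .3), pop = (100, 300) -> 0.25
    pd2 <- matrix(c(0.1, 0.3), 2, 40)
    g2 <- prediction_grid(c(0, 20, 0, 10), res = 10)
    pg2 <- structure(list(draws = pd2, year = 2010,
                          grid = modifyList(g2, list(pop = c(100, 300)))),
                     class = "grid_prediction")
    agg2 <- aggregate_admin(pg2, list(square_feature("u", 0, 20, 0, 10)))
    expect_equal(agg2$prev_median, 0.25, tolerance = 1e-12)
    # split partition: population-weighted combination recovers the whole
    aggLR <- aggregate_admin(pg, list(left, right))
    wmean <- sum(aggLR$population * aggLR$prev_median) # not additive in general,
    # but counts are additive per draw:
    cL <- colSums(pg$draws[grid$points[, 1] < 100, ] * grid$pop[grid$points[, 1] < 100])
    expect_equal(aggLR$count_median[aggLR$unit == "L"], median(cL), tolerance = 1e-9)
    expect_equal(attr(aggLR, "n_unassigned"), 0L)
    # zero-population unit flagged
    pgz <- pg
    pgz$grid$pop[] <- 0
    expect_warning(aggregate_admin(pgz, list(whole)), "zero population")
  })
})

test_that("relative_change follows the earlier-minus-later convention", {
  expect_equal(relative_change(0.2, 0.2)$rel_change, 0)
  # 0.10 -> 0.28: (0.10 - 0.28)/0.10 = -1.8, i.e. a 180% increase
  rc <- relative_change(0.10, 0.28)
  expect_equal(rc$rel_change, -1.8, tolerance = 1e-12)
  expect_equal(rc$pct_change, 180, tolerance = 1e-12)
  expect_equal(relative_change(0.5, 0)$rel_change, 1)
  expect_true(is.na(relative_change(0, 0.1)$rel_change))
  expect_error(relative_change(c(0.1, 0.2), 0.1), "grid")
})

test_that("classify_trend reproduces all three branches and antisymmetry", {
  expect_equal(classify_trend(0.10, 0.12, 0.18), "decreasing")
  expect_equal(classify_trend(0.20, 0.12, 0.18), "increasing")
  expect_equal(classify_trend(0.15, 0.12, 0.18), "stable")
  # vectorized
  expect_equal(classify_trend(c(0.1, 0.2, 0.15), c(0.12, 0.12, 0.12),
                              c(0.18, 0.18, 0.18)),
               c("decreasing", "increasing", "stable"))
  # antisymmetric under swapping strictly separated summaries
  expect_equal(classify_trend(0.05, 0.2, 0.3), "decreasing")
  expect_equal(classify_trend(0.25, 0.01, 0.08), "increasing")
})

test_that("GeoJSON polygons parse and point-in-polygon works on them", {
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", id = "d1", properties = list(name = "west"),
         geometry = list(type = "Polygon",
                         coordinates = list(list(list(0, 0), list(50, 0),
                                                 list(50, 100), list(0, 100),
                                                 list(0, 0))))),
    list(type = "Feature", id = "d2", properties = list(name = "east"),
         geometry = list(type = "MultiPolygon",
                         coordinates = list(list(list(list(50, 0), list(100, 0),
                                                      list(100, 100), list(50, 100),
                                                      list(50, 0)))))))
  )
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  feats <- read_geojson_features(path)
  expect_length(feats, 2)
  expect_equal(feats[[1]]$id, "d1")
  expect_true(point_in_ring(cbind(25, 50), feats[[1]]$rings[[1]]))
  expect_false(point_in_ring(cbind(75, 50), feats[[1]]$rings[[1]]))
  expect_true(point_in_ring(cbind(75, 50), feats[[2]]$rings[[1]]))
  # distances: inside -> 0; outside -> to boundary
  expect_equal(distance_to_features(cbind(25, 50), feats), 0)
  expect_equal(distance_to_features(cbind(-10, 50), feats[1]), 10)
})
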