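## Map products: prediction of prevalence over a regular grid, pixel-level
## uncertainty and infected counts, population-adjusted aggregation to
## administrative units (always at the draw level — quantiles are not
## additive), trend classification and relative change between years.

#' Build a prediction grid with covariates and population
#'
#' Pixel centers on a regular `res`-km grid over `bounds`; covariate
#' surfaces are extracted at pixel centers (nearest pixel) and standardized
#' with the *training* (mean, sd) pairs so grid covariates live on the scale
#' the model was fitted on.
#'
#' @param bounds `c(xmin, xmax, ymin, ymax)` km.
#' @param res pixel size in km (default 5, the mapping resolution).
#' @param surfaces named list of [grid_raster()] covariate surfaces.
#' @param pop optional [grid_raster()] of population per pixel (default 1
#'   per pixel).
#' @param std optional named list of `(mean, sd)` pairs (as returned by
#'   [standardize()]) applied to the matching surface.
#' @return `prediction_grid`: `points` (pixel centers), `X` (covariate
#'   matrix), `pop`, `res`, `bounds`, `nx`, `ny`.
#' @export
prediction_grid <- function(bounds, res = 5, surfaces = list(), pop = NULL,
                            std = NULL) {
  stop_if_not_scalar_pos(res, "res")
  nx <- max(1L, floor((bounds[2] - bounds[1]) / res + 1e-9))
  ny <- max(1L, floor((bounds[4] - bounds[3]) / res + 1e-9))
  xs <- bounds[1] + (seq_len(nx) - 0.5) * res
  ys <- bounds[3] + (seq_len(ny) - 0.5) * res
  pts <- cbind(x = rep(xs, times = ny), y = rep(ys, each = nx))
  X <- NULL
  if (length(surfaces)) {
    X <- sapply(names(surfaces), function(nm) {
      v <- as.numeric(extract_at_points(surfaces[[nm]], pts))
      if (!is.null(std[[nm]])) v <- (v - std[[nm]]$mean) / std[[nm]]$sd
      v
    })
    X <- as.matrix(X)
  }
  popv <- if (is.null(pop)) rep(1, nrow(pts)) else
    as.numeric(extract_at_points(pop, pts))
  structure(list(points = pts, X = X, pop = popv, res = res, bounds = bounds,
                 nx = nx, ny = ny),
            class = "prediction_grid")
}

#' Posterior prevalence over a prediction grid
#'
#' Per draw, `p = plogis(beta0 + X beta + A xi(year))` at every pixel; the
#' location effect is excluded (its variance is reported separately).
#' Pixels with missing covariates are masked and counted.
#'
#' @param fit an `spdeprev_fit`.
#' @param grid a [prediction_grid()].
#' @param year prediction year (within the knot span).
#' @return `grid_prediction`: `draws` (pixels x draws, masked rows `NA`),
#'   `summary` (median, sd, lower, upper per pixel), `year`, `grid`,
#'   `n_masked`.
#' @export
predict_grid <- function(fit, grid, year) {
  stopifnot(inherits(grid, "prediction_grid"))
  X <- grid$X
  masked <- if (is.null(X)) rep(FALSE, nrow(grid$points)) else
    apply(X, 1, function(r) any(!is.finite(r)))
  ok <- which(!masked)
  draws <- matrix(NA_real_, nrow(grid$points), nrow(fit$draws))
  Xok <- if (is.null(X)) matrix(0, length(ok), 0) else X[ok, , drop = FALSE]
  draws[ok, ] <- predict_prevalence_draws(fit, Xok, grid$points[ok, , drop = FALSE],
                                          year)
  qs <- matrix(NA_real_, nrow(draws), 3)
  qs[ok, ] <- t(apply(draws[ok, , drop = FALSE], 1, quantile,
                      c(0.5, 0.025, 0.975), names = FALSE))
  summ <- data.frame(x = grid$points[, 1], y = grid$points[, 2],
                     median = qs[, 1], sd = apply(draws, 1, sd),
                     lower = qs[, 2], upper = qs[, 3])
  if (sum(masked))
    message(sum(masked), " pixel(s) masked for missing covariates")
  structure(list(draws = draws, summary = summ, year = year, grid = grid,
                 n_masked = sum(masked)),
            class = "grid_prediction")
}

#' Pixel-level infected counts
#'
#' Count draw = prevalence draw x pixel population; summaries per pixel.
#'
#' @param pred a [predict_grid()] result (or a prevalence draw matrix).
#' @param population population per pixel (defaults to the grid's).
#' @return list: `draws` (count draws), `summary` (median, lower, upper).
#' @export
infected_counts <- function(pred, population = NULL) {
  draws <- if (inherits(pred, "grid_prediction")) pred$draws else as.matrix(pred)
  if (is.null(population) && inherits(pred, "grid_prediction"))
    population <- pred$grid$pop
  if (any(population < 0, na.rm = TRUE)) stop("negative population", call. = FALSE)
  cd <- draws * population
  ok <- which(apply(cd, 1, function(r) all(is.finite(r))))
  qs <- matrix(NA_real_, nrow(cd), 3)
  qs[ok, ] <- t(apply(cd[ok, , drop = FALSE], 1, quantile,
                      c(0.5, 0.025, 0.975), names = FALSE))
  list(draws = cd, summary = data.frame(median = qs[, 1], lower = qs[, 2],
                                        upper = qs[, 3]))
}

#' Population-adjusted prevalence and counts by administrative unit
#'
#' Pixels are assigned to units by pixel-center containment (boundary ties
#' to the unit with the smaller id); per draw, unit prevalence is the
#' population-weighted mean of pixel prevalence and the unit count its
#' population-weighted sum; summaries are taken over draws.
#'
#' @param pred a [predict_grid()] result.
#' @param admin feature list from [read_geojson_features()] (polygons).
#' @param population per-pixel population (defaults to the grid's).
#' @return data.frame, one row per unit (plus attribute `n_unassigned`):
#'   prevalence and count medians with 95% intervals and unit population.
#' @export
aggregate_admin <- function(pred, admin, population = NULL) {
  stopifnot(inherits(pred, "grid_prediction"))
  if (is.null(population)) population <- pred$grid$pop
  pts <- pred$grid$points
  ids <- vapply(admin, function(f) as.character(f$id), character(1))
  ord <- order(ids)                      # smaller id wins boundary ties
  unit <- rep(NA_character_, nrow(pts))
  for (k in ord) {
    f <- admin[[k]]
    if (!f$type %in% c("Polygon", "MultiPolygon"))
      stop("admin features must be polygons", call. = FALSE)
    inside <- rep(FALSE, nrow(pts))
    for (ring in f$rings) inside <- inside | point_in_ring(pts, ring)
    unit[is.na(unit) & inside] <- ids[k]
  }
  rows <- list()
  for (u in ids[ord]) {
    px <- which(unit == u & is.finite(pred$draws[, 1]))
    popu <- sum(population[px])
    if (length(px) == 0 || popu <= 0) {
      warning("unit ", u, " has zero population; prevalence undefined")
      rows[[u]] <- data.frame(unit = u, population = popu,
                              prev_median = NA, prev_lower = NA, prev_upper = NA,
                              count_median = NA, count_lower = NA, count_upper = NA)
      next
    }
    count_draws <- colSums(pred$draws[px, , drop = FALSE] * population[px])
    prev_draws <- count_draws / popu
    qp <- quantile(prev_draws, c(0.5, 0.025, 0.975), names = FALSE)
    qc <- quantile(count_draws, c(0.5, 0.025, 0.975), names = FALSE)
    rows[[u]] <- data.frame(unit = u, population = popu,
                            prev_median = qp[1], prev_lower = qp[2], prev_upper = qp[3],
                            count_median = qc[1], count_lower = qc[2], count_upper = qc[3])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_unassigned") <- sum(is.na(unit))
  attr(out, "year") <- pred$year
  out
}

#' Relative change between two prevalence maps
#'
#' Per pixel, `(p_a - p_b) / p_a`: the earlier-minus-later convention, under
#' which an *increase* yields a negative value; the sign-flipped percentage
#' (`pct_change`, positive = increase) is returned alongside, both labelled.
#' Pixels with `p_a = 0` are masked.
#'
#' @param p_a median prevalence map for the reference (earlier) year.
#' @param p_b median prevalence map for the comparison (later) year.
#' @return data.frame: `rel_change` (`(p_a - p_b)/p_a`) and `pct_change`
#'   (`100 (p_b - p_a)/p_a`, positive = increase).
#' @export
relative_change <- function(p_a, p_b) {
  a <- if (inherits(p_a, "grid_prediction")) p_a$summary$median else as.numeric(p_a)
  b <- if (inherits(p_b, "grid_prediction")) p_b$summary$median else as.numeric(p_b)
  if (length(a) != length(b)) stop("maps must share a grid", call. = FALSE)
  rc <- (a - b) / a
  rc[a == 0] <- NA
  data.frame(rel_change = rc, pct_change = -100 * rc)
}

#' Classify the temporal trend of a unit between two surveys
#'
#' `decreasing` iff the current median falls below the previous 95% lower
#' bound; `increasing` iff it exceeds the previous upper bound; otherwise
#' `stable`.
#'
#' @param median_t current-year posterior median (vectorized).
#' @param lower_prev,upper_prev previous-year 95% interval bounds.
#' @return character vector: `"increasing"`, `"stable"` or `"decreasing"`.
#' @export
classify_trend <- function(median_t, lower_prev, upper_prev) {
  ifelse(median_t < lower_prev, "decreasing",
         ifelse(median_t > upper_prev, "increasing", "stable"))
}

#' Turn a per-pixel vector into a raster on the prediction grid
#' @param grid a [prediction_grid()].
#' @param values numeric vector, one per pixel.
#' @return a [grid_raster()].
#' @export
as_raster <- function(grid, values) {
  stopifnot(inherits(grid, "prediction_grid"), length(values) == nrow(grid$points))
  grid_raster(matrix(values, grid$ny, grid$nx, byrow = TRUE),
              xmin = grid$bounds[1], ymin = grid$bounds[3], res = grid$res)
}

#' Write the map products of a grid prediction
#'
#' One plain-text raster per product, named `{product}_{year}.asc`
#' (`median`, `sd`, `lower`, `upper`, and with a population surface also
#' `counts`); administrative aggregates go to `admin_{year}_{level}.csv`.
#'
#' @param pred a [predict_grid()] result.
#' @param dir output directory (created if needed).
#' @param admin optional polygon features for aggregation.
#' @param level label used in the admin file name (e.g. `"adm1"`).
#' @return invisibly, the paths written.
#' @export
export_map_products <- function(pred, dir, admin = NULL, level = "adm1") {
  stopifnot(inherits(pred, "grid_prediction"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- pred$grid
  paths <- character(0)
  for (prod in c("median", "sd", "lower", "upper")) {
    p <- file.path(dir, sprintf("%s_%s.asc", prod, pred$year))
    write_grid_raster(as_raster(g, pred$summary[[prod]]), p)
    paths <- c(paths, p)
  }
  if (!all(g$pop == 1)) {
    ic <- infected_counts(pred)
    p <- file.path(dir, sprintf("counts_%s.asc", pred$year))
    write_grid_raster(as_raster(g, ic$summary$median), p)
    paths <- c(paths, p)
  }
  if (!is.null(admin)) {
    p <- file.path(dir, sprintf("admin_%s_%s.csv", pred$year, level))
    write.csv(aggregate_admin(pred, admin), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
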