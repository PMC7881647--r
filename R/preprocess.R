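## From individual survey rows to the model's design: cluster aggregation,
## standardization with stored parameters, correlation pruning, raster
## point-extraction, water distance, annual averaging, and the SAR smoothness
## diagnostic that justifies nearest-pixel extraction under DHS coordinate
## displacement.

#' Aggregate individual survey rows to cluster level
#'
#' One output row per `(cluster_id, year)`: `n` = respondent count, `y` =
#' positive count; continuous covariates averaged, binary covariates turned
#' into proportions (a binary column is one with only 0/1 values).  Rows with
#' missing coordinates are dropped and counted.
#'
#' @param rows data.frame with `cluster_id`, `year`, `x_km`, `y_km`, binary
#'   `outcome`, plus covariate columns.
#' @param covariates character vector of covariate column names (default: all
#'   remaining numeric columns).
#' @return cluster-level data.frame; attribute `n_dropped` counts rows lost
#'   to missing coordinates.
#' @export
aggregate_to_clusters <- function(rows, covariates = NULL) {
  req <- c("cluster_id", "year", "x_km", "y_km", "outcome")
  if (!all(req %in% names(rows)))
    stop("rows need columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (nrow(rows) == 0) {
    warning("empty input; returning empty cluster table")
    out <- rows[, c("cluster_id", "year", "x_km", "y_km")]
    out$n <- integer(0); out$y <- integer(0)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  miss <- is.na(rows$x_km) | is.na(rows$y_km)
  n_dropped <- sum(miss)
  if (n_dropped > 0)
    message(n_dropped, " individual row(s) dropped for missing coordinates")
  rows <- rows[!miss, , drop = FALSE]
  if (is.null(covariates))
    covariates <- setdiff(names(rows)[vapply(rows, is.numeric, logical(1))],
                          c("year", "x_km", "y_km", "outcome"))
  key <- interaction(rows$cluster_id, rows$year, drop = TRUE)
  idx <- split(seq_len(nrow(rows)), key)
  out <- do.call(rbind, lapply(idx, function(ii) {
    r1 <- rows[ii[1], c("cluster_id", "year", "x_km", "y_km"), drop = FALSE]
    r1$n <- length(ii)
    r1$y <- sum(rows$outcome[ii])
    for (cv in covariates) r1[[cv]] <- mean(rows[[cv]][ii])
    r1
  }))
  rownames(out) <- NULL
  out <- out[order(out$year, out$cluster_id), , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Standardize a column to mean zero, sd one
#'
#' Returns the standardized values together with the `(mean, sd)` used, so
#' the identical transform can be re-applied to prediction-grid covariates.
#'
#' @param x numeric vector with at least two distinct values.
#' @param name column name used in error messages.
#' @return list: `values`, `mean`, `sd`.
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  m <- mean(x); s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop(sprintf("column `%s` has zero variance; cannot standardize", name),
         call. = FALSE)
  list(values = (x - m) / s, mean = m, sd = s)
}

#' @rdname standardize
#' @param z standardized values.
#' @param pars list with `mean` and `sd` as returned by `standardize`.
#' @export
unstandardize <- function(z, pars) z * pars$sd + pars$mean

#' Drop one of every highly correlated predictor pair
#'
#' For each pair with `|r| > threshold` the lower-priority member is dropped,
#' greedily in priority order (ties in the study resolved on subject-matter
#' grounds, e.g. women's over husbands' education).
#'
#' @param table data.frame of candidate predictors (numeric columns).
#' @param threshold absolute Pearson correlation above which a pair conflicts
#'   (default 0.8).
#' @param priority character vector of column names, most important first;
#'   must cover every column involved in a conflicted pair.
#' @return list: `kept` (column names), `dropped`, and `report` (data.frame of
#'   conflicted pairs with r, kept, dropped).
#' @export
prune_collinear <- function(table, threshold = 0.8, priority = names(table)) {
  cols <- names(table)
  R <- suppressWarnings(stats::cor(as.matrix(table)))
  conflicted <- which(abs(R) > threshold & upper.tri(R), arr.ind = TRUE)
  need <- unique(cols[c(conflicted)])
  if (!all(need %in% priority))
    stop("priority ranking missing for: ",
         paste(setdiff(need, priority), collapse = ", "), call. = FALSE)
  rank_of <- match(cols, priority)
  dropped <- character(0)
  report <- list()
  if (nrow(conflicted)) {
    ## visit pairs by the better priority of the two members
    ord <- order(pmin(rank_of[conflicted[, 1]], rank_of[conflicted[, 2]]))
    for (k in ord) {
      i <- conflicted[k, 1]; j <- conflicted[k, 2]
      a <- cols[i]; b <- cols[j]
      if (a %in% dropped || b %in% dropped) next
      loser <- if (rank_of[i] <= rank_of[j]) b else a
      winner <- setdiff(c(a, b), loser)
      dropped <- c(dropped, loser)
      report[[length(report) + 1L]] <- data.frame(
        var1 = a, var2 = b, r = R[i, j], kept = winner, dropped = loser)
    }
  }
  list(kept = setdiff(cols, dropped), dropped = dropped,
       report = if (length(report)) do.call(rbind, report) else
         data.frame(var1 = character(0), var2 = character(0), r = numeric(0),
                    kept = character(0), dropped = character(0)))
}

#' Extract raster values at the nearest pixel center
#'
#' No interpolation: each point receives the value of the pixel whose center
#' is nearest; a point on a pixel boundary resolves to the lower (row, then
#' column) index; points outside the extent are assigned the nearest edge
#' pixel (count reported via attribute `n_outside`).
#'
#' @param surface a [grid_raster()].
#' @param points two-column matrix of (x, y) in km.
#' @return numeric vector of pixel values (`NA` where the pixel is nodata).
#' @export
extract_at_points <- function(surface, points) {
  stopifnot(inherits(surface, "grid_raster"))
  points <- rbind(points)
  nr <- nrow(surface$values); nc <- ncol(surface$values)
  col <- nearest_pixel_index(points[, 1], surface$xmin, surface$res, nc)
  row <- nearest_pixel_index(points[, 2], surface$ymin, surface$res, nr)
  outside <- points[, 1] < surface$xmin | points[, 1] > surface$xmin + nc * surface$res |
             points[, 2] < surface$ymin | points[, 2] > surface$ymin + nr * surface$res
  out <- surface$values[cbind(row, col)]
  attr(out, "n_outside") <- sum(outside)
  out
}

#' Distance from cluster points to the nearest water feature
#'
#' Straight-line (planar km) distance to the nearest feature; points inside a
#' water polygon get 0.
#'
#' @param points two-column matrix (km).
#' @param water feature list from [read_geojson_features()] or list of
#'   coordinate matrices.
#' @return numeric vector of distances (km), `>= 0`.
#' @export
distance_to_water <- function(points, water) distance_to_features(points, water)

#' Annual mean of a per-pixel time series
#'
#' Arithmetic mean of the within-year slices, missing slices excluded per
#' pixel; a pixel (or the whole year) with no observations becomes `NA`.
#'
#' @param slices list of [grid_raster()] (or numeric vectors/matrices), all
#'   congruent, each tagged with a time.
#' @param times numeric time stamps, one per slice (e.g. decimal months).
#' @param year the year to average; slices with `floor(times) == year` enter.
#' @return object of the same kind as the slices with the annual mean, or
#'   `NA` if the year has no slices.
#' @export
annual_mean <- function(slices, times, year) {
  sel <- which(floor(times) == year)
  if (length(sel) == 0) {
    warning("no observations in year ", year)
    return(NA)
  }
  is_raster <- inherits(slices[[sel[1]]], "grid_raster")
  mats <- lapply(slices[sel], function(s) if (inherits(s, "grid_raster")) s$values else s)
  arr <- simplify2array(mats)
  m <- apply(arr, seq_len(length(dim(arr)) - 1L), mean, na.rm = TRUE)
  m[is.nan(m)] <- NA
  if (is_raster) {
    r <- slices[[sel[1]]]
    grid_raster(m, r$xmin, r$ymin, r$res)
  } else m
}

#' Convert a continuous variable to a three-level categorical form
#'
#' Default cut points are the tertiles (configurable); returns a factor with
#' levels `low`, `mid`, `high` plus the indicator design columns for the two
#' non-reference levels.
#'
#' @param x numeric vector.
#' @param cuts two interior cut points; default the 1/3 and 2/3 quantiles.
#' @param name variable name for error messages.
#' @return list: `factor`, `design` (n x 2 indicator matrix), `cuts`.
#' @export
categorize3 <- function(x, cuts = NULL, name = deparse(substitute(x))) {
  if (is.null(cuts)) cuts <- unname(quantile(x, c(1 / 3, 2 / 3)))
  if (length(unique(cuts)) < 2 || any(cuts <= min(x)) || any(cuts >= max(x)))
    stop(sprintf("cannot form 3 levels for `%s`: tied or degenerate cut points", name),
         call. = FALSE)
  f <- cut(x, c(-Inf, cuts, Inf), labels = c("low", "mid", "high"))
  design <- cbind(mid = as.numeric(f == "mid"), high = as.numeric(f == "high"))
  list(factor = f, design = design, cuts = cuts)
}

#' SAR smoothness coefficient of a surface
#'
#' Fits the pure simultaneous autoregressive model `z = rho_sar W z + e` by
#' profile maximum likelihood, with `W` the row-standardized rook-contiguity
#' weight matrix and `z` the mean-centred pixel values.  Coefficients near 1
#' indicate a smooth surface, for which nearest-pixel extraction under DHS
#' coordinate displacement is approximately unbiased; white noise gives ~0
#' and a checkerboard a negative coefficient.
#'
#' @param surface a [grid_raster()] or numeric matrix, at least 3 x 3,
#'   non-constant.
#' @return the SAR autocorrelation coefficient, in (-1, 1).
#' @export
sar_smoothness <- function(surface) {
  v <- if (inherits(surface, "grid_raster")) surface$values else as.matrix(surface)
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3 || nc < 3) stop("raster must be at least 3 x 3", call. = FALSE)
  z <- as.vector(v)
  if (sd(z) == 0) stop("constant surface: zero variance", call. = FALSE)
  z <- z - mean(z)
  n <- nr * nc
  idx <- function(r, c) (c - 1L) * nr + r
  ii <- c(); jj <- c()
  rr <- rep(seq_len(nr), nc); cc <- rep(seq_len(nc), each = nr)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    r2 <- rr + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ii <- c(ii, idx(rr[ok], cc[ok])); jj <- c(jj, idx(r2[ok], c2[ok]))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  dsum <- Matrix::rowSums(A)
  W <- A / dsum
  ## eigenvalues of W are those of the symmetric D^-1/2 A D^-1/2
  s <- 1 / sqrt(dsum)
  lam <- eigen(as.matrix(A) * outer(s, s), symmetric = TRUE, only.values = TRUE)$values
  Wz <- as.vector(W %*% z)
  lo <- 1 / min(lam) + 1e-6
  negll <- function(rho) {
    r <- z - rho * Wz
    -(sum(log1p(-rho * lam)) - (n / 2) * log(sum(r^2) / n))
  }
  optimize(negll, c(lo, 1 - 1e-6))$minimum
}
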