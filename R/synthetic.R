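## DHS-like synthetic surveys with known ground truth.  The generator states
## a world matching the study design: a few hundred clusters per survey year
## on a planar-km domain, ~30 respondents per cluster, binomial outcomes from
## a logit model over standardized covariates, a Matern space-time field at
## the survey knots, an i.i.d. location effect, and DHS-style coordinate
## displacement (urban <= 2 km, rural <= 10 km).

#' Configuration of the synthetic survey generator
#'
#' Defaults are the study's stated conditions where it states them (3 survey
#' years at knots 2007/2010.5/2014, ~30 respondents per cluster, urban 2 km /
#' rural 10 km displacement) and field-realistic choices elsewhere (domain a
#' 300 km square — a Bangladesh-like extent at reduced size; ~400 clusters
#' per year; spatial range ~50 km and spatial variance ~0.15, the scale of
#' the fitted model; non-spatial variance 0.06).
#'
#' @param bounds numeric `c(xmin, xmax, ymin, ymax)` in km; non-degenerate.
#' @param n_clusters clusters per survey year (>= 1).
#' @param urban_frac fraction of clusters flagged urban.
#' @param respondents_mean mean respondents per cluster (Poisson, truncated
#'   at `respondents_min`).
#' @param respondents_min minimum respondents per cluster (>= 1).
#' @param beta0 true intercept (logit scale).
#' @param beta true covariate coefficients (standardized scale); its length
#'   sets the number of covariate surfaces.
#' @param spde true `spde_params` of the latent field.
#' @param temporal true [temporal_spec()].
#' @param years survey years (projected onto the knots).
#' @param sigma2_nonsp variance of the i.i.d. location effect (> 0).
#' @param cov_range spatial range (km) of the covariate surfaces: `Inf` gives
#'   constant surfaces, `0` white noise.
#' @param grid_res pixel size (km) of generated surfaces.
#' @param pop_mean mean WOCBA population per pixel of the population surface.
#' @param rural_one_percent if `TRUE`, use the DHS convention that rural
#'   displacement is <= 5 km except for a random 1% of clusters (<= 10 km);
#'   default `FALSE` follows the flat 0-10 km description.
#' @param seed RNG seed; identical seed gives bit-identical output.
#' @return `sim_config` list.
#' @export
sim_config <- function(bounds = c(0, 300, 0, 300),
                       n_clusters = 400,
                       urban_frac = 0.3,
                       respondents_mean = 30,
                       respondents_min = 5,
                       beta0 = logit(0.13),
                       beta = c(-0.18, 0.08),
                       spde = spde_params_from_range(50, 0.15),
                       temporal = temporal_spec(c(2007, 2010.5, 2014), "ar1", rho = 0.3),
                       years = c(2007, 2011, 2014),
                       sigma2_nonsp = 0.06,
                       cov_range = 60,
                       grid_res = 10,
                       pop_mean = 5000,
                       rural_one_percent = FALSE,
                       seed = 1L) {
  if (length(bounds) != 4 || bounds[2] <= bounds[1] || bounds[4] <= bounds[3])
    stop("bounds must be c(xmin, xmax, ymin, ymax) with positive extents", call. = FALSE)
  if (n_clusters < 1) stop("n_clusters must be >= 1", call. = FALSE)
  if (respondents_min < 1) stop("respondents_min must be >= 1", call. = FALSE)
  if (sigma2_nonsp <= 0) stop("sigma2_nonsp must be > 0", call. = FALSE)
  stopifnot(inherits(spde, "spde_params"), inherits(temporal, "temporal_spec"))
  if (grid_res <= 0) stop("grid resolution must be positive", call. = FALSE)
  structure(list(bounds = bounds, n_clusters = n_clusters, urban_frac = urban_frac,
                 respondents_mean = respondents_mean, respondents_min = respondents_min,
                 beta0 = beta0, beta = beta, spde = spde, temporal = temporal,
                 years = years, sigma2_nonsp = sigma2_nonsp, cov_range = cov_range,
                 grid_res = grid_res, pop_mean = pop_mean,
                 rural_one_percent = rural_one_percent, seed = as.integer(seed)),
            class = "sim_config")
}

## coarse mesh used by the generator over the config domain
sim_mesh <- function(config, max_edge) {
  b <- config$bounds
  corners <- cbind(c(b[1], b[1], b[2], b[2]), c(b[3], b[4], b[3], b[4]))
  build_mesh(corners, max_edge = max_edge, cutoff = max_edge / 100,
             extension = max(max_edge, spatial_range(config$spde)))
}

#' Generate smooth covariate and population surfaces
#'
#' Covariate surfaces reuse the Matern machinery (a GMRF sampled on a coarse
#' mesh, projected to pixel centers, scaled to unit variance).  `cov_range =
#' Inf` yields constant surfaces, `0` i.i.d. white noise.  The last surface
#' returned is a nonnegative population surface (`pop`).
#'
#' @param config a [sim_config()].
#' @param n_surfaces number of covariate surfaces (default `length(beta)`).
#' @return named list of [grid_raster()] objects (`cov1`, ..., `pop`).
#' @export
gen_covariate_surfaces <- function(config, n_surfaces = length(config$beta)) {
  set.seed(derive_seed(config$seed, 11))
  b <- config$bounds
  nx <- max(2L, ceiling((b[2] - b[1]) / config$grid_res))
  ny <- max(2L, ceiling((b[4] - b[3]) / config$grid_res))
  template <- grid_raster(matrix(0, ny, nx), xmin = b[1], ymin = b[3],
                          res = config$grid_res)
  ctr <- raster_centers(template)
  out <- list()
  if (is.infinite(config$cov_range)) {
    for (k in seq_len(n_surfaces))
      out[[paste0("cov", k)]] <- grid_raster(matrix(0, ny, nx), b[1], b[3], config$grid_res)
    pop_field <- matrix(0, ny, nx)
  } else if (config$cov_range <= 0) {
    for (k in seq_len(n_surfaces))
      out[[paste0("cov", k)]] <- grid_raster(matrix(rnorm(ny * nx), ny, nx),
                                             b[1], b[3], config$grid_res)
    pop_field <- matrix(rnorm(ny * nx), ny, nx)
  } else {
    sp <- spde_params_from_range(config$cov_range, 1)
    mesh <- sim_mesh(config, max_edge = max(config$cov_range / 2.5, config$grid_res))
    Q <- spde_precision(mesh, sp)
    A <- projection_matrix(mesh, ctr)
    draws <- sample_gmrf(Q, n_surfaces + 1)
    vals <- as.matrix(A %*% draws)
    for (k in seq_len(n_surfaces)) {
      v <- vals[, k]
      v <- (v - mean(v)) / max(sd(v), 1e-12)
      out[[paste0("cov", k)]] <- grid_raster(matrix(v, ny, nx), b[1], b[3], config$grid_res)
    }
    pop_field <- matrix(vals[, n_surfaces + 1], ny, nx)
  }
  ## log-Gaussian population surface around pop_mean
  if (sd(pop_field) > 0) pop_field <- pop_field / sd(pop_field)
  out$pop <- grid_raster(config$pop_mean * exp(0.5 * pop_field - 0.125),
                         b[1], b[3], config$grid_res)
  out
}

#' Sample cluster locations with DHS-style coordinate displacement
#'
#' True locations are uniform on the domain; the released (displaced)
#' location adds a uniform random direction and uniform random distance up to
#' 2 km (urban) or 10 km (rural) — or the 5 km / 1%-at-10 km DHS convention
#' when `rural_one_percent` is set.  Displaced points falling outside the
#' domain are clipped to the boundary (count reported as attribute
#' `n_clipped`).  Both coordinate sets are returned so displacement bias can
#' be measured.
#'
#' @param config a [sim_config()].
#' @return data.frame: `cluster_id`, `year`, `x_true`, `y_true`, `x_km`,
#'   `y_km` (displaced), `urban`.
#' @export
sample_clusters <- function(config) {
  set.seed(derive_seed(config$seed, 22))
  b <- config$bounds
  rows <- list()
  idc <- 0L
  for (yr in config$years) {
    n <- config$n_clusters
    xt <- runif(n, b[1], b[2]); yt <- runif(n, b[3], b[4])
    urban <- runif(n) < config$urban_frac
    maxd <- ifelse(urban, 2, 10)
    if (config$rural_one_percent) {
      rural <- which(!urban)
      maxd[rural] <- 5
      far <- rural[runif(length(rural)) < 0.01]
      maxd[far] <- 10
    }
    ang <- runif(n, 0, 2 * pi)
    dist <- runif(n, 0, maxd)
    xd <- xt + dist * cos(ang); yd <- yt + dist * sin(ang)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = sprintf("c%04d", idc + seq_len(n)), year = yr,
      x_true = xt, y_true = yt, x_km = xd, y_km = yd, urban = urban)
    idc <- idc + n
  }
  df <- do.call(rbind, rows)
  clipped <- df$x_km < b[1] | df$x_km > b[2] | df$y_km < b[3] | df$y_km > b[4]
  df$x_km <- pmin(pmax(df$x_km, b[1]), b[2])
  df$y_km <- pmin(pmax(df$y_km, b[3]), b[4])
  attr(df, "n_clipped") <- sum(clipped)
  df
}

#' Simulate the latent space-time field at mesh vertices
#'
#' AR1 mode: `xi_t = rho xi_(t-1) + w_t` with innovations `w_t ~ N(0, Qs^-1)`
#' (spatial variance `sigma2_sp`) and `xi_1 ~ N(0, Qs^-1 / (1 - rho^2))`, so
#' every knot has marginal variance `sigma2_sp / (1 - rho^2)`.  Exchangeable
#' mode: independent knot fields with marginal variance `sigma2_sp`.
#'
#' @param mesh an `spde_mesh`.
#' @param spde true `spde_params`.
#' @param temporal a [temporal_spec()].
#' @param seed optional seed (`set.seed` applied if given).
#' @return matrix `G` x `T` of field values at vertices by knot.
#' @export
simulate_field <- function(mesh, spde, temporal, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (temporal$mode == "ar1" && abs(temporal$rho) >= 1)
    stop("|rho| must be < 1", call. = FALSE)
  Qs <- spde_precision(mesh, spde)
  T <- temporal$T
  G <- nrow(Qs)
  xi <- matrix(0, G, T)
  if (temporal$mode == "ar1") {
    rho <- temporal$rho
    xi[, 1] <- sample_gmrf(Qs, 1) / sqrt(1 - rho^2)
    if (T > 1) for (t in 2:T) xi[, t] <- rho * xi[, t - 1] + sample_gmrf(Qs, 1)
  } else {
    xi[] <- sample_gmrf(Qs, T)
  }
  xi
}

#' Simulate binomial outcomes for clusters
#'
#' `y ~ Binomial(n, plogis(beta0 + X beta + delta + lambda))`.  Clusters with
#' `n = 0` are skipped with a warning (their `y` is `NA`).
#'
#' @param n interviewed count per cluster-year.
#' @param X standardized covariate matrix (rows = clusters).
#' @param beta0,beta true fixed effects.
#' @param delta projected field value per cluster-year.
#' @param lambda location effect per cluster-year (default 0).
#' @param seed optional seed.
#' @return list: integer `y`, numeric `p` (true prevalence).
#' @export
simulate_outcomes <- function(n, X, beta0, beta, delta = 0, lambda = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  eta <- beta0 + as.vector(X %*% beta) + delta + lambda
  p <- plogis(eta)
  y <- rep(NA_integer_, length(n))
  ok <- n > 0
  if (any(!ok)) warning(sum(!ok), " cluster(s) with n = 0 skipped")
  y[ok] <- rbinom(sum(ok), n[ok], p[ok])
  list(y = y, p = p)
}

#' Generate a complete synthetic survey with known truth
#'
#' Runs the full generative chain: covariate + population surfaces, cluster
#' locations with displacement, respondents per cluster (Poisson around the
#' mean, truncated), the latent Matern space-time field on a simulation mesh,
#' i.i.d. location effects, and binomial outcomes.  Covariates entering the
#' truth are extracted at the *true* coordinates and standardized across the
#' generated clusters, so the fitted model is well-specified when smooth
#' surfaces are used.
#'
#' @param config a [sim_config()].
#' @param mesh optional `spde_mesh` for the field (a coarse default mesh over
#'   the domain is built otherwise).
#' @param constrain_field impose the model's identifiability constraints on
#'   the simulated latent effects (default `TRUE`): the field is conditioned
#'   (by kriging) to integrate to zero per knot and to be orthogonal to the
#'   fixed-effect design at the cluster locations, and the location effects
#'   are centred.  Under restricted spatial regression these constraints
#'   *define* which part of the variation belongs to `beta0`/`beta` versus
#'   the field, so a recovery test against the stated truth is only coherent
#'   in the constrained world; set `FALSE` for an unconstrained field.
#' @return list: `clusters` (data.frame with `cluster_id`, `year`, coords,
#'   `urban`, `n`, `y`, covariate columns `cov*`), `surfaces`, `mesh`,
#'   `truth` (field `xi`, `lambda`, `p`, config).
#' @export
simulate_survey <- function(config, mesh = NULL, constrain_field = TRUE) {
  surfaces <- gen_covariate_surfaces(config)
  cl <- sample_clusters(config)
  if (is.null(mesh))
    mesh <- sim_mesh(config, max_edge = max(spatial_range(config$spde) / 2.5,
                                            config$grid_res))
  set.seed(derive_seed(config$seed, 33))
  n <- pmax(rpois(nrow(cl), config$respondents_mean), config$respondents_min)
  xi <- simulate_field(mesh, config$spde, config$temporal)
  A <- projection_matrix(mesh, cbind(cl$x_true, cl$y_true))
  W <- temporal_projection(cl$year, config$temporal$knots)
  lam_by_loc <- rnorm(nrow(cl), 0, sqrt(config$sigma2_nonsp))
  covs <- sapply(seq_along(config$beta), function(k)
    extract_at_points(surfaces[[paste0("cov", k)]], cbind(cl$x_true, cl$y_true)))
  covs <- as.matrix(covs)
  colnames(covs) <- paste0("cov", seq_along(config$beta))
  Xs <- apply(covs, 2, function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v)
  if (constrain_field) {
    G <- nrow(mesh$loc); Tk <- config$temporal$T
    blocks <- lapply(seq_len(Tk), function(k) A * W[, k])
    A_st <- do.call(cbind, blocks)
    cs <- constraint_set(X = cbind(1, Xs), A_st = A_st,
                         mass = Matrix::diag(fem_matrices(mesh)$C),
                         G = G, T = Tk, n_lambda = 0)
    Qst <- spacetime_precision(spde_precision(mesh, config$spde),
                               temporal_precision(config$temporal))
    xi <- matrix(apply_constraints(as.vector(xi), cs, Q = Qst), G, Tk)
    lam_by_loc <- lam_by_loc - mean(lam_by_loc)
  }
  delta <- rowSums(as.matrix(A %*% xi) * W)
  out <- simulate_outcomes(n, Xs, config$beta0, config$beta, delta, lam_by_loc)
  clusters <- cbind(cl, n = n, y = out$y, as.data.frame(Xs))
  list(clusters = clusters, surfaces = surfaces, mesh = mesh,
       truth = list(xi = xi, lambda = lam_by_loc, delta = delta, p = out$p,
                    config = config))
}

#' Write / read a cluster table as CSV
#' @param clusters cluster data.frame.
#' @param path file path.
#' @export
write_cluster_table <- function(clusters, path) {
  write.csv(clusters, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Save / load a simulation configuration as JSON
#'
#' All fields of [sim_config()] including the SPDE and temporal components;
#' the round trip reproduces the configuration (and hence, with the same
#' seed, the identical survey).
#'
#' @param config a `sim_config`.
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  out <- config[setdiff(names(config), c("spde", "temporal"))]
  out$spde <- unclass(config$spde)
  out$temporal <- unclass(config$temporal)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  num <- as.numeric            # JSON readback must not demote doubles to int
  sim_config(bounds = num(x$bounds), n_clusters = num(x$n_clusters),
             urban_frac = num(x$urban_frac),
             respondents_mean = num(x$respondents_mean),
             respondents_min = num(x$respondents_min),
             beta0 = num(x$beta0), beta = num(x$beta),
             spde = spde_params(x$spde$kappa, x$spde$tau, x$spde$nu),
             temporal = temporal_spec(num(x$temporal$knots), x$temporal$mode,
                                      x$temporal$rho),
             years = num(x$years), sigma2_nonsp = num(x$sigma2_nonsp),
             cov_range = num(x$cov_range %||% Inf), grid_res = num(x$grid_res),
             pop_mean = num(x$pop_mean),
             rural_one_percent = isTRUE(x$rural_one_percent),
             seed = x$seed)
}
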