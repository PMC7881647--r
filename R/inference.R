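## Posterior computation for the constrained logit-binomial space-time model.
## The latent Gaussian block (beta0, beta, lambda, xi) is updated by
## independence Metropolis-Hastings from the sparse Gaussian (Laplace-style)
## approximation centred at its conditional mode.  Hyperparameters move by an
## alternation of adaptive non-centred rescale moves, joint mode-refresh
## moves, and exact Gibbs draws for the two variance components (conjugate
## gamma for the location-effect precision; univariate slice sampling for the
## field amplitude) -- an interweaving scheme.  Linear constraints are imposed
## on every draw by conditioning-by-kriging, with the exact
## conditional-density correction carried through every acceptance ratio.

## evaluate an expression, returning NULL on numerical failure; CHOLMOD
## emits a warning before erroring on an indefinite matrix, so both are
## silenced here — failure is handled by rejecting the proposal
safe_try <- function(expr) tryCatch(suppressWarnings(expr), error = function(e) NULL)

## univariate slice sampler (stepping out + shrinkage), for log-concave
## one-dimensional conditionals
slice_1d <- function(logf, x0, w = 0.5, max_steps = 30) {
  f0 <- logf(x0)
  if (!is.finite(f0)) return(x0)
  ly <- f0 + log(runif(1))
  lo <- x0 - w * runif(1); hi <- lo + w
  k <- max_steps
  while (k > 0 && logf(lo) > ly) { lo <- lo - w; k <- k - 1 }
  k <- max_steps
  while (k > 0 && logf(hi) > ly) { hi <- hi + w; k <- k - 1 }
  for (rep in seq_len(100)) {
    x1 <- runif(1, lo, hi)
    if (logf(x1) > ly) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
  x0
}

## dense k-dimensional log N(x; m, S)
dmvn_dense <- function(x, m, S) {
  k <- length(x)
  chS <- chol((S + t(S)) / 2)
  d <- backsolve(chS, x - m, transpose = TRUE)
  -0.5 * k * log(2 * pi) - sum(log(diag(chS))) - 0.5 * sum(d^2)
}

#' Fit the Bayesian geostatistical logit-binomial model by blocked MCMC
#'
#' @param data data.frame with columns `x_km`, `y_km`, `year`, `n`, `y`, and
#'   the covariate columns named in `covariates` (already standardized).
#' @param covariates character vector of design column names (may be empty).
#' @param mesh an `spde_mesh`; built automatically over the data locations
#'   when `NULL` (see `mesh_args`).
#' @param temporal a [temporal_spec()]; default: exchangeable knots at the
#'   unique survey years.
#' @param prior a [prior_spec()].
#' @param field include the Matern space-time field (default `TRUE`).
#' @param lambda include the i.i.d. location effect (default `TRUE`).
#' @param constraints impose sum-to-zero / integrate-to-zero / design
#'   orthogonality constraints (default `TRUE` when the field is on).
#' @param family `"binomial"` (the model) or `"gaussian"` (a conjugate test
#'   stub: `y ~ N(eta, gaussian_sd^2)`, `n` ignored).
#' @param gaussian_sd observation sd for the gaussian stub.
#' @param chains,iter,warmup,thin chain plan (kept draws = chains * iter / thin).
#' @param seed integer seed; identical config + seed gives identical chains.
#' @param mesh_args list overriding the automatic mesh: `max_edge`, `cutoff`,
#'   `extension`.
#' @param latent_sweeps latent-only independence updates per iteration (default 3).
#' @param fix_theta optional named vector fixing the hyperparameters
#'   (`log_kappa`, `log_sigma` = half log spatial variance, `f_rho`,
#'   `log_prec_lambda`): no hyperparameter moves are made.  Used for cheap
#'   screening fits conditional on full-model estimates.
#' @param verbose print progress.
#' @return `spdeprev_fit` object: scalar draw matrix `draws` (columns
#'   `beta0`, `beta_*`, `kappa`, `tau`, `rho`, `sigma2_nonsp`, `sigma2_sp`,
#'   `range`), `lambda_draws`, `xi_draws`, per-observation `loglik_draws`,
#'   diagnostics (`ess`, `rhat`, acceptance rates), the mesh and model
#'   layout needed for prediction.
#' @export
fit_geostat <- function(data, covariates = character(0), mesh = NULL,
                        temporal = NULL, prior = prior_spec(),
                        field = TRUE, lambda = TRUE, constraints = field,
                        family = c("binomial", "gaussian"), gaussian_sd = 1,
                        chains = 4, iter = 2000, warmup = 2000, thin = 1,
                        seed = 1L, mesh_args = list(), latent_sweeps = 3,
                        fix_theta = NULL, verbose = FALSE) {
  family <- match.arg(family)
  stopifnot(all(c("x_km", "y_km", "year", "y") %in% names(data)))
  if (family == "binomial") {
    stopifnot("n" %in% names(data))
    if (any(data$y < 0 | data$y > data$n)) stop("need 0 <= y <= n", call. = FALSE)
  }
  nobs <- nrow(data)
  if (nobs < 2) stop("need at least 2 clusters", call. = FALSE)
  y <- as.numeric(data$y)
  ntr <- if (family == "binomial") as.numeric(data$n) else rep(1, nobs)

  if (is.null(temporal)) {
    yrs <- sort(unique(data$year))
    temporal <- temporal_spec(yrs, mode = "exchangeable")
  }
  X <- if (length(covariates)) as.matrix(data[, covariates, drop = FALSE]) else
    matrix(0, nobs, 0)
  p <- ncol(X)
  Xd <- cbind(1, X)
  if (qr(Xd)$rank < ncol(Xd))
    stop("design matrix is rank deficient after preprocessing", call. = FALSE)

  ## location index for lambda
  loc_key <- paste(signif(data$x_km, 10), signif(data$y_km, 10))
  uloc <- !duplicated(loc_key)
  loc_idx <- match(loc_key, loc_key[uloc])
  L <- if (lambda) sum(uloc) else 0L

  ## mesh / projector / FEM pieces
  G <- 0L; Tk <- temporal$T; A_st <- NULL; fem <- NULL
  if (field) {
    if (is.null(mesh)) {
      ## grid-only mesh spanning the data bounding box: the field is read at
      ## observation points through the projector, so data locations need not
      ## be vertices (keeps the latent dimension modest)
      xr <- range(data$x_km); yr <- range(data$y_km)
      corners <- cbind(c(xr[1], xr[1], xr[2], xr[2]), c(yr[1], yr[2], yr[1], yr[2]))
      dd <- max(diff(xr), diff(yr), 1)
      ma <- mesh_args$max_edge %||% (dd / 8)
      mesh <- build_mesh(corners, max_edge = ma,
                         cutoff = mesh_args$cutoff %||% (ma / 20),
                         extension = mesh_args$extension %||% (dd / 3))
    }
    G <- nrow(mesh$loc)
    A_obs <- projection_matrix(mesh, cbind(data$x_km, data$y_km))
    Wt <- temporal_projection(data$year, temporal$knots)
    blocks <- lapply(seq_len(Tk), function(k) A_obs * Wt[, k])
    A_st <- do.call(cbind, blocks)
    fem <- fem_matrices(mesh)
  }

  ## latent layout: (beta0, beta) | lambda | xi
  nfix <- 1L + p
  N <- nfix + L + G * Tk
  M <- methods::as(cbind(
    Matrix::Matrix(Xd, sparse = TRUE),
    if (L) Matrix::sparseMatrix(i = seq_len(nobs), j = loc_idx, x = 1,
                                dims = c(nobs, L)) else NULL,
    A_st), "CsparseMatrix")

  ## constraints over (lambda, xi), padded with zero columns for fixed effects
  Bz <- NULL
  if (constraints && (field || L)) {
    cs <- constraint_set(X = if (field) Xd else NULL,
                         A_st = if (field) A_st else NULL,
                         mass = if (field) Matrix::diag(fem$C) else NULL,
                         G = G, T = if (field) Tk else 0L, n_lambda = L)
    Bz <- cbind(matrix(0, nrow(cs$B), nfix), cs$B)
  }

  ## hyperparameter layout
  use_rho <- field && temporal$mode == "ar1" && Tk > 1
  th_names <- c(if (field) c("log_kappa", "log_sigma"),
                if (use_rho) "f_rho",
                if (L) "log_prec_lambda")
  nth <- length(th_names)
  do_theta <- is.null(fix_theta)
  if (!do_theta && !all(th_names %in% names(fix_theta)))
    stop("fix_theta must provide: ", paste(th_names, collapse = ", "), call. = FALSE)

  ## --- fast precision assembly on fixed sparsity templates --------------
  ## The sparsity pattern of the joint prior precision never changes with
  ## theta, so P is assembled by pure value arithmetic on a precomputed
  ## template, and all Cholesky factorizations reuse a cached symbolic
  ## analysis (Matrix::update on CHMfactor objects).
  Bzt <- if (!is.null(Bz)) t(Bz) else NULL
  as_dsc <- function(x) methods::as(methods::as(
    Matrix::forceSymmetric(x), "CsparseMatrix"), "dMatrix")
  bdiag_parts <- function(...) {
    parts <- Filter(Negate(is.null), list(...))
    as_dsc(do.call(Matrix::bdiag, parts))
  }
  Dfix <- Matrix::Diagonal(nfix, x = rep(1, nfix))
  Dlam <- if (L) Matrix::Diagonal(L, x = rep(1, L)) else NULL
  if (field) {
    cdiag <- Matrix::diag(fem$C)
    Cm <- as_dsc(fem$C)
    G1 <- as_dsc(fem$G)
    G2 <- as_dsc(fem$G %*% ((1 / cdiag) * fem$G))
    Ts <- as_dsc(Cm + G1 + G2)                  # spatial template pattern
    cx  <- (Cm + 0 * Ts)@x
    g1x <- (G1 + 0 * Ts)@x
    g2x <- (G2 + 0 * Ts)@x
    ## dense lookup: (row, col) of the general expansion -> symmetric x-index
    Tidx <- Ts; Tidx@x <- as.double(seq_along(Ts@x))
    Dlookup <- as.matrix(methods::as(Tidx, "generalMatrix"))
    ## Kronecker template over a fully dense T x T temporal pattern
    QsPat <- Ts; QsPat@x <- rep(1, length(Ts@x))
    Kt <- as_dsc(Matrix::kronecker(
      as_dsc(Matrix::Matrix(1, Tk, Tk, sparse = TRUE)), QsPat))
    Kcols <- rep(seq_len(ncol(Kt)), diff(Kt@p))
    Krows <- Kt@i + 1L
    k_qt_pos <- ((Kcols - 1L) %/% G) * Tk + ((Krows - 1L) %/% G) + 1L  # col-major
    k_qs_pos <- Dlookup[cbind((Krows - 1L) %% G + 1L, (Kcols - 1L) %% G + 1L)]
    P0 <- bdiag_parts(Dfix, Dlam, Kt)
    if (length(P0@x) != nfix + L + length(Kt@x))
      stop("internal error: precision template layout mismatch")
    qs1 <- cx + 2 * g1x + g2x                   # kappa = tau = 1 values (PD)
    Qs1 <- Ts; Qs1@x <- qs1
    chQs_sym <- Matrix::Cholesky(Qs1, LDL = FALSE, perm = TRUE)
  } else {
    P0 <- bdiag_parts(Dfix, Dlam)
    Ts <- NULL
  }
  ## constraint-correction pieces: S = B P^-1 B' decomposes over the prior
  ## blocks; the field part is Kronecker algebra through Qs^-1 only, so no
  ## N-dimensional factorization is needed per hyperparameter proposal
  if (!is.null(Bz)) {
    Blam <- Bz[, nfix + seq_len(L), drop = FALSE]
    Slam0 <- Blam %*% t(Blam)
    if (field) {
      Bxi <- Bz[, nfix + L + seq_len(G * Tk), drop = FALSE]
      ## u_{r,t}: row r's weights on knot t's field block, as columns
      U_t <- lapply(seq_len(Tk), function(t)
        t(Bxi[, (t - 1) * G + seq_len(G), drop = FALSE]))
    }
  }

  build_P <- function(th) {
    dpre <- rep(1 / prior$beta_var, nfix)
    ld <- sum(log(dpre))
    lam_x <- numeric(0)
    if (L) {
      pl <- exp(th[["log_prec_lambda"]])
      lam_x <- rep(pl, L)
      ld <- ld + L * th[["log_prec_lambda"]]
    }
    kr_x <- numeric(0)
    if (field) {
      kappa <- exp(th[["log_kappa"]])
      tau <- exp(-0.5 * log(4 * pi) - th[["log_kappa"]] - th[["log_sigma"]])
      qs_x <- tau^2 * (kappa^4 * cx + 2 * kappa^2 * g1x + g2x)
      rho <- if (use_rho) tanh(th[["f_rho"]] / 2) else 0
      Qt <- as.matrix(temporal_precision(
        if (temporal$mode == "ar1" && Tk > 1)
          temporal_spec(temporal$knots, "ar1", rho)
        else temporal_spec(temporal$knots, "exchangeable")))
      kr_x <- as.vector(Qt)[k_qt_pos] * qs_x[k_qs_pos]
      Qs <- Ts; Qs@x <- qs_x
      chQs <- suppressWarnings(Matrix::update(chQs_sym, Qs))
      ldQs <- as.numeric(2 * determinant(chQs, logarithm = TRUE, sqrt = TRUE)$modulus)
      ldQt <- as.numeric(determinant(Qt, logarithm = TRUE)$modulus)
      ld <- ld + Tk * ldQs + G * ldQt
    }
    P <- P0
    P@x <- c(dpre, lam_x, kr_x)
    cterm <- 0
    if (!is.null(Bz)) {
      S <- as.matrix(Slam0) / (if (L) exp(th[["log_prec_lambda"]]) else 1)
      if (field) {
        Qti <- solve(Qt)
        Y <- lapply(U_t, function(u) as.matrix(Matrix::solve(chQs, u, system = "A")))
        for (t1 in seq_len(Tk)) for (t2 in seq_len(Tk))
          if (abs(Qti[t1, t2]) > 0)
            S <- S + Qti[t1, t2] * crossprod(U_t[[t1]], Y[[t2]])
      }
      cterm <- 0.5 * as.numeric(determinant(S, logarithm = TRUE)$modulus) +
        0.5 * nrow(Bz) * log(2 * pi)
    }
    list(P = P, logdet = ld, cterm = cterm)
  }

  ## constrained latent log prior (up to an additive constant in z)
  lp_latent <- function(z, Pb) {
    -0.5 * sum(z * as.vector(Pb$P %*% z)) + 0.5 * Pb$logdet + Pb$cterm
  }

  loglik_obs <- function(eta) {
    if (family == "binomial")
      dbinom(y, ntr, plogis(eta), log = TRUE)
    else dnorm(y, eta, gaussian_sd, log = TRUE)
  }

  lik_weights <- function(eta) {
    if (family == "binomial") {
      pr <- plogis(eta)
      W <- pmax(ntr * pr * (1 - pr), 1e-10)
      list(W = W, g = y - ntr * pr)
    } else {
      list(W = rep(1 / gaussian_sd^2, nobs), g = (y - eta) / gaussian_sd^2)
    }
  }

  ## Gaussian approximation of the latent full conditional, centred at its
  ## mode (found by Newton iteration; the binomial likelihood is log-concave
  ## so the mode is unique).  The mode depends on theta only, making the
  ## latent update an independence sampler with cheap repeated draws.
  ## fixed template for the conditional precision P + M'WM, with value maps
  ## from the P template and the crossprod pattern into the union pattern
  Ct0 <- as_dsc(Matrix::crossprod(M))
  QcT <- as_dsc(P0 + Ct0)
  qc_map <- local({
    idx_of <- function(A) {           # destination slots of A's entries in QcT
      Ai <- A; Ai@x <- as.double(seq_along(A@x))
      (Ai + 0 * QcT)@x                # 0 where QcT has no entry from A
    }
    p_in_qc <- idx_of(P0); c_in_qc <- idx_of(Ct0)
    list(p_dst = which(p_in_qc > 0), p_src = p_in_qc[p_in_qc > 0],
         c_dst = which(c_in_qc > 0), c_src = c_in_qc[c_in_qc > 0])
  })
  make_Qc <- function(Px, cpx) {
    xx <- numeric(length(QcT@x))
    xx[qc_map$p_dst] <- Px[qc_map$p_src]
    xx[qc_map$c_dst] <- xx[qc_map$c_dst] + cpx[qc_map$c_src]
    Qc <- QcT; Qc@x <- xx
    Qc
  }
  chC_sym <- NULL   # symbolic analysis cached on first (real, PD) Qc
  gapprox_mode <- function(z0, P, newton_iter = 25, tol = 1e-7) {
    z <- z0
    ch <- NULL
    for (k in seq_len(newton_iter)) {
      eta <- as.vector(M %*% z)
      lw <- lik_weights(eta)
      Mw <- M * sqrt(lw$W)
      Qc <- make_Qc(P@x, Matrix::crossprod(Mw)@x)
      if (is.null(chC_sym))
        chC_sym <<- Matrix::Cholesky(Qc, LDL = FALSE, perm = TRUE)
      ch <- suppressWarnings(Matrix::update(chC_sym, Qc))
      b <- as.vector(Matrix::crossprod(M, lw$W * eta + lw$g))
      m <- as.vector(Matrix::solve(ch, b, system = "A"))
      step <- m - z
      ## damped step for stability far from the mode
      snorm <- sqrt(mean(step^2))
      if (!is.finite(snorm)) stop("non-finite posterior at initialization", call. = FALSE)
      z <- z + if (snorm > 5) step * (5 / snorm) else step
      if (snorm < tol) break
    }
    ld <- as.numeric(2 * determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
    ga <- list(ch = ch, m = z, logdet = ld, Qc = Qc)
    if (!is.null(Bz)) {
      V <- as.matrix(Matrix::solve(ch, t(Bz), system = "A"))
      ga$V <- V
      ga$S <- as.matrix(Bz %*% V)
      if (!all(is.finite(ga$S)) || rcond(ga$S) < 1e-13)
        stop("ill-conditioned constraint system at this hyperparameter value")
      ga$logq_corr <- -dmvn_dense(rep(0, nrow(Bz)), as.vector(Bz %*% z), ga$S)
    } else ga$logq_corr <- 0
    ga
  }

  ga_sample <- function(ga) {
    zr <- rnorm(N)
    u <- Matrix::solve(ga$ch, zr, system = "Lt")
    x <- ga$m + as.vector(Matrix::solve(ga$ch, u, system = "Pt"))
    if (!is.null(Bz)) x <- x - as.vector(ga$V %*% solve(ga$S, as.vector(Bz %*% x)))
    x
  }

  ## log proposal density (constrained) at a point satisfying Bz x = 0
  ga_logq <- function(x, ga) {
    d <- x - ga$m
    -0.5 * N * log(2 * pi) + 0.5 * ga$logdet -
      0.5 * sum(d * as.vector(ga$Qc %*% d)) + ga$logq_corr
  }

  lp_theta <- function(th) {
    lp <- 0
    if (field) {
      ## priors are stated on (log kappa, log tau); the sampling scale
      ## (log kappa, log sigma) is a unit-Jacobian linear map of it
      logtau <- -0.5 * log(4 * pi) - th[["log_kappa"]] - th[["log_sigma"]]
      lp <- lp + dnorm(th[["log_kappa"]], prior$logkappa_mean,
                       sqrt(prior$logkappa_var), log = TRUE) +
        dnorm(logtau, prior$logtau_mean, sqrt(prior$logtau_var), log = TRUE)
    }
    if (use_rho)
      lp <- lp + dnorm(th[["f_rho"]], 0, sqrt(prior$rho_var), log = TRUE)
    if (L) {
      t3 <- th[["log_prec_lambda"]]
      lp <- lp + dgamma(exp(t3), shape = prior$lambda_shape,
                        rate = prior$lambda_rate, log = TRUE) + t3
    }
    lp
  }

  ## one-time self-check: the template-assembled precision must equal the
  ## reference block assembly (guards the value-layout assumptions)
  if (field) {
    th_chk <- setNames(c(log(0.7), -0.5 * log(4 * pi) - log(0.7) - log(1.3),
                         if (use_rho) 0.4, if (L) log(2))[seq_len(nth)], th_names)
    rho_chk <- if (use_rho) tanh(0.2) else 0
    Q_ref <- spacetime_precision(
      spde_precision(fem, spde_params(0.7, 1.3)),
      if (temporal$mode == "ar1" && Tk > 1)
        temporal_precision(temporal_spec(temporal$knots, "ar1", rho_chk))
      else Matrix::Diagonal(Tk))
    P_ref <- Matrix::bdiag(Matrix::Diagonal(nfix, 1 / prior$beta_var),
                           if (L) Matrix::Diagonal(L, 2), Q_ref)
    if (max(abs(build_P(th_chk)$P - P_ref)) > 1e-10)
      stop("internal error: fast precision assembly disagrees with reference")
  }

  ## initial values
  pbar <- if (family == "binomial")
    min(max(sum(y) / max(sum(ntr), 1), 0.01), 0.99) else 0.5
  init_theta <- function() {
    th <- numeric(nth); names(th) <- th_names
    if (field) {
      dd <- max(diff(range(data$x_km)), diff(range(data$y_km)), 1)
      sp0 <- spde_params_from_range(0.3 * dd, 0.3)
      th[["log_kappa"]] <- log(sp0$kappa)
      th[["log_sigma"]] <- 0.5 * log(spatial_variance(sp0))
    }
    if (use_rho) th[["f_rho"]] <- 0
    if (L) th[["log_prec_lambda"]] <- log(1 / 0.1)
    th
  }

  kept_per_chain <- floor(iter / thin)
  K <- chains * kept_per_chain
  sc_names <- c("beta0", if (p) paste0("beta_", colnames(X) %||% covariates),
                if (field) c("kappa", "tau", "sigma2_sp", "range"),
                if (use_rho) "rho",
                if (L) "sigma2_nonsp", "lp")
  draws <- matrix(NA_real_, K, length(sc_names),
                  dimnames = list(NULL, sc_names))
  lambda_draws <- if (L) matrix(NA_real_, L, K) else NULL
  eta_draws <- matrix(NA_real_, nobs, K)
  xi_draws <- if (field) matrix(NA_real_, G * Tk, K) else NULL
  loglik_draws <- matrix(NA_real_, nobs, K)
  chain_id <- integer(K)
  acc_lat <- acc_th <- 0; n_lat <- n_th <- 0

  ptr <- 0L
  for (ch_i in seq_len(chains)) {
    set.seed(derive_seed(seed, 1000 + ch_i))
    th <- if (do_theta) init_theta() else fix_theta[th_names]
    Pb <- build_P(th)
    z0 <- numeric(N); z0[1] <- if (family == "binomial") logit(pbar) else mean(y)
    ga <- gapprox_mode(z0, Pb$P)     # cached per accepted theta
    z <- ga_sample(ga)
    ll_vec <- loglik_obs(as.vector(M %*% z))
    if (!all(is.finite(ll_vec)))
      stop("non-finite posterior at initialization", call. = FALSE)
    ll <- sum(ll_vec)
    ## separate adapted step sizes: the rescale move has a high acceptance
    ## ceiling, the refresh move is capped by the latent-refresh acceptance
    lstep_r <- rep(0.25, max(nth, 1))
    lstep_f <- rep(0.15, max(nth, 1))
    ga_stale <- FALSE

    ## marginal sd of the latent field / location effect implied by theta,
    ## used by the non-centred rescaling move
    field_sd <- function(th) {
      if (!field) return(1)
      rho <- if (use_rho) tanh(th[["f_rho"]] / 2) else 0
      exp(th[["log_sigma"]]) / sqrt(1 - rho^2)
    }

    total <- warmup + iter
    for (it in seq_len(total)) {
      ## --- hyperparameter updates: alternate a non-centred rescaling move
      ## (field amplitude follows the proposed variances; deterministic
      ## transform with Jacobian) and a joint mode-refresh move (whole
      ## latent block redrawn under the proposed theta)
      if (do_theta && nth > 0) {
        ## two cheap rescale sweeps, then a refresh move every other iteration
        for (mv in c("rescale", "rescale", if (it %% 2L == 0L) "refresh")) {
          refresh <- mv == "refresh"
          th_p <- th + rnorm(nth, 0, if (refresh) lstep_f else lstep_r)
          names(th_p) <- th_names
          Pb_p <- if (max(abs(th_p)) < 12) safe_try(build_P(th_p)) else NULL
          if (is.null(Pb_p)) { n_th <- n_th + 1; next }
          if (refresh) {
            ga_p <- safe_try(gapprox_mode(ga$m, Pb_p$P))
            if (is.null(ga_p)) { n_th <- n_th + 1; next }
            z_p <- ga_sample(ga_p)
            ljac <- 0
            lq <- ga_logq(z, ga) - ga_logq(z_p, ga_p)
          } else {
            z_p <- z
            ljac <- 0
            if (field) {
              cxi <- field_sd(th_p) / field_sd(th)
              idx <- nfix + L + seq_len(G * Tk)
              z_p[idx] <- z[idx] * cxi
              ljac <- ljac + G * Tk * log(cxi)
            }
            if (L) {
              cl <- exp(-0.5 * (th_p[["log_prec_lambda"]] - th[["log_prec_lambda"]]))
              z_p[nfix + seq_len(L)] <- z[nfix + seq_len(L)] * cl
              ljac <- ljac + L * log(cl)
            }
            lq <- 0
          }
          ll_vec_p <- loglik_obs(as.vector(M %*% z_p))
          ll_p <- sum(ll_vec_p)
          la <- (ll_p + lp_latent(z_p, Pb_p) + lp_theta(th_p)) -
                (ll + lp_latent(z, Pb) + lp_theta(th)) + ljac + lq
          n_th <- n_th + 1
          if (is.finite(la) && log(runif(1)) < la) {
            th <- th_p; Pb <- Pb_p
            z <- z_p; ll <- ll_p; ll_vec <- ll_vec_p
            if (refresh) { ga <- ga_p; ga_stale <- FALSE } else ga_stale <- TRUE
            acc_th <- acc_th + 1
          }
          if (it <= warmup) {
            adj <- (min(1, exp(min(la, 0))) - (if (refresh) 0.15 else 0.30)) /
              sqrt(it)
            if (refresh) lstep_f <- pmax(exp(log(lstep_f) + adj), 1e-3)
            else lstep_r <- pmax(exp(log(lstep_r) + adj), 1e-3)
          }
        }
      }
      ## --- interleaved Gibbs draws for the variance parameters (every
      ## other iteration, so the mode rebuild coincides with the refresh
      ## move's): the location-effect precision has an exact conjugate
      ## gamma conditional given lambda (one degree of freedom absorbed by
      ## the sum-to-zero constraint); the field amplitude log sigma has a
      ## one-dimensional log-concave conditional given xi (the precision
      ## scales as 1/sigma^2 at fixed kappa, rho), sampled by slice sampling.
      ## Together with the non-centred rescale move this forms an
      ## interweaving pair, which mixes the variance components well.
      if (do_theta && it %% 2L == 0L && nth > 0) {
        th_keep <- th
        if (L) {
          lam_cur <- z[nfix + seq_len(L)]
          dfree <- L - (if (!is.null(Bz)) 1L else 0L)
          prec_new <- rgamma(1, shape = prior$lambda_shape + dfree / 2,
                             rate = prior$lambda_rate + sum(lam_cur^2) / 2)
          if (is.finite(prec_new) && prec_new > 0) {
            th[["log_prec_lambda"]] <- min(max(log(prec_new), -12), 12)
            ga_stale <- TRUE
          }
        }
        if (field) {
          xi_cur <- z[nfix + L + seq_len(G * Tk)]
          u_cur <- th[["log_sigma"]]
          zf <- numeric(N); zf[nfix + L + seq_len(G * Tk)] <- xi_cur
          q0 <- sum(zf * as.vector(Pb$P %*% zf)) * exp(2 * u_cur)  # at sigma = 1
          kf <- if (!is.null(Bz)) sum(rowSums(abs(
            Bz[, nfix + L + seq_len(G * Tk), drop = FALSE])) > 0) else 0L
          logf <- function(u) {
            logtau <- -0.5 * log(4 * pi) - th[["log_kappa"]] - u
            -(G * Tk - kf) * u - 0.5 * q0 * exp(-2 * u) +
              dnorm(logtau, prior$logtau_mean, sqrt(prior$logtau_var), log = TRUE) +
              dnorm(th[["log_kappa"]], prior$logkappa_mean,
                    sqrt(prior$logkappa_var), log = TRUE)
          }
          u_new <- slice_1d(logf, u_cur, w = 0.3)
          if (is.finite(u_new) && abs(u_new - u_cur) > 0) {
            th[["log_sigma"]] <- min(max(u_new, -10), 10)
            ga_stale <- TRUE
          }
        }
        if (ga_stale) {
          Pb_new <- safe_try(build_P(th))
          if (is.null(Pb_new)) {          # numerically bad Gibbs draw: revert
            th <- th_keep; ga_stale <- FALSE
          } else Pb <- Pb_new
          ll <- sum(ll_vec)   # likelihood unchanged; prior pieces refreshed
        }
      }
      ## --- latent-only independence updates from the cached approximation
      if (ga_stale) {
        ga_new <- safe_try(gapprox_mode(ga$m, Pb$P))
        if (!is.null(ga_new)) ga <- ga_new
        ga_stale <- FALSE
      }
      for (sw in seq_len(latent_sweeps)) {
        z_p <- ga_sample(ga)
        ll_vec_p <- loglik_obs(as.vector(M %*% z_p))
        ll_p <- sum(ll_vec_p)
        la <- (ll_p + lp_latent(z_p, Pb) - ga_logq(z_p, ga)) -
              (ll + lp_latent(z, Pb) - ga_logq(z, ga))
        n_lat <- n_lat + 1
        if (is.finite(la) && log(runif(1)) < la) {
          z <- z_p; ll <- ll_p; ll_vec <- ll_vec_p
          acc_lat <- acc_lat + 1
        }
      }
      ## --- store
      if (it > warmup && (it - warmup) %% thin == 0) {
        ptr <- ptr + 1L
        row <- c(beta0 = z[1])
        if (p) row <- c(row, setNames(z[2:(1 + p)], sc_names[2:(1 + p)]))
        if (field) {
          kap <- exp(th[["log_kappa"]])
          ta <- exp(-0.5 * log(4 * pi) - th[["log_kappa"]] - th[["log_sigma"]])
          spp <- spde_params(kap, ta, 1)
          row <- c(row, kappa = kap, tau = ta,
                   sigma2_sp = spatial_variance(spp), range = spatial_range(spp))
        }
        if (use_rho) row <- c(row, rho = tanh(th[["f_rho"]] / 2))
        if (L) row <- c(row, sigma2_nonsp = 1 / exp(th[["log_prec_lambda"]]))
        row <- c(row, lp = ll + lp_latent(z, Pb) + lp_theta(th))
        draws[ptr, ] <- row[sc_names]
        if (L) lambda_draws[, ptr] <- z[nfix + seq_len(L)]
        if (field) xi_draws[, ptr] <- z[nfix + L + seq_len(G * Tk)]
        loglik_draws[, ptr] <- ll_vec
        eta_draws[, ptr] <- as.vector(M %*% z)
        chain_id[ptr] <- ch_i
      }
      if (verbose && it %% 500 == 0)
        message(sprintf("chain %d iter %d/%d", ch_i, it, total))
    }
  }
  if (n_lat > 0 && acc_lat / n_lat < 0.01)
    stop("sampler divergence: latent acceptance below 1%", call. = FALSE)

  diag_cols <- setdiff(sc_names, "lp")
  ess <- vapply(diag_cols, function(cn) ess_draws(draws[, cn], chain_id), numeric(1))
  rhat <- vapply(diag_cols, function(cn) split_rhat(draws[, cn], chain_id), numeric(1))

  structure(list(
    draws = draws, lambda_draws = lambda_draws, xi_draws = xi_draws,
    loglik_draws = loglik_draws, eta_draws = eta_draws, chain_id = chain_id,
    mesh = mesh, temporal = temporal, prior = prior, covariates = covariates,
    field = field, lambda = lambda, use_rho = use_rho, constraints = Bz,
    G = G, T = Tk, L = L, loc_idx = loc_idx, family = family,
    data = data, y = y, ntr = ntr,
    acceptance = c(latent = if (n_lat) acc_lat / n_lat else NA,
                   hyper = if (n_th) acc_th / n_th else NA),
    ess = ess, rhat = rhat,
    seed = seed,
    config = list(chains = chains, iter = iter, warmup = warmup, thin = thin,
                  latent_sweeps = latent_sweeps)),
    class = "spdeprev_fit")
}

#' @export
print.spdeprev_fit <- function(x, ...) {
  cat(sprintf("<spdeprev_fit> %d draws (%d chains), %d obs, field=%s, lambda=%s\n",
              nrow(x$draws), x$config$chains, length(x$y), x$field, x$L > 0))
  cat(sprintf("  acceptance: latent %.2f, hyper %s\n", x$acceptance["latent"],
              ifelse(is.na(x$acceptance["hyper"]), "-",
                     sprintf("%.2f", x$acceptance["hyper"]))))
  print(posterior_summary(x))
  invisible(x)
}

## effective sample size via initial-positive-sequence autocorrelation
ess_draws <- function(x, chain_id = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4 || sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(200, n - 2), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0) break
    s <- s + ac[k]
  }
  max(1, n / (1 + 2 * s))
}

## split-chain potential scale reduction
split_rhat <- function(x, chain_id) {
  groups <- split(x, chain_id)
  halves <- unlist(lapply(groups, function(g) {
    h <- floor(length(g) / 2)
    if (h < 2) return(list(g))
    list(g[seq_len(h)], g[(h + 1):(2 * h)])
  }), recursive = FALSE)
  halves <- halves[vapply(halves, length, 1L) >= 2]
  if (length(halves) < 2) return(NA_real_)
  m <- length(halves); nn <- min(vapply(halves, length, 1L))
  halves <- lapply(halves, function(g) g[seq_len(nn)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars); B <- nn * var(means)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Posterior summaries (median and central 95% interval)
#'
#' @param fit an `spdeprev_fit` (or a numeric vector / matrix of draws).
#' @param quantity optional scalar-parameter name (column of `fit$draws`);
#'   default all scalar parameters.
#' @return data.frame with `median`, `lower` (2.5%), `upper` (97.5%),
#'   `significant` (95% interval excludes zero), `ess`, `rhat`.
#' @export
posterior_summary <- function(fit, quantity = NULL) {
  if (inherits(fit, "spdeprev_fit")) {
    cols <- quantity %||% setdiff(colnames(fit$draws), "lp")
    dm <- fit$draws[, cols, drop = FALSE]
    ess <- fit$ess[cols]; rhat <- fit$rhat[cols]
  } else {
    dm <- as.matrix(fit)
    if (is.null(colnames(dm))) colnames(dm) <- quantity %||% "draws"
    ess <- rep(NA, ncol(dm)); rhat <- rep(NA, ncol(dm))
  }
  if (nrow(dm) < 100)
    stop("need at least 100 draws for posterior summaries", call. = FALSE)
  qs <- t(apply(dm, 2, quantile, c(0.5, 0.025, 0.975), names = FALSE))
  out <- data.frame(parameter = colnames(dm), median = qs[, 1],
                    lower = qs[, 2], upper = qs[, 3],
                    significant = qs[, 2] > 0 | qs[, 3] < 0,
                    ess = as.numeric(ess), rhat = as.numeric(rhat))
  rownames(out) <- NULL
  out
}

#' Choose the temporal mode from the AR1 fit
#'
#' Returns `"exchangeable"` iff the 95% credible interval of `rho` contains
#' zero (closed interval: a bound exactly at zero keeps the simpler model);
#' the final model is then refitted under the returned mode.
#'
#' @param fit an `spdeprev_fit` fitted with `temporal` in AR1 mode.
#' @return `"ar1"` or `"exchangeable"`.
#' @export
decide_temporal_mode <- function(fit) {
  if (inherits(fit, "spdeprev_fit")) {
    if (!fit$use_rho) stop("fit has no rho; run with ar1 temporal mode", call. = FALSE)
    ci <- quantile(fit$draws[, "rho"], c(0.025, 0.975), names = FALSE)
  } else ci <- range(fit)   # allow a bare (lower, upper) pair
  if (ci[1] <= 0 && ci[2] >= 0) "exchangeable" else "ar1"
}

#' Posterior draws of prevalence at new locations
#'
#' Kriging through the latent field: per retained draw,
#' `p = plogis(beta0 + X beta + A xi(year))` with the field projected by
#' barycentric mesh weights and degree-one temporal weights.  The location
#' effect `lambda` is excluded at new locations (standard geostatistical
#' convention); set `add_lambda_noise = TRUE` to add `N(0, sigma2_nonsp)`
#' noise draws instead.
#'
#' @param fit an `spdeprev_fit`.
#' @param X covariate matrix for the new points (columns as in the fit;
#'   standardized with the training parameters).
#' @param points two-column matrix of locations (km).
#' @param year prediction year (scalar, within the knot span).
#' @param add_lambda_noise add i.i.d. location-effect noise.
#' @return matrix of prevalence draws, `nrow(points)` x n_draws.
#' @export
predict_prevalence_draws <- function(fit, X, points, year, add_lambda_noise = FALSE) {
  K <- nrow(fit$draws)
  np <- nrow(rbind(points))
  bcols <- grep("^beta_", colnames(fit$draws))
  eta <- matrix(rep(fit$draws[, "beta0"], each = np), np, K)
  if (length(bcols)) {
    X <- as.matrix(X)
    eta <- eta + X %*% t(fit$draws[, bcols, drop = FALSE])
  }
  if (fit$field) {
    A <- projection_matrix(fit$mesh, points)
    wt <- temporal_projection(year, fit$temporal$knots)[1, ]
    for (k in which(wt > 0)) {
      xi_k <- fit$xi_draws[(k - 1) * fit$G + seq_len(fit$G), , drop = FALSE]
      eta <- eta + wt[k] * as.matrix(A %*% xi_k)
    }
  }
  if (add_lambda_noise && fit$L) {
    s <- sqrt(fit$draws[, "sigma2_nonsp"])
    eta <- eta + matrix(rnorm(np * K, 0, rep(s, each = np)), np, K)
  }
  plogis(eta)
}

#' Write posterior outputs to plain-text files
#'
#' `draws.csv` (columnar scalar draws with chain id), `summary.csv`
#' (posterior summaries) and `diagnostics.json` (acceptance rates, effective
#' sample sizes, split-chain convergence statistics, seed and chain plan).
#'
#' @param fit an `spdeprev_fit`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_posterior <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "draws.csv")
  write.csv(cbind(chain = fit$chain_id, as.data.frame(fit$draws)), p1,
            row.names = FALSE)
  p2 <- file.path(dir, "summary.csv")
  write.csv(posterior_summary(fit), p2, row.names = FALSE)
  p3 <- file.path(dir, "diagnostics.json")
  jsonlite::write_json(list(
    acceptance = as.list(fit$acceptance),
    ess = as.list(fit$ess), rhat = as.list(fit$rhat),
    seed = fit$seed, config = fit$config), p3, auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(c(p1, p2, p3))
}
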