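## Separable space-time structure: the latent field lives on mesh vertices at
## a small set of time knots; its precision is the Kronecker product of a
## temporal AR1 (or exchangeable/identity) precision with the spatial SPDE
## precision.  Survey years between knots are reached by degree-one B-spline
## (linear interpolation) weights.

#' Temporal specification for the latent field
#'
#' @param knots strictly increasing numeric time knots (e.g. `c(2007, 2010.5,
#'   2014)`).  AR1 mode requires equally spaced knots.
#' @param mode `"ar1"` or `"exchangeable"` (independent knot fields).
#' @param rho AR1 coefficient, `|rho| < 1`; ignored for exchangeable mode.
#' @return `temporal_spec` object with `knots`, `mode`, `rho`, `T`.
#' @export
temporal_spec <- function(knots, mode = c("ar1", "exchangeable"), rho = NULL) {
  mode <- match.arg(mode)
  knots <- as.numeric(knots)
  if (length(knots) < 1 || is.unsorted(knots, strictly = TRUE))
    stop("knots must be strictly increasing", call. = FALSE)
  if (mode == "ar1") {
    if (length(knots) > 2 && max(abs(diff(diff(knots)))) > 1e-8)
      stop("ar1 mode requires equally spaced knots", call. = FALSE)
    if (is.null(rho)) rho <- 0
    if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  } else rho <- NULL
  structure(list(knots = knots, mode = mode, rho = rho, T = length(knots)),
            class = "temporal_spec")
}

#' AR1 precision matrix
#'
#' Tridiagonal precision of a stationary AR1 process over `T` knots.  With
#' `scale = "marginal"` (default) it is the inverse of the AR1 correlation
#' matrix, i.e. unit marginal variance; with `scale = "innovation"` it is
#' scaled so innovations have unit variance and the marginal variance is
#' `1/(1 - rho^2)` — the convention used for the latent field, whose
#' innovations carry the spatial variance.
#'
#' @param T number of knots (`>= 1`).
#' @param rho AR1 coefficient, `|rho| < 1`.
#' @param scale `"marginal"` or `"innovation"`.
#' @return sparse symmetric `T` x `T` precision matrix.
#' @export
ar1_precision <- function(T, rho, scale = c("marginal", "innovation")) {
  scale <- match.arg(scale)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (T < 1) stop("T must be >= 1", call. = FALSE)
  if (T == 1) {
    Q <- Matrix::Matrix(if (scale == "marginal") 1 else 1 - rho^2, 1, 1, sparse = TRUE)
    return(methods::as(Matrix::forceSymmetric(Q), "CsparseMatrix"))
  }
  d <- c(1, rep(1 + rho^2, T - 2), 1)
  Q <- Matrix::bandSparse(T, k = c(0, 1), symmetric = TRUE,
                          diagonals = list(d, rep(-rho, T - 1)))
  if (scale == "marginal") Q <- Q / (1 - rho^2)
  methods::as(Matrix::forceSymmetric(Q), "CsparseMatrix")
}

## Qt for a temporal_spec under the model's (innovation) convention;
## exchangeable = identity
temporal_precision <- function(tspec) {
  if (tspec$mode == "ar1")
    ar1_precision(tspec$T, tspec$rho, scale = "innovation")
  else
    methods::as(Matrix::forceSymmetric(Matrix::Diagonal(tspec$T)), "CsparseMatrix")
}

#' Separable space-time precision (Kronecker product)
#'
#' `Q = Qt %x% Qs`: the field is stacked time-block-major,
#' `xi = (xi_1', ..., xi_T')'` with each `xi_t` of length `G`, so an identity
#' `Qt` gives a block-diagonal matrix with `T` copies of `Qs`.
#'
#' @param Qs sparse spatial precision (G x G, SPD).
#' @param Qt temporal precision (T x T, SPD).
#' @return sparse `TG` x `TG` precision.
#' @export
spacetime_precision <- function(Qs, Qt) {
  if (nrow(Qs) != ncol(Qs) || nrow(Qt) != ncol(Qt))
    stop("Qs and Qt must be square", call. = FALSE)
  methods::as(Matrix::forceSymmetric(Matrix::kronecker(
    methods::as(Qt, "CsparseMatrix"), methods::as(Qs, "CsparseMatrix"))),
    "CsparseMatrix")
}

#' Degree-one B-spline weights of a year on the time knots
#'
#' Linear interpolation between the two bracketing knots: nonnegative weights
#' summing to one, an indicator vector at a knot.  No extrapolation.
#'
#' @param year numeric year(s) within `[min(knots), max(knots)]`.
#' @param knots strictly increasing knot vector.
#' @return matrix of weights, one row per year, one column per knot.
#' @export
temporal_projection <- function(year, knots) {
  knots <- as.numeric(knots)
  T <- length(knots)
  out <- matrix(0, length(year), T)
  for (i in seq_along(year)) {
    y <- year[i]
    if (y < knots[1] - 1e-9 || y > knots[T] + 1e-9)
      stop(sprintf("year %g outside knot span [%g, %g]", y, knots[1], knots[T]),
           call. = FALSE)
    if (T == 1) { out[i, 1] <- 1; next }
    k <- max(which(knots <= y + 1e-9))
    if (k == T) { out[i, T] <- 1; next }
    w <- (y - knots[k]) / (knots[k + 1] - knots[k])
    out[i, k] <- 1 - w
    out[i, k + 1] <- w
  }
  out
}

#' Binomial log-likelihood of the logit model
#'
#' `sum(dbinom(y, n, plogis(eta), log = TRUE))` where the linear predictor
#' `eta` already contains intercept, covariate effects, projected field and
#' location effect.
#'
#' @param y positive counts (0 <= y <= n).
#' @param n interviewed counts.
#' @param eta linear predictor on the logit scale.
#' @return scalar log-likelihood.
#' @export
loglik_binomial <- function(y, n, eta) {
  if (any(y < 0 | y > n)) stop("need 0 <= y <= n", call. = FALSE)
  sum(dbinom(y, n, plogis(eta), log = TRUE))
}

#' Prior specification
#'
#' Defaults follow the study's minimally informative choices:
#' `beta0, beta ~ N(0, 1000)` (second argument a variance),
#' `log((1+rho)/(1-rho)) ~ N(0, 0.15)` with 0.15 read as a *precision*
#' (variance 1/0.15; the conventional vague choice — switchable),
#' `log(tau) ~ N(0.378, 10)`, `log(kappa) ~ N(-1.64, 10)` (variances), and
#' `1/sigma2_nonsp ~ gamma(shape 1, rate 0.00005)` on the precision of the
#' location effect.
#'
#' @param beta_var variance of the normal prior on `beta0` and each `beta`.
#' @param logtau_mean,logtau_var normal prior on `log(tau)`.
#' @param logkappa_mean,logkappa_var normal prior on `log(kappa)`.
#' @param rho_par second parameter of the normal prior on the Fisher transform
#'   of `rho`.
#' @param rho_convention `"precision"` (default) or `"variance"`: how
#'   `rho_par` is read.
#' @param lambda_gamma `c(shape, rate)` of the gamma prior on `1/sigma2_nonsp`.
#' @return `prior_spec` list.
#' @export
prior_spec <- function(beta_var = 1000,
                       logtau_mean = 0.378, logtau_var = 10,
                       logkappa_mean = -1.64, logkappa_var = 10,
                       rho_par = 0.15,
                       rho_convention = c("precision", "variance"),
                       lambda_gamma = c(1, 0.00005)) {
  rho_convention <- match.arg(rho_convention)
  rho_var <- if (rho_convention == "precision") 1 / rho_par else rho_par
  structure(list(beta_var = beta_var,
                 logtau_mean = logtau_mean, logtau_var = logtau_var,
                 logkappa_mean = logkappa_mean, logkappa_var = logkappa_var,
                 rho_var = rho_var, rho_convention = rho_convention,
                 lambda_shape = lambda_gamma[1], lambda_rate = lambda_gamma[2]),
            class = "prior_spec")
}

#' Joint log-prior of model parameters
#'
#' Sum of the stated log prior densities, each evaluated in its stated
#' parameterization (normals on `beta0`/`beta`, on `log tau`, `log kappa` and
#' on the Fisher transform of `rho`; gamma on the precision `1/sigma2_nonsp`).
#' Out-of-support values return `-Inf`.
#'
#' @param params named list with any of `beta0`, `beta`, `kappa`, `tau`,
#'   `rho`, `sigma2_nonsp`.
#' @param prior a [prior_spec()].
#' @return scalar log prior density.
#' @export
log_prior <- function(params, prior = prior_spec()) {
  lp <- 0
  if (!is.null(params[["beta0"]]))
    lp <- lp + dnorm(params[["beta0"]], 0, sqrt(prior$beta_var), log = TRUE)
  if (!is.null(params[["beta"]]))
    lp <- lp + sum(dnorm(params[["beta"]], 0, sqrt(prior$beta_var), log = TRUE))
  if (!is.null(params[["tau"]])) {
    if (params[["tau"]] <= 0) return(-Inf)
    lp <- lp + dnorm(log(params[["tau"]]), prior$logtau_mean, sqrt(prior$logtau_var), log = TRUE)
  }
  if (!is.null(params[["kappa"]])) {
    if (params[["kappa"]] <= 0) return(-Inf)
    lp <- lp + dnorm(log(params[["kappa"]]), prior$logkappa_mean, sqrt(prior$logkappa_var), log = TRUE)
  }
  if (!is.null(params[["rho"]])) {
    if (abs(params[["rho"]]) >= 1) return(-Inf)
    r <- log((1 + params[["rho"]]) / (1 - params[["rho"]]))
    lp <- lp + dnorm(r, 0, sqrt(prior$rho_var), log = TRUE)
  }
  if (!is.null(params[["sigma2_nonsp"]])) {
    if (params[["sigma2_nonsp"]] <= 0) return(-Inf)
    lp <- lp + dgamma(1 / params[["sigma2_nonsp"]], shape = prior$lambda_shape,
                      rate = prior$lambda_rate, log = TRUE)
  }
  lp
}

#' Linear constraints for identifiability
#'
#' Assembles the constraint matrix `B` acting on the latent vector
#' `(lambda, xi)`:
#' * one sum-to-zero row for the location effects `lambda`;
#' * one integrate-to-zero row per time knot for the field `xi` (weights are
#'   the lumped mass, i.e. vertex areas);
#' * orthogonality rows restricting the *projected* field at the data points
#'   to the orthogonal complement of the fixed-effect design (rows `Q' A_st`
#'   with `Q` from the thin QR of the design matrix) — the restricted spatial
#'   regression device against spatial confounding.
#'
#' @param X design matrix including the intercept column (n x (p+1)), or
#'   `NULL` to skip orthogonality rows.
#' @param A_st sparse space-time projection matrix (n x TG), or `NULL`.
#' @param mass vertex lumped-mass weights (length G), or `NULL` for unit
#'   weights.
#' @param G,T field dimensions.
#' @param n_lambda number of location effects (0 to skip the lambda row).
#' @return `constraint_set`: list with dense matrix `B` (k x (n_lambda + TG))
#'   and row labels.
#' @export
constraint_set <- function(X = NULL, A_st = NULL, mass = NULL, G, T, n_lambda = 0) {
  N <- n_lambda + G * T
  rows <- list(); labels <- character(0)
  if (n_lambda > 0) {
    r <- numeric(N); r[seq_len(n_lambda)] <- 1
    rows <- c(rows, list(r)); labels <- c(labels, "sum_lambda")
  }
  w <- if (is.null(mass)) rep(1, G) else as.numeric(mass)
  for (t in seq_len(T)) {
    r <- numeric(N)
    r[n_lambda + (t - 1) * G + seq_len(G)] <- w / sum(w)
    rows <- c(rows, list(r)); labels <- c(labels, sprintf("int_zero_knot%d", t))
  }
  if (!is.null(X) && !is.null(A_st)) {
    qr_q <- qr.Q(qr(as.matrix(X)))
    O <- as.matrix(Matrix::crossprod(methods::as(A_st, "CsparseMatrix"), qr_q))  # TG x (p+1)
    for (j in seq_len(ncol(O))) {
      r <- numeric(N)
      r[n_lambda + seq_len(G * T)] <- O[, j]
      rows <- c(rows, list(r)); labels <- c(labels, sprintf("orth_design%d", j))
    }
  }
  B <- do.call(rbind, rows)
  ## drop numerically dependent rows (QR with pivoting)
  qrB <- qr(t(B))
  rank <- qrB$rank
  if (rank < nrow(B)) {
    keep <- sort(qrB$pivot[seq_len(rank)])
    B <- B[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  structure(list(B = B, labels = labels, n_lambda = n_lambda, G = G, T = T),
            class = "constraint_set")
}

#' Apply linear constraints to a latent draw (conditioning by kriging)
#'
#' Corrects a draw `x` so that `B x = 0`, by the kriging update
#' `x - Sigma B' (B Sigma B')^-1 B x`, where `Sigma` is the covariance used
#' for conditioning.  With `Q` the sparse precision of `x`, `Sigma B'` is
#' obtained by sparse solves; with `Q = NULL` the Euclidean projection is
#' used.  The correction is idempotent and leaves conforming draws unchanged.
#'
#' @param x latent draw (vector or matrix with draws in columns), length
#'   `ncol(B)`.
#' @param constraints a [constraint_set()] (or plain matrix `B`).
#' @param Q optional sparse precision matrix of `x` for proper conditioning.
#' @return corrected draw(s), same shape as `x`.
#' @export
apply_constraints <- function(x, constraints, Q = NULL) {
  B <- if (inherits(constraints, "constraint_set")) constraints$B else as.matrix(constraints)
  if (qr(B)$rank < nrow(B)) stop("constraint rows are rank deficient", call. = FALSE)
  xm <- as.matrix(x)
  if (is.null(Q)) {
    V <- t(B)                             # Sigma = I
  } else {
    ch <- Matrix::Cholesky(methods::as(Q, "symmetricMatrix"), LDL = FALSE, perm = TRUE)
    V <- as.matrix(Matrix::solve(ch, t(B), system = "A"))   # Q^-1 B'
  }
  S <- B %*% V                            # B Sigma B'
  corr <- V %*% solve(S, B %*% xm)
  out <- xm - corr
  if (is.vector(x)) drop(out) else out
}
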