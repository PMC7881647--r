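## Sparse Matern precision via the SPDE finite-element route: the Matern
## field with smoothness nu on R^2 solves a (fractional) SPDE whose
## finite-element discretization on the mesh yields a sparse precision.
## nu = 1 (operator order alpha = 2) is assembled exactly from the mass and
## stiffness matrices with mass lumping; nu = 0.5 (alpha = 1.5) uses a dense
## matrix power of the scaled operator and is intended for moderate meshes
## (it is the model's sensitivity setting, not the default).

#' Matern-SPDE parameter set
#'
#' @param kappa spatial scaling parameter (1/km); larger kappa = shorter range.
#' @param tau precision parameter of the SPDE; together with kappa it fixes
#'   the marginal variance.
#' @param nu smoothness, fixed at 1 (default) or 0.5.
#' @return `spde_params` object.
#' @export
spde_params <- function(kappa, tau, nu = 1) {
  stop_if_not_scalar_pos(kappa, "kappa")
  stop_if_not_scalar_pos(tau, "tau")
  if (!nu %in% c(1, 0.5)) stop("nu must be 1 or 0.5", call. = FALSE)
  structure(list(kappa = kappa, tau = tau, nu = nu), class = "spde_params")
}

#' @export
print.spde_params <- function(x, ...) {
  cat(sprintf("<spde_params> kappa=%.4g tau=%.4g nu=%g  (sigma2_sp=%.4g, range=%.4g km)\n",
              x$kappa, x$tau, x$nu, spatial_variance(x), spatial_range(x)))
  invisible(x)
}

#' Matern correlation function
#'
#' `C(d) = (kappa d)^nu K_nu(kappa d)` normalized so that `C(0) = 1`
#' (i.e. divided by `2^(nu-1) Gamma(nu)`), with `K_nu` the modified Bessel
#' function of the second kind.  Strictly decreasing in `d`.
#'
#' @param d distance(s), km, `>= 0`.
#' @param params an `spde_params` object (or list with kappa, nu).
#' @return correlation values in `[0, 1]`.
#' @export
matern_correlation <- function(d, params) {
  if (any(d < 0)) stop("distance must be >= 0", call. = FALSE)
  kappa <- params$kappa; nu <- params$nu
  u <- kappa * d
  out <- ifelse(u == 0, 1, u^nu * besselK(u, nu) / (2^(nu - 1) * gamma(nu)))
  out[u > 700] <- 0                        # besselK underflow guard
  out
}

#' Spatial range of the Matern field
#'
#' `R = sqrt(8 nu) / kappa`, the distance at which correlation becomes
#' negligible (about 0.14 at nu = 1).
#' @param params an `spde_params`.
#' @export
spatial_range <- function(params) {
  if (params$kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  sqrt(8 * params$nu) / params$kappa
}

#' Marginal variance of the Matern field
#'
#' `sigma2_sp = Gamma(nu) / (Gamma(nu + 1) (4 pi) kappa^(2 nu) tau^2)`,
#' which at the default nu = 1 is the familiar `1 / (4 pi kappa^2 tau^2)`.
#' @param params an `spde_params`.
#' @export
spatial_variance <- function(params) {
  if (params$kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  with(params, gamma(nu) / (gamma(nu + 1) * 4 * pi * kappa^(2 * nu) * tau^2))
}

#' kappa and tau from range and variance (convenience inverse)
#' @param range spatial range R in km.
#' @param sigma2 marginal variance.
#' @param nu smoothness (1 or 0.5).
#' @return `spde_params`.
#' @export
spde_params_from_range <- function(range, sigma2, nu = 1) {
  kappa <- sqrt(8 * nu) / range
  tau <- sqrt(gamma(nu) / (gamma(nu + 1) * 4 * pi * kappa^(2 * nu) * sigma2))
  spde_params(kappa, tau, nu)
}

#' Finite-element matrices of a mesh
#'
#' Lumped mass matrix `C` (diagonal, vertex areas) and stiffness matrix `G`
#' of piecewise-linear basis functions, the building blocks of the SPDE
#' precision.
#'
#' @param mesh an `spde_mesh`.
#' @return list with sparse `C` (diagonal) and `G`.
#' @export
fem_matrices <- function(mesh) {
  loc <- mesh$loc; tri <- mesh$tri
  nv <- nrow(loc)
  p1 <- loc[tri[, 1], , drop = FALSE]
  p2 <- loc[tri[, 2], , drop = FALSE]
  p3 <- loc[tri[, 3], , drop = FALSE]
  ## edge vectors opposite each vertex
  e1 <- p3 - p2; e2 <- p1 - p3; e3 <- p2 - p1
  area <- 0.5 * abs(e3[, 1] * (-e2[, 2]) - e3[, 2] * (-e2[, 1]))
  area <- pmax(area, 1e-300)
  gij <- function(ea, eb) rowSums(ea * eb) / (4 * area)
  ii <- c(tri[, 1], tri[, 2], tri[, 3], tri[, 1], tri[, 1], tri[, 2],
          tri[, 2], tri[, 3], tri[, 3])
  jj <- c(tri[, 1], tri[, 2], tri[, 3], tri[, 2], tri[, 3], tri[, 1],
          tri[, 3], tri[, 1], tri[, 2])
  xx <- c(gij(e1, e1), gij(e2, e2), gij(e3, e3), gij(e1, e2), gij(e1, e3),
          gij(e2, e1), gij(e2, e3), gij(e3, e1), gij(e3, e2))
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nv, nv))
  cdiag <- as.vector(Matrix::sparseMatrix(
    i = c(tri[, 1], tri[, 2], tri[, 3]), j = rep(1L, 3 * nrow(tri)),
    x = rep(area / 3, 3), dims = c(nv, 1)))
  list(C = Matrix::Diagonal(x = cdiag), G = methods::as(G, "CsparseMatrix"))
}

#' Sparse SPDE precision matrix of the Matern field
#'
#' For nu = 1: `Q = tau^2 (kappa^4 C + 2 kappa^2 G + G C^-1 G)` with lumped
#' mass `C`; sparse, symmetric positive definite.  For nu = 0.5 the
#' half-integer operator power is computed by dense eigendecomposition of the
#' symmetrized operator (exact up to discretization, but dense — use on
#' moderate meshes only).
#'
#' @param mesh an `spde_mesh` (or a precomputed `fem_matrices()` list).
#' @param params an `spde_params`.
#' @return sparse symmetric positive-definite precision (`nrow(mesh$loc)` square).
#' @export
spde_precision <- function(mesh, params) {
  stopifnot(inherits(params, "spde_params"))
  fem <- if (inherits(mesh, "spde_mesh")) fem_matrices(mesh) else mesh
  kappa <- params$kappa; tau <- params$tau
  C <- fem$C; G <- fem$G
  cinv <- 1 / Matrix::diag(C)
  if (params$nu == 1) {
    GCG <- G %*% (cinv * G)
    Q <- tau^2 * (kappa^4 * C + 2 * kappa^2 * G + GCG)
  } else {
    ## alpha = nu + 1 = 1.5: Q = tau^2 C^1/2 (C^-1/2 K C^-1/2)^1.5 C^1/2
    K <- kappa^2 * C + G
    s <- sqrt(cinv)
    M <- as.matrix(K) * outer(s, s)
    eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
    lam <- pmax(eg$values, 1e-12)
    Mp <- eg$vectors %*% (lam^1.5 * t(eg$vectors))
    Q <- tau^2 * (Mp * outer(1 / s, 1 / s))
    Q <- methods::as(Matrix::Matrix(Q, sparse = TRUE), "CsparseMatrix")
  }
  Matrix::forceSymmetric(Q)
}

#' Sample a zero-mean GMRF from its sparse precision
#'
#' Draws via the permuted sparse Cholesky factor `Q = P' L L' P`:
#' `x = P' L^-T z`, `z ~ N(0, I)`.
#'
#' @param Q sparse symmetric positive-definite precision matrix.
#' @param n number of independent draws.
#' @return matrix, `nrow(Q)` x `n`.
#' @export
sample_gmrf <- function(Q, n = 1) {
  ch <- Matrix::Cholesky(methods::as(Q, "symmetricMatrix"), LDL = FALSE, perm = TRUE)
  z <- matrix(rnorm(nrow(Q) * n), nrow(Q), n)
  u <- Matrix::solve(ch, z, system = "Lt")
  as.matrix(Matrix::solve(ch, u, system = "Pt"))
}

#' Export / import a sparse matrix in coordinate (triplet) text format
#'
#' One `i j x` line per nonzero, 1-based indices, preceded by a header line
#' `nrow ncol nnz`; symmetric matrices are expanded to general form.
#'
#' @param Q a sparse matrix.
#' @param path file path.
#' @export
write_sparse_triplet <- function(Q, path) {
  Tm <- methods::as(methods::as(Q, "generalMatrix"), "TsparseMatrix")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d %d", nrow(Tm), ncol(Tm), length(Tm@x)), con)
  writeLines(sprintf("%d %d %.17g", Tm@i + 1L, Tm@j + 1L, Tm@x), con)
  invisible(path)
}

#' @rdname write_sparse_triplet
#' @export
read_sparse_triplet <- function(path) {
  hd <- scan(path, nlines = 1, quiet = TRUE)
  m <- matrix(scan(path, skip = 1, quiet = TRUE), ncol = 3, byrow = TRUE)
  Matrix::sparseMatrix(i = m[, 1], j = m[, 2], x = m[, 3],
                       dims = c(hd[1], hd[2]))
}
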