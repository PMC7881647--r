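#' @importFrom stats dbinom dnorm optimize qnorm quantile rbinom rnorm rpois
#'   runif sd var median aggregate plogis qlogis dgamma rgamma setNames
#' @importFrom methods as is
#' @importFrom Matrix determinant solve t isSymmetric diag
#' @importFrom utils head read.csv write.csv
NULL

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}

#' Deterministic small jitter derived from coordinates
#'
#' Used to break cocircular degeneracies in mesh refinement grids; purely a
#' function of the coordinates, so identical inputs give identical meshes.
#' @noRd
coord_hash_jitter <- function(xy, scale) {
  h1 <- sin(xy[, 1] * 127.1 + xy[, 2] * 311.7) * 43758.5453
  h2 <- sin(xy[, 1] * 269.5 + xy[, 2] * 183.3) * 28001.8384
  cbind(h1 - floor(h1) - 0.5, h2 - floor(h2) - 0.5) * (2 * scale)
}

## split a master seed into reproducible sub-seeds (kept < 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629)
}
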