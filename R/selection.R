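## Model comparison and validation: DIC and the CPO-based marginal
## predictive likelihood, the two-stage variable selection (functional form
## per predictor, then all subsets), and k-fold cross-validation with
## kriging prediction of held-out clusters.

#' Posterior-median hyperparameters of a fit, on the sampling scale
#'
#' Named vector (`log_kappa`, `log_sigma`, `f_rho`, `log_prec_lambda`)
#' suitable for `fit_geostat(fix_theta = )` screening fits.
#'
#' @param fit an `spdeprev_fit` with a field and/or location effect.
#' @return named numeric vector.
#' @export
theta_hat <- function(fit) {
  d <- fit$draws
  out <- c()
  if (fit$field) {
    out <- c(out,
             log_kappa = log(median(d[, "kappa"])),
             log_sigma = 0.5 * log(median(d[, "sigma2_sp"])))
  }
  if (fit$use_rho) {
    r <- median(d[, "rho"])
    out <- c(out, f_rho = log((1 + r) / (1 - r)))
  }
  if (fit$L) out <- c(out, log_prec_lambda = -log(median(d[, "sigma2_nonsp"])))
  out
}

#' Deviance information criterion of a fitted model
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance and
#' `pD = Dbar - Dhat`, the deviance evaluated at the posterior mean of the
#' linear predictor (the natural plug-in for a latent Gaussian model).
#'
#' @param fit an `spdeprev_fit`.
#' @return list: `dic`, `dbar`, `dhat`, `pd`.
#' @export
dic <- function(fit) {
  ll <- fit$loglik_draws
  if (is.null(ll) || ncol(ll) < 2) stop("need at least 2 draws", call. = FALSE)
  dev_draws <- -2 * colSums(ll)
  dbar <- mean(dev_draws)
  eta_hat <- rowMeans(fit$eta_draws)
  ll_hat <- if (fit$family == "binomial")
    dbinom(fit$y, fit$ntr, plogis(eta_hat), log = TRUE)
  else dnorm(fit$y, eta_hat, 1, log = TRUE)
  dhat <- -2 * sum(ll_hat)
  pd <- dbar - dhat
  list(dic = dbar + pd, dbar = dbar, dhat = dhat, pd = pd)
}

#' Conditional predictive ordinates
#'
#' Leave-one-out predictive density of each observation, approximated by the
#' harmonic mean of its per-draw likelihood: `CPO_i = 1 / mean(1 / f(y_i |
#' draw))`.  Observations whose CPO underflows to zero are flagged.
#'
#' @param fit an `spdeprev_fit`.
#' @return list: `cpo` (vector), `flagged` (indices with zero CPO).
#' @export
cpo <- function(fit) {
  ll <- fit$loglik_draws
  if (is.null(ll) || ncol(ll) < 2) stop("need at least 2 draws", call. = FALSE)
  ## log CPO_i = -logmeanexp(-ll_i.)
  neg <- -ll
  mx <- apply(neg, 1, max)
  lme <- mx + log(rowMeans(exp(neg - mx)))
  logcpo <- -lme
  cpo_v <- exp(logcpo)
  flagged <- which(!is.finite(logcpo) | cpo_v == 0)
  if (length(flagged))
    warning("CPO numerically zero for observation(s): ",
            paste(flagged, collapse = ", "))
  list(cpo = cpo_v, logcpo = logcpo, flagged = flagged)
}

#' Marginal predictive likelihood score
#'
#' `MPL = -sum(log CPO_i)`; smaller is better.  Uses the harmonic-mean CPO
#' approximation of [cpo()].
#'
#' @param fit an `spdeprev_fit`.
#' @return scalar MPL.
#' @export
mpl <- function(fit) -sum(cpo(fit)$logcpo)

#' Choose linear vs three-level categorical form for one predictor
#'
#' Fits two univariate geostatistical models — the standardized linear form
#' and the tertile-categorical form — and returns the form preferred by the
#' criterion (DIC by default; when DIC and MPL disagree the configured
#' criterion wins and the disagreement is reported).
#'
#' @param data cluster data.frame (see [fit_geostat()]).
#' @param variable name of a continuous column of `data`.
#' @param criterion `"dic"` or `"mpl"` — the arbiter when the two disagree.
#' @param cuts optional interior cut points for the categorical form.
#' @param fit_args list of arguments passed on to [fit_geostat()] (chain
#'   plan, mesh, temporal spec, ...).
#' @return list: `form` (`"linear"` or `"categorical3"`), `table`
#'   (DIC and MPL for both forms), `agreement` (did DIC and MPL agree).
#' @export
select_form <- function(data, variable, criterion = c("dic", "mpl"),
                        cuts = NULL, fit_args = list()) {
  criterion <- match.arg(criterion)
  x <- data[[variable]]
  if (is.null(x)) stop("no column `", variable, "` in data", call. = FALSE)
  dl <- data
  dl$.lin <- standardize(x, name = variable)$values
  cat3 <- categorize3(x, cuts = cuts, name = variable)
  dc <- data
  dc$.mid <- cat3$design[, "mid"]; dc$.high <- cat3$design[, "high"]
  f_lin <- do.call(fit_geostat, c(list(data = dl, covariates = ".lin"), fit_args))
  f_cat <- do.call(fit_geostat, c(list(data = dc, covariates = c(".mid", ".high")),
                                  fit_args))
  tab <- data.frame(form = c("linear", "categorical3"),
                    dic = c(dic(f_lin)$dic, dic(f_cat)$dic),
                    mpl = c(mpl(f_lin), mpl(f_cat)))
  pick <- function(crit) tab$form[which.min(tab[[crit]])]
  agreement <- identical(pick("dic"), pick("mpl"))
  list(form = pick(criterion), table = tab, agreement = agreement)
}

#' All-subsets covariate selection by DIC / MPL
#'
#' Fits the geostatistical model for every subset of the candidate
#' predictors (including the empty model) at screening settings and ranks
#' them; the winning subset is refit at the final settings.
#'
#' @param data cluster data.frame.
#' @param candidates character vector of candidate covariate columns
#'   (standardized); at most `cap`.
#' @param criterion `"dic"` (default) or `"mpl"`.
#' @param cap guard rail on the number of candidates (2^k fits).
#' @param fit_args screening-fit arguments for [fit_geostat()].
#' @param final_args overrides for the final refit (defaults to `fit_args`).
#' @param screen_fix_hyper hold the hyperparameters at the full-candidate
#'   model's posterior medians during screening (default `TRUE`); see the
#'   methods vignette for why this matters.
#' @return `selection_report`: `table` (one row per subset with dic, mpl),
#'   `chosen` (character vector of retained predictors), `final_fit`.
#' @export
all_subsets <- function(data, candidates, criterion = c("dic", "mpl"),
                        cap = 15, fit_args = list(), final_args = fit_args,
                        screen_fix_hyper = TRUE) {
  criterion <- match.arg(criterion)
  k <- length(candidates)
  if (k > cap)
    stop("more than ", cap, " candidates (", k,
         "): prune the candidate list first", call. = FALSE)
  ## screening fits condition on the hyperparameters estimated once from the
  ## full-candidate model: subset ranking then reflects covariate structure
  ## rather than Monte-Carlo noise in the variance parameters
  screen_args <- fit_args
  if (screen_fix_hyper) {
    f_full <- do.call(fit_geostat, c(list(data = data, covariates = candidates),
                                     fit_args))
    screen_args$fix_theta <- theta_hat(f_full)
  }
  subsets <- lapply(0:(2^k - 1), function(m) candidates[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
  rows <- vector("list", length(subsets))
  for (s in seq_along(subsets)) {
    f <- do.call(fit_geostat, c(list(data = data, covariates = subsets[[s]]),
                                screen_args))
    rows[[s]] <- data.frame(
      subset = paste(subsets[[s]], collapse = "+"),
      size = length(subsets[[s]]),
      dic = dic(f)$dic, mpl = mpl(f))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab[[criterion]]), ]
  rownames(tab) <- NULL
  chosen <- subsets[[which.min(vapply(rows, function(r) r[[criterion]], 1))]]
  final_fit <- do.call(fit_geostat, c(list(data = data, covariates = chosen),
                                      final_args))
  structure(list(table = tab, chosen = chosen, criterion = criterion,
                 final_fit = final_fit),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d subsets ranked by %s; chosen: {%s}\n",
              nrow(x$table), x$criterion,
              paste(x$chosen, collapse = ", ")))
  print(head(x$table, 5))
  invisible(x)
}

#' k-fold cross-validation of the geostatistical model
#'
#' Survey clusters are randomly partitioned into `k` folds; for each fold
#' the model is refit on the remaining clusters and the held-out clusters
#' receive posterior predictive prevalence (median and central 95% interval)
#' by kriging through the latent field (the location effect is excluded at
#' new locations).  Reported metrics follow the survey-validation
#' convention: mean error = mean(observed prevalence - predicted median), and
#' coverage = percentage of held-out observed prevalences inside their 95%
#' interval.
#'
#' @param data cluster data.frame.
#' @param covariates covariate column names for the model.
#' @param k number of folds (default 10); needs at least `k` clusters.
#' @param seed fold-assignment seed.
#' @param predictive `"observed"` (default): the 95% interval is the full
#'   posterior predictive of the observed prevalence `y/n` — location-effect
#'   noise plus binomial sampling — so a well-specified model attains
#'   near-nominal coverage; `"latent"`: the interval covers latent prevalence
#'   only (what a risk map reports), which on cluster data sits well below
#'   nominal because observed `y/n` carries binomial noise.
#' @param fit_args arguments for the per-fold [fit_geostat()] refits.
#' @return `cv_result`: `folds` (assignment per row), `table` (per-fold mean
#'   error and coverage), `mean_error` (prevalence units), `coverage_pct`,
#'   and per-observation predictions `pred`.
#' @export
cross_validate <- function(data, covariates = character(0), k = 10,
                           seed = 1L, predictive = c("observed", "latent"),
                           fit_args = list()) {
  predictive <- match.arg(predictive)
  nobs <- nrow(data)
  if (nobs < k) stop("need at least k clusters", call. = FALSE)
  set.seed(derive_seed(seed, 77))
  folds <- sample(rep(seq_len(k), length.out = nobs))
  pred <- data.frame(row = seq_len(nobs), obs = data$y / data$n,
                     median = NA_real_, lower = NA_real_, upper = NA_real_)
  for (fold in seq_len(k)) {
    hold <- which(folds == fold)
    if (length(hold) == 0) stop("fold ", fold, " is empty", call. = FALSE)
    train <- data[-hold, , drop = FALSE]
    f <- do.call(fit_geostat, c(list(data = train, covariates = covariates),
                                fit_args))
    for (yr in unique(data$year[hold])) {
      hh <- hold[data$year[hold] == yr]
      Xh <- if (length(covariates))
        as.matrix(data[hh, covariates, drop = FALSE]) else
        matrix(0, length(hh), 0)
      pts <- cbind(data$x_km[hh], data$y_km[hh])
      pd <- predict_prevalence_draws(f, Xh, pts, yr)
      pred$median[hh] <- apply(pd, 1, median)
      if (predictive == "observed") {
        ppd <- predict_prevalence_draws(f, Xh, pts, yr, add_lambda_noise = TRUE)
        ystar <- matrix(rbinom(length(ppd), rep(data$n[hh], ncol(ppd)), ppd),
                        nrow(ppd)) / data$n[hh]
        qs <- t(apply(ystar, 1, quantile, c(0.025, 0.975), names = FALSE))
      } else {
        qs <- t(apply(pd, 1, quantile, c(0.025, 0.975), names = FALSE))
      }
      pred$lower[hh] <- qs[, 1]; pred$upper[hh] <- qs[, 2]
    }
  }
  covered <- pred$obs >= pred$lower & pred$obs <= pred$upper
  err <- pred$obs - pred$median
  tab <- data.frame(
    fold = seq_len(k),
    n = as.vector(table(folds)),
    mean_error = vapply(seq_len(k), function(f) mean(err[folds == f]), 1),
    coverage_pct = vapply(seq_len(k), function(f) 100 * mean(covered[folds == f]), 1))
  structure(list(folds = folds, table = tab, pred = pred,
                 mean_error = mean(err), coverage_pct = 100 * mean(covered)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds: mean error %+.4f (prevalence), 95%% coverage %.1f%%\n",
              nrow(x$table), x$mean_error, x$coverage_pct))
  invisible(x)
}

#' Write a selection report or cross-validation result to disk
#'
#' CSV for the tabular part plus a JSON sidecar with the chosen subset /
#' pooled metrics and fold assignments, for reproducibility.
#'
#' @param x a `selection_report` or `cv_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "selection_report")) {
    p1 <- file.path(dir, "subsets.csv")
    write.csv(x$table, p1, row.names = FALSE)
    p2 <- file.path(dir, "selection.json")
    jsonlite::write_json(list(chosen = x$chosen, criterion = x$criterion),
                         p2, auto_unbox = TRUE)
  } else if (inherits(x, "cv_result")) {
    p1 <- file.path(dir, "cv_folds.csv")
    write.csv(cbind(fold = x$folds, x$pred), p1, row.names = FALSE)
    p2 <- file.path(dir, "cv.json")
    jsonlite::write_json(list(mean_error = x$mean_error,
                              coverage_pct = x$coverage_pct,
                              per_fold = x$table), p2, auto_unbox = TRUE,
                         digits = NA)
  } else stop("unsupported object", call. = FALSE)
  invisible(c(p1, p2))
}
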