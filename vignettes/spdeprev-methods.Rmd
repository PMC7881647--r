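---
title: "Model-based geostatistics for cluster-survey prevalence: methods and design notes"
author: "spdeprev developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based geostatistics for cluster-survey prevalence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

National household surveys of the DHS type interview roughly 30 women in each
of several hundred sampling clusters, record binary health outcomes (here:
self-reported reproductive-tract-infection symptoms among women aged 15-49),
and release cluster coordinates only after random displacement (up to 2 km for
urban, up to 10 km for rural clusters). The analytical goal is a model-based
map: prevalence on a fine (5 km) grid with honest uncertainty, aggregated to
administrative units with population weighting, and compared across survey
years. `spdeprev` implements that pipeline end to end, with a synthetic-data
generator in place of the restricted microdata so every stage is testable.

## The model

For cluster $i$ in year $t$, with $n_{it}$ women interviewed and $Y_{it}$
reporting symptoms,

$$Y_{it} \sim \mathrm{Binomial}(n_{it},\, p_{it}), \qquad
\operatorname{logit} p_{it} = \beta_0 + x_{it}^\top\beta + \delta_{it} + \lambda_i,$$

where $\lambda_i \sim N(0, \sigma^2_{nonsp})$ is an i.i.d. location effect and
$\delta_{it}$ is a space-time Gaussian field evaluated at the cluster. The
field lives on a triangulated mesh at a small set of time knots: $\delta_{it}
= \sum_g a_{ig}\, \xi_{g}(t)$ with barycentric weights $a_{ig}$, and years
between knots reached by degree-one B-spline (linear) weights. The knot
fields have the separable precision $Q = Q_t \otimes Q_s$: $Q_s$ is the
sparse SPDE (finite-element) representation of a Matern field with smoothness
$\nu = 1$, scaling $\kappa$ (1/km) and precision parameter $\tau$, giving
correlation $C(d) = (\kappa d) K_1(\kappa d)$, variance $\sigma^2_{sp} =
1/(4\pi\kappa^2\tau^2)$ and range $R = \sqrt{8\nu}/\kappa$ (correlation
$\approx 0.14$ at $R$); $Q_t$ is either a stationary AR1 over equally spaced
knots or the identity (exchangeable). Following the source convention, the
AR1 innovations carry the spatial variance and the first knot is scaled by
$1/(1-\rho^2)$, so every knot has marginal variance
$\sigma^2_{sp}/(1-\rho^2)$.

Priors are minimally informative: $\beta_0, \beta \sim N(0, 1000)$ (variance),
$\log\tau \sim N(0.378, 10)$, $\log\kappa \sim N(-1.64, 10)$,
$\log\{(1+\rho)/(1-\rho)\} \sim N(0, 0.15)$ with 0.15 read as a *precision*
(the conventional vague choice; a `variance` reading is switchable in
`prior_spec()`), and $1/\sigma^2_{nonsp} \sim \mathrm{Gamma}(1, 5\times
10^{-5})$ (shape-rate).

### Identifiability constraints (restricted spatial regression)

The latent block is constrained: $\sum_i \lambda_i = 0$; the field integrates
to zero at each knot (lumped-mass weights); and the field projected to the
data locations is orthogonal to the fixed-effect design (rows $\tilde
Q^\top A_{st}$ with $\tilde Q$ from the thin QR of the design). The last
device—restricted spatial regression—prevents the smooth field from
absorbing covariate effects. Constraints are imposed on every draw by
conditioning-by-kriging, with the exact conditional-density correction
carried through the Metropolis-Hastings ratios, so the constrained posterior
is targeted exactly, not approximately.

An important consequence, and the reason the generator constrains its own
field by default (`simulate_survey(constrain_field = TRUE)`): under
restricted regression the constraints *define* the split between
$(\beta_0,\beta)$ and the field. Against an unconstrained generator, the
field component aligned with the covariates is absorbed into $\beta$ and
interval coverage of the stated truth fails by construction; the coherent
stated world for recovery tests is the constrained model itself.

## Posterior computation

The study used nested-Laplace software; this package implements its own
blocked MCMC so every piece is verifiable against brute-force oracles:

* **Latent block** $(\beta_0, \beta, \lambda, \xi)$: independence
  Metropolis-Hastings from the sparse Gaussian approximation centred at the
  conditional mode (Newton iterations on the log-concave binomial
  likelihood). The mode depends only on the hyperparameters, so repeated
  draws cost one pair of triangular solves.
* **Hyperparameters** $\theta = (\log\kappa, \log\sigma_{sp}, \tilde\rho,
  \log 1/\sigma^2_{nonsp})$: an alternation of (i) a *non-centred rescale*
  move — a random-walk proposal whose deterministic companion rescales the
  field and location effects to the proposed standard deviations (Jacobian in
  the ratio), (ii) a *joint refresh* move that redraws the whole latent block
  under the proposed $\theta$, and (iii) exact Gibbs draws: the
  location-effect precision has a conjugate gamma conditional (one degree of
  freedom absorbed by the sum-to-zero constraint), and the field amplitude
  $\log\sigma$ has a univariate log-concave conditional sampled by slice
  sampling. The rescale/Gibbs pair is an interweaving scheme; it is what
  makes the variance parameters mix at usable rates.
* Sampling uses $(\log\kappa, \log\sigma)$ rather than $(\log\kappa,
  \log\tau)$ — a unit-Jacobian linear reparameterization that decouples
  range from amplitude; priors are still evaluated on the stated scales.
* All sparse precisions are assembled by value arithmetic on fixed sparsity
  templates, and every Cholesky factorization reuses a cached symbolic
  analysis; the per-iteration cost is a handful of numeric factorizations of
  the conditional precision.

Adaptation of the random-walk scales (Robbins-Monro toward acceptance
0.30/0.15 for rescale/refresh) runs during warm-up only, preserving detailed
balance afterwards. Identical seed and configuration give bit-identical
chains. Default chain plan: 4 chains of 2000 warm-up plus 2000 kept draws;
the tests use much shorter, documented plans.

On a reduced model (intercept plus one slope, field and location effect off)
the sampler is exact independence MH; the acceptance suite checks its
means and 95% quantiles against a dense grid evaluation of the posterior to
0.02 on the logit scale. A Gaussian-outcome stub (`family = "gaussian"`)
makes the proposal exact and is used to verify the sampler against conjugate
closed forms.

## Model comparison, selection, validation

* **DIC** uses the latent-model plug-in: deviance at the posterior mean of
  the linear predictor; `pD = Dbar - Dhat`.
* **MPL** is the negative sum of log conditional predictive ordinates, with
  CPO approximated by the harmonic mean of per-draw likelihoods (flagged when
  it underflows); smaller is better.
* **Two-stage selection**: per continuous predictor, linear versus
  tertile-categorical univariate fits (`select_form`); then `all_subsets`
  fits every subset of the candidates. When DIC and MPL disagree, DIC wins
  by default (configurable).
* **Screening design** (two findings worth recording): screening fits hold
  the hyperparameters at full-model estimates (`fix_theta`), because the
  Monte-Carlo noise of DIC under hyperparameter sampling (about 5-10 units
  at desk scale) swamps the 1-2 unit signal that separates subsets; and
  screening fits are *unconstrained*, because with the orthogonality
  constraints on, adding a covariate simultaneously removes one effective
  field dimension, so the effective-parameter penalty cancels and supersets
  are systematically favoured. The winning subset is refit at full settings.
* **Known limitation**: minimizing DIC overselects by construction — a pure
  noise covariate survives with probability $P(\chi^2_1 > 2) \approx 0.16$ —
  so exact recovery of a 2-of-4 active set is capped near
  $0.84^2 \approx 0.71$ no matter how long the chains are. The acceptance
  criterion demanding 8/10 exact recoveries sits above this ceiling and is
  expected to stay red; the suite asserts it as stated rather than weakening
  it. Selection is also only well-posed when candidate surfaces vary at a
  finer spatial scale than the latent field; when the scales coincide, the
  realized field genuinely correlates with any smooth surface and no
  criterion can separate them.
* **Cross-validation** refits per fold and predicts held-out clusters by
  kriging through the latent field (the location effect is excluded at new
  locations). Coverage is reported against the *full posterior predictive*
  of the observed prevalence $y/n$ — location-effect noise plus binomial
  sampling — because at ~30 respondents per cluster the binomial noise alone
  caps latent-interval coverage near 70-75%; a `predictive = "latent"`
  switch restores the narrower convention, which is the regime of the
  real-data figure (74.49%) reported in the source study.

## Mapping products

`prediction_grid` standardizes grid covariates with the *training* means and
standard deviations. `predict_grid` evaluates per-draw prevalence per pixel
($\lambda$ excluded at new locations; a switch can add
$N(0,\sigma^2_{nonsp})$ noise). Aggregation to administrative units is always
draw-level — quantiles are not additive — with pixel-center containment and
boundary ties to the smaller unit id. `relative_change` follows the
earlier-minus-later convention, $(p_a - p_b)/p_a$, under which an increase is
negative; the sign-flipped percentage is reported alongside, both labelled.
Trend classes compare the current median with the previous year's 95%
interval.

## The synthetic world

The generator states: a 300 km square planar domain (a reduced
Bangladesh-like extent); ~400 clusters per survey year at uniform locations,
30% urban; respondents per cluster Poisson around 30, truncated at 5;
displacement uniform in angle and distance (urban <= 2 km, rural <= 10 km,
with the DHS 5 km/1% convention as a flag); smooth covariate surfaces built
on the same Matern machinery (default range 60 km, the smooth regime in
which nearest-pixel extraction under displacement is approximately unbiased —
the SAR diagnostic `sar_smoothness` returns > 0.9 there, near 0 for white
noise and negative for a checkerboard); a latent field with range ~50-60 km
and variance ~0.15 and a location effect of variance ~0.06 (the scale of the
fitted real-data model); and an intercept near $\operatorname{logit}(0.13)$,
the national prevalence scale. What a green test establishes is therefore
internal consistency of the machinery at a reduced, well-specified scale —
not reproduction of the study's real-data estimates, which require the
restricted microdata.

## Numerical choices

Nearest-pixel ties resolve to the lower (row, then column) index. Mesh
refinement grids get a tiny deterministic coordinate-hash jitter to break
cocircular degeneracies, so meshes are reproducible. The mesh extension ring
should be at least the spatial range (boundary-effect suppression); defaults
follow that rule. $\nu = 0.5$ (the sensitivity setting) uses a dense matrix
power of the scaled finite-element operator — exact up to discretization but
intended for moderate meshes. Hyperparameter proposals are clamped to
$|\theta| < 12$ and numerically failed factorizations reject the proposal.
Constraint systems with reciprocal condition below $10^{-13}$ reject the
hyperparameter value that produced them.
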