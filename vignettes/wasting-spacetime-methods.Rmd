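---
title: "Space-time mapping of child wasting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-time mapping of child wasting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wastemap)
```

## The problem

Acute malnutrition (wasting, low weight-for-height) in children under five is
monitored in food-insecure settings through repeated cluster surveys: at each
surveyed settlement, field teams record how many children were examined and
how many were wasted, together with the survey's year and season. Survey
coverage is sparse and uneven in space and time, while programme decisions —
where and when to pre-position therapeutic feeding — need prevalence
estimates everywhere, every season. `wastemap` implements a Bayesian
hierarchical space–time binomial model that interpolates cluster-level
counts into seasonal prevalence surfaces, classifies them against the WHO
severity trigger levels, and converts them into population-weighted counts
of wasted children by administrative zone.

The package is organized around a synthetic study: a generator produces a
three-zone planar region, smooth environmental covariate surfaces, a latent
space–time field, cluster survey records and an under-five population grid
with the same statistical structure the estimator assumes. Everything
downstream — covariate selection, inference, mapping, validation — is
exercised end to end on that synthetic study, so every claim the test suite
makes is about quantities whose truth is known.

## Observation model and latent structure

Counts are binomial at cluster level:

$$y_i \mid \eta_i \sim \mathrm{Binomial}(n_i,\ \mathrm{logit}^{-1}(\eta_i)),$$

with a structured additive predictor

$$\eta_i = \beta_0 + \mathbf{x}_i^\top\beta + u(s_i, t_i) + s_{\,\mathrm{season}(i)} + v_{c(i)}.$$

Here $\beta$ are effects of standardized environmental covariates (rainfall,
EVI, mean temperature, distance to water, urbanization), $u(s,t)$ is a
space–time Gaussian field, $s_j$ a seasonal effect (model 2 only) and
$v_c \sim N(0, \sigma_c^2)$ iid cluster effects absorbing within-cluster
clustering. The logit link is used throughout: reported effect sizes are
odds (OD) or log-odds (LOD). The whole latent vector
$\theta = (\beta_0, \beta, u, s, v)$ is jointly Gaussian with a sparse
precision matrix $Q(\psi)$, and observations touch it through a sparse
design matrix whose field block holds the barycentric weights of each
cluster in its mesh triangle.

### The SPDE/GMRF spatial field

The spatial field is a Matérn field (smoothness $\nu = 1$ in 2-D,
corresponding to SPDE order $\alpha = 2$) represented as a Gaussian Markov
random field through the finite-element discretization of

$$(\kappa(u)^2 - \Delta)\,(\tau(u)\, x(u)) = W(u),$$

on a triangulation of the region plus an outer buffer. With lumped mass
matrix $C$, stiffness $G_1$ and $G_2 = G_1 C^{-1} G_1$, the precision is

$$Q_s = T\,(K^2 C K^2 + K^2 G_1 + G_1 K^2 + G_2)\,T,
\qquad T = \mathrm{diag}(\tau_i),\ K = \mathrm{diag}(\kappa_i).$$

In the stationary case the implied range is $\sqrt{8}/\kappa$ and the
marginal variance $1/(4\pi\kappa^2\tau^2)$; the test suite verifies both
against a dense-inverse oracle and the closed-form Matérn correlation
$(\kappa r)K_1(\kappa r)$, to within 0.03 in correlation and 10% in
variance on a fine mesh. Non-stationarity enters through log-linear basis
expansions $\log\tau(u) = B_\tau\theta_\tau$, $\log\kappa(u) =
B_\kappa\theta_\kappa$; the default basis is intercept + linear x + linear
y. The default *fit* uses the intercept-only (stationary) basis: with the
cluster counts available at desk scale, spatially varying range/variance
fields are weakly identified and double the hyperparameter dimension of the
derivative-free outer optimization, so the richer basis is opt-in
(`model_config(nonstationary = TRUE)`).

**Meshing.** The mesh is a structured triangulated lattice: a regular grid
of vertices over the region plus buffer, each cell split into two triangles,
with the spacing chosen so no inner edge (including diagonals) exceeds
`max_edge_km`. Regular lattices are a standard meshing choice for SPDE
models on rectangular domains; they make point location O(1) and the FEM
assembly exactly reproducible. The buffer (default on the order of the
spatial range) absorbs the Neumann boundary inflation; the Matérn-oracle
test only trusts nodes at least one range away from the buffer.

### Temporal dynamics and the two model configurations

Time is indexed by year–season steps, seasons ordered (Jilaal, Gu, Hagaa,
Deyr) within each year. The space–time field is separable,
$Q_{st} = Q_t \otimes Q_s$, with $Q_t$ the exact precision of a stationary
AR(2) normalized to unit marginal variance (the field's scale is carried by
$\tau$). The AR(2) is parameterized by partial autocorrelations, mapped to
the stationary region by a logistic transform; its precision is assembled
from the bivariate stationary margin of $(x_1, x_2)$ plus the conditional
innovations, which is exact for any length — the tests verify the dense
inverse against the Yule–Walker autocovariances.

* **Model 1** places the AR(2) on all $4\,n_\mathrm{years}$ year–season
  steps: seasonality is absorbed into the temporal dynamics, and the fit's
  purpose is the per-year-season prevalence surface.
* **Model 2** places the AR(2) on years only and adds an explicit seasonal
  component of length $4\,n_\mathrm{years}$ with period $m = 4$: a GMRF
  whose density penalizes the $m$-term moving sums,
  $$\pi(x \mid \tau_s) \propto \tau_s^{(n-m+1)/2}
  \exp\Big\{-\tfrac{\tau_s}{2}\sum_{i=1}^{n-m+1}\big(x_i + x_{i+1} + \dots +
  x_{i+m-1}\big)^2\Big\},$$
  i.e. structure matrix $S = D^\top D$ with $D$ the moving-sum matrix, rank
  $n - m + 1$. Consecutive season effects therefore average toward zero over
  each cycle while pure periodic zero-sum patterns are unpenalized. The
  per-season effect sizes are read off as the seasonal component averaged
  over years and centred to sum to zero (identifiability against the
  intercept), with delta-method intervals.

The seasonal block receives a tiny ridge ($10^{-6}$) in the joint precision
so that the assembled $Q(\psi)$ is strictly positive definite; with two or
more years of data the likelihood identifies the seasonal levels and the
ridge is numerically irrelevant.

## Covariate selection

Candidate covariates are screened before the spatial fit with best-subset
binomial regression under the extended BIC,

$$\mathrm{BIC}_\gamma = D + k\log n + 2\gamma\log\binom{p}{k},$$

where $D$ is the residual deviance, $k$ the number of covariates in the
subset, $p$ the number of candidates, and the combinatorial term is the
uniform-prior-over-models-of-fixed-size penalty. All $2^p$ subsets are
fitted exhaustively (intercept always included, covariates standardized) by
a from-scratch IRLS implementation; `glm()` serves as an independent
cross-check in the tests, never as the implementation. The printed
criterion's "log(pk)" is read as $\log\binom{p}{k}$: that is the only
reading under which the stated uniform prior on models of fixed size is
correct and $k = 0$ is well defined. $\gamma$ defaults to 1 and is
configurable. Ties are broken toward smaller subsets, then lexicographic
order; non-convergent subsets (e.g. complete separation) are scored $+\infty$
and flagged.

## Inference: Laplace approximation with empirical-Bayes hyperparameters

At fixed hyperparameters $\psi$ (log $\tau$/$\kappa$ coefficients, AR
partial autocorrelations, cluster and seasonal log-precisions), the latent
posterior is log-concave; its mode $\hat\theta$ is found by Newton
iterations with step halving, each step a sparse supernodal Cholesky solve
of $H = Q(\psi) + A^\top W A$. The hyperparameters are then chosen to
maximize the Laplace-approximate marginal posterior

$$\log\pi(\psi \mid y) \approx \log p(y \mid \hat\theta) -
\tfrac12 \hat\theta^\top Q \hat\theta + \tfrac12\log|Q(\psi)| -
\tfrac12\log|H(\psi)| + \log\pi(\psi),$$

by Nelder–Mead (dimension ≤ 8, two starts by default, the second jittered).
$\log|Q|$ is assembled analytically from the blocks using
$\log|Q_t \otimes Q_s| = n_t\log|Q_s| + n_v\log|Q_t|$, so each evaluation
costs one small spatial factorization plus the Newton solves. Hyperpriors
are Gaussian on the transformed scale (SD 3 on log-parameters, SD 1.5 on the
Fisher-z of the partial autocorrelations).

Two corrections move the reported summaries beyond the plain Gaussian
approximation:

1. **Skewness correction of the mean.** The joint mode of a latent binomial
   model sits away from the marginal means by a term driven by the third
   derivative of the log-likelihood. The reported posterior mean is
   $\hat\theta + \tfrac12 H^{-1} A^\top\big(\ell'''\!\circ\!
   \mathrm{var}(\eta)\big)$ — one extra sparse solve. On a 25-node test
   instance this moves the Laplace mean to within Monte-Carlo error of a
   long MCMC run.
2. **Hyperparameter uncertainty in fixed-effect intervals.** Empirical-Bayes
   intervals conditioned on $\hat\psi$ are too narrow. The forward-difference
   Hessian of the log marginal posterior at $\hat\psi$ gives
   $\mathrm{cov}(\psi)$, and the same evaluations yield the sensitivities
   $\partial\hat\beta/\partial\psi$; the reported fixed-effect SDs add the
   propagated term $J\,\mathrm{cov}(\psi)\,J^\top$.

The verification oracle is a preconditioned Metropolis-adjusted Langevin
sampler (`mcmc_oracle`) targeting the exact latent posterior at fixed
$\psi$, with the mode-curvature preconditioner and step-size adaptation
during burn-in only; it is restricted to latent dimension ≤ 2000 and exists
for testing, not analysis.

**What the calibration tests do and do not show.** With a Gaussian
likelihood the fit must (and does) match the conjugate closed form to
numerical precision. On binomial instances the Laplace mean matches MCMC
within 3 Monte-Carlo standard errors. Frequentist coverage of the 95%
fixed-effect intervals is checked over 20 reduced-scale replicates (300
clusters of 80 children over four years); it clears the suite's 16-of-20
bound, but coverage can dip below nominal when a covariate surface
is incidentally correlated with the realized latent field — the familiar
spatial-confounding effect, which no within-fit variance estimate can see.
This is a known limitation, not an implementation defect.

## Prediction, risk classes, validation

Prevalence surfaces evaluate the linear predictor at the corrected posterior
mean on each pixel (covariates standardized with the training parameters,
cluster effect at its prior mean of zero), with pixel SDs from the Gaussian
approximation mapped through the delta method $p(1-p)\,\mathrm{sd}(\eta)$;
Monte-Carlo averaging of the inverse logit over latent draws is available
via `model_config(predict_mc = ...)`. Pixels outside the mesh are masked and
counted, never silently dropped.

WHO severity classes partition prevalence as [0, 5%), [5, 10%), [10, 15%),
[15%, 20%], (20%, 100%]: the guideline's wording ("15–20%", "greater than
20%") forces 20% itself into the critical class. Expected wasted-children
counts multiply pixel prevalence by the under-five population and aggregate
by zone, year–season and class; counts stay real-valued in machine output,
and the "<50" masking of small cells is purely a formatting layer.

Validation holds out 10% of clusters, de-clustered over space and time:
observations are stratified by (year, season) crossed with spatial k-means
blocks ($k = \lceil 1/\mathrm{fraction}\rceil$) and sampled proportionally
with largest-remainder allocation, so the test size is exactly
$\mathrm{round}(0.1\,N)$ and no stratum is overdrawn. Reported indices are
RMSE, mean error, mean absolute error and Pearson correlation between
predicted and observed cluster proportions; a constant vector leaves the
correlation `NA` with a flag rather than a fabricated value.

## The synthetic study

The generator's defaults are the study conditions: ~1,066 clusters assigned
to 2007–2010 with survey-effort weights 36/27/22/14%, seasons uniform, 30–120
children per cluster, pooled prevalence near 21% (intercept
$\mathrm{logit}(0.2133)$), covariate effects negative for rainfall and EVI,
positive for temperature and null for distance-to-water and urbanization,
seasonal log-odds offsets (0.035, −0.035, 0.025, −0.025) for (Jilaal, Gu,
Hagaa, Deyr) — dry seasons worse — a Matérn field with 100 km range and 0.3
log-odds SD driven by AR(2) partial autocorrelations (0.5, 0.1), and
cluster-effect SD 0.25. Rainfall surfaces are clipped to the observed 2–104
mm monthly range, EVI to [0, 1], urbanization is a binary top-5% indicator.
Coordinates are planar kilometres: the model is metric, and at the scale of
the emulated region an equirectangular projection makes geographic
distortion second order, so no projection math lives in the core.

What the generator does **not** emulate: real covariate fields (its surfaces
are smooth random fields, not climate data), preferential survey placement
(locations are uniform), migration and conflict-driven displacement,
within-cluster covariate heterogeneity, or reporting error in the counts.
Green tests therefore demonstrate that the estimator recovers the structure
it assumes at realistic sizes — not that the assumptions hold for any real
survey.

## Numerical choices and problem sizes

Defaults that matter: IRLS tolerance $10^{-10}$ on the deviance with a
50-iteration cap and separation flagged at |log-odds| > 12; inner Newton
gradient tolerance $10^{-6}$, 50-iteration cap, step halving to a floor of
$2^{-27}$; Nelder–Mead `maxit` 150 with relative tolerance $10^{-6}$;
forward-difference step 0.1 on the transformed hyperparameter scale; the
seasonal ridge $10^{-6}$; the fixed-effect prior precision $10^{-4}$;
Cholesky factorizations are supernodal with a symbolic pattern reused across
Newton and hyperparameter iterations. Degenerate inputs error early and
loudly: zero-area triangles name the triangle, out-of-mesh locations list
their row indices, misaligned grids and orphan populated pixels are
rejected.

The packaged analyses and tests run at desk scale by design: meshes of
~100–4,600 nodes, 120–1,066 clusters, 8–16 time steps. These sizes were
chosen so the dense oracles (full inverses, MCMC) remain exact enough to
verify against while the full pipeline stays interactive; the same code
paths scale to finer meshes, the cost being driven by the sparse
factorization of $H$.

## Reproducibility

Every stochastic step takes an explicit seed and results carry it in
metadata; generators are pure functions of (arguments, seed), restoring the
caller's RNG state. The numbered scripts under `analysis/` run the study
end to end and write their tables under `results/analysis/`;
`scripts/acceptance.R --seed N --out path.json` recomputes the headline
quantities from scratch against the installed package.
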