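---
title: "Joint mapping of two areal count outcomes: model, sampler, and design notes"
author: "sharedcar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint mapping of two areal count outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharedcar)
```

## The problem

Two count outcomes are observed on the same partition of a region into
small areas -- in the motivating application, police calls reporting
street-level crime and calls reporting intimate-partner violence across a
city's census block groups. Three questions drive the analysis:

1. How much of the between-area variation in risk is **shared** between
   the two outcomes, and how much is outcome-specific?
2. After adjusting for neighbourhood covariates, what is each area's
   **relative risk** for each outcome?
3. Where do the two risk surfaces **coincide** (both above or both below
   the city average) and where do they diverge?

The package implements the full chain: a shared-component joint Poisson
model, per-outcome convolution (BYM) regressions, and a risk-surface
comparison stage, plus a synthetic-data generator with known ground truth
so that every stage is validated by parameter recovery. Real data of this
kind are typically confidential; the generator stands in for them under
controlled conditions.

## Models

**Joint shared-component model.** Counts are conditionally independent
Poisson, $Y_{ik} \sim \mathrm{Po}(\mu_{ik})$ for area $i$ and outcome
$k \in \{1, 2\}$, with

$$\log \mu_{i1} = \log E_{i1} + \alpha_1 + \phi_i\,\delta + \psi_{i1},
\qquad
\log \mu_{i2} = \log E_{i2} + \alpha_2 + \phi_i/\delta + \psi_{i2}.$$

$E_{ik}$ are expected counts (the standardization offset), $\alpha_k$
intercepts with improper flat priors, $\phi$ the shared spatial surface
and $\psi_k$ the outcome-specific surfaces. The scaling factor $\delta >
0$ lets the common surface act with different strength on the two
outcomes; $\delta = 1$ means equal strength. Each surface is the sum of a
spatially **structured** part with an intrinsic CAR (ICAR) prior,

$$\phi_i \mid \phi_{-i} \sim
N\!\Big(\tfrac{1}{n_i}\sum_{j \sim i} \phi_j,\; \sigma^2 / n_i\Big),$$

and an **unstructured** iid Gaussian part -- six latent fields and six
scale parameters in total. The shared-variance fraction per outcome is
the empirical variance ratio, evaluated at every retained draw:

$$\eta_1 = \frac{V(\delta\phi)}{V(\delta\phi) + V(\psi_1)},
\qquad
\eta_2 = \frac{V(\phi/\delta)}{V(\phi/\delta) + V(\psi_2)},$$

with $V$ the across-area variance of the full (structured plus
unstructured) field. The fields entering $\eta_k$ and the exported map
are the full surfaces, scaled exactly as they enter the linear predictor.

**Per-outcome spatial regression.** For each outcome separately,

$$\log \mu_{ik} = \log E_{ik} + \alpha_k + X_i \beta_k + \phi_i +
\theta_i,$$

with an ICAR field $\phi$, iid heterogeneity $\theta$, and vague Gaussian
priors (variance $10^5$) on the coefficients. The area relative risk is
$RR_i = \exp(\alpha + X_i\beta + \phi_i + \theta_i)$: 1 is the average
risk, 2 twice the average. A covariate is reported as *relevant* when the
posterior probability of its coefficient being positive, or negative,
exceeds 80%.

**Comparison stage.** Posterior-mean relative risks of the two outcomes
are correlated on the log scale (Pearson), and each area is classified
high/low for each outcome against $RR = 1$, giving matched (high--high,
low--low) and mismatched percentages. Ties sit exactly on the threshold
and are classified low ("high" means strictly above average).

## Priors and their defaults

| parameter | prior | default | notes |
|---|---|---|---|
| $\alpha_k$ | improper flat | -- | propriety restored by the Poisson likelihood with $E > 0$ |
| $\beta$ | $N(0, v)$ | $v = 10^5$ | `beta_variance`; covariates are z-scored by default so this is genuinely vague |
| $\sigma$ (all six scales) | $U(0, u)$ | $u = 2$ | `sigma_upper`; generous for log-risk surfaces |
| $\log\delta$ | $N(0, s^2)$ | $s = 0.3$ | `log_delta_sd`; weak shrinkage of the scaling factor toward 1 |

The prior on $\delta$ is a design choice: the model needs *some* proper
prior on the scaling factor for stable estimation, and a lognormal with
sd 0.3 keeps $\delta$ within a factor of ~2 of unity a priori while
letting the data dominate. All three values are configurable through
`prior_config()`.

Expected counts use internal standardization,
$E_{ik} = T_k\, p_i / \sum_j p_j$ with $T_k$ the outcome total and $p$
the populations, so $\sum_i E_{ik} = \sum_i Y_{ik}$ when $E$ is computed
from the observed totals and relative risks are read against the map-wide
average. User-supplied `e1`, `e2` columns are taken verbatim.

Because the relative risk of the regression stage includes $\alpha$, it
is measured **against the expected-counts baseline**: multiplying every
$E_{ik}$ by a constant $c$ shifts $\hat\alpha$ by $-\log c$ and divides
every $RR$ by $c$, while all area-to-area risk ratios and the risk
ranking are unchanged. Internal standardization keeps the baseline at the
map average, which is what gives "RR = 1 is average" its meaning.

## The sampler

Inference is Metropolis-within-Gibbs with an update schedule built around
one structural fact: *every latent-field prior in both models is diagonal
in the eigenbasis of the common ICAR structure matrix* $Q = D - W$
(unstructured iid priors are diagonal in any orthonormal basis, and one
$\lambda = 0$ vector per graph component carries the directions the ICAR
prior leaves flat). Each sweep combines:

* **Single-site random-walk updates** of every latent field, vectorized
  over graph-colour classes (areas of one colour share no edge, so their
  full conditionals are mutually independent); one adapted proposal scale
  per field, targeting 0.44 acceptance, frozen after the adaptation
  horizon (`adapt_until`, never beyond burn-in).
* **Smooth-mode block updates**: the twelve smallest-eigenvalue modes of
  each structured field get a joint Metropolis proposal preconditioned by
  the local Gaussian curvature (prior $\lambda_k/\sigma^2$ plus
  likelihood $\approx \bar\mu$). Single-site walks cross these
  large-scale directions only by slow diffusion.
* **Collapsed hyperparameter updates**: the likelihood constrains only
  the total predictors $t_k = \log\mu_k - \log E_k - \alpha_k$. Given
  $(t_1, t_2)$, the marginal over all six fields of the joint model is a
  $2 \times 2$ Gaussian per eigenmode with field variances
  $\sigma_{str}^2/\lambda + \sigma_{het}^2$, so $(\log\delta$, six
  $\log\sigma)$ are **slice-sampled** on that marginal -- no tuning, full
  steps along the hyperparameter ridge. The regression model gets the
  same treatment for $(\sigma_\phi, \sigma_\theta)$.
* **Exact field redraws**: after the collapsed update, all latent fields
  are redrawn from their exact Gaussian conditional given the totals and
  hyperparameters, mode by mode -- first the shared surface, then the
  specific surfaces as residuals, then each surface's structured/
  unstructured split. The predictors (and hence the likelihood) are
  unchanged by construction.
* **Scale-parameter Gibbs**: given its field, each precision
  $1/\sigma^2$ has a truncated-Gamma full conditional under the
  $U(0, u)$ prior on $\sigma$, sampled by inverse CDF.
* **Funnel moves**: joint proposals $(f, \sigma) \to (cf, c\sigma)$ whose
  prior and Jacobian terms cancel, leaving the likelihood delta plus
  $\log c$ -- these walk the funnel between a nearly-null field and its
  scale.
* Scalar random walks for $\alpha_k$ and a likelihood-side walk for
  $\log\delta$.

Without the collapsed updates, the shared-versus-specific allocation and
the structured-versus-unstructured split are ridges that single-site
samplers cross extremely slowly -- the classical remedy is simply very
long runs (the 100,000-iteration regime of general-purpose Gibbs
software, available here via `mcmc_config(n_iter = 1e5, burn_in = 1e4)`).
With them, the desk-scale default of 4 chains $\times$ 6,000 iterations
(1,000 burn-in, thin 5) reaches split-$\hat R$ below 1.1 on the
validation problems in the test suite.

**Identifiability handling.** Structured fields are recentred to sum to
zero within each graph component after every sweep, the removed mean
absorbed into the intercepts (exactly when the graph is connected; for
multi-component graphs the per-component means cannot all be absorbed
into one intercept, and centering-on-the-fly without compensation is
used, the standard practice). The $\phi$/$\theta$ decomposition of the
regression model is only weakly identified pointwise, as in any
convolution model; validation therefore targets the ordering of
$\sigma_\phi$ versus $\sigma_\theta$, not pointwise field recovery. The
joint model's scaling symmetry ($\phi \to c\phi$ with $\psi$ adjusted to
keep $\mu$ fixed) is a prior-identified, not likelihood-identified,
direction; the collapsed updates sample it rather than fight it.

**Correctness validation.** Beyond the unit oracles (exact kernel
identities against the generalized-inverse Gaussian density;
Gibbs-versus-exact-sampler Kolmogorov--Smirnov checks; the Poisson pmf
identity), the full joint sampler is checked by simulation-based
calibration in the test suite: truth drawn from the priors, counts
simulated forward, and the posterior rank of the truth recorded across
seeded replicates -- the rank distribution is uniform for a correct
sampler, and the suite asserts its mean for $\delta$ and all six scales.

**Diagnostics.** Split-$\hat R$ (each chain halved, between/within
variance ratio) and an effective-sample-size estimate (Geyer's initial
positive sequence on split chains) are reported per scalar. A fit whose
worst split-$\hat R$ exceeds 1.1 is flagged `converged = FALSE` with a
warning; it is never silently accepted. Per-chain seeds derive
deterministically from the configuration seed, so identical
configurations give bit-identical draws.

## The synthetic-data generator

`simulate_joint_dataset()` draws fields forward through the same
equations the model fits. Its defaults are the package's validation
conditions: a connected rook lattice; equal populations; expected counts
of 50 per area per outcome (mid-sized areas: large enough for the
likelihood to carry spatial signal, small enough that Poisson noise
matters); $\delta = 1$; a shared surface with across-area variance 0.16
(sd 0.4 on the log-risk scale, i.e. typical areas within $\pm$50% of
average risk); shared-variance targets of 0.6 for outcome 1 and 0.9 for
outcome 2 (one outcome dominated by the common pattern, the other with
substantial specific structure -- the regime the joint model is designed
to detect); and three quarters of each surface's variance spatially
structured (structured dominating unstructured, as fitted scale
parameters in this literature usually indicate).

Scale parameters are calibrated **exactly**, not by simulation: for an
ICAR draw on a given graph the expected across-area variance is
$\sum_k \lambda_k^{-1} / (n - 1)$ over the positive eigenvalues, so
target variances translate to conditional scales in closed form. The
*realized* fraction of a single drawn map still fluctuates around the
target -- a single ICAR realisation has few effective degrees of freedom
in its smooth modes -- which is why `simulate_joint_dataset()` records
`realized_eta`, and recovery is always judged against the realized, not
nominal, values.

What the generator does **not** emulate about real areal data: irregular
adjacency structure and heavy-tailed neighbour counts (lattices are more
regular than census geographies), unequal populations and hence unequal
$E_{ik}$, covariates that are themselves spatially autocorrelated and
cross-correlated (the scheme draws them independently at reference
moments, then z-scores), overdispersion beyond the convolution model, and
any data-collection artefacts (geocoding error, reporting bias). Passing
recovery tests here shows the machinery is correct and well-calibrated
under the model's own assumptions; it cannot show the model is adequate
for any particular real dataset.

## Numerical choices and degenerate inputs

* ICAR sampling and the eigenbasis use one dense symmetric
  eigendecomposition per graph component, cached per fit. Exact and
  simple; the practical ceiling is a few thousand areas (seconds at 400,
  roughly a minute at 2,500). Sparse methods would extend this but add
  code paths this package does not need at its working scales.
* Areas with zero counts are fine (Poisson mass at zero); zero or
  negative expected counts, populations, islands (areas with no
  neighbours), and rank-deficient design matrices are rejected at load
  with named errors. Constant covariates cannot be z-scored and are
  rejected by name.
* Equal-tailed 95% intervals are empirical 2.5/97.5 percentiles
  (`stats::quantile`, type 7). Posterior summaries of $RR$ are on the RR
  scale (mean and percentiles of $\exp(\cdot)$), since the comparison
  stage thresholds at $RR = 1$ and maps callers read at $RR = 2$.
* $\eta_k$ with a constant shared and constant specific field is
  undefined; the package returns `NA` with a warning rather than a
  fabricated value.
* Ties at the coincidence threshold are classified low, recorded in the
  result's `tie_rule` field.
* The 80% relevance rule is a *liberal descriptive heuristic*, not a
  calibrated test: for a vague prior under a zero effect, the posterior
  probability of a positive sign is approximately uniform, so the rule
  flags roughly $2\,(1 - \Phi(\Phi^{-1}(0.8))) = 40\%$ of null
  covariates. Read the flags as "the sign is consistent across the
  posterior", not as error-controlled discoveries.

## Problem sizes used in validation

The test-suite and acceptance runs use a 20 x 20 lattice (400 areas, the
same order of magnitude as a mid-sized city's block groups) for the
joint model at 4 chains x 6,000 iterations; 200 areas and 2 x 3,000
iterations for the regression recovery; twenty 200-area replicates for
interval coverage; and ten 100-area paired runs for the
shared-versus-independent correlation ordering. These sizes were chosen
so each check exercises the asymptotic regime it tests while the whole
suite stays comfortably runnable on a laptop.

## Known limitations

* Two outcomes only; the shared-component idea generalizes to more, but
  the scaling-factor parametrization used here does not.
* No covariates inside the joint model (by design -- covariates belong to
  the regression stage).
* No formal model comparison (DIC/WAIC) and no spatio-temporal extension.
* The coincidence classification uses posterior-mean relative risks; it
  does not propagate classification uncertainty (exceedance probabilities
  are exported and could be thresholded instead).
* Binary contiguity only; no distance-band or row-standardized general
  weights.
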