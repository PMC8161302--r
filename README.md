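# sharedcar

Bayesian joint mapping of two spatially indexed count outcomes over small
areas: how much of the between-area risk variation do the outcomes share,
what is each area's covariate-adjusted relative risk, and where do the two
risk surfaces coincide?

The package is built for the kind of question asked of paired areal count
data — e.g. two categories of police calls across a city's census block
groups, two diseases across health districts — where the analysis of
interest is (i) a **shared-component joint model**, (ii) per-outcome
**spatial (BYM) Poisson regressions** with neighbourhood covariates, and
(iii) a **coincidence analysis** of the fitted relative-risk surfaces.
Because such data are usually confidential, the package ships a
synthetic-data generator with known ground truth, and every stage is
validated by parameter recovery.

## The models

Counts $Y_{ik}$ for area $i$ and outcome $k \in \{1,2\}$ are conditionally
independent Poisson with expected counts $E_{ik}$ as offsets. The joint
model partitions log relative risk into one shared and two specific
spatial surfaces:

$$\log \mu_{i1} = \log E_{i1} + \alpha_1 + \phi_i\,\delta + \psi_{i1},
\qquad
\log \mu_{i2} = \log E_{i2} + \alpha_2 + \phi_i/\delta + \psi_{i2},$$

each surface the sum of an intrinsic CAR (ICAR) structured part,
$\phi_i \mid \phi_{-i} \sim N(\bar\phi_{\partial i},\, \sigma^2/n_i)$,
and an iid unstructured part. The scaling factor $\delta$ measures the
relative strength of the shared surface on the two outcomes; the
shared-variance fraction
$\eta_k = V(\text{shared}_k) / (V(\text{shared}_k) + V(\psi_k))$ is
derived per posterior draw. The regression stage fits, per outcome,

$$\log \mu_{ik} = \log E_{ik} + \alpha_k + X_i\beta_k + \phi_i + \theta_i,$$

reports relative risks $RR_i = \exp(\alpha + X_i\beta + \phi_i + \theta_i)$
(1 = average risk) with 95% credible intervals and exceedance
probabilities $P(RR_i > 1)$, and flags covariates whose posterior
probability of a positive (or negative) coefficient exceeds 80%. The
comparison stage computes the Pearson correlation of the log relative
risks and classifies every area high/low for each outcome against
$RR = 1$ (matched = high–high or low–low).

Inference is an adaptive Metropolis-within-Gibbs sampler with collapsed
(field-marginalized) hyperparameter updates and exact per-eigenmode field
redraws — see the methods vignette
(`vignettes/shared-component-mapping.Rmd`) for the full scheme, priors,
and design notes. Split-$\hat R$ and effective sample sizes are reported
for every scalar; non-convergence is flagged, never silently accepted.

## Worked example

```r
library(sharedcar)

graph <- build_lattice(20, 20, "rook")         # synthetic 400-area city
sim   <- simulate_joint_dataset(graph, joint_scenario(graph), seed = 1)
fit   <- fit_joint(sim$dataset, graph, mcmc_config(seed = 2))
print(fit)
```

```
Shared-component joint Poisson model fit
  param      mean     sd    q2.5  q97.5 rhat n_eff
 alpha1 -0.000614 0.0202 -0.0407 0.0389 1.01   272
 alpha2  0.012610 0.0174 -0.0207 0.0468 1.01   309
  delta  1.077142 0.0911  0.9330 1.2748 1.01   361
   eta1  0.685754 0.1311  0.4749 0.9711 1.01   410
   eta2  0.823965 0.1034  0.6235 0.9883 1.01   438
max split-Rhat: 1.012 (converged)
```

The generator's truth for this seed was $\delta = 1$ with realized
shared-variance fractions 0.564 (outcome 1) and 0.910 (outcome 2): the
fit finds a scaling factor indistinguishable from 1 (the shared surface
acts equally on both outcomes) and attributes most of outcome 2's
variation, and about two thirds of outcome 1's, to the shared component.
Fitting the two per-outcome regressions on the same data and comparing
their risk surfaces:

```r
fits <- lapply(1:2, function(k)
  fit_regression(sim$dataset, k, graph, mcmc_config(seed = 2 + k)))
compare_surfaces(fits[[1]]$risk_surface, fits[[2]]$risk_surface)
```

```
Risk-surface coincidence analysis
  Pearson r (log RR): 0.743
  matched: 74.8%  mismatched: 25.2%

high_high   low_low  high_low  low_high
      145       154        43        58
```

so about three quarters of the areas sit on the same side of the average
risk for both outcomes — the direct, map-ready summary of spatial
overlap. `export_shared_surface()` and the `risk_surface` data frames
hold the per-area values for choropleth rendering.

The same flow runs as a scripted analysis under `analysis/`
(`01_simulate.R` … `04_compare.R`, outputs under `results/`), or as one
configured call: `run_pipeline(config, out_dir)` executes
simulate → joint fit → two regressions → comparison and writes a manifest
with seeds, checksums and convergence flags; identical configurations
reproduce bit-identical outputs.

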