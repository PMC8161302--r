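#!/usr/bin/env Rscript
# Stage 3 -- fit the per-outcome spatial (BYM) Poisson regressions.
#
# Two fits per dataset, one per outcome. On the covariate dataset the
# regressions recover the known effects beta = (0.5, -0.3) and apply the
# 80% posterior-sign-probability relevance rule. On the shared-component
# dataset the regressions are intercept-only: their purpose is the
# relative-risk surface of each outcome, the input of the coincidence
# analysis in stage 4. Every surface carries per-area posterior mean RR,
# a 95% credible interval, and the exceedance probability P(RR > 1).

library(sharedcar)

dir.create("results/regression", recursive = TRUE, showWarnings = FALSE)

# covariate recovery fits
reg_graph <- read_adjacency("results/data/reg_graph_edges.csv",
                            "edge_list_csv")
reg_data <- read_area_table("results/data/reg_dataset.csv")
cfg <- mcmc_config(n_iter = 3000, burn_in = 500, thin = 5, n_chains = 2,
                   seed = 3L)
for (k in 1:2) {
  fit <- fit_regression(reg_data, k, reg_graph, cfg)
  write.csv(fit$summary,
            sprintf("results/regression/covariate_summary_outcome%d.csv", k),
            row.names = FALSE)
  write.csv(fit$covariates,
            sprintf("results/regression/relevance_outcome%d.csv", k),
            row.names = FALSE)
  cat(sprintf("Outcome %d (covariate dataset): max Rhat %.3f\n",
              k, fit$max_rhat))
  print(fit$covariates[, c("covariate", "mean", "p_positive", "relevant",
                           "direction")], row.names = FALSE, digits = 3)
}

# risk surfaces of the shared-component city, for the comparison stage
graph <- read_adjacency("results/data/graph_edges.csv", "edge_list_csv")
dataset <- read_area_table("results/data/joint_dataset.csv")
for (k in 1:2) {
  fit <- fit_regression(dataset, k, graph, mcmc_config(seed = 3L + k))
  write.csv(fit$risk_surface,
            sprintf("results/regression/risk_surface_outcome%d.csv", k),
            row.names = FALSE)
  write.csv(fit$summary,
            sprintf("results/regression/summary_outcome%d.csv", k),
            row.names = FALSE)
  cat(sprintf(
    "Outcome %d (joint dataset): sigma_phi %.3f > sigma_theta %.3f; max Rhat %.3f\n",
    k, fit$summary$mean[fit$summary$param == "sigma_phi"],
    fit$summary$mean[fit$summary$param == "sigma_theta"], fit$max_rhat))
}
cat("Outputs under results/regression/.\n")
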