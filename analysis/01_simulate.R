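#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic study area and datasets.
#
# The real data behind this kind of analysis (two police-call count
# outcomes over a city's census block groups) are confidential, so the
# whole analysis runs on a synthetic city: a 20 x 20 rook lattice of 400
# areas with equal populations and expected counts of about 50 per area
# per outcome. Two datasets are produced:
#
#   * a shared-component dataset: one latent spatial surface common to
#     both outcomes (scaled by delta = 1 and 1/delta), plus
#     outcome-specific surfaces sized so that the shared component carries
#     about 60% of outcome 1's and 90% of outcome 2's between-area
#     log-risk variance -- the regime the joint model is built for;
#   * a covariate dataset: two neighbourhood covariates with effects
#     beta = (0.5, -0.3) on top of moderate spatial fields, for the
#     regression stage.
#
# Ground truth (fields, scales, realized variance fractions) is saved next
# to each dataset so later stages can report recovery, not just fits.

library(sharedcar)

seed <- 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

graph <- build_lattice(20, 20, "rook")
write_adjacency(graph, "results/data/graph_edges.csv", "edge_list_csv")

joint <- simulate_joint_dataset(graph, joint_scenario(graph), seed = seed)
write_area_dataset(joint$dataset, "results/data/joint_dataset.csv")
jsonlite::write_json(joint$truth, "results/data/joint_truth.json",
                     auto_unbox = TRUE, digits = NA)

reg_graph <- build_lattice(10, 20, "rook")
write_adjacency(reg_graph, "results/data/reg_graph_edges.csv",
                "edge_list_csv")
reg <- simulate_regression_dataset(reg_graph, beta = c(0.5, -0.3),
                                   sigma_phi = 0.3, sigma_theta = 0.1,
                                   seed = seed)
write_area_dataset(reg$dataset, "results/data/reg_dataset.csv")
jsonlite::write_json(reg$truth, "results/data/reg_truth.json",
                     auto_unbox = TRUE, digits = NA)

cat(sprintf(
  "Simulated %d-area joint dataset (seed %d):\n", graph$n_areas, seed))
cat(sprintf("  true delta = %.3f\n", joint$truth$delta))
cat(sprintf("  realized shared-variance fractions: %.3f (outcome 1), %.3f (outcome 2)\n",
            joint$truth$realized_eta[1], joint$truth$realized_eta[2]))
cat(sprintf("Simulated %d-area regression dataset with beta = (0.5, -0.3).\n",
            reg_graph$n_areas))
cat("Outputs under results/data/.\n")
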