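test_that("joint mean structure matches the shared-component form", {
  n <- 4L
  E <- matrix(c(10, 20, 30, 40, 5, 5, 5, 5), n, 2L)
  null <- list(alpha = c(0, 0), log_delta = 0,
               phi_str = numeric(n), phi_het = numeric(n),
               psi_str = matrix(0, n, 2L), psi_het = matrix(0, n, 2L))
  expect_equal(joint_log_mu(null, E, 1), E[, 1L])
  expect_equal(joint_log_mu(null, E, 2), E[, 2L])
  expect_error(joint_log_mu(null, E, 3), "outcome")

  # delta at the published point estimate: phi = 0.5 contributes
  # 0.5 * 1.004 = 0.502 to outcome 1 and 0.5 / 1.004 to outcome 2
  st <- null
  st$log_delta <- log(1.004)
  st$phi_str <- rep(0.5, n)
  expect_equal(log(joint_log_mu(st, E, 1)) - log(E[, 1L]),
               rep(0.502, n))
  expect_equal(log(joint_log_mu(st, E, 2)) - log(E[, 2L]),
               rep(0.5 / 1.004, n))
})

test_that("swapping outcomes, psi and delta <-> 1/delta swaps the means", {
  n <- 5L
  set.seed(3)
  E <- matrix(runif(2L * n, 5, 50), n, 2L)
  st <- random_joint_state(n, seed = 13L)
  sw <- st
  sw$alpha <- rev(st$alpha)
  sw$log_delta <- -st$log_delta
  sw$psi_str <- st$psi_str[, 2:1]
  sw$psi_het <- st$psi_het[, 2:1]
  Esw <- E[, 2:1]
  expect_equal(joint_log_mu(sw, Esw, 1), joint_log_mu(st, E, 2))
  expect_equal(joint_log_mu(sw, Esw, 2), joint_log_mu(st, E, 1))
})

test_that("shared-variance fractions follow the variance-ratio definition", {
  n <- 3L
  base <- list(alpha = c(0, 0), log_delta = 0,
               phi_str = c(1, -1, 0), phi_het = numeric(n),
               psi_str = matrix(0, n, 2L), psi_het = matrix(0, n, 2L))
  # no specific variation: eta = 1
  expect_equal(shared_variance_fractions(base)[1L], 1)

  # equal variances: eta = 0.5
  eq <- base
  eq$psi_str[, 1L] <- c(-1, 1, 0)
  expect_equal(shared_variance_fractions(eq)[1L], 0.5)

  # hand case: delta = 2, phi = (1, -1), psi_2 = (1, -1) on 2 areas
  hand <- list(alpha = c(0, 0), log_delta = log(2),
               phi_str = c(1, -1), phi_het = c(0, 0),
               psi_str = cbind(c(0, 0), c(1, -1)),
               psi_het = matrix(0, 2L, 2L))
  # V(phi/2) / (V(phi/2) + V(psi2)) = 0.5 / (0.5 + 2) = 0.2
  expect_equal(shared_variance_fractions(hand)[2L], 0.2)

  degenerate <- base
  degenerate$phi_str <- numeric(n)
  expect_warning(eta <- shared_variance_fractions(degenerate), "undefined")
  expect_true(all(is.na(eta)))
})

test_that("model log-likelihood matches the Poisson pmf oracle", {
  g <- build_lattice(4, 4)
  n <- g$n_areas
  set.seed(5)
  E <- matrix(runif(2L * n, 20, 80), n, 2L)
  for (s in 1:5) {
    st <- random_joint_state(n, seed = s)
    mu <- cbind(joint_log_mu(st, E, 1), joint_log_mu(st, E, 2))
    Y <- matrix(rpois(2L * n, mu), n, 2L)
    own <- sharedcar:::poisson_loglik(Y, mu)
    oracle <- sum(dpois(Y, mu, log = TRUE))
    expect_equal(own, oracle, tolerance = 1e-10)
  }
})

test_that("rescaling phi with compensating psi leaves the means unchanged", {
  # the identifiability flat direction the sampler exploits
  n <- 6L
  st <- random_joint_state(n, seed = 21L)
  E <- matrix(50, n, 2L)
  c_ <- 1.7
  d <- exp(st$log_delta)
  tr <- st
  tr$phi_str <- c_ * st$phi_str
  tr$phi_het <- c_ * st$phi_het
  phi <- st$phi_str + st$phi_het
  tr$psi_het[, 1L] <- st$psi_het[, 1L] + d * (1 - c_) * phi
  tr$psi_het[, 2L] <- st$psi_het[, 2L] + (1 - c_) / d * phi
  expect_equal(joint_log_mu(tr, E, 1), joint_log_mu(st, E, 1),
               tolerance = 1e-12)
  expect_equal(joint_log_mu(tr, E, 2), joint_log_mu(st, E, 2),
               tolerance = 1e-12)
})

test_that("a quick joint fit returns coherent posterior structure", {
  g <- build_lattice(6, 6)
  sim <- simulate_joint_dataset(g, joint_scenario(g), seed = 2)
  fit <- suppressWarnings(
    fit_joint(sim$dataset, g, quick_mcmc(seed = 3)))
  expect_s3_class(fit, "joint_posterior")
  expect_setequal(
    fit$summary$param,
    c("alpha1", "alpha2", "delta", "eta1", "eta2",
      paste0("sigma_", c("phi_str", "phi_het", "psi_str1", "psi_het1",
                         "psi_str2", "psi_het2"))))
  # eta draws stay in [0, 1] and delta positive, draw by draw
  pooled <- do.call(rbind, fit$draws)
  expect_true(all(pooled[, "eta1"] >= 0 & pooled[, "eta1"] <= 1))
  expect_true(all(pooled[, "eta2"] >= 0 & pooled[, "eta2"] <= 1))
  expect_true(all(pooled[, "delta"] > 0))
  expect_true(all(pooled[, grep("sigma", colnames(pooled))] <
                    prior_config()$sigma_upper))
  expect_equal(nrow(fit$shared_surface), g$n_areas)

  # identical config reruns bit-identically
  fit2 <- suppressWarnings(
    fit_joint(sim$dataset, g, quick_mcmc(seed = 3)))
  expect_identical(fit$draws, fit2$draws)
})

test_that("shared surface export is keyed by id and row-order invariant", {
  g <- build_lattice(4, 4)
  sim <- simulate_joint_dataset(g, joint_scenario(g), seed = 10)
  fit <- suppressWarnings(fit_joint(sim$dataset, g, quick_mcmc(seed = 1)))
  tab <- data.frame(area_id = g$area_ids, extra = seq_len(g$n_areas))
  out1 <- export_shared_surface(fit, tab)
  out2 <- export_shared_surface(fit, tab[rev(seq_len(nrow(tab))), ])
  expect_identical(out1, out2)
  expect_equal(nrow(out1), g$n_areas)
  expect_error(export_shared_surface(fit, tab[-1L, ]), "missing")

  # the mappable surface is centred on the log scale
  expect_lt(abs(mean(fit$shared_surface$mean)), 0.05)
})
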