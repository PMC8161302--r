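test_that("regression mean structure matches the convolution form", {
  n <- 3L
  E <- c(10, 20, 30)
  null <- list(alpha = 0, beta = numeric(0), phi = numeric(n),
               theta = numeric(n))
  expect_equal(regression_log_mu(null, E), E)

  one <- list(alpha = 0, beta = 0.5, phi = numeric(n), theta = numeric(n))
  X <- matrix(2, n, 1L)
  expect_equal(regression_log_mu(one, E, X), E * exp(1))

  # additivity: beta and phi contributions commute
  both <- one
  both$phi <- c(0.1, -0.2, 0.1)
  via_phi_first <- list(alpha = 0, beta = 0.5, phi = both$phi,
                        theta = numeric(n))
  expect_equal(regression_log_mu(both, E, X),
               regression_log_mu(via_phi_first, E, X))
  expect_equal(regression_log_mu(both, E, X),
               E * exp(1 + both$phi))

  expect_error(regression_log_mu(one, E, matrix(1, n, 2L)), "mismatch")
})

test_that("covariate relevance implements the 80% sign-probability rule", {
  all_pos <- covariate_relevance(cbind(a = rep(1, 100)))
  expect_equal(all_pos$p_positive, 1)
  expect_true(all_pos$relevant)
  expect_equal(all_pos$direction, "positive")

  sym <- covariate_relevance(cbind(a = rep(c(1, -1), 50)))
  expect_equal(sym$p_positive, 0.5)
  expect_false(sym$relevant)
  expect_equal(sym$direction, "none")

  # 850 of 1000 positive: P = 0.85 > 0.8
  draws <- c(rep(0.2, 850), rep(-0.2, 150))
  rep85 <- covariate_relevance(cbind(a = draws))
  expect_equal(rep85$p_positive, 0.85)
  expect_true(rep85$relevant)

  neg <- covariate_relevance(cbind(a = -draws))
  expect_true(neg$relevant)
  expect_equal(neg$direction, "negative")

  expect_error(covariate_relevance(cbind(a = draws), threshold = 1.2),
               "threshold")
})

test_that("relative risks summarize draws on the RR scale", {
  n <- 3L
  draws <- list(alpha = rep(0, 100),
                beta = matrix(numeric(0), 100, 0),
                phi = matrix(0, 100, n),
                theta = matrix(rep(c(0, log(2), -log(2)), each = 100),
                               100, n))
  rs <- relative_risk(draws, area_ids = c("a", "b", "c"))
  expect_equal(rs$rr_mean, c(1, 2, 0.5))
  expect_equal(rs$p_exceed_1, c(0, 1, 0))
  expect_true(all(rs$rr_mean > 0))
})

test_that("collinear designs are rejected naming the columns", {
  g <- build_lattice(4, 4)
  n <- g$n_areas
  set.seed(1)
  x <- rnorm(n)
  X <- cbind(immigration = x, immigration_dup = x)
  Y <- matrix(rpois(2L * n, 50), n, 2L)
  d <- area_dataset(g$area_ids, rep(100, n), Y, matrix(50, n, 2L), X)
  expect_error(
    fit_regression(d, 1L, g, quick_mcmc()),
    "collinear.*immigration_dup")
})

test_that("a quick regression fit has coherent structure and risk surface", {
  g <- build_lattice(6, 6)
  sim <- simulate_regression_dataset(g, beta = c(0.4, -0.4),
                                     sigma_phi = 0.2, sigma_theta = 0.05,
                                     seed = 12)
  fit <- suppressWarnings(
    fit_regression(sim$dataset, 1L, g, quick_mcmc(seed = 5)))
  expect_s3_class(fit, "regression_posterior")
  expect_setequal(fit$summary$param,
                  c("alpha", "beta_mean_income", "beta_education",
                    "sigma_phi", "sigma_theta"))
  expect_equal(nrow(fit$risk_surface), g$n_areas)
  expect_true(all(fit$risk_surface$rr_mean > 0))
  expect_true(all(fit$risk_surface$p_exceed_1 >= 0 &
                    fit$risk_surface$p_exceed_1 <= 1))
  expect_true(all(fit$risk_surface$rr_q2.5 <= fit$risk_surface$rr_q97.5))
  expect_equal(nrow(fit$covariates), 2L)

  # likelihood identity against the pmf oracle on the fitted draws scale
  st <- list(alpha = 0.1, beta = c(0.2, -0.1),
             phi = rnorm(g$n_areas, 0, 0.1),
             theta = rnorm(g$n_areas, 0, 0.1))
  mu <- regression_log_mu(st, sim$dataset$E[, 1L], scale(sim$dataset$X))
  own <- sharedcar:::poisson_loglik(sim$dataset$Y[, 1L], mu)
  expect_equal(own, sum(dpois(sim$dataset$Y[, 1L], mu, log = TRUE)),
               tolerance = 1e-10)
})

test_that("sigma attribution follows the data-generating field", {
  g <- build_lattice(8, 8)
  cfg <- mcmc_config(n_iter = 1200, burn_in = 400, thin = 2,
                     n_chains = 2, seed = 6)
  theta_only <- simulate_regression_dataset(g, beta = numeric(0),
                                            sigma_phi = 0,
                                            sigma_theta = 0.4, seed = 31)
  fit_t <- suppressWarnings(
    fit_regression(theta_only$dataset, 1L, g, cfg))
  s_t <- fit_t$summary
  expect_lt(s_t$mean[s_t$param == "sigma_phi"],
            s_t$mean[s_t$param == "sigma_theta"])

  phi_only <- simulate_regression_dataset(g, beta = numeric(0),
                                          sigma_phi = 0.6,
                                          sigma_theta = 0, seed = 32)
  fit_p <- suppressWarnings(
    fit_regression(phi_only$dataset, 1L, g, cfg))
  s_p <- fit_p$summary
  expect_gt(s_p$mean[s_p$param == "sigma_phi"],
            s_p$mean[s_p$param == "sigma_theta"])
})

test_that("rescaling all E shifts the intercept and rescales RR exactly", {
  # the relative risk includes the intercept, so it is measured against the
  # expected-counts baseline: doubling every E makes alpha refit by -log 2
  # and divides every RR by 2, leaving the risk RANKING and all RR ratios
  # between areas unchanged
  g <- build_lattice(6, 6)
  sim <- simulate_regression_dataset(g, beta = 0.3, sigma_phi = 0.2,
                                     sigma_theta = 0.05, seed = 14)
  d1 <- sim$dataset
  d2 <- area_dataset(d1$area_ids, d1$population, d1$Y, 2 * d1$E, d1$X)
  cfg <- mcmc_config(n_iter = 1500, burn_in = 500, thin = 2,
                     n_chains = 2, seed = 7)
  f1 <- suppressWarnings(fit_regression(d1, 1L, g, cfg))
  f2 <- suppressWarnings(fit_regression(d2, 1L, g, cfg))
  a1 <- f1$summary$mean[f1$summary$param == "alpha"]
  a2 <- f2$summary$mean[f2$summary$param == "alpha"]
  expect_equal(a2 - a1, -log(2), tolerance = 0.05)
  expect_equal(f2$risk_surface$rr_mean / f1$risk_surface$rr_mean,
               rep(0.5, g$n_areas), tolerance = 0.1)
  # area-to-area risk ratios are baseline-free
  rel1 <- f1$risk_surface$rr_mean / f1$risk_surface$rr_mean[1L]
  rel2 <- f2$risk_surface$rr_mean / f2$risk_surface$rr_mean[1L]
  expect_equal(rel2, rel1, tolerance = 0.1)
})
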