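# random-walk model over a generic log target, for exercising run_chains
rw_model <- function(log_target, n_par, scale = 1, init = NULL) {
  list(make_chain = function(chain_id) {
    x <- if (is.null(init)) rnorm(n_par) else init
    list(
      sweep = function(adapt) {
        for (j in seq_len(n_par)) {
          xp <- x
          xp[j] <- x[j] + rnorm(1L, 0, scale)
          if (log(runif(1L)) < log_target(xp) - log_target(x)) x <<- xp
        }
      },
      monitor = function() setNames(x, paste0("x", seq_len(n_par)))
    )
  })
}

test_that("split-Rhat behaves as a convergence diagnostic should", {
  set.seed(1)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_lt(rhat(iid), 1.05)

  apart <- cbind(rnorm(500, 0), rnorm(500, 10))
  expect_gt(rhat(apart), 3)

  # invariant to chain relabelling
  expect_equal(rhat(iid), rhat(iid[, c(3, 1, 4, 2)]))

  expect_error(rhat(iid[, 1, drop = FALSE]), "2 chains")
  expect_error(rhat(iid[1:3, ]), "4 draws")
  expect_warning(r0 <- rhat(matrix(1, 100, 2)), "zero")
  expect_true(is.na(r0))
})

test_that("summaries report mean, sd, equal-tailed CrI, and Rhat", {
  const <- summarize_draws(matrix(3.5, 50, 1, dimnames = list(NULL, "c")))
  expect_equal(const$mean, 3.5)
  expect_equal(const$sd, 0)
  expect_equal(const$q2.5, 3.5)
  expect_equal(const$q97.5, 3.5)

  seq100 <- summarize_draws(matrix(1:100, 100, 1,
                                   dimnames = list(NULL, "s")))
  expect_equal(seq100$mean, 50.5)

  set.seed(2)
  z1 <- matrix(rnorm(2e4, 2, 3), ncol = 1, dimnames = list(NULL, "z"))
  z2 <- matrix(rnorm(2e4, 2, 3), ncol = 1, dimnames = list(NULL, "z"))
  s <- summarize_draws(list(z1, z2))
  expect_equal(s$q2.5, 2 - 1.96 * 3, tolerance = 0.05)
  expect_equal(s$q97.5, 2 + 1.96 * 3, tolerance = 0.05)
  expect_lt(s$rhat, 1.01)
})

test_that("mcmc_config validates its fields", {
  expect_error(mcmc_config(n_iter = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_config(thin = 0), "invalid")
  expect_error(mcmc_config(adapt_until = 5000, burn_in = 1000), "frozen")
  expect_error(prior_config(sigma_upper = 0), "positive")
})

test_that("run_chains recovers a standard-normal toy target", {
  model <- rw_model(function(x) -sum(x^2) / 2, n_par = 1L, scale = 2.4)
  fit <- run_chains(model, mcmc_config(n_iter = 3000, burn_in = 500,
                                       thin = 1, n_chains = 4, seed = 11))
  expect_lt(abs(fit$summary$mean), 0.05)
  expect_equal(fit$summary$sd, 1, tolerance = 0.05)
  expect_lt(fit$summary$rhat, 1.01)

  # determinism under the same config
  fit2 <- run_chains(model, mcmc_config(n_iter = 3000, burn_in = 500,
                                        thin = 1, n_chains = 4, seed = 11))
  expect_identical(fit$draws, fit2$draws)
})

test_that("run_chains recovers a correlated bivariate normal", {
  rho <- 0.7
  Qi <- solve(matrix(c(1, rho, rho, 1), 2))
  model <- rw_model(function(x) -drop(t(x) %*% Qi %*% x) / 2, n_par = 2L,
                    scale = 1.2)
  fit <- run_chains(model, mcmc_config(n_iter = 6000, burn_in = 1000,
                                       thin = 1, n_chains = 2, seed = 4))
  pooled <- do.call(rbind, fit$draws)
  expect_equal(cor(pooled[, 1], pooled[, 2]), rho, tolerance = 0.05)
})

test_that("initialization at a non-finite target is reported by block", {
  model <- list(make_chain = function(chain_id) {
    list(sweep = function(adapt) NULL,
         monitor = function() c(good = 1, bad = Inf))
  })
  expect_error(run_chains(model, quick_mcmc()), "bad")
})

test_that("slice sampler reproduces a known distribution", {
  set.seed(8)
  x <- 0.3
  draws <- replicate(4000, {
    x <<- sharedcar:::slice_cycle(x, function(z) dgamma(z, 3, 2, log = TRUE))
    x
  })
  expect_equal(mean(draws), 1.5, tolerance = 0.05)
  expect_equal(var(draws), 0.75, tolerance = 0.08)
  ks <- suppressWarnings(
    ks.test(draws[seq(1, 4000, by = 4)], pgamma, 3, 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("Gibbs scale draw matches the truncated-Gamma law", {
  # draw_sigma targets p(sigma) ~ sigma^-rank exp(-ss/(2 sigma^2)) on (0, u)
  set.seed(9)
  ss <- 4; rank <- 10; u <- 2
  draws <- replicate(5000, sharedcar:::draw_sigma(0.5, ss, rank, u))
  # oracle: inverse-cdf on a fine grid of the same kernel
  grid <- seq(1e-4, u, length.out = 20000)
  dens <- grid^(-rank) * exp(-ss / (2 * grid^2))
  cdf <- cumsum(dens) / sum(dens)
  oracle <- grid[findInterval(runif(5000), cdf) + 1L]
  ks <- suppressWarnings(ks.test(draws, oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("proposal adaptation freezes after the adaptation horizon", {
  tuner <- sharedcar:::make_tuner("a", init_scale = 0.1, target = 0.44)
  for (i in 1:200) sharedcar:::tune_record(tuner, "a", 1L, 1L, TRUE)
  adapted <- tuner$scale[["a"]]
  expect_gt(adapted, 0.1)  # all-accepts push the scale up
  for (i in 1:200) sharedcar:::tune_record(tuner, "a", 1L, 1L, FALSE)
  expect_identical(tuner$scale[["a"]], adapted)
})
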