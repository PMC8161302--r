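test_that("expected counts standardize internally", {
  expect_equal(drop(compute_expected_counts(c(100, 100), 10)), c(5, 5))
  expect_equal(drop(compute_expected_counts(c(100, 300), 8)), c(2, 6))
  set.seed(1)
  pop <- runif(17, 50, 5000)
  E <- compute_expected_counts(pop, c(123, 4567))
  expect_equal(colSums(E), c(123, 4567))
  expect_error(compute_expected_counts(c(0, 10), 5), "positive")
})

test_that("joint simulation is reproducible and respects the model form", {
  g <- build_lattice(5, 5)
  sc <- joint_scenario(g)
  a <- simulate_joint_dataset(g, sc, seed = 3)
  b <- simulate_joint_dataset(g, sc, seed = 3)
  expect_identical(a$dataset$Y, b$dataset$Y)
  expect_identical(a$truth$phi, b$truth$phi)
  expect_false(identical(
    a$dataset$Y, simulate_joint_dataset(g, sc, seed = 4)$dataset$Y))

  # counts are nonnegative integers; structured parts sum to zero
  expect_true(all(a$dataset$Y >= 0))
  expect_true(all(a$dataset$Y == round(a$dataset$Y)))
  expect_lt(abs(sum(a$truth$phi_str)), 1e-8)
  expect_lt(abs(sum(a$truth$psi_str[, 1L])), 1e-8)
})

test_that("null joint scenario reduces to pure Poisson noise around E", {
  g <- build_lattice(20, 20)
  sc <- joint_scenario(g, shared_var = 0, target_eta = c(0.5, 0.5))
  sc$sigma_phi[] <- 0; sc$sigma_psi[] <- 0
  sim <- simulate_joint_dataset(g, sc, seed = 5)
  # mu = E exactly, so mean(Y/E) ~ 1 +- 3 Monte-Carlo standard errors
  ratio <- sim$dataset$Y / sim$dataset$E
  mc_se <- sqrt(1 / mean(sim$dataset$E)) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 1), 3 * mc_se)
})

test_that("delta scales the two outcomes reciprocally", {
  # Table-2-sized scaling factor: phi = 1 contributes delta and 1/delta
  st <- list(alpha = c(0, 0), log_delta = log(1.004),
             phi_str = rep(1, 2L), phi_het = rep(0, 2L),
             psi_str = matrix(0, 2L, 2L), psi_het = matrix(0, 2L, 2L))
  E <- matrix(1, 2L, 2L)
  expect_equal(log(joint_log_mu(st, E, 1))[1L], 1.004)
  expect_equal(log(joint_log_mu(st, E, 2))[1L], 1 / 1.004)
})

test_that("with delta = 1 both outcomes share an identical shared part", {
  g <- build_lattice(6, 6)
  sim <- simulate_joint_dataset(g, joint_scenario(g, delta = 1), seed = 8)
  d <- sim$truth$delta
  expect_identical(sim$truth$phi * d, sim$truth$phi / d)
})

test_that("generator hits the target shared-variance ratio at scale", {
  # a single ICAR realisation has few effective degrees of freedom in its
  # smooth modes, so the realized variance ratio of one map fluctuates;
  # the calibration target is the mean ratio at the 2500-area scale
  g <- build_lattice(50, 50)
  sc <- joint_scenario(g, target_eta = c(0.6, 0.9))
  st <- sharedcar:::icar_eigen(g)
  n <- g$n_areas
  R <- 8L
  set.seed(33)
  draw_field <- function(s_str, s_het) {
    sharedcar:::icar_sample_exact(g, s_str, R, structure = st) +
      matrix(rnorm(R * n, 0, s_het), R, n)
  }
  phi <- draw_field(sc$sigma_phi[["str"]], sc$sigma_phi[["het"]])
  psi1 <- draw_field(sc$sigma_psi["str", 1L], sc$sigma_psi["het", 1L])
  psi2 <- draw_field(sc$sigma_psi["str", 2L], sc$sigma_psi["het", 2L])
  eta <- vapply(seq_len(R), function(r) {
    vs <- var(phi[r, ])
    c(vs / (vs + var(psi1[r, ])), vs / (vs + var(psi2[r, ])))
  }, numeric(2L))
  expect_lt(abs(mean(eta[1L, ]) - 0.6), 0.05)
  expect_lt(abs(mean(eta[2L, ]) - 0.9), 0.05)
})

test_that("regression generator recovers its slope under a Poisson ML oracle", {
  g <- build_lattice(20, 20)
  sim <- simulate_regression_dataset(g, beta = 0.5, sigma_phi = 0,
                                     sigma_theta = 0, seed = 6)
  d <- sim$dataset
  ml <- stats::glm(d$Y[, 1L] ~ d$X[, 1L] + offset(log(d$E[, 1L])),
                   family = stats::poisson())
  expect_lt(abs(unname(stats::coef(ml)[2L]) - 0.5), 0.1)

  # beta = 0, no fields: Y/E fluctuates around 1
  null <- simulate_regression_dataset(g, beta = 0, sigma_phi = 0,
                                      sigma_theta = 0, seed = 7)
  ratio <- null$dataset$Y / null$dataset$E
  mc_se <- sqrt(1 / mean(null$dataset$E)) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 1), 3 * mc_se)

  expect_identical(
    simulate_regression_dataset(g, beta = 0.5, seed = 9)$dataset$Y,
    simulate_regression_dataset(g, beta = 0.5, seed = 9)$dataset$Y)
})

test_that("covariate scheme is z-scored with reference moments available", {
  g <- build_lattice(8, 8)
  sim <- simulate_regression_dataset(g, beta = c(0.2, -0.2, 0.1), seed = 2)
  X <- sim$dataset$X
  expect_equal(unname(colMeans(X)), rep(0, 3L), tolerance = 1e-10)
  expect_equal(unname(apply(X, 2L, sd)), rep(1, 3L), tolerance = 1e-10)
  expect_equal(colnames(X)[1:2], c("mean_income", "education"))
  sch <- covariate_scheme()
  expect_equal(nrow(sch), 11L)
  expect_true(all(sch$sd > 0))
})

test_that("invalid generator parameters are rejected", {
  g <- build_lattice(3, 3)
  sc <- joint_scenario(g)
  sc$delta <- -1
  expect_error(simulate_joint_dataset(g, sc, seed = 1), "positive")
  expect_error(simulate_regression_dataset(g, beta = 0.5, sigma_phi = -0.1,
                                           seed = 1), "nonnegative")
  expect_error(joint_scenario(g, delta = 0), "delta")
})

test_that("area_dataset validates its invariants", {
  expect_error(area_dataset(c("a", "b"), c(1, 1),
                            matrix(c(-1, 0, 0, 0), 2L), matrix(1, 2L, 2L)),
               "nonnegative")
  expect_error(area_dataset(c("a", "b"), c(1, 1),
                            matrix(0L, 2L, 2L), matrix(0, 2L, 2L)),
               "positive")
  expect_error(area_dataset(c("a", "b"), c(1, -1),
                            matrix(0L, 2L, 2L), matrix(1, 2L, 2L)),
               "population")
})
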