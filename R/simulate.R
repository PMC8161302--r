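#' Areal datasets
#'
#' An `area_dataset` bundles everything the models consume: per-area
#' populations, observed counts \eqn{Y_{ik}} for up to two outcomes,
#' positive expected counts \eqn{E_{ik}} (the standardization offset that
#' makes the latent surface a relative risk), and an optional covariate
#' matrix.
#'
#' @param area_ids character area labels, in graph order.
#' @param population positive numeric vector.
#' @param Y matrix of nonnegative integer counts (areas by outcomes).
#' @param E matrix of positive expected counts, same shape as `Y`.
#' @param X optional numeric covariate matrix (areas by covariates) with
#'   column names.
#' @return Object of class `area_dataset`.
#' @export
area_dataset <- function(area_ids, population, Y, E, X = NULL) {
  area_ids <- as.character(area_ids)
  n <- length(area_ids)
  Y <- as.matrix(Y); E <- as.matrix(E)
  if (nrow(Y) != n || nrow(E) != n)
    stop("Y and E must have one row per area")
  if (!identical(dim(Y), dim(E)))
    stop("Y and E must have the same shape")
  if (length(population) != n || any(population <= 0))
    stop("population must be positive, one value per area")
  if (any(Y < 0) || any(Y != round(Y)))
    stop("counts must be nonnegative integers")
  if (any(E <= 0)) stop("expected counts must be strictly positive")
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (ncol(X) == 0L) X <- NULL
    else {
      if (nrow(X) != n) stop("X must have one row per area")
      if (is.null(colnames(X)))
        colnames(X) <- paste0("x", seq_len(ncol(X)))
    }
  }
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  if (is.null(colnames(E))) colnames(E) <- paste0("e", seq_len(ncol(E)))
  structure(list(area_ids = area_ids, population = as.numeric(population),
                 Y = Y, E = E, X = X, n_areas = n),
            class = "area_dataset")
}

#' @export
print.area_dataset <- function(x, ...) {
  cat(sprintf("area_dataset: %d areas, %d outcome(s), %s covariate(s)\n",
              x$n_areas, ncol(x$Y),
              if (is.null(x$X)) "no" else ncol(x$X)))
  invisible(x)
}

# reorder a dataset's rows to the graph's area ordering (keyed by id);
# errors if the two area sets differ
align_dataset <- function(data, graph) {
  if (identical(data$area_ids, graph$area_ids)) return(data)
  only_d <- setdiff(data$area_ids, graph$area_ids)
  only_g <- setdiff(graph$area_ids, data$area_ids)
  if (length(only_d) || length(only_g))
    stop("dataset and graph areas differ; only in dataset: ",
         paste(only_d, collapse = ", "), "; only in graph: ",
         paste(only_g, collapse = ", "))
  idx <- match(graph$area_ids, data$area_ids)
  area_dataset(graph$area_ids, data$population[idx],
               data$Y[idx, , drop = FALSE], data$E[idx, , drop = FALSE],
               if (is.null(data$X)) NULL else data$X[idx, , drop = FALSE])
}

#' Expected counts by internal standardization
#'
#' Allocates each outcome's total count across areas proportionally to
#' population: \eqn{E_{ik} = T_k \, p_i / \sum_j p_j}. The column sums
#' reproduce the totals exactly, so observed/expected ratios average 1 and
#' the latent surface reads as relative risk against the whole-map average.
#'
#' @param population positive numeric vector.
#' @param total_counts positive total per outcome.
#' @return Matrix of expected counts (areas by outcomes).
#' @examples
#' compute_expected_counts(c(100, 300), 8)  # 2 and 6
#' @export
compute_expected_counts <- function(population, total_counts) {
  if (any(population <= 0)) stop("populations must be strictly positive")
  if (any(total_counts <= 0)) stop("totals must be strictly positive")
  outer(population / sum(population), as.numeric(total_counts))
}

# expected across-area empirical variance of an exact ICAR draw with
# conditional sigma = 1: E[var(x)] = sum_k 1/lambda_k / (n - 1)
icar_marginal_variance <- function(graph, structure = NULL) {
  if (is.null(structure)) structure <- icar_eigen(graph)
  sum(vapply(structure, function(st) sum(1 / st$values), 0)) /
    (graph$n_areas - 1)
}

#' Shared-component simulation scenario
#'
#' Translates interpretable targets -- the across-area variance of the
#' shared log-risk surface and the shared-variance fraction
#' \eqn{\eta_k} for each outcome -- into the conditional scale parameters of
#' the structured (ICAR) and unstructured (iid Gaussian) field parts, using
#' the exact eigenvalue formula for the marginal variance of an ICAR draw on
#' the given graph. Defaults encode the study conditions the package is
#' validated under: a unit scaling factor, a shared surface with standard
#' deviation 0.4 on the log-risk scale, shared-variance fractions of 0.6
#' (outcome 1) and 0.9 (outcome 2), three quarters of each field's variance
#' spatially structured, and expected counts of about 50 per area.
#'
#' @param graph an [area_graph()].
#' @param alpha length-2 log-scale intercepts.
#' @param delta positive scaling factor of the shared component (multiplies
#'   outcome 1's share, divides outcome 2's).
#' @param shared_var across-area variance of the shared field
#'   \eqn{\phi} (structured + unstructured).
#' @param target_eta length-2 shared-variance fractions used to size the
#'   outcome-specific fields (nominal; the realized fractions of a finite
#'   draw are recorded in the simulation truth).
#' @param structured_frac fraction of each field's variance carried by the
#'   structured (ICAR) part.
#' @param mean_expected expected count per area per outcome.
#' @return Named list of scenario parameters consumed by
#'   [simulate_joint_dataset()].
#' @export
joint_scenario <- function(graph, alpha = c(0, 0), delta = 1,
                           shared_var = 0.16, target_eta = c(0.6, 0.9),
                           structured_frac = 0.75, mean_expected = 50) {
  stopifnot(delta > 0, shared_var >= 0, all(target_eta > 0),
            all(target_eta <= 1), structured_frac >= 0,
            structured_frac <= 1, mean_expected > 0)
  v1 <- icar_marginal_variance(graph)
  sig <- function(total_var) {
    c(str = sqrt(total_var * structured_frac / v1),
      het = sqrt(total_var * (1 - structured_frac)))
  }
  # eta_k = V(shared as seen by k) / (V(shared) + V(psi_k));
  # outcome 1 sees delta * phi, outcome 2 sees phi / delta
  v_seen <- shared_var * c(delta^2, 1 / delta^2)
  psi_var <- v_seen * (1 / target_eta - 1)
  list(alpha = alpha, delta = delta,
       sigma_phi = sig(shared_var),
       sigma_psi = cbind(sig(psi_var[1L]), sig(psi_var[2L])),
       mean_expected = mean_expected)
}

# draw structured + unstructured field parts; sigma = 0 disables a part
draw_field_parts <- function(graph, sigma_str, sigma_het, seed, tag) {
  n <- graph$n_areas
  str <- if (sigma_str > 0)
    with_seed(mix_seed(seed, paste0(tag, "_str")),
              drop(icar_sample_exact(graph, sigma_str, 1L)))
  else numeric(n)
  het <- if (sigma_het > 0)
    with_seed(mix_seed(seed, paste0(tag, "_het")),
              stats::rnorm(n, 0, sigma_het))
  else numeric(n)
  list(str = str, het = het)
}

#' Simulate a two-outcome dataset from the shared-component model
#'
#' Forward simulation of the joint model: one shared spatial surface
#' \eqn{\phi} (structured ICAR part plus unstructured Gaussian part) enters
#' outcome 1 scaled by \eqn{\delta} and outcome 2 scaled by
#' \eqn{1/\delta}; each outcome additionally gets its own specific surface
#' \eqn{\psi_k}. Counts are Poisson around
#' \eqn{\mu_{i1} = E_{i1} \exp(\alpha_1 + \delta\phi_i + \psi_{i1})} and
#' \eqn{\mu_{i2} = E_{i2} \exp(\alpha_2 + \phi_i/\delta + \psi_{i2})}.
#' Populations are equal across areas by default, and expected counts come
#' from internal standardization so that each area's expected count equals
#' `mean_expected`.
#'
#' @param graph an [area_graph()].
#' @param scenario parameter list from [joint_scenario()]; any element can
#'   be overridden there.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param population optional positive vector overriding the equal-
#'   population default.
#' @return List with `dataset` (an [area_dataset()]) and `truth`, the full
#'   simulation ground truth: intercepts, `delta`, all field parts, all
#'   scale parameters, and `realized_eta`, the shared-variance fractions
#'   actually realized by the drawn fields (the recovery target for finite
#'   maps).
#' @export
simulate_joint_dataset <- function(graph, scenario = joint_scenario(graph),
                                   seed = 1L, population = NULL) {
  n <- graph$n_areas
  if (scenario$delta <= 0) stop("delta must be positive")
  if (any(unlist(scenario[c("sigma_phi", "sigma_psi")]) < 0))
    stop("field scale parameters must be nonnegative")
  if (is.null(population)) population <- rep(1000, n)
  E <- compute_expected_counts(population,
                               rep(scenario$mean_expected * n, 2L))

  phi <- draw_field_parts(graph, scenario$sigma_phi[["str"]],
                          scenario$sigma_phi[["het"]], seed, "phi")
  psi1 <- draw_field_parts(graph, scenario$sigma_psi["str", 1L],
                           scenario$sigma_psi["het", 1L], seed, "psi1")
  psi2 <- draw_field_parts(graph, scenario$sigma_psi["str", 2L],
                           scenario$sigma_psi["het", 2L], seed, "psi2")
  phi_full <- phi$str + phi$het
  psi_full <- cbind(psi1$str + psi1$het, psi2$str + psi2$het)
  d <- scenario$delta
  log_mu <- cbind(log(E[, 1L]) + scenario$alpha[1L] + phi_full * d +
                    psi_full[, 1L],
                  log(E[, 2L]) + scenario$alpha[2L] + phi_full / d +
                    psi_full[, 2L])
  Y <- with_seed(mix_seed(seed, "counts"),
                 matrix(stats::rpois(2L * n, exp(log_mu)), n, 2L))

  shared_seen <- cbind(phi_full * d, phi_full / d)
  realized_eta <- vapply(1:2, function(k) {
    vs <- stats::var(shared_seen[, k])
    vs / (vs + stats::var(psi_full[, k]))
  }, 0)

  list(dataset = area_dataset(graph$area_ids, population, Y, E),
       truth = list(alpha = scenario$alpha, delta = d,
                    phi = phi_full, phi_str = phi$str, phi_het = phi$het,
                    psi = psi_full,
                    psi_str = cbind(psi1$str, psi2$str),
                    psi_het = cbind(psi1$het, psi2$het),
                    sigma = list(phi = scenario$sigma_phi,
                                 psi = scenario$sigma_psi),
                    realized_eta = realized_eta, seed = seed))
}

#' Reference covariate scheme
#'
#' Marginal moments for the eleven neighbourhood covariates the regression
#' stage is designed around (income, education, vulnerability, physical
#' disorder and decay, vacant lots, immigration, residential instability,
#' and three alcohol-outlet densities). Only means and standard deviations
#' are specified; covariates are drawn as independent Gaussians at these
#' moments and then z-scored before entering a model.
#'
#' @return Data frame with columns `name`, `mean`, `sd`.
#' @export
covariate_scheme <- function() {
  data.frame(
    name = c("mean_income", "education", "vulnerability",
             "physical_disorder", "physical_decay", "vacant_lots",
             "immigration", "residential_instability",
             "off_premise_density", "restaurant_cafe_density",
             "bar_density"),
    mean = c(12285, 3.15, 3.07, 8.88, 3.04, 1.03, 15.16, 229.70,
             55.13, 48.83, 154.06),
    sd = c(4031.33, 0.33, 0.34, 5.13, 2.79, 3.11, 7.31, 91.18,
           66.8, 72.2, 127.3))
}

#' Simulate a dataset from the spatial (BYM) Poisson regression model
#'
#' Forward simulation of the convolution regression: for each outcome,
#' \eqn{\log\mu_{ik} = \log E_{ik} + \alpha_k + X_i\beta_k + \phi_{ik} +
#' \theta_{ik}} with a structured ICAR field \eqn{\phi} and an iid Gaussian
#' heterogeneity field \eqn{\theta}, each drawn independently per outcome.
#' Covariates are drawn from [covariate_scheme()] moments (recycled as
#' standard normals beyond the scheme's eleven columns) and z-scored.
#'
#' @param graph an [area_graph()].
#' @param beta coefficient vector (applied to both outcomes) or a
#'   `p x 2` matrix with one column per outcome.
#' @param alpha length-2 log-scale intercepts.
#' @param sigma_phi,sigma_theta nonnegative field scales (0 disables the
#'   field).
#' @param mean_expected expected count per area per outcome.
#' @param seed integer seed.
#' @param population optional positive vector (equal by default).
#' @return List with `dataset` (covariates attached) and `truth` holding
#'   `alpha`, `beta` (as a `p x 2` matrix), the per-outcome fields and all
#'   scales.
#' @export
simulate_regression_dataset <- function(graph, beta, alpha = c(0, 0),
                                        sigma_phi = 0.3, sigma_theta = 0.1,
                                        mean_expected = 50, seed = 1L,
                                        population = NULL) {
  n <- graph$n_areas
  beta <- if (is.matrix(beta)) beta else cbind(beta, beta)
  if (ncol(beta) != 2L) stop("beta must be a vector or a p x 2 matrix")
  p <- nrow(beta)
  if (sigma_phi < 0 || sigma_theta < 0)
    stop("field scale parameters must be nonnegative")
  if (is.null(population)) population <- rep(1000, n)
  E <- compute_expected_counts(population, rep(mean_expected * n, 2L))

  scheme <- covariate_scheme()
  X <- with_seed(mix_seed(seed, "covariates"), {
    raw <- matrix(stats::rnorm(n * p), n, p)
    for (j in seq_len(min(p, nrow(scheme))))
      raw[, j] <- scheme$mean[j] + scheme$sd[j] * raw[, j]
    raw
  })
  X <- scale(X)[, , drop = FALSE]  # z-scored design
  colnames(X) <- c(scheme$name, paste0("x", seq_len(max(0, p - 11))))[
    seq_len(p)]

  fields <- lapply(1:2, function(k) {
    phi <- if (sigma_phi > 0)
      with_seed(mix_seed(seed, paste0("phi", k)),
                drop(icar_sample_exact(graph, sigma_phi, 1L)))
    else numeric(n)
    theta <- if (sigma_theta > 0)
      with_seed(mix_seed(seed, paste0("theta", k)),
                stats::rnorm(n, 0, sigma_theta))
    else numeric(n)
    list(phi = phi, theta = theta)
  })
  log_mu <- vapply(1:2, function(k) {
    log(E[, k]) + alpha[k] + drop(X %*% beta[, k]) +
      fields[[k]]$phi + fields[[k]]$theta
  }, numeric(n))
  Y <- with_seed(mix_seed(seed, "counts"),
                 matrix(stats::rpois(2L * n, exp(log_mu)), n, 2L))

  list(dataset = area_dataset(graph$area_ids, population, Y, E, X),
       truth = list(alpha = alpha, beta = beta,
                    phi = vapply(fields, `[[`, numeric(n), "phi"),
                    theta = vapply(fields, `[[`, numeric(n), "theta"),
                    sigma = c(phi = sigma_phi, theta = sigma_theta),
                    seed = seed))
}
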