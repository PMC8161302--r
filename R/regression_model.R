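#' Regression-model mean structure
#'
#' Evaluates the Poisson means of the spatial (BYM/convolution) regression:
#' \eqn{\log\mu_i = \log E_i + \alpha + X_i\beta + \phi_i + \theta_i}, with
#' a spatially structured field \eqn{\phi} and an unstructured
#' heterogeneity field \eqn{\theta}.
#'
#' @param state list with `alpha`, `beta` (length p, may be empty), `phi`,
#'   `theta`.
#' @param E per-area positive expected counts (vector).
#' @param X covariate matrix (areas by p), or `NULL` for intercept-only.
#' @return Per-area positive vector of means.
#' @export
regression_log_mu <- function(state, E, X = NULL) {
  n <- length(E)
  if (length(state$phi) != n || length(state$theta) != n)
    stop("field lengths must match the number of areas")
  xb <- 0
  if (length(state$beta)) {
    if (is.null(X) || ncol(X) != length(state$beta) || nrow(X) != n)
      stop("dimension mismatch between X and beta")
    xb <- drop(X %*% state$beta)
  }
  exp(log(E) + state$alpha + xb + state$phi + state$theta)
}

#' Relative-risk surface from posterior draws
#'
#' For each retained draw, the area relative risk is
#' \eqn{RR_i = \exp(\alpha + X_i\beta + \phi_i + \theta_i)} -- the risk
#' relative to the map-wide average, so 1 is the average risk and 2 twice
#' the average. Draws are summarized on the RR scale: posterior mean, 95%
#' credible interval, and the exceedance probability \eqn{P(RR_i > 1)}.
#'
#' @param draws list of posterior draws: `alpha` (vector, length = number of
#'   retained draws), `beta` (draws by p matrix, may have 0 columns),
#'   `phi` and `theta` (draws by areas matrices).
#' @param X covariate matrix (areas by p), or `NULL`.
#' @param area_ids optional area labels.
#' @return Object of class `risk_surface`: data frame with `area_id`,
#'   `rr_mean`, `rr_q2.5`, `rr_q97.5`, `p_exceed_1`.
#' @export
relative_risk <- function(draws, X = NULL, area_ids = NULL) {
  n <- ncol(draws$phi)
  lin <- draws$alpha + draws$phi + draws$theta
  if (!is.null(draws$beta) && ncol(draws$beta) > 0) {
    if (is.null(X)) stop("X required when beta draws are present")
    lin <- lin + draws$beta %*% t(X)
  }
  rr <- exp(lin)
  if (is.null(area_ids)) area_ids <- as.character(seq_len(n))
  out <- data.frame(
    area_id = area_ids,
    rr_mean = colMeans(rr),
    rr_q2.5 = apply(rr, 2L, stats::quantile, 0.025),
    rr_q97.5 = apply(rr, 2L, stats::quantile, 0.975),
    p_exceed_1 = colMeans(rr > 1),
    row.names = NULL)
  class(out) <- c("risk_surface", "data.frame")
  out
}

#' Covariate relevance by posterior probability of sign
#'
#' A covariate is flagged as relevant when the posterior probability of its
#' coefficient being positive, or of being negative, exceeds the threshold
#' (default 80%). The direction of the association is reported alongside.
#'
#' @param beta_draws matrix of coefficient draws (draws by covariates) with
#'   column names, or a vector for a single covariate.
#' @param threshold posterior-probability cutoff in (0.5, 1).
#' @return Data frame with one row per covariate: posterior `mean`, `sd`,
#'   95% CrI, `p_positive`, `relevant`, `direction`
#'   (`"positive"`/`"negative"`/`"none"`).
#' @examples
#' covariate_relevance(cbind(x = c(rep(1, 85), rep(-1, 15))))
#' @export
covariate_relevance <- function(beta_draws, threshold = 0.8) {
  if (is.null(dim(beta_draws))) beta_draws <- cbind(beta = beta_draws)
  if (threshold <= 0.5 || threshold >= 1)
    stop("threshold must lie in (0.5, 1)")
  if (ncol(beta_draws) == 0L)
    return(data.frame(covariate = character(0), mean = numeric(0),
                      sd = numeric(0), q2.5 = numeric(0),
                      q97.5 = numeric(0), p_positive = numeric(0),
                      relevant = logical(0), direction = character(0)))
  if (nrow(beta_draws) == 0L) stop("no draws supplied")
  nms <- colnames(beta_draws)
  if (is.null(nms)) nms <- paste0("beta", seq_len(ncol(beta_draws)))
  out <- lapply(seq_len(ncol(beta_draws)), function(j) {
    b <- beta_draws[, j]
    p_pos <- mean(b > 0)
    relevant <- max(p_pos, 1 - p_pos) > threshold
    q <- unname(stats::quantile(b, c(0.025, 0.975)))
    data.frame(covariate = nms[j], mean = mean(b), sd = stats::sd(b),
               q2.5 = q[1L], q97.5 = q[2L], p_positive = p_pos,
               relevant = relevant,
               direction = if (!relevant) "none"
                           else if (p_pos >= 0.5) "positive" else "negative")
  })
  do.call(rbind, out)
}

#' Fit a spatial (BYM) Poisson regression for one outcome
#'
#' Metropolis-within-Gibbs sampler for the convolution model: Poisson counts
#' with offset `E`, flat intercept, vague Gaussian priors (variance
#' `beta_variance`) on coefficients, an ICAR structured field and an iid
#' heterogeneity field with U(0, `sigma_upper`) hyperpriors on their scales.
#' Covariates are z-scored by default before fitting (raw-units mode via
#' `standardize = FALSE`). The structured field is recentred to sum to zero
#' per graph component after every sweep, the removed mean absorbed into the
#' intercept.
#'
#' @param data an [area_dataset()].
#' @param outcome which outcome column of `data$Y` to fit (1 or 2).
#' @param graph the matching [area_graph()].
#' @param mcmc an [mcmc_config()].
#' @param priors a [prior_config()].
#' @param standardize z-score the covariate columns before fitting.
#' @param relevance_threshold cutoff for [covariate_relevance()].
#' @return Object of class `regression_posterior`: `summary` (posterior
#'   table for \eqn{\alpha}, each \eqn{\beta}, \eqn{\sigma_\phi},
#'   \eqn{\sigma_\theta}), `risk_surface` (a [relative_risk()] surface),
#'   `covariates` (a [covariate_relevance()] report; empty for
#'   intercept-only fits), `draws`, `max_rhat`, `converged`.
#' @export
fit_regression <- function(data, outcome = 1L, graph,
                           mcmc = mcmc_config(), priors = prior_config(),
                           standardize = TRUE, relevance_threshold = 0.8) {
  stopifnot(inherits(data, "area_dataset"), inherits(graph, "area_graph"))
  if (!outcome %in% c(1L, 2L)) stop("outcome must be 1 or 2")
  data <- align_dataset(data, graph)
  n <- graph$n_areas
  Y <- data$Y[, outcome]
  E <- data$E[, outcome]
  X <- data$X
  p <- if (is.null(X)) 0L else ncol(X)
  if (p > 0L) {
    if (standardize) {
      X <- scale(X)
      if (any(!is.finite(X)))
        stop("constant covariate column(s) cannot be standardized: ",
             paste(colnames(data$X)[apply(!is.finite(X), 2L, any)],
                   collapse = ", "))
      X <- X[, , drop = FALSE]
    }
    dec <- qr(cbind(`(intercept)` = 1, X))
    if (dec$rank < p + 1L) {
      bad <- colnames(cbind(`(intercept)` = 1, X))[
        dec$pivot[(dec$rank + 1L):(p + 1L)]]
      stop("rank-deficient design; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
  }
  comps <- connected_components(graph)
  colors <- graph_coloring(graph)
  W <- adjacency_matrix(graph)
  W_rows <- lapply(colors, function(S) W[S, , drop = FALSE])
  nnb <- graph$n_neighbors
  rank_str <- n - length(comps)
  one_comp <- length(comps) == 1L
  beta_names <- if (p > 0L) colnames(X) else character(0)
  icar_str <- icar_eigen(graph)
  basis <- icar_full_basis(graph, icar_str)
  V_all <- basis$V
  invlam <- basis$invlam
  # smoothest eigenmodes get a preconditioned block update (single-site
  # walks cross these large-scale directions only by slow diffusion)
  n_modes <- min(12L, rank_str)
  ord <- order(basis$lam + ifelse(basis$lam == 0, Inf, 0))[seq_len(n_modes)]
  mode_v <- V_all[, ord, drop = FALSE]
  mode_lam <- basis$lam[ord]

  model <- list(make_chain = function(chain_id) {
    env <- new.env(parent = emptyenv())
    env$Y1 <- Y
    sumY <- sum(Y)
    alpha <- log(sumY / sum(E))
    beta <- numeric(p)
    phi <- numeric(n); theta <- numeric(n)
    sigma <- c(phi = 0.5, theta = 0.5)

    xb <- numeric(n)
    recompute_lin <- function() {
      env$lin1 <- alpha + xb + phi + theta
      env$mu1 <- E * exp(env$lin1)
    }
    recompute_lin()

    tnames <- c("phi", "theta", "alpha", "modes_phi", "scl_phi",
                "scl_theta", if (p > 0L) paste0("beta_", beta_names))
    tuner <- make_tuner(tnames, init_scale = 0.1,
                        target = mcmc$target_accept)
    tuner$scale["alpha"] <- 0.05
    tuner$scale["modes_phi"] <- 0.5
    if (p > 0L) tuner$scale[paste0("beta_", beta_names)] <- 0.05

    upd_beta <- function(j, adapt) {
      name <- paste0("beta_", beta_names[j])
      db <- stats::rnorm(1L, 0, tuner$scale[name])
      dlin <- X[, j] * db
      dll <- sum(Y * dlin - env$mu1 * (exp(dlin) - 1))
      bn <- beta[j] + db
      dpr <- -(bn^2 - beta[j]^2) / (2 * priors$beta_variance)
      acc <- log(stats::runif(1L)) < dll + dpr
      if (acc) {
        beta[j] <<- bn
        xb <<- xb + dlin
        env$lin1 <- env$lin1 + dlin
        env$mu1 <- env$mu1 * exp(dlin)
      }
      tune_record(tuner, name, acc, 1L, adapt)
    }

    # preconditioned block update of phi along the smooth eigenmodes
    upd_modes <- function(adapt) {
      sd_k <- 1 / sqrt(mode_lam / sigma[["phi"]]^2 + mean(env$mu1))
      t <- stats::rnorm(n_modes, 0, sd_k) * tuner$scale["modes_phi"]
      df <- as.numeric(mode_v %*% t)
      dll <- sum(Y * df - env$mu1 * (exp(df) - 1))
      proj <- as.numeric(crossprod(mode_v, phi))
      dpr <- -sum(mode_lam * (2 * t * proj + t^2)) /
        (2 * sigma[["phi"]]^2)
      acc <- log(stats::runif(1L)) < dll + dpr
      if (acc) {
        phi <<- phi + df
        env$lin1 <- env$lin1 + df
        env$mu1 <- env$mu1 * exp(df)
      }
      tune_record(tuner, "modes_phi", acc, 1L, adapt)
    }

    # the likelihood constrains only t = phi + theta; slice-sample the two
    # scales on the collapsed marginal of t (Gaussian, diagonal in the
    # eigenbasis with per-mode variance sigma_phi^2/lambda + sigma_theta^2),
    # then redraw the phi/theta split exactly, mode by mode
    hyper_logpost <- function(x, w) {
      sg2 <- exp(2 * x)
      if (any(sg2 >= priors$sigma_upper^2)) return(-Inf)
      v <- sg2[1L] * invlam + sg2[2L]
      -0.5 * sum(log(v) + w^2 / v) + sum(x)
    }
    gibbs_hyper_fields <- function() {
      t_tot <- env$lin1 - alpha - xb
      w <- as.numeric(crossprod(V_all, t_tot))
      x <- slice_cycle(log(c(sigma[["phi"]], sigma[["theta"]])),
                       function(z) hyper_logpost(z, w), w = 0.5)
      sigma <<- stats::setNames(exp(x), names(sigma))
      vs <- sigma[["phi"]]^2 * invlam
      v <- vs + sigma[["theta"]]^2
      phk <- w * vs / v + stats::rnorm(n) * sqrt(vs * (v - vs) / v)
      phi <<- as.numeric(V_all %*% phk)
      theta <<- t_tot - phi
      recompute_lin()
    }

    # joint rescale of a field and its scale (funnel move); the prior and
    # Jacobian terms cancel, leaving the likelihood delta plus log c
    upd_scale_pair <- function(get, set, sname, tname, adapt) {
      lc <- stats::rnorm(1L, 0, tuner$scale[tname])
      cc <- exp(lc)
      s_new <- cc * sigma[[sname]]
      acc <- FALSE
      if (s_new < priors$sigma_upper) {
        f <- get()
        dlin <- (cc - 1) * f
        dll <- sum(Y * dlin - env$mu1 * (exp(dlin) - 1))
        if (log(stats::runif(1L)) < dll + lc) {
          acc <- TRUE
          sigma[sname] <<- s_new
          set(cc * f)
          env$lin1 <- env$lin1 + dlin
          env$mu1 <- env$mu1 * exp(dlin)
        }
      }
      tune_record(tuner, tname, acc, 1L, adapt)
    }
    upd_alpha <- function(adapt) {
      da <- stats::rnorm(1L, 0, tuner$scale["alpha"])
      dll <- sumY * da - sum(env$mu1) * (exp(da) - 1)
      acc <- log(stats::runif(1L)) < dll
      if (acc) {
        alpha <<- alpha + da
        env$lin1 <- env$lin1 + da
        env$mu1 <- env$mu1 * exp(da)
      }
      tune_record(tuner, "alpha", acc, 1L, adapt)
    }
    upd_sig <- function(name, ss, rank) {
      sigma[name] <<- draw_sigma(sigma[[name]], ss, rank,
                                 priors$sigma_upper)
    }
    recenter <- function() {
      changed <- FALSE
      for (idx in comps) {
        m <- mean(phi[idx])
        phi[idx] <<- phi[idx] - m
        if (one_comp) alpha <<- alpha + m else changed <- TRUE
      }
      if (changed) recompute_lin()
    }

    list(
      sweep = function(adapt) {
        for (ci in seq_along(colors)) {
          S <- colors[[ci]]
          s_nb <- as.numeric(W_rows[[ci]] %*% phi)
          res <- update_field_block(env, phi, S, tuner$scale["phi"], 1, 0,
            function(cur, prop)
              -(nnb[S] * (prop^2 - cur^2) - 2 * (prop - cur) * s_nb) /
                (2 * sigma[["phi"]]^2))
          phi <<- res$f
          tune_record(tuner, "phi", res$n_acc, length(S), adapt)
        }
        res <- update_field_block(env, theta, seq_len(n),
          tuner$scale["theta"], 1, 0,
          function(cur, prop) -(prop^2 - cur^2) /
            (2 * sigma[["theta"]]^2))
        theta <<- res$f
        tune_record(tuner, "theta", res$n_acc, n, adapt)
        upd_modes(adapt)
        upd_alpha(adapt)
        if (p > 0L) for (j in seq_len(p)) upd_beta(j, adapt)
        gibbs_hyper_fields()
        upd_scale_pair(function() phi, function(f) phi <<- f,
                       "phi", "scl_phi", adapt)
        upd_scale_pair(function() theta, function(f) theta <<- f,
                       "theta", "scl_theta", adapt)
        upd_sig("phi", icar_pairwise_ss(phi, graph), rank_str)
        upd_sig("theta", sum(theta^2), n)
        recenter()
      },
      monitor = function() {
        c(alpha = alpha,
          if (p > 0L) stats::setNames(beta, paste0("beta_", beta_names)),
          sigma_phi = sigma[["phi"]], sigma_theta = sigma[["theta"]])
      },
      fields = function() list(phi = phi, theta = theta)
    )
  })

  fit <- run_chains(model, mcmc)
  pooled <- do.call(rbind, fit$draws)
  beta_cols <- if (p > 0L) paste0("beta_", beta_names) else character(0)
  draws <- list(
    alpha = pooled[, "alpha"],
    beta = pooled[, beta_cols, drop = FALSE],
    phi = do.call(rbind, lapply(fit$fields, `[[`, "phi")),
    theta = do.call(rbind, lapply(fit$fields, `[[`, "theta")))
  colnames(draws$beta) <- beta_names
  surface <- relative_risk(draws, X = if (p > 0L) X else NULL,
                           area_ids = data$area_ids)
  covariates <- covariate_relevance(draws$beta, relevance_threshold)
  converged <- is.finite(fit$max_rhat) && fit$max_rhat <= 1.1
  if (!converged)
    warning(sprintf("convergence not reached: max split-Rhat = %.3f",
                    fit$max_rhat))
  structure(list(summary = fit$summary, risk_surface = surface,
                 covariates = covariates, draws = draws, outcome = outcome,
                 config = mcmc, priors = priors, max_rhat = fit$max_rhat,
                 converged = converged),
            class = "regression_posterior")
}

#' @export
print.regression_posterior <- function(x, ...) {
  cat(sprintf("Spatial Poisson regression fit (outcome %d)\n", x$outcome))
  print(x$summary, row.names = FALSE, digits = 3)
  cat(sprintf("max split-Rhat: %.3f (%s)\n", x$max_rhat,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
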