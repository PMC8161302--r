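# Poisson log-likelihood written out explicitly (validated against the
# dpois oracle in the test suite)
poisson_loglik <- function(Y, mu) {
  sum(Y * log(mu) - mu - lgamma(Y + 1))
}

#' Joint-model mean structure
#'
#' Evaluates the Poisson means of the shared-component model for one
#' outcome: \eqn{\log\mu_{i1} = \log E_{i1} + \alpha_1 + \delta\phi_i +
#' \psi_{i1}} and \eqn{\log\mu_{i2} = \log E_{i2} + \alpha_2 + \phi_i/\delta
#' + \psi_{i2}}, where \eqn{\phi} and each \eqn{\psi_k} are the sums of
#' their structured and unstructured parts.
#'
#' @param state joint-model state: a list with `alpha` (length 2),
#'   `log_delta`, `phi_str`, `phi_het` (per-area vectors) and `psi_str`,
#'   `psi_het` (areas by 2 matrices).
#' @param E expected-counts matrix (areas by 2).
#' @param outcome 1 or 2.
#' @return Per-area positive vector of means.
#' @export
joint_log_mu <- function(state, E, outcome) {
  if (!outcome %in% c(1, 2)) stop("outcome must be 1 or 2")
  delta <- exp(state$log_delta)
  phi <- state$phi_str + state$phi_het
  psi <- state$psi_str[, outcome] + state$psi_het[, outcome]
  shared <- if (outcome == 1) phi * delta else phi / delta
  exp(log(E[, outcome]) + state$alpha[outcome] + shared + psi)
}

#' Shared-variance fractions
#'
#' The proportion of each outcome's between-area log-risk variation carried
#' by the shared component:
#' \eqn{\eta_1 = V(\delta\phi) / (V(\delta\phi) + V(\psi_1))} and
#' \eqn{\eta_2 = V(\phi/\delta) / (V(\phi/\delta) + V(\psi_2))},
#' where V is the empirical variance across areas and each field is the sum
#' of its structured and unstructured parts. In a fit this is evaluated per
#' retained draw and then summarized.
#'
#' @param state joint-model state (see [joint_log_mu()]).
#' @return Length-2 vector `(eta1, eta2)` in `[0, 1]`; `NA` with a warning
#'   for an outcome whose shared and specific variances are both zero.
#' @export
shared_variance_fractions <- function(state) {
  delta <- exp(state$log_delta)
  phi <- state$phi_str + state$phi_het
  out <- vapply(1:2, function(k) {
    vs <- stats::var(phi * if (k == 1) delta else 1 / delta)
    vp <- stats::var(state$psi_str[, k] + state$psi_het[, k])
    if (vs + vp == 0) return(NA_real_)
    vs / (vs + vp)
  }, 0)
  if (anyNA(out))
    warning("shared and specific variances both zero; eta undefined")
  out
}

# vectorized Metropolis update of a latent field over one set of sites that
# share no edge (or all sites, for unstructured fields); mutates `env`
# fields lin1/lin2/mu1/mu2 and returns the updated field values
# (coefficients c1, c2 say how a unit field change enters each outcome's
# linear predictor)
update_field_block <- function(env, f, S, scale, c1, c2, dprior_fn) {
  cur <- f[S]
  d <- stats::rnorm(length(S), 0, scale)
  prop <- cur + d
  dll <- 0
  if (c1 != 0) {
    dlin1 <- c1 * d
    dll <- dll + env$Y1[S] * dlin1 - env$mu1[S] * (exp(dlin1) - 1)
  }
  if (c2 != 0) {
    dlin2 <- c2 * d
    dll <- dll + env$Y2[S] * dlin2 - env$mu2[S] * (exp(dlin2) - 1)
  }
  acc <- log(stats::runif(length(S))) < dll + dprior_fn(cur, prop)
  if (any(acc)) {
    idx <- S[acc]
    f[idx] <- prop[acc]
    if (c1 != 0) {
      env$lin1[idx] <- env$lin1[idx] + c1 * d[acc]
      env$mu1[idx] <- env$mu1[idx] * exp(c1 * d[acc])
    }
    if (c2 != 0) {
      env$lin2[idx] <- env$lin2[idx] + c2 * d[acc]
      env$mu2[idx] <- env$mu2[idx] * exp(c2 * d[acc])
    }
  }
  list(f = f, n_acc = sum(acc))
}

# exact Gibbs draw of a field scale parameter under a U(0, upper) prior on
# sigma: the precision tau = 1/sigma^2 has a Gamma((rank - 1)/2, ss/2) full
# conditional truncated to tau > 1/upper^2, sampled by inverse CDF.
# `ss` is the field sum of squares (pairwise for ICAR fields), `rank` the
# field's effective dimension (n - C structured, n unstructured).
draw_sigma <- function(sigma, ss, rank, upper) {
  if (ss <= 0) return(sigma)  # degenerate all-zero field; leave unchanged
  shape <- (rank - 1) / 2
  rate <- ss / 2
  lo <- 1 / upper^2
  p_lo <- stats::pgamma(lo, shape, rate)
  if (p_lo >= 1) return(upper * (1 - 1e-12))
  tau <- stats::qgamma(stats::runif(1L, p_lo, 1), shape, rate)
  1 / sqrt(tau)
}

#' Fit the shared-component joint Poisson model
#'
#' Metropolis-within-Gibbs sampler for the two-outcome shared-component
#' model: Poisson counts with offsets `E`, flat intercepts, a shared
#' spatial surface (ICAR structured part plus iid unstructured part) scaled
#' by \eqn{\delta} for outcome 1 and \eqn{1/\delta} for outcome 2,
#' outcome-specific surfaces of the same composition, U(0, `sigma_upper`)
#' hyperpriors on all six field scales, and a Normal(0, `log_delta_sd`)
#' prior on \eqn{\log\delta}. Latent fields are updated by vectorized
#' single-site random walks over graph-colour classes; structured fields are
#' recentred to sum to zero per graph component after every sweep, with the
#' removed mean absorbed into the intercepts. The shared-variance fractions
#' \eqn{\eta_k} are derived at every retained draw.
#'
#' @param data an [area_dataset()] with two outcomes.
#' @param graph the matching [area_graph()].
#' @param mcmc an [mcmc_config()].
#' @param priors a [prior_config()].
#' @return Object of class `joint_posterior`: `summary` (posterior table for
#'   \eqn{\alpha_1, \alpha_2, \delta, \eta_1, \eta_2} and the six scales),
#'   `shared_surface` (per-area posterior mean and 95% CrI of the shared
#'   component on the log-risk scale), `draws`, `config`, `max_rhat`, and
#'   `converged` (`FALSE`, with a warning, if any split-Rhat exceeds 1.1).
#' @export
fit_joint <- function(data, graph, mcmc = mcmc_config(),
                      priors = prior_config()) {
  stopifnot(inherits(data, "area_dataset"), inherits(graph, "area_graph"))
  if (ncol(data$Y) != 2L) stop("the joint model needs exactly two outcomes")
  data <- align_dataset(data, graph)
  n <- graph$n_areas
  comps <- connected_components(graph)
  colors <- graph_coloring(graph)
  W <- adjacency_matrix(graph)
  W_rows <- lapply(colors, function(S) W[S, , drop = FALSE])
  nnb <- graph$n_neighbors
  rank_str <- n - length(comps)
  one_comp <- length(comps) == 1L
  icar_str <- icar_eigen(graph)  # reused by the allocation Gibbs draw

  # smoothest ICAR eigenmodes (smallest positive eigenvalues): single-site
  # walks traverse these large-scale directions by slow diffusion, so they
  # get their own preconditioned block update
  n_modes <- min(12L, rank_str)
  mode_v <- matrix(0, n, 0)
  mode_lam <- numeric(0)
  for (st in icar_str) {
    vv <- matrix(0, n, length(st$values))
    vv[st$idx, ] <- st$vectors
    mode_v <- cbind(mode_v, vv)
    mode_lam <- c(mode_lam, st$values)
  }
  ord <- order(mode_lam)[seq_len(n_modes)]
  mode_v <- mode_v[, ord, drop = FALSE]
  mode_lam <- mode_lam[ord]

  # every field prior is diagonal in the shared full eigenbasis, which is
  # what makes the collapsed hyperparameter update and the exact joint
  # field redraw below possible
  basis <- icar_full_basis(graph, icar_str)
  V_all <- basis$V
  invlam <- basis$invlam

  model <- list(make_chain = function(chain_id) {
    env <- new.env(parent = emptyenv())
    env$Y1 <- data$Y[, 1L]; env$Y2 <- data$Y[, 2L]
    E1 <- data$E[, 1L]; E2 <- data$E[, 2L]
    sumY1 <- sum(env$Y1); sumY2 <- sum(env$Y2)

    alpha <- c(log(sumY1 / sum(E1)), log(sumY2 / sum(E2)))
    ld <- 0
    phi_s <- numeric(n); phi_h <- numeric(n)
    psi_s <- matrix(0, n, 2L); psi_h <- matrix(0, n, 2L)
    sigma <- c(phi_str = 0.5, phi_het = 0.5, psi_str1 = 0.5,
               psi_het1 = 0.5, psi_str2 = 0.5, psi_het2 = 0.5)

    recompute_lin <- function() {
      d <- exp(ld)
      phi <- phi_s + phi_h
      env$lin1 <- alpha[1L] + d * phi + psi_s[, 1L] + psi_h[, 1L]
      env$lin2 <- alpha[2L] + phi / d + psi_s[, 2L] + psi_h[, 2L]
      env$mu1 <- E1 * exp(env$lin1)
      env$mu2 <- E2 * exp(env$lin2)
    }
    recompute_lin()

    tuner <- make_tuner(
      c("phi_str", "phi_het", "psi_str1", "psi_het1", "psi_str2",
        "psi_het2", "alpha1", "alpha2", "log_delta",
        paste0("scl_", names(sigma)),
        "modes_phi", "modes_psi1", "modes_psi2"),
      init_scale = 0.1, target = mcmc$target_accept)
    tuner$scale[c("alpha1", "alpha2", "log_delta")] <- 0.05
    tuner$scale[c("modes_phi", "modes_psi1", "modes_psi2")] <- 0.5

    upd_str_field <- function(f, sig, c1, c2, name, adapt) {
      for (ci in seq_along(colors)) {
        S <- colors[[ci]]
        s_nb <- as.numeric(W_rows[[ci]] %*% f)
        res <- update_field_block(env, f, S, tuner$scale[name], c1, c2,
          function(cur, prop)
            -(nnb[S] * (prop^2 - cur^2) - 2 * (prop - cur) * s_nb) /
              (2 * sig^2))
        f <- res$f
        tune_record(tuner, name, res$n_acc, length(S), adapt)
      }
      f
    }
    upd_het_field <- function(f, sig, c1, c2, name, adapt) {
      S <- seq_len(n)
      res <- update_field_block(env, f, S, tuner$scale[name], c1, c2,
        function(cur, prop) -(prop^2 - cur^2) / (2 * sig^2))
      tune_record(tuner, name, res$n_acc, n, adapt)
      res$f
    }
    upd_alpha <- function(k, adapt) {
      name <- paste0("alpha", k)
      da <- stats::rnorm(1L, 0, tuner$scale[name])
      sumY <- if (k == 1L) sumY1 else sumY2
      mu <- if (k == 1L) env$mu1 else env$mu2
      dll <- sumY * da - sum(mu) * (exp(da) - 1)
      acc <- log(stats::runif(1L)) < dll
      if (acc) {
        alpha[k] <<- alpha[k] + da
        if (k == 1L) {
          env$lin1 <- env$lin1 + da; env$mu1 <- env$mu1 * exp(da)
        } else {
          env$lin2 <- env$lin2 + da; env$mu2 <- env$mu2 * exp(da)
        }
      }
      tune_record(tuner, name, acc, 1L, adapt)
    }
    upd_delta <- function(adapt) {
      dl <- stats::rnorm(1L, 0, tuner$scale["log_delta"])
      ld_new <- ld + dl
      d_old <- exp(ld); d_new <- exp(ld_new)
      phi <- phi_s + phi_h
      dlin1 <- (d_new - d_old) * phi
      dlin2 <- (1 / d_new - 1 / d_old) * phi
      dll <- sum(env$Y1 * dlin1 - env$mu1 * (exp(dlin1) - 1)) +
        sum(env$Y2 * dlin2 - env$mu2 * (exp(dlin2) - 1))
      dpr <- -(ld_new^2 - ld^2) / (2 * priors$log_delta_sd^2)
      acc <- log(stats::runif(1L)) < dll + dpr
      if (acc) {
        ld <<- ld_new
        env$lin1 <- env$lin1 + dlin1; env$mu1 <- env$mu1 * exp(dlin1)
        env$lin2 <- env$lin2 + dlin2; env$mu2 <- env$mu2 * exp(dlin2)
      }
      tune_record(tuner, "log_delta", acc, 1L, adapt)
    }
    upd_sig <- function(name, ss, rank) {
      sigma[name] <<- draw_sigma(sigma[[name]], ss, rank,
                                 priors$sigma_upper)
    }
    # The likelihood constrains only the two total predictors
    # t_k = lin_k - alpha_k; given them, all six latent fields and the
    # hyperparameters are driven by the priors alone. In the shared
    # eigenbasis the marginal of (t_1, t_2) over all six fields is a
    # 2 x 2 Gaussian per mode with per-mode field variances
    # v = sigma_str^2/lambda + sigma_het^2, so (a) the hyperparameters
    # (log delta + six log scales) can be slice-sampled on that collapsed
    # marginal, and (b) all six fields can then be redrawn exactly, mode by
    # mode: first the shared total phi | t, then the specific totals as
    # psi_k = t_k - (scaled) phi, then each total split into its structured
    # and unstructured parts. Every mu_ik is kept fixed exactly.
    hyper_logpost <- function(x, w1, w2) {
      d2 <- exp(2 * x[1L])
      sg2 <- exp(2 * x[-1L])
      if (any(sg2 >= priors$sigma_upper^2)) return(-Inf)
      vphi <- sg2[1L] * invlam + sg2[2L]
      vps1 <- sg2[3L] * invlam + sg2[4L]
      vps2 <- sg2[5L] * invlam + sg2[6L]
      M11 <- d2 * vphi + vps1
      M12 <- vphi
      M22 <- vphi / d2 + vps2
      det <- M11 * M22 - M12^2
      quad <- (M22 * w1^2 - 2 * M12 * w1 * w2 + M11 * w2^2) / det
      -0.5 * sum(log(det) + quad) -
        x[1L]^2 / (2 * priors$log_delta_sd^2) + sum(x[-1L])
    }
    gibbs_hyper_fields <- function() {
      t1 <- env$lin1 - alpha[1L]
      t2 <- env$lin2 - alpha[2L]
      w1 <- as.numeric(crossprod(V_all, t1))
      w2 <- as.numeric(crossprod(V_all, t2))
      x <- slice_cycle(c(ld, log(sigma)),
                       function(z) hyper_logpost(z, w1, w2), w = 0.5)
      ld <<- x[1L]
      sigma <<- stats::setNames(exp(x[-1L]), names(sigma))
      d <- exp(ld)
      vphi_s <- sigma[["phi_str"]]^2 * invlam
      vps1_s <- sigma[["psi_str1"]]^2 * invlam
      vps2_s <- sigma[["psi_str2"]]^2 * invlam
      vphi <- vphi_s + sigma[["phi_het"]]^2
      vps1 <- vps1_s + sigma[["psi_het1"]]^2
      vps2 <- vps2_s + sigma[["psi_het2"]]^2
      prec <- 1 / vphi + d^2 / vps1 + 1 / (d^2 * vps2)
      m <- (d * w1 / vps1 + w2 / (d * vps2)) / prec
      phik <- m + stats::rnorm(n) / sqrt(prec)
      p1k <- w1 - d * phik
      p2k <- w2 - phik / d
      split_str <- function(tot, vs, v) {
        tot * vs / v + stats::rnorm(n) * sqrt(vs * (v - vs) / v)
      }
      phs <- split_str(phik, vphi_s, vphi)
      p1s <- split_str(p1k, vps1_s, vps1)
      p2s <- split_str(p2k, vps2_s, vps2)
      phi_s <<- as.numeric(V_all %*% phs)
      phi_h <<- as.numeric(V_all %*% (phik - phs))
      psi_s[, 1L] <<- as.numeric(V_all %*% p1s)
      psi_h[, 1L] <<- as.numeric(V_all %*% (p1k - p1s))
      psi_s[, 2L] <<- as.numeric(V_all %*% p2s)
      psi_h[, 2L] <<- as.numeric(V_all %*% (p2k - p2s))
      recompute_lin()  # guard the caches against floating-point drift
    }

    # preconditioned block update of a structured field along the smooth
    # eigenmodes: proposal sd per mode from the local Gaussian
    # approximation (prior curvature lambda_k/sigma^2 plus likelihood
    # curvature ~ mean(mu) per unit mode norm), with one adapted global
    # factor per field
    upd_modes <- function(f, sig, c1, c2, name, adapt) {
      curve_ll <- (if (c1 != 0) c1^2 * mean(env$mu1) else 0) +
        (if (c2 != 0) c2^2 * mean(env$mu2) else 0)
      sd_k <- 1 / sqrt(mode_lam / sig^2 + curve_ll)
      t <- stats::rnorm(n_modes, 0, sd_k) * tuner$scale[name]
      df <- as.numeric(mode_v %*% t)
      dll <- 0
      dlin1 <- NULL; dlin2 <- NULL
      if (c1 != 0) {
        dlin1 <- c1 * df
        dll <- dll + sum(env$Y1 * dlin1 - env$mu1 * (exp(dlin1) - 1))
      }
      if (c2 != 0) {
        dlin2 <- c2 * df
        dll <- dll + sum(env$Y2 * dlin2 - env$mu2 * (exp(dlin2) - 1))
      }
      proj <- as.numeric(crossprod(mode_v, f))
      dpr <- -sum(mode_lam * (2 * t * proj + t^2)) / (2 * sig^2)
      acc <- log(stats::runif(1L)) < dll + dpr
      if (acc) {
        f <- f + df
        if (c1 != 0) {
          env$lin1 <- env$lin1 + dlin1; env$mu1 <- env$mu1 * exp(dlin1)
        }
        if (c2 != 0) {
          env$lin2 <- env$lin2 + dlin2; env$mu2 <- env$mu2 * exp(dlin2)
        }
      }
      tune_record(tuner, name, acc, 1L, adapt)
      f
    }

    # joint rescale of one field part and its scale parameter,
    # (f, sigma) -> (c f, c sigma); the prior kernel and rank terms cancel
    # against the Jacobian, leaving the likelihood delta plus log c. This
    # walks the funnel between a nearly-null field and its scale.
    upd_scale_pair <- function(f, sname, c1, c2, tname, adapt) {
      lc <- stats::rnorm(1L, 0, tuner$scale[tname])
      cc <- exp(lc)
      s_new <- cc * sigma[[sname]]
      if (s_new < priors$sigma_upper) {
        dll <- 0
        dlin1 <- NULL; dlin2 <- NULL
        if (c1 != 0) {
          dlin1 <- c1 * (cc - 1) * f
          dll <- dll + sum(env$Y1 * dlin1 - env$mu1 * (exp(dlin1) - 1))
        }
        if (c2 != 0) {
          dlin2 <- c2 * (cc - 1) * f
          dll <- dll + sum(env$Y2 * dlin2 - env$mu2 * (exp(dlin2) - 1))
        }
        if (log(stats::runif(1L)) < dll + lc) {
          sigma[sname] <<- s_new
          if (c1 != 0) {
            env$lin1 <- env$lin1 + dlin1; env$mu1 <- env$mu1 * exp(dlin1)
          }
          if (c2 != 0) {
            env$lin2 <- env$lin2 + dlin2; env$mu2 <- env$mu2 * exp(dlin2)
          }
          tune_record(tuner, tname, 1L, 1L, adapt)
          return(cc * f)
        }
      }
      tune_record(tuner, tname, 0L, 1L, adapt)
      f
    }

    recenter <- function() {
      d <- exp(ld)
      changed <- FALSE
      for (idx in comps) {
        m <- mean(phi_s[idx])
        phi_s[idx] <<- phi_s[idx] - m
        if (one_comp) {
          alpha[1L] <<- alpha[1L] + d * m
          alpha[2L] <<- alpha[2L] + m / d
        } else changed <- TRUE
        for (k in 1:2) {
          mk <- mean(psi_s[idx, k])
          psi_s[idx, k] <<- psi_s[idx, k] - mk
          if (one_comp) alpha[k] <<- alpha[k] + mk else changed <- TRUE
        }
      }
      if (changed) recompute_lin()
    }

    list(
      sweep = function(adapt) {
        d <- exp(ld)
        phi_s <<- upd_str_field(phi_s, sigma[["phi_str"]], d, 1 / d,
                                "phi_str", adapt)
        phi_h <<- upd_het_field(phi_h, sigma[["phi_het"]], d, 1 / d,
                                "phi_het", adapt)
        psi_s[, 1L] <<- upd_str_field(psi_s[, 1L], sigma[["psi_str1"]],
                                      1, 0, "psi_str1", adapt)
        psi_h[, 1L] <<- upd_het_field(psi_h[, 1L], sigma[["psi_het1"]],
                                      1, 0, "psi_het1", adapt)
        psi_s[, 2L] <<- upd_str_field(psi_s[, 2L], sigma[["psi_str2"]],
                                      0, 1, "psi_str2", adapt)
        psi_h[, 2L] <<- upd_het_field(psi_h[, 2L], sigma[["psi_het2"]],
                                      0, 1, "psi_het2", adapt)
        phi_s <<- upd_modes(phi_s, sigma[["phi_str"]], d, 1 / d,
                            "modes_phi", adapt)
        psi_s[, 1L] <<- upd_modes(psi_s[, 1L], sigma[["psi_str1"]], 1, 0,
                                  "modes_psi1", adapt)
        psi_s[, 2L] <<- upd_modes(psi_s[, 2L], sigma[["psi_str2"]], 0, 1,
                                  "modes_psi2", adapt)
        upd_alpha(1L, adapt); upd_alpha(2L, adapt)
        upd_delta(adapt)
        gibbs_hyper_fields()
        d <- exp(ld)
        phi_s <<- upd_scale_pair(phi_s, "phi_str", d, 1 / d,
                                 "scl_phi_str", adapt)
        phi_h <<- upd_scale_pair(phi_h, "phi_het", d, 1 / d,
                                 "scl_phi_het", adapt)
        psi_s[, 1L] <<- upd_scale_pair(psi_s[, 1L], "psi_str1", 1, 0,
                                       "scl_psi_str1", adapt)
        psi_h[, 1L] <<- upd_scale_pair(psi_h[, 1L], "psi_het1", 1, 0,
                                       "scl_psi_het1", adapt)
        psi_s[, 2L] <<- upd_scale_pair(psi_s[, 2L], "psi_str2", 0, 1,
                                       "scl_psi_str2", adapt)
        psi_h[, 2L] <<- upd_scale_pair(psi_h[, 2L], "psi_het2", 0, 1,
                                       "scl_psi_het2", adapt)
        upd_sig("phi_str", icar_pairwise_ss(phi_s, graph), rank_str)
        upd_sig("phi_het", sum(phi_h^2), n)
        upd_sig("psi_str1", icar_pairwise_ss(psi_s[, 1L], graph), rank_str)
        upd_sig("psi_het1", sum(psi_h[, 1L]^2), n)
        upd_sig("psi_str2", icar_pairwise_ss(psi_s[, 2L], graph), rank_str)
        upd_sig("psi_het2", sum(psi_h[, 2L]^2), n)
        recenter()
      },
      monitor = function() {
        st <- list(alpha = alpha, log_delta = ld, phi_str = phi_s,
                   phi_het = phi_h, psi_str = psi_s, psi_het = psi_h)
        eta <- suppressWarnings(shared_variance_fractions(st))
        c(alpha1 = alpha[1L], alpha2 = alpha[2L], delta = exp(ld),
          eta1 = eta[1L], eta2 = eta[2L],
          stats::setNames(sigma, paste0("sigma_", names(sigma))))
      },
      fields = function() list(shared = phi_s + phi_h)
    )
  })

  fit <- run_chains(model, mcmc)
  shared_draws <- do.call(rbind, lapply(fit$fields, `[[`, "shared"))
  surf <- data.frame(
    area_id = data$area_ids,
    mean = colMeans(shared_draws),
    q2.5 = apply(shared_draws, 2L, stats::quantile, 0.025),
    q97.5 = apply(shared_draws, 2L, stats::quantile, 0.975),
    row.names = NULL)
  converged <- is.finite(fit$max_rhat) && fit$max_rhat <= 1.1
  if (!converged)
    warning(sprintf("convergence not reached: max split-Rhat = %.3f",
                    fit$max_rhat))
  structure(list(summary = fit$summary, shared_surface = surf,
                 draws = fit$draws, config = mcmc, priors = priors,
                 max_rhat = fit$max_rhat, converged = converged),
            class = "joint_posterior")
}

#' @export
print.joint_posterior <- function(x, ...) {
  cat("Shared-component joint Poisson model fit\n")
  show <- x$summary[x$summary$param %in%
                      c("alpha1", "alpha2", "delta", "eta1", "eta2"), ]
  print(show, row.names = FALSE, digits = 3)
  cat(sprintf("max split-Rhat: %.3f (%s)\n", x$max_rhat,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Export the shared spatial surface
#'
#' Per-area posterior summary of the shared component on the log-risk
#' scale, the mappable quantity of the joint model. Values are centred
#' (component means near zero), so they are read comparatively: positive
#' values mark areas where both outcomes' risks are jointly elevated.
#'
#' @param posterior a `joint_posterior` from [fit_joint()].
#' @param area_table optional data frame with an `area_id` column (and any
#'   extra columns to carry along, e.g. map coordinates); merged by id, so
#'   its row order does not matter.
#' @param path optional CSV output path.
#' @return Data frame ordered by area id: `area_id`, `mean`, `q2.5`,
#'   `q97.5`, plus any `area_table` columns.
#' @export
export_shared_surface <- function(posterior, area_table = NULL,
                                  path = NULL) {
  stopifnot(inherits(posterior, "joint_posterior"))
  out <- posterior$shared_surface
  if (!is.null(area_table)) {
    if (!"area_id" %in% names(area_table))
      stop("area_table needs an 'area_id' column")
    missing <- setdiff(out$area_id, area_table$area_id)
    if (length(missing))
      stop("area_table is missing area(s): ",
           paste(missing, collapse = ", "))
    out <- merge(out, area_table, by = "area_id", sort = FALSE)
  }
  out <- out[order(out$area_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
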