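#' MCMC run configuration
#'
#' @param n_iter total iterations per chain.
#' @param burn_in iterations discarded from the front; must be `< n_iter`.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param n_chains number of independent chains (at least 2 for split-Rhat).
#' @param seed master seed; per-chain seeds are derived deterministically.
#' @param adapt_until proposal scales adapt only during the first
#'   `adapt_until` iterations; must not exceed `burn_in` so retained draws
#'   come from a fixed kernel.
#' @param target_accept target acceptance rate for adapted random-walk
#'   proposals (0.44 is standard for componentwise updates).
#' @return A validated `mcmc_config` list.
#' @export
mcmc_config <- function(n_iter = 6000L, burn_in = 1000L, thin = 5L,
                        n_chains = 4L, seed = 1L, adapt_until = burn_in,
                        target_accept = 0.44) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin); n_chains <- as.integer(n_chains)
  adapt_until <- as.integer(adapt_until)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (burn_in < 0L || thin < 1L || n_chains < 1L)
    stop("invalid MCMC configuration")
  if (adapt_until > burn_in)
    stop("adapt_until must not exceed burn_in (retained draws must come ",
         "from a frozen kernel)")
  if (target_accept <= 0 || target_accept >= 1)
    stop("target_accept must lie in (0, 1)")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 n_chains = n_chains, seed = as.integer(seed),
                 adapt_until = adapt_until, target_accept = target_accept),
            class = "mcmc_config")
}

#' Prior configuration
#'
#' Defaults: vague zero-mean Gaussians with variance 1e5 on regression
#' coefficients, uniform U(0, `sigma_upper`) hyperpriors on all field scale
#' parameters, improper flat priors on intercepts, and a weakly informative
#' Normal(0, `log_delta_sd`) prior on the log scaling factor (shrinking
#' delta gently toward 1).
#'
#' @param beta_variance prior variance of regression coefficients.
#' @param sigma_upper upper bound of the uniform hyperprior on scales.
#' @param log_delta_sd prior standard deviation of log(delta).
#' @return A validated `prior_config` list.
#' @export
prior_config <- function(beta_variance = 1e5, sigma_upper = 2,
                         log_delta_sd = 0.3) {
  if (beta_variance <= 0 || sigma_upper <= 0 || log_delta_sd <= 0)
    stop("all prior parameters must be strictly positive")
  structure(list(beta_variance = beta_variance, sigma_upper = sigma_upper,
                 log_delta_sd = log_delta_sd), class = "prior_config")
}

#' Split-Rhat convergence diagnostic
#'
#' Each chain is split in half; the potential scale reduction factor is
#' computed over the resulting 2m sequences as
#' \eqn{\sqrt{((n-1)/n \, W + B/n) / W}} with between-sequence variance B
#' and within-sequence variance W. Values near 1 indicate the chains have
#' mixed; values above about 1.1 flag non-convergence.
#'
#' @param chains matrix of draws (iterations by chains) or a list of equal-
#'   length numeric vectors, at least 2 chains of at least 4 draws.
#' @return Scalar Rhat; `NA` with a warning if all draws are identical.
#' @export
rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stop("rhat needs at least 2 chains")
  if (nrow(chains) < 4L) stop("rhat needs at least 4 draws per chain")
  half <- nrow(chains) %/% 2L
  splits <- cbind(chains[seq_len(half), , drop = FALSE],
                  chains[half + seq_len(half), , drop = FALSE])
  W <- mean(apply(splits, 2L, stats::var))
  B <- half * stats::var(colMeans(splits))
  if (!is.finite(W) || W == 0) {
    warning("zero within-chain variance; Rhat undefined")
    return(NA_real_)
  }
  sqrt(((half - 1) / half * W + B / half) / W)
}

# effective sample size via Geyer's initial positive sequence on the
# chain-averaged autocorrelations (split chains as in rhat)
ess <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  half <- nrow(chains) %/% 2L
  splits <- cbind(chains[seq_len(half), , drop = FALSE],
                  chains[half + seq_len(half), , drop = FALSE])
  m <- ncol(splits); n <- nrow(splits)
  vars <- apply(splits, 2L, stats::var)
  if (all(vars == 0) || n < 4L) return(NA_real_)
  W <- mean(vars)
  B <- n * stats::var(colMeans(splits))
  var_plus <- (n - 1) / n * W + B / n
  max_lag <- min(n - 2L, 200L)
  acov <- vapply(seq_len(m), function(j) {
    x <- splits[, j] - mean(splits[, j])
    vapply(0:max_lag, function(l)
      sum(x[seq_len(n - l)] * x[l + seq_len(n - l)]) / n, 0)
  }, numeric(max_lag + 1L))
  rho <- 1 - (W - rowMeans(acov)[-1L]) / var_plus
  # sum consecutive pairs while positive
  tau <- 1
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    k <- k + 2L
  }
  m * n / tau
}

#' Summarize posterior draws
#'
#' Posterior mean, standard deviation, equal-tailed 95% credible interval
#' (2.5 and 97.5 percentiles), split-Rhat and effective sample size for each
#' monitored scalar.
#'
#' @param draws list with one matrix per chain (retained iterations by
#'   parameters, identical column names), or a single matrix for one chain.
#' @return Data frame with one row per parameter: `param`, `mean`, `sd`,
#'   `q2.5`, `q97.5`, `rhat`, `n_eff`.
#' @export
summarize_draws <- function(draws) {
  if (is.matrix(draws)) draws <- list(draws)
  params <- colnames(draws[[1L]])
  pooled <- do.call(rbind, draws)
  multi <- length(draws) >= 2L && nrow(draws[[1L]]) >= 4L
  out <- lapply(params, function(p) {
    x <- pooled[, p]
    per_chain <- vapply(draws, function(d) d[, p],
                        numeric(nrow(draws[[1L]])))
    q <- unname(stats::quantile(x, c(0.025, 0.975), type = 7))
    constant <- stats::sd(x) == 0
    data.frame(param = p, mean = mean(x), sd = stats::sd(x),
               q2.5 = q[1L], q97.5 = q[2L],
               rhat = if (multi && !constant) suppressWarnings(
                 rhat(per_chain)) else NA_real_,
               n_eff = if (multi && !constant) ess(per_chain) else NA_real_)
  })
  do.call(rbind, out)
}

# --- adaptive random-walk tuning -------------------------------------------

# one tuner per proposal block: log-scale adapted in batches of 50 attempts
# toward the target acceptance rate, frozen once `adapt` is FALSE
make_tuner <- function(names, init_scale = 0.1, target = 0.44) {
  env <- new.env(parent = emptyenv())
  env$scale <- stats::setNames(rep(init_scale, length(names)), names)
  env$acc <- stats::setNames(numeric(length(names)), names)
  env$att <- stats::setNames(numeric(length(names)), names)
  env$batch <- stats::setNames(numeric(length(names)), names)
  env$target <- target
  env
}

tune_record <- function(tuner, name, accepted, attempted, adapt) {
  tuner$acc[name] <- tuner$acc[name] + accepted
  tuner$att[name] <- tuner$att[name] + attempted
  if (adapt && tuner$att[name] >= 50) {
    tuner$batch[name] <- tuner$batch[name] + 1
    rate <- tuner$acc[name] / tuner$att[name]
    step <- min(0.1, 1 / sqrt(tuner$batch[name]))
    tuner$scale[name] <- tuner$scale[name] *
      exp(if (rate > tuner$target) step else -step)
    tuner$acc[name] <- 0; tuner$att[name] <- 0
  }
  invisible(NULL)
}

# one cycle of univariate slice sampling (stepping out + shrinkage,
# Neal 2003) over the coordinates of x; logf must return -Inf outside the
# support. Used for low-dimensional collapsed updates whose density is
# cheap to evaluate.
slice_cycle <- function(x, logf, w = 0.5, max_step = 30L) {
  w <- rep_len(w, length(x))
  for (j in seq_along(x)) {
    fx <- logf(x)
    if (!is.finite(fx)) stop("slice sampler started outside the support")
    y <- fx - stats::rexp(1L)
    lo <- x; hi <- x
    u <- stats::runif(1L)
    lo[j] <- x[j] - w[j] * u
    hi[j] <- x[j] + w[j] * (1 - u)
    k <- max_step
    while (k > 0L && logf(lo) > y) { lo[j] <- lo[j] - w[j]; k <- k - 1L }
    k <- max_step
    while (k > 0L && logf(hi) > y) { hi[j] <- hi[j] + w[j]; k <- k - 1L }
    repeat {
      xp <- x
      xp[j] <- stats::runif(1L, lo[j], hi[j])
      if (logf(xp) > y) { x <- xp; break }
      if (xp[j] < x[j]) lo[j] <- xp[j] else hi[j] <- xp[j]
      if (hi[j] - lo[j] < 1e-12) break
    }
  }
  x
}

#' Run independent MCMC chains over a model specification
#'
#' Generic Metropolis-within-Gibbs driver. A model is a list with one
#' function, `make_chain(chain_id)`, called under the chain's derived seed;
#' it must return a list of closures: `sweep(adapt)` advancing the state by
#' one full update sweep, `monitor()` returning the named scalar vector to
#' record, and optionally `fields()` returning a named list of per-area
#' vectors recorded at retained iterations. The initial `monitor()` value
#' must be finite, otherwise initialization fails naming the offending
#' block.
#'
#' @param model model specification (see Details).
#' @param config an [mcmc_config()].
#' @return List with `draws` (per chain, retained iterations by monitored
#'   scalars), `fields` (per chain, named list of retained-by-area
#'   matrices), `summary` (from [summarize_draws()]), `config`, and
#'   `max_rhat`.
#' @export
run_chains <- function(model, config = mcmc_config()) {
  stopifnot(inherits(config, "mcmc_config"))
  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  if (n_keep < 1L) stop("no retained iterations; adjust n_iter/burn_in/thin")
  draws <- vector("list", config$n_chains)
  fields <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    res <- with_seed(mix_seed(config$seed, paste0("chain", ch)), {
      chain <- model$make_chain(ch)
      mon0 <- chain$monitor()
      bad <- is.nan(mon0) | is.infinite(mon0)  # NA = defined sentinel
      if (any(bad))
        stop("non-finite value at initialization in block(s): ",
             paste(names(mon0)[bad], collapse = ", "))
      keep <- matrix(NA_real_, n_keep, length(mon0),
                     dimnames = list(NULL, names(mon0)))
      fkeep <- NULL
      if (!is.null(chain$fields)) {
        f0 <- chain$fields()
        fkeep <- lapply(f0, function(v)
          matrix(NA_real_, n_keep, length(v)))
      }
      row <- 0L
      for (it in seq_len(config$n_iter)) {
        chain$sweep(it <= config$adapt_until)
        if (it > config$burn_in &&
            (it - config$burn_in) %% config$thin == 0L) {
          row <- row + 1L
          keep[row, ] <- chain$monitor()
          if (!is.null(fkeep)) {
            fv <- chain$fields()
            for (nm in names(fkeep)) fkeep[[nm]][row, ] <- fv[[nm]]
          }
        }
      }
      list(keep = keep, fkeep = fkeep)
    })
    draws[[ch]] <- res$keep
    fields[[ch]] <- res$fkeep
  }
  summ <- summarize_draws(draws)
  list(draws = draws, fields = fields, summary = summ, config = config,
       max_rhat = suppressWarnings(max(summ$rhat, na.rm = TRUE)))
}
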