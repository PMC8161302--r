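# small graphs reused across tests
path_graph <- function(n, ids = LETTERS[seq_len(n)]) {
  area_graph(ids, cbind(seq_len(n - 1L), 2:n))
}

cycle_graph <- function(n) {
  area_graph(as.character(seq_len(n)),
             cbind(seq_len(n), c(2:n, 1L)))
}

star_graph <- function(n) {
  area_graph(as.character(seq_len(n)), cbind(1L, 2:n))
}

complete_graph <- function(n) {
  e <- t(utils::combn(n, 2L))
  area_graph(as.character(seq_len(n)), e)
}

# all connected labeled graphs on n nodes (n small), as edge matrices
all_connected_graphs <- function(n) {
  pairs <- t(utils::combn(n, 2L))
  m <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^m - 1L)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
    e <- pairs[sel, , drop = FALSE]
    deg <- tabulate(c(e), n)
    if (any(deg == 0L)) next
    g <- area_graph(as.character(seq_len(n)), e)
    if (length(connected_components(g)) == 1L) out[[length(out) + 1L]] <- g
  }
  out
}

# seeded random connected graph: spanning tree plus random extra edges
random_connected_graph <- function(n, extra = 2L, seed = 1L) {
  set.seed(seed)
  e <- cbind(2:n, vapply(2:n, function(v) sample.int(v - 1L, 1L), 0L))
  pairs <- t(utils::combn(n, 2L))
  add <- pairs[sample.int(nrow(pairs), min(extra, nrow(pairs))), ,
               drop = FALSE]
  area_graph(as.character(seq_len(n)), rbind(e, add))
}

# evaluate code under a temporary seed without disturbing the session RNG
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

quick_mcmc <- function(seed = 1L, n_iter = 600L, burn_in = 200L,
                       n_chains = 2L, thin = 2L) {
  mcmc_config(n_iter = n_iter, burn_in = burn_in, thin = thin,
              n_chains = n_chains, seed = seed)
}

# random joint-model state on a graph, for likelihood identities
random_joint_state <- function(n, seed = 1L) {
  set.seed(seed)
  list(alpha = rnorm(2L, 0, 0.3), log_delta = rnorm(1L, 0, 0.2),
       phi_str = rnorm(n, 0, 0.3), phi_het = rnorm(n, 0, 0.2),
       psi_str = matrix(rnorm(2L * n, 0, 0.3), n, 2L),
       psi_het = matrix(rnorm(2L * n, 0, 0.2), n, 2L))
}
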