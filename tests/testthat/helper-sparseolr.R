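# Shared fixtures and oracles, all generated in code.

# Random ordinal model with strictly increasing, well-separated thresholds
# (tiny segments make the likelihood curvature explode, which would test the
# finite-difference oracle rather than the gradient).
rand_model <- function(D, C, scale = 0.5) {
  ordinal_model(stats::rnorm(D, sd = scale),
                cumsum(c(stats::rnorm(1), stats::runif(C - 2, 0.2, 1.5))))
}

# Random dataset containing every class at least once when N >= C.
rand_dataset <- function(N, D, C) {
  y <- sample(c(seq_len(C), sample(seq_len(C), max(N - C, 0), replace = TRUE)))
  labeled_dataset(matrix(stats::rnorm(N * D), N, D), y[seq_len(N)], C)
}

# Central finite differences of the log likelihood, the gradient oracle.
fd_gradient <- function(model, data, h = 1e-5) {
  gw <- vapply(seq_len(model$n_features), function(j) {
    mp <- model; mp$weights[j] <- mp$weights[j] + h
    mm <- model; mm$weights[j] <- mm$weights[j] - h
    (log_likelihood(mp, data) - log_likelihood(mm, data)) / (2 * h)
  }, numeric(1))
  gm <- vapply(seq_len(model$n_classes - 1L), function(j) {
    mp <- model; mp$thresholds[j] <- mp$thresholds[j] + h
    mm <- model; mm$thresholds[j] <- mm$thresholds[j] - h
    (log_likelihood(mp, data) - log_likelihood(mm, data)) / (2 * h)
  }, numeric(1))
  list(weights = gw, thresholds = gm)
}

# Simulation draw shared by several tests.
sim_draw <- function(seed, n_features, n_train, n_test = 1000, ...) {
  cfg <- simulation_config(n_features = n_features, n_train = n_train,
                           n_test = n_test, ...)
  set.seed(seed)
  means <- generate_class_means(cfg)
  list(cfg = cfg, means = means,
       train = sample_dataset(cfg, means, cfg$n_train),
       test = sample_dataset(cfg, means, cfg$n_test))
}

# The hard-regime paired sweep (D = 1000, N = 100, 20 repetitions) is used
# by two acceptance checks; compute it once per test run.
.accept_cache <- new.env(parent = emptyenv())

hard_regime_sweep <- function() {
  if (is.null(.accept_cache$hard)) {
    .accept_cache$hard <- suppressMessages(run_sweep(
      simulation_config(n_features = 1000, n_train = 100),
      algorithms = c("solr", "l2olr", "slir", "smlr"),
      sweep_axis = "dims", axis_values = 1000,
      n_repetitions = 20, seed = 20240501))
  }
  .accept_cache$hard
}
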