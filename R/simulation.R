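#' Configuration for the Gaussian class-conditional simulation benchmark
#'
#' Five (by default) `D`-dimensional Gaussian class distributions share a
#' diagonal covariance with per-dimension standard deviation `noise_sd`
#' (default 3.0). The first class mean is the origin; each subsequent mean
#' adds a positive increment in the first `n_informative` (default 10)
#' coordinates only, so the informative coordinates increase monotonically
#' with the class label (an ordinal feature-space structure) while the
#' remaining coordinates are irrelevant.
#'
#' @param n_features total number of input dimensions `D`.
#' @param n_train number of training samples `N` (split equally across
#'   classes).
#' @param n_test number of test samples (default 1000).
#' @param n_classes number of ordered classes (default 5).
#' @param n_informative number of class-informative leading dimensions
#'   (default 10; must not exceed `n_features`).
#' @param noise_sd per-dimension Gaussian standard deviation (default 3.0).
#' @param increment_mode `"exponential"` draws each mean increment from an
#'   exponential distribution with mean 1.0; `"fixed"` sets all increments
#'   to 1.0, giving equally spaced class means.
#' @param n_repetitions default number of simulation repetitions for
#'   [run_sweep()] (default 100).
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_features = 1000L, n_train = 100L,
                              n_test = 1000L, n_classes = 5L,
                              n_informative = 10L, noise_sd = 3.0,
                              increment_mode = c("exponential", "fixed"),
                              n_repetitions = 100L) {
  increment_mode <- match.arg(increment_mode)
  stopifnot(n_informative <= n_features, n_features >= 1, n_train >= n_classes,
            n_test >= 2, n_classes >= 2, noise_sd > 0)
  structure(list(n_features = as.integer(n_features),
                 n_train = as.integer(n_train),
                 n_test = as.integer(n_test),
                 n_classes = as.integer(n_classes),
                 n_informative = as.integer(n_informative),
                 noise_sd = noise_sd,
                 increment_mode = increment_mode,
                 n_repetitions = as.integer(n_repetitions)),
            class = "simulation_config")
}

#' Generate the class means of the simulation benchmark
#'
#' The first mean is the zero vector; mean `c` equals mean `c - 1` plus an
#' increment vector that is nonzero only in the first `n_informative`
#' coordinates. Increments are drawn from `Exp(mean = 1)` (or all set to
#' 1.0 under `increment_mode = "fixed"`). Uses the current RNG state; seed
#' with `set.seed()` for reproducibility.
#'
#' @param config a [simulation_config()].
#' @return a `n_classes x n_features` matrix of class means.
#' @export
generate_class_means <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  C <- config$n_classes; D <- config$n_features; k <- config$n_informative
  M <- matrix(0, C, D)
  for (cc in 2:C) {
    h <- if (config$increment_mode == "exponential") stats::rexp(k, rate = 1)
         else rep(1, k)
    M[cc, ] <- M[cc - 1L, ]
    M[cc, seq_len(k)] <- M[cc, seq_len(k)] + h
  }
  M
}

# Equal per-class allocation; any remainder goes to the lowest class indices.
.class_counts <- function(n_samples, C) {
  base <- n_samples %/% C
  rem <- n_samples %% C
  counts <- rep(base, C)
  if (rem > 0L) {
    counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
    message(sprintf("n_samples = %d not divisible by %d classes; remainder assigned to the lowest class indices", n_samples, C))
  }
  counts
}

#' Sample a labeled dataset from the simulation generator
#'
#' Draws equal numbers of samples per class (remainders go to the lowest
#' class indices) from the class-conditional Gaussians
#' `N(m_c, noise_sd^2 I)`. Uses the current RNG state.
#'
#' @param config a [simulation_config()].
#' @param means class-mean matrix from [generate_class_means()].
#' @param n_samples total number of samples to draw.
#' @return a [labeled_dataset()].
#' @export
sample_dataset <- function(config, means, n_samples) {
  stopifnot(inherits(config, "simulation_config"))
  C <- config$n_classes; D <- config$n_features
  stopifnot(nrow(means) == C, ncol(means) == D)
  if (n_samples < C) stop("n_samples must be at least the number of classes")
  counts <- .class_counts(n_samples, C)
  labels <- rep(seq_len(C), counts)
  X <- means[labels, , drop = FALSE] +
    matrix(stats::rnorm(n_samples * D, sd = config$noise_sd), n_samples, D)
  labeled_dataset(X, labels, n_classes = C)
}

#' Spearman rank correlation between true and predicted labels
#'
#' Pearson correlation of average ranks (ties receive the average rank).
#' Returns `NA_real_` when either vector is constant, for which the rank
#' correlation is undefined; callers such as [run_sweep()] exclude these
#' from means with a logged count.
#'
#' @param true_labels,predicted_labels equal-length vectors (length >= 2).
#' @return a number in `[-1, 1]`, or `NA_real_` for a constant input.
#' @export
spearman <- function(true_labels, predicted_labels) {
  stopifnot(length(true_labels) == length(predicted_labels),
            length(true_labels) >= 2L)
  if (stats::sd(true_labels) == 0 || stats::sd(predicted_labels) == 0)
    return(NA_real_)
  stats::cor(true_labels, predicted_labels, method = "spearman")
}

# Fit/predict registry used by run_sweep() and the contrast task.
.fit_algorithm <- function(algorithm, train, options = fit_options()) {
  switch(algorithm,
         solr = fit_solr(train, options),
         l2olr = fit_l2olr(train, options),
         slir = fit_slir(train, options),
         smlr = fit_smlr(train, options),
         stop(sprintf("unknown algorithm '%s'", algorithm)))
}

.predict_labels <- function(fit, X) {
  if (inherits(fit, "slir_fit")) predict_slir_ordinal(fit, X)
  else predict(fit, X)
}

#' Run a simulation sweep over input dimensions or training-set size
#'
#' For each axis value and repetition, draws fresh class means and fresh
#' train/test sets, fits every requested algorithm on the identical
#' training data, and scores predictions on the identical test set by
#' [spearman()] (a paired design). A master seed spawns one child seed per
#' (axis value, repetition) cell so repetitions are independent and
#' individually replayable. Fit failures and undefined (constant-
#' prediction) scores are excluded from the summary with a logged count,
#' never silently.
#'
#' @param config a [simulation_config()] providing the non-swept values.
#' @param algorithms subset of `c("solr", "l2olr", "slir", "smlr")`.
#' @param sweep_axis `"dims"` to sweep `n_features`, `"n_train"` to sweep
#'   the training-set size.
#' @param axis_values numeric vector of axis values.
#' @param n_repetitions repetitions per axis value; defaults to
#'   `config$n_repetitions`.
#' @param seed master seed.
#' @param options [fit_options()] shared by all fits.
#' @return an object of class `solr_sweep`: list with `results` (long
#'   data.frame: axis, axis_value, repetition, algorithm, spearman, seed),
#'   `summary` (mean/sd per axis value and algorithm), `n_failed`,
#'   `config`, `seed`.
#' @export
run_sweep <- function(config, algorithms = c("solr", "l2olr", "slir", "smlr"),
                      sweep_axis = c("dims", "n_train"), axis_values,
                      n_repetitions = config$n_repetitions, seed = 1L,
                      options = fit_options()) {
  stopifnot(inherits(config, "simulation_config"))
  sweep_axis <- match.arg(sweep_axis)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  set.seed(seed)
  seed_mat <- matrix(sample.int(.Machine$integer.max, length(axis_values) * n_repetitions),
                     nrow = length(axis_values))
  rows <- vector("list", length(axis_values) * n_repetitions * length(algorithms))
  n_failed <- 0L
  k <- 0L
  for (i in seq_along(axis_values)) {
    cfg <- config
    if (sweep_axis == "dims") cfg$n_features <- as.integer(axis_values[i])
    else cfg$n_train <- as.integer(axis_values[i])
    for (r in seq_len(n_repetitions)) {
      set.seed(seed_mat[i, r])
      means <- generate_class_means(cfg)
      train <- sample_dataset(cfg, means, cfg$n_train)
      test <- sample_dataset(cfg, means, cfg$n_test)
      for (alg in algorithms) {
        rho <- tryCatch({
          fit <- .fit_algorithm(alg, train, options)
          spearman(test$labels, .predict_labels(fit, test$features))
        }, error = function(e) {
          message(sprintf("fit failure (%s, axis %g, rep %d): %s",
                          alg, axis_values[i], r, conditionMessage(e)))
          NA_real_
        })
        k <- k + 1L
        rows[[k]] <- data.frame(axis = sweep_axis, axis_value = axis_values[i],
                                repetition = r, algorithm = alg,
                                spearman = rho, seed = seed_mat[i, r])
      }
    }
  }
  results <- do.call(rbind, rows)
  n_failed <- sum(is.na(results$spearman))
  if (n_failed > 0L)
    message(sprintf("%d of %d scores undefined or failed; excluded from summary",
                    n_failed, nrow(results)))
  summary <- stats::aggregate(spearman ~ axis_value + algorithm, data = results,
                              FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                                  sd = stats::sd(v, na.rm = TRUE)))
  summary <- data.frame(axis_value = summary$axis_value,
                        algorithm = summary$algorithm,
                        mean = summary$spearman[, "mean"],
                        sd = summary$spearman[, "sd"])
  structure(list(results = results, summary = summary, n_failed = n_failed,
                 config = config, sweep_axis = sweep_axis, seed = seed),
            class = "solr_sweep")
}

#' @export
print.solr_sweep <- function(x, ...) {
  cat(sprintf("Simulation sweep over %s (%d repetitions, master seed %d)\n",
              x$sweep_axis, max(x$results$repetition), x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Plot mean +/- SD Spearman curves from a sweep
#'
#' @param x a `solr_sweep` object.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the wide matrix of mean scores.
#' @export
plot.solr_sweep <- function(x, ...) {
  s <- x$summary
  algs <- sort(unique(s$algorithm))
  vals <- sort(unique(s$axis_value))
  M <- sapply(algs, function(a) s$mean[s$algorithm == a][order(s$axis_value[s$algorithm == a])])
  graphics::matplot(vals, M, type = "b", pch = 19, lty = 1, log = "x",
                    xlab = x$sweep_axis, ylab = "Spearman rank correlation", ...)
  for (j in seq_along(algs)) {
    sj <- s[s$algorithm == algs[j], ]
    sj <- sj[order(sj$axis_value), ]
    graphics::arrows(vals, sj$mean - sj$sd, vals, sj$mean + sj$sd,
                     angle = 90, code = 3, length = 0.03, col = j)
  }
  graphics::legend("bottomleft", legend = toupper(algs), col = seq_along(algs),
                   pch = 19, bty = "n")
  invisible(M)
}
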