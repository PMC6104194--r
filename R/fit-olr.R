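#' Fitting options for the Bayesian OLR estimators
#'
#' @param max_iterations maximum number of outer variational iterations.
#' @param step_tolerance convergence tolerance: the outer loop stops when
#'   the maximum absolute change across the weights and thresholds falls
#'   to this value or below. Default 0.001.
#' @param prune_threshold relevance precision above which a feature is
#'   frozen at weight 0 and dropped from subsequent Newton systems.
#' @param newton_max_iter maximum number of step halvings in the
#'   backtracking line searches.
#' @param alpha_init initial relevance precision (per feature for SOLR,
#'   scalar for L2OLR).
#' @param alpha_update ARD precision update rule for the sparse fitters:
#'   `"mackay"` (default) uses the MacKay/Tipping effective-degrees form
#'   `alpha_d = (1 - alpha_d S_dd) / w_d^2`, whose geometric growth on
#'   irrelevant features drives them to the prune threshold within tens of
#'   iterations; `"vb"` uses the variational posterior mean
#'   `alpha_d = 1 / (w_d^2 + S_dd)`, which shrinks but in practice never
#'   prunes before the step-tolerance stopping rule fires (see the methods
#'   vignette). L2OLR always uses its scalar update
#'   `alpha = D / (||w||^2 + sum(S_dd))`.
#' @param update_alpha if `FALSE` the relevance precision is frozen at
#'   `alpha_init` (useful to study L2OLR as a fixed-ridge fit).
#' @param seed optional integer recorded in the model metadata. The
#'   fitters themselves are deterministic.
#' @param verbose print per-iteration progress.
#' @return a list of class `fit_options`.
#' @export
fit_options <- function(max_iterations = 500L, step_tolerance = 1e-3,
                        prune_threshold = 1e8, newton_max_iter = 30L,
                        alpha_init = 1, alpha_update = c("mackay", "vb"),
                        update_alpha = TRUE, seed = NULL, verbose = FALSE) {
  stopifnot(step_tolerance > 0, prune_threshold > 0, alpha_init > 0)
  alpha_update <- match.arg(alpha_update)
  structure(list(max_iterations = as.integer(max_iterations),
                 step_tolerance = step_tolerance,
                 prune_threshold = prune_threshold,
                 newton_max_iter = as.integer(newton_max_iter),
                 alpha_init = alpha_init,
                 alpha_update = alpha_update,
                 update_alpha = isTRUE(update_alpha),
                 seed = seed,
                 verbose = isTRUE(verbose)),
            class = "fit_options")
}

# ARD precision update given the current mode w, Laplace variances sdiag and
# current precisions alpha.  Capped at 1e12 so the prune test stays finite.
.ard_update <- function(w, sdiag, alpha, rule) {
  if (rule == "mackay") {
    gam <- pmin(pmax(1 - alpha * sdiag, 1e-12), 1)
    pmin(gam / pmax(w^2, 1e-300), 1e12)
  } else {
    pmin(1 / pmax(w^2 + sdiag, 1e-300), 1e12)
  }
}

.check_fit_data <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (anyNA(data$features)) stop("features contain NA")
  if (length(unique(data$labels)) < 2L)
    stop("labels are constant: need at least two observed classes")
  counts <- tabulate(data$labels, data$n_classes)
  if (any(counts == 0L))
    warning(sprintf("class(es) %s have no training samples; thresholds for empty segments are driven by their neighbors",
                    paste(which(counts == 0L), collapse = ", ")))
  invisible(data)
}

# Log joint density (up to the flat-threshold-prior constant) over the given
# feature set: likelihood + Gaussian ARD prior on w + the scale-invariant
# alpha prior p(alpha_d) = 1/alpha_d.
.log_joint_terms <- function(loglik, w, alpha) {
  loglik + sum(0.5 * log(alpha / (2 * pi)) - 0.5 * alpha * w^2) +
    sum(-log(alpha))
}

#' Fit sparse ordinal logistic regression (SOLR)
#'
#' MAP estimation of the cumulative-logit model under an ARD prior
#' `w_d ~ N(0, 1/alpha_d)` with the non-informative hyperprior
#' `p(alpha_d) = 1/alpha_d`, by mean-field variational Bayes with a Laplace
#' approximation. Each outer iteration takes a damped Newton step in the
#' weights and thresholds at the current relevance precisions, forms the
#' Laplace posterior weight variances `S_dd` from the inverse Newton
#' system, and updates the precisions (MacKay form
#' `alpha_d = (1 - alpha_d S_dd) / w_d^2` by default; see
#' [fit_options()]). Features whose precision exceeds
#' `prune_threshold` are frozen at exactly zero and dropped, which performs
#' automatic feature (voxel) selection. The method has no hyperparameters
#' to tune.
#'
#' @param data a [labeled_dataset()].
#' @param options a [fit_options()] list.
#' @return an object of class `c("solr_fit", "olr_fit")`: list with
#'   `model` (an [ordinal_model()]), `relevance` (list with `alpha`,
#'   `posterior_var`, `pruned`), `n_iterations`, `converged`,
#'   `objective_trace` (log joint over active features per iteration).
#' @seealso [fit_l2olr()], [selected_features()], [log_joint()]
#' @export
fit_solr <- function(data, options = fit_options()) {
  .check_fit_data(data)
  X <- data$features; y <- data$labels; C <- data$n_classes
  D <- ncol(X)
  alpha <- rep(options$alpha_init, D)
  w <- numeric(D)
  active <- rep(TRUE, D)
  pvar <- rep(1 / options$alpha_init, D)
  theta <- .init_theta(y, C)
  mu <- .theta_to_mu(theta)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < options$max_iterations) {
    it <- it + 1L
    w_old <- w; mu_old <- mu
    ia <- which(active)
    Xa <- X[, ia, drop = FALSE]
    w[ia] <- .newton_w_step(Xa, y, mu, w[ia], alpha[ia], options$newton_max_iter)
    z <- drop(Xa %*% w[ia])
    theta <- .newton_theta_step(z, y, theta, C, options$newton_max_iter)
    mu <- .theta_to_mu(theta)
    tr <- .olr_terms(z, y, mu)
    sdiag <- pmax(.lowrank_solve(alpha[ia], Xa, tr$lam, want_diag = TRUE)$diag, 0)
    pvar[ia] <- sdiag
    if (options$update_alpha)
      alpha[ia] <- .ard_update(w[ia], sdiag, alpha[ia], options$alpha_update)
    drop_now <- active & alpha > options$prune_threshold
    if (any(drop_now)) {
      w[drop_now] <- 0
      pvar[drop_now] <- 0
      active[drop_now] <- FALSE
    }
    trace[it] <- .log_joint_terms(sum(log(tr$p)), w[active], alpha[active])
    delta <- max(abs(w - w_old), abs(mu - mu_old))
    if (options$verbose)
      message(sprintf("iter %3d: active %4d, delta %.3g", it, sum(active), delta))
    if (delta <= options$step_tolerance) { converged <- TRUE; break }
  }
  model <- ordinal_model(w, mu, metadata = list(
    algorithm = "solr", n_iterations = it, converged = converged,
    seed = options$seed, step_tolerance = options$step_tolerance))
  structure(list(model = model,
                 relevance = list(alpha = alpha, posterior_var = pvar,
                                  pruned = !active),
                 n_iterations = it, converged = converged,
                 objective_trace = trace),
            class = c("solr_fit", "olr_fit"))
}

#' Fit L2-regularized ordinal logistic regression (L2OLR)
#'
#' Same variational scheme as [fit_solr()] but with an isotropic Gaussian
#' prior `w ~ N(0, I/alpha)` whose single precision is updated as
#' `alpha = D / (||w||^2 + sum_d S_dd)`. No feature is ever pruned: all
#' weights are generically nonzero, so L2OLR acts as a ridge-type
#' baseline against which the effect of ARD sparseness is measured.
#'
#' @inheritParams fit_solr
#' @return an object of class `c("l2olr_fit", "olr_fit")` with fields as
#'   in [fit_solr()] except that `alpha` is a scalar and `relevance$pruned`
#'   is all-`FALSE`.
#' @export
fit_l2olr <- function(data, options = fit_options()) {
  .check_fit_data(data)
  X <- data$features; y <- data$labels; C <- data$n_classes
  D <- ncol(X)
  a <- options$alpha_init
  w <- numeric(D)
  pvar <- rep(1 / a, D)
  theta <- .init_theta(y, C)
  mu <- .theta_to_mu(theta)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < options$max_iterations) {
    it <- it + 1L
    w_old <- w; mu_old <- mu
    w <- .newton_w_step(X, y, mu, w, rep(a, D), options$newton_max_iter)
    z <- drop(X %*% w)
    theta <- .newton_theta_step(z, y, theta, C, options$newton_max_iter)
    mu <- .theta_to_mu(theta)
    tr <- .olr_terms(z, y, mu)
    pvar <- pmax(.lowrank_solve(rep(a, D), X, tr$lam, want_diag = TRUE)$diag, 0)
    if (options$update_alpha)
      a <- D / max(sum(w^2) + sum(pvar), 1e-300)
    trace[it] <- .log_joint_terms(sum(log(tr$p)), w, rep(a, D))
    delta <- max(abs(w - w_old), abs(mu - mu_old))
    if (options$verbose)
      message(sprintf("iter %3d: alpha %.3g, delta %.3g", it, a, delta))
    if (delta <= options$step_tolerance) { converged <- TRUE; break }
  }
  model <- ordinal_model(w, mu, metadata = list(
    algorithm = "l2olr", n_iterations = it, converged = converged,
    seed = options$seed, step_tolerance = options$step_tolerance))
  structure(list(model = model,
                 alpha = a,
                 relevance = list(alpha = rep(a, D),
                                  posterior_var = pvar,
                                  pruned = rep(FALSE, D)),
                 n_iterations = it, converged = converged,
                 objective_trace = trace),
            class = c("l2olr_fit", "olr_fit"))
}

#' @export
predict.olr_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' @export
print.olr_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d iterations, converged = %s\n",
              toupper(x$model$metadata$algorithm %||% "olr"),
              x$n_iterations, x$converged))
  print(x$model)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Indices of features retained by an ARD fit
#'
#' For sparse fits, the features that were not pruned (equivalently, the
#' features with nonzero weights). For L2OLR and other non-pruning fits,
#' all feature indices.
#'
#' @param result a fit object from [fit_solr()], [fit_l2olr()],
#'   [fit_slir()] or [fit_smlr()].
#' @return integer vector of selected feature indices.
#' @export
selected_features <- function(result) {
  UseMethod("selected_features")
}

#' @export
selected_features.solr_fit <- function(result) {
  which(!result$relevance$pruned)
}

#' @export
selected_features.l2olr_fit <- function(result) {
  seq_len(result$model$n_features)
}

#' @export
selected_features.slir_fit <- function(result) {
  which(!result$relevance$pruned)
}

#' @export
selected_features.smlr_fit <- function(result) {
  which(rowSums(!result$pruned) > 0L)
}

#' Log joint density of weights, thresholds and relevance precisions
#'
#' `log p(w, mu, alpha, Y | X)` up to the constant contributed by the flat
#' threshold prior: the ordinal log likelihood, plus the ARD Gaussian prior
#' `log N(w; 0, diag(1/alpha))`, plus the scale-invariant hyperprior
#' `sum_d log(1/alpha_d)`.
#'
#' @param model an [ordinal_model()].
#' @param relevance list with a positive `alpha` vector of length `D`
#'   (as in the `relevance` field of a fit).
#' @param data a [labeled_dataset()].
#' @return a single number.
#' @export
log_joint <- function(model, relevance, data) {
  alpha <- relevance$alpha
  stopifnot(length(alpha) == model$n_features, all(alpha > 0))
  .log_joint_terms(log_likelihood(model, data), model$weights, alpha)
}
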