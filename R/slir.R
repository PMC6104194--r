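#' Fit sparse linear regression (SLiR)
#'
#' ARD Bayesian linear regression in the relevance-vector-machine style,
#' treating the ordinal label as a continuous response. Features and
#' response are centered before fitting and the intercept is restored.
#' Per-feature precisions follow the same ARD update as [fit_solr()]
#' (MacKay/Tipping form `alpha_d = gamma_d / m_d^2` with
#' `gamma_d = 1 - alpha_d S_dd` by default); the noise precision is
#' re-estimated each iteration as `beta = (N - sum(gamma_d)) / ||resid||^2`.
#' Features with diverging precision are pruned to exactly zero.
#'
#' @inheritParams fit_solr
#' @return an object of class `slir_fit`: list with `weights`,
#'   `intercept`, `noise_precision`, `relevance` (`alpha`,
#'   `posterior_var`, `pruned`), `n_iterations`, `converged`.
#' @seealso [predict_slir_ordinal()]
#' @export
fit_slir <- function(data, options = fit_options()) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (anyNA(data$features)) stop("features contain NA")
  X <- data$features
  yv <- as.numeric(data$labels)
  N <- nrow(X); D <- ncol(X)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  ybar <- mean(yv)
  yc <- yv - ybar
  beta <- if (stats::var(yc) > 0) 1 / stats::var(yc) else 1
  alpha <- rep(options$alpha_init, D)
  m <- numeric(D)
  pvar <- rep(1 / options$alpha_init, D)
  active <- rep(TRUE, D)
  converged <- FALSE
  it <- 0L
  while (it < options$max_iterations) {
    it <- it + 1L
    m_old <- m
    ia <- which(active)
    Xa <- Xc[, ia, drop = FALSE]
    sol <- .lowrank_solve(alpha[ia], Xa, rep(beta, N),
                          b = beta * drop(crossprod(Xa, yc)),
                          want_diag = TRUE)
    m[ia] <- sol$x
    sdiag <- pmax(sol$diag, 0)
    pvar[ia] <- sdiag
    gamma_eff <- max(length(ia) - sum(alpha[ia] * sdiag), 0)
    if (options$update_alpha)
      alpha[ia] <- .ard_update(m[ia], sdiag, alpha[ia], options$alpha_update)
    drop_now <- active & alpha > options$prune_threshold
    if (any(drop_now)) {
      m[drop_now] <- 0
      pvar[drop_now] <- 0
      active[drop_now] <- FALSE
    }
    resid <- yc - drop(Xc[, active, drop = FALSE] %*% m[active])
    beta <- min(max(N - gamma_eff, 1) / max(sum(resid^2), 1e-12), 1e12)
    delta <- max(abs(m - m_old))
    if (options$verbose)
      message(sprintf("iter %3d: active %4d, beta %.3g, delta %.3g",
                      it, sum(active), beta, delta))
    if (delta <= options$step_tolerance) { converged <- TRUE; break }
  }
  structure(list(weights = m,
                 intercept = ybar - sum(xbar * m),
                 noise_precision = beta,
                 relevance = list(alpha = alpha, posterior_var = pvar,
                                  pruned = !active),
                 n_iterations = it, converged = converged,
                 n_classes = data$n_classes),
            class = "slir_fit")
}

#' @export
predict.slir_fit <- function(object, newdata, ...) {
  X <- .as_row_matrix(newdata, length(object$weights))
  drop(X %*% object$weights) + object$intercept
}

#' @export
print.slir_fit <- function(x, ...) {
  cat(sprintf("SLiR fit: %d/%d features retained, %d iterations, converged = %s\n",
              sum(!x$relevance$pruned), length(x$weights),
              x$n_iterations, x$converged))
  invisible(x)
}

#' Assign SLiR's continuous outputs to the nearest ordinal labels
#'
#' Rounds the continuous prediction to the nearest integer label in
#' `{1..n_classes}`. Exact midpoints (`k + 0.5`) go to the lower label;
#' outputs outside the label range are clipped.
#'
#' @param model an `slir_fit` object.
#' @param x numeric vector of length `D` or `N x D` matrix.
#' @param n_classes number of ordinal classes `C`; defaults to the class
#'   count recorded at fit time.
#' @return integer labels in `{1..n_classes}`.
#' @export
predict_slir_ordinal <- function(model, x, n_classes = model$n_classes) {
  cont <- predict(model, x)
  cls <- ceiling(cont - 0.5)   # midpoints round down
  as.integer(pmin(pmax(cls, 1), n_classes))
}
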