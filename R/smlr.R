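.softmax_probs <- function(Eta) {
  # Eta: N x C linear predictors (reference class column included as zeros)
  M <- Eta - apply(Eta, 1L, max)
  E <- exp(M)
  E / rowSums(E)
}

.smlr_objective <- function(P, y, W, alpha) {
  sum(log(pmax(P[cbind(seq_along(y), y)], 1e-300))) - 0.5 * sum(alpha * W^2)
}

#' Fit sparse multinomial logistic regression (SMLR)
#'
#' Multinomial (softmax) logistic regression with an ARD prior on every
#' weight entry, estimated by the same variational Bayes / Laplace scheme
#' as [fit_solr()]. Class `C` is the reference class with its weight
#' vector fixed at zero; each remaining class has its own weight vector
#' and unpenalized intercept, so decision boundaries are unconstrained
#' (unlike the parallel boundaries of ordinal regression) and the class
#' order is ignored. Weights whose relevance precision diverges are
#' pruned to exactly zero.
#'
#' @inheritParams fit_solr
#' @return an object of class `smlr_fit`: list with `weight_matrix`
#'   (`D x C`, reference column zero), `intercepts` (length `C`),
#'   `alpha` (`D x (C-1)` relevance precisions), `posterior_var`,
#'   `pruned` (`D x (C-1)` logical), `n_iterations`, `converged`.
#' @export
fit_smlr <- function(data, options = fit_options()) {
  .check_fit_data(data)
  X <- data$features; y <- data$labels; C <- data$n_classes
  N <- nrow(X); D <- ncol(X)
  K <- C - 1L
  X1 <- cbind(1, X)                      # intercept column first
  W <- matrix(0, D + 1L, K)              # per-class [b_j; w_j]
  alpha <- matrix(options$alpha_init, D + 1L, K)
  alpha[1L, ] <- 1e-8                    # intercepts effectively unpenalized
  pvar <- 1 / alpha
  active <- matrix(TRUE, D + 1L, K)
  Yind <- data$indicator
  converged <- FALSE
  it <- 0L
  while (it < options$max_iterations) {
    it <- it + 1L
    W_old <- W
    for (j in seq_len(K)) {
      Eta <- cbind(X1 %*% W, 0)
      P <- .softmax_probs(Eta)
      pij <- P[, j]
      ia <- which(active[, j])
      Xa <- X1[, ia, drop = FALSE]
      g <- drop(crossprod(Xa, Yind[, j] - pij)) - alpha[ia, j] * W[ia, j]
      lam <- pmax(pij * (1 - pij), 1e-10)
      dir <- .lowrank_solve(alpha[ia, j], Xa, lam, b = g)$x
      gd <- sum(g * dir)
      if (!is.finite(gd) || gd <= 0) { dir <- g; gd <- sum(g^2) }
      obj0 <- .smlr_objective(P, y, W, alpha)
      step <- 1
      for (ls in seq_len(options$newton_max_iter)) {
        W1 <- W; W1[ia, j] <- W[ia, j] + step * dir
        P1 <- .softmax_probs(cbind(X1 %*% W1, 0))
        obj1 <- .smlr_objective(P1, y, W1, alpha)
        if (is.finite(obj1) && obj1 >= obj0 + 1e-4 * step * gd) {
          W <- W1
          break
        }
        step <- step / 2
      }
      # Laplace posterior variance for this block, then the ARD update
      P <- .softmax_probs(cbind(X1 %*% W, 0))
      lam <- pmax(P[, j] * (1 - P[, j]), 1e-10)
      sdiag <- pmax(.lowrank_solve(alpha[ia, j], Xa, lam, want_diag = TRUE)$diag, 0)
      pvar[ia, j] <- sdiag
      if (options$update_alpha) {
        upd <- .ard_update(W[ia, j], sdiag, alpha[ia, j], options$alpha_update)
        keep_intercept <- ia == 1L
        alpha[ia[!keep_intercept], j] <- upd[!keep_intercept]
      }
    }
    drop_now <- active & alpha > options$prune_threshold
    drop_now[1L, ] <- FALSE               # never prune intercepts
    if (any(drop_now)) {
      W[drop_now] <- 0
      pvar[drop_now] <- 0
      active[drop_now] <- FALSE
    }
    delta <- max(abs(W - W_old))
    if (options$verbose)
      message(sprintf("iter %3d: active %4d, delta %.3g",
                      it, sum(active[-1L, ]), delta))
    if (delta <= options$step_tolerance) { converged <- TRUE; break }
  }
  weight_matrix <- cbind(W[-1L, , drop = FALSE], 0)
  colnames(weight_matrix) <- paste0("class", seq_len(C))
  structure(list(weight_matrix = weight_matrix,
                 intercepts = c(W[1L, ], 0),
                 alpha = alpha[-1L, , drop = FALSE],
                 posterior_var = pvar[-1L, , drop = FALSE],
                 pruned = !active[-1L, , drop = FALSE],
                 n_iterations = it, converged = converged,
                 n_classes = C),
            class = "smlr_fit")
}

#' @export
predict.smlr_fit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- .as_row_matrix(newdata, nrow(object$weight_matrix))
  Eta <- sweep(X %*% object$weight_matrix, 2L, object$intercepts, `+`)
  P <- .softmax_probs(Eta)
  if (type == "prob") return(P)
  as.integer(max.col(P, ties.method = "first"))
}

#' @export
print.smlr_fit <- function(x, ...) {
  cat(sprintf("SMLR fit: %d classes, %d/%d nonzero weights, %d iterations, converged = %s\n",
              x$n_classes, sum(x$weight_matrix != 0),
              length(x$pruned), x$n_iterations, x$converged))
  invisible(x)
}
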