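# Internal numerics shared by the OLR-family fitters.
#
# Per-sample quantities for the cumulative logistic likelihood.  For sample n
# with class c the likelihood term is p = F(a) - F(b), a = mu_c - z,
# b = mu_{c-1} - z.  Returns p (floored at 1e-300), the first derivative of
# log p with respect to z (gz) and minus the second derivative (lam >= 0 by
# log-concavity of the cumulative logistic likelihood; clamped at 0 against
# roundoff).
.olr_terms <- function(z, y, mu) {
  upper <- c(mu, Inf)[y]
  lower <- c(-Inf, mu)[y]
  a <- upper - z
  b <- lower - z
  Fa <- stats::plogis(a); Fb <- stats::plogis(b)
  fa <- Fa * (1 - Fa);    fb <- Fb * (1 - Fb)
  p <- pmax(Fa - Fb, 1e-300)
  gz <- (fb - fa) / p
  lam <- gz^2 + (fb * (1 - 2 * Fb) - fa * (1 - 2 * Fa)) / p
  lam <- pmax(lam, 0)
  list(p = p, gz = gz, lam = lam, fa = fa, fb = fb)
}

# Gradient of the log likelihood with respect to the thresholds mu.
# Class y contributes +f(a)/p to mu_y (if y <= C-1) and -f(b)/p to mu_{y-1}.
.mu_grad <- function(terms, y, C) {
  up <- terms$fa / terms$p
  lo <- terms$fb / terms$p
  g <- numeric(C - 1)
  for (k in seq_len(C - 1))
    g[k] <- sum(up[y == k]) - sum(lo[y == k + 1L])
  g
}

# Threshold reparameterization mu = (theta_1, theta_1 + exp(theta_2), ...)
# keeps the ordering unconditionally during unconstrained Newton steps.
# Increments are capped so exp() cannot overflow.
.theta_to_mu <- function(theta) {
  if (length(theta) == 1L) return(theta)
  cumsum(c(theta[1], exp(pmin(theta[-1], 30))))
}

.mu_to_theta <- function(mu) {
  if (length(mu) == 1L) return(mu)
  c(mu[1], log(pmax(diff(mu), 1e-8)))
}

# Initial thresholds: logistic quantiles of the empirical cumulative class
# frequencies (with w = 0 these reproduce the class proportions exactly).
.init_theta <- function(y, C) {
  cf <- cumsum(tabulate(y, C)) / length(y)
  q <- stats::qlogis(pmin(pmax(cf[seq_len(C - 1)], 1e-3), 1 - 1e-3))
  if (C > 2L) q <- q[1] + cumsum(c(0, pmax(diff(q), 1e-3)))
  .mu_to_theta(q)
}

# Solve (diag(alpha) + X' diag(lam) X) x = b and/or return the diagonal of
# the inverse.  Uses a direct Cholesky when D is moderate and the Woodbury
# identity when D >> N (cost O(N^2 D) instead of O(D^3)).  A 1e-8 diagonal
# jitter is added if the factorization fails.
.lowrank_solve <- function(alpha, X, lam, b = NULL, want_diag = FALSE) {
  D <- ncol(X); N <- nrow(X)
  out <- list()
  if (D <= 400L || D <= 2L * N) {
    K <- crossprod(X * sqrt(lam))
    diag(K) <- diag(K) + alpha
    R <- tryCatch(chol(K), error = function(e) {
      message("lowrank_solve: adding 1e-8 jitter to Newton system diagonal")
      chol(K + diag(1e-8, D))
    })
    if (!is.null(b))
      out$x <- drop(backsolve(R, backsolve(R, b, transpose = TRUE)))
    if (want_diag)
      out$diag <- diag(chol2inv(R))
  } else {
    s <- sqrt(lam)
    Xs <- X * s                 # rows scaled by sqrt(lam)
    Tt <- t(Xs) / alpha         # D x N = A^{-1} Xs'
    M <- diag(N) + Xs %*% Tt
    R <- tryCatch(chol(M), error = function(e) {
      message("lowrank_solve: adding 1e-8 jitter to Woodbury core diagonal")
      chol(M + diag(1e-8, N))
    })
    if (!is.null(b)) {
      u <- Xs %*% (b / alpha)
      out$x <- drop(b / alpha -
                      Tt %*% backsolve(R, backsolve(R, u, transpose = TRUE)))
    }
    if (want_diag) {
      Minv <- chol2inv(R)
      out$diag <- 1 / alpha - rowSums((Tt %*% Minv) * Tt)
    }
  }
  out
}

.pen_loglik <- function(X, y, mu, w, alpha) {
  tr <- .olr_terms(drop(X %*% w), y, mu)
  sum(log(tr$p)) - 0.5 * sum(alpha * w^2)
}

# One damped Newton ascent step on the alpha-penalized log likelihood in w
# (thresholds held fixed).  Backtracking line search with an Armijo
# condition guarantees the penalized objective does not decrease.
.newton_w_step <- function(X, y, mu, w, alpha, max_halvings = 30L) {
  z <- drop(X %*% w)
  tr <- .olr_terms(z, y, mu)
  obj0 <- sum(log(tr$p)) - 0.5 * sum(alpha * w^2)
  g <- drop(crossprod(X, tr$gz)) - alpha * w
  dir <- .lowrank_solve(alpha, X, tr$lam, b = g)$x
  gd <- sum(g * dir)
  if (!is.finite(gd) || gd <= 0) { dir <- g / max(alpha); gd <- sum(g * dir) }
  step <- 1
  for (i in seq_len(max_halvings)) {
    w1 <- w + step * dir
    obj1 <- .pen_loglik(X, y, mu, w1, alpha)
    if (is.finite(obj1) && obj1 >= obj0 + 1e-4 * step * gd) return(w1)
    step <- step / 2
  }
  w
}

# One damped Newton step on the thresholds in the order-preserving theta
# parameterization.  The small (C-1)x(C-1) Hessian is obtained by central
# differences of the analytic theta-gradient.
.theta_grad <- function(z, y, theta, C) {
  mu <- .theta_to_mu(theta)
  gmu <- .mu_grad(.olr_terms(z, y, mu), y, C)
  g <- numeric(C - 1)
  g[1] <- sum(gmu)
  if (C > 2L)
    for (j in 2:(C - 1))
      g[j] <- exp(min(theta[j], 30)) * sum(gmu[j:(C - 1)])
  g
}

.newton_theta_step <- function(z, y, theta, C, max_halvings = 30L) {
  K <- C - 1L
  g <- .theta_grad(z, y, theta, C)
  H <- matrix(0, K, K)
  h <- 1e-5
  for (j in seq_len(K)) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- (.theta_grad(z, y, tp, C) - .theta_grad(z, y, tm, C)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  dir <- tryCatch(drop(solve(-H + diag(1e-8, K), g)),
                  error = function(e) g)
  gd <- sum(g * dir)
  if (!is.finite(gd) || gd <= 0) { dir <- g; gd <- sum(g^2) }
  obj0 <- sum(log(.olr_terms(z, y, .theta_to_mu(theta))$p))
  step <- 1
  for (i in seq_len(max_halvings)) {
    t1 <- theta + step * dir
    obj1 <- sum(log(.olr_terms(z, y, .theta_to_mu(t1))$p))
    if (is.finite(obj1) && obj1 >= obj0 + 1e-4 * step * gd) return(t1)
    step <- step / 2
  }
  theta
}
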