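#' Logistic sigmoid
#'
#' The cumulative distribution function of the standard logistic
#' distribution, `F(z) = 1 / (1 + exp(-z))`. Saturates to 0/1 at extreme
#' arguments (including `-Inf`/`Inf`) without overflow.
#'
#' @param z numeric vector.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @examples
#' sigmoid(0)    # 0.5
#' sigmoid(2)    # 0.8807971
#' @export
sigmoid <- function(z) stats::plogis(z)

#' Construct a cumulative-link ordinal model
#'
#' An ordinal logistic regression model is defined by a weight vector `w`
#' and strictly increasing thresholds `mu_1 < ... < mu_{C-1}` cutting the
#' latent axis `z = w'x + eps` (logistic noise) into `C` ordered segments.
#' The boundary conventions `mu_0 = -Inf`, `mu_C = +Inf` are implicit and
#' never stored.
#'
#' @param weights numeric vector of length `D`.
#' @param thresholds numeric vector of length `C - 1`, strictly increasing.
#' @param metadata optional named list (algorithm, seed, options, ...)
#'   carried through serialization.
#' @return an object of class `ordinal_model` with fields `weights`,
#'   `thresholds`, `n_classes`, `n_features`, `metadata`.
#' @seealso [class_probabilities()], [predict.ordinal_model()]
#' @export
ordinal_model <- function(weights, thresholds, metadata = list()) {
  weights <- as.numeric(weights)
  thresholds <- as.numeric(thresholds)
  if (length(weights) < 1L) stop("'weights' must have length >= 1")
  if (length(thresholds) < 1L) stop("'thresholds' must have length >= 1 (C >= 2)")
  if (anyNA(weights) || anyNA(thresholds))
    stop("'weights' and 'thresholds' must not contain NA")
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  structure(
    list(weights = weights,
         thresholds = thresholds,
         n_classes = length(thresholds) + 1L,
         n_features = length(weights),
         metadata = metadata),
    class = "ordinal_model")
}

#' @export
print.ordinal_model <- function(x, ...) {
  cat(sprintf("Ordinal logistic model: %d features, %d classes\n",
              x$n_features, x$n_classes))
  cat(sprintf("  nonzero weights: %d\n", sum(x$weights != 0)))
  cat("  thresholds:", format(x$thresholds, digits = 4), "\n")
  invisible(x)
}

.check_model <- function(model) {
  if (!inherits(model, "ordinal_model")) stop("not an 'ordinal_model'")
  if (any(diff(model$thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  invisible(model)
}

.as_row_matrix <- function(x, d) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != d)
    stop(sprintf("feature dimension mismatch: got %d, model has %d", ncol(x), d))
  x
}

#' Latent decision value
#'
#' The deterministic part of the latent variable, `z = w'x`.
#'
#' @param model an [ordinal_model()].
#' @param x numeric vector of length `D`, or an `N x D` matrix.
#' @return numeric vector of length `N` (length 1 for a single sample).
#' @export
decision_value <- function(model, x) {
  .check_model(model)
  X <- .as_row_matrix(x, model$n_features)
  drop(X %*% model$weights)
}

#' Class probabilities under the cumulative logistic link
#'
#' `p_c = F(mu_c - w'x) - F(mu_{c-1} - w'x)` with `mu_0 = -Inf`,
#' `mu_C = +Inf`. The probabilities are non-negative and telescope to 1.
#'
#' @inheritParams decision_value
#' @return an `N x C` matrix of probabilities (a vector of length `C`
#'   for a single sample supplied as a vector).
#' @export
class_probabilities <- function(model, x) {
  .check_model(model)
  single <- is.null(dim(x))
  z <- decision_value(model, x)
  cuts <- c(-Inf, model$thresholds, Inf)
  C <- model$n_classes
  Fz <- stats::plogis(outer(-z, cuts, `+`))   # N x (C+1): F(mu_k - z)
  P <- Fz[, 2:(C + 1), drop = FALSE] - Fz[, 1:C, drop = FALSE]
  P[P < 0] <- 0
  colnames(P) <- paste0("class", seq_len(C))
  if (single) drop(P) else P
}

#' Log likelihood of an ordinal model
#'
#' Sum over samples of the log probability of the observed class,
#' `sum_n sum_c y_nc log[F(mu_c - w'x_n) - F(mu_{c-1} - w'x_n)]`.
#' Per-class probabilities are floored at `1e-300` before the log is taken,
#' so the value is always finite (never `-Inf`).
#'
#' @param model an [ordinal_model()].
#' @param data a [labeled_dataset()].
#' @return a single number `<= 0`.
#' @export
log_likelihood <- function(model, data) {
  .check_model(model)
  stopifnot(inherits(data, "labeled_dataset"))
  if (data$n_classes != model$n_classes)
    stop("class count mismatch between model and data")
  z <- decision_value(model, data$features)
  tr <- .olr_terms(z, data$labels, model$thresholds)
  sum(log(tr$p))
}

#' Analytic gradient of the ordinal log likelihood
#'
#' Gradient of [log_likelihood()] with respect to the weights and the
#' thresholds, used by the Newton steps of the fitting routines.
#'
#' @inheritParams log_likelihood
#' @return a list with components `weights` (length `D`) and
#'   `thresholds` (length `C - 1`).
#' @export
log_likelihood_gradient <- function(model, data) {
  .check_model(model)
  stopifnot(inherits(data, "labeled_dataset"))
  z <- decision_value(model, data$features)
  tr <- .olr_terms(z, data$labels, model$thresholds)
  list(weights = drop(crossprod(data$features, tr$gz)),
       thresholds = .mu_grad(tr, data$labels, model$n_classes))
}

#' Predict ordinal class labels
#'
#' The class with the highest predictive probability is chosen; ties are
#' broken toward the lowest class index. For the cumulative logistic link
#' this coincides with reading off the segment of the latent axis that
#' `w'x` falls into, so predictions are monotone non-decreasing in `w'x`.
#'
#' @param object an [ordinal_model()].
#' @param newdata numeric vector of length `D` or `N x D` matrix.
#' @param type `"class"` for integer labels in `{1..C}`, `"prob"` for the
#'   probability matrix, `"link"` for the latent value `w'x`.
#' @param ... unused.
#' @return integer labels, a probability matrix, or latent values.
#' @export
predict.ordinal_model <- function(object, newdata, type = c("class", "prob", "link"), ...) {
  type <- match.arg(type)
  if (type == "link") return(decision_value(object, newdata))
  P <- class_probabilities(object, newdata)
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  if (type == "prob") return(P)
  as.integer(max.col(P, ties.method = "first"))
}

#' Construct a labeled ordinal dataset
#'
#' Bundles an `N x D` feature matrix with integer labels in `{1..C}` and
#' the derived 1-of-K indicator matrix `Y` (`y_nc = 1` iff sample `n` has
#' label `c`).
#'
#' @param features numeric `N x D` matrix (no missing values).
#' @param labels integer vector of length `N`, values in `{1..n_classes}`.
#' @param n_classes number of ordered classes `C`; defaults to
#'   `max(labels)`.
#' @return an object of class `labeled_dataset` with fields `features`,
#'   `labels`, `indicator`, `n_classes`, `n_samples`, `n_features`.
#' @export
labeled_dataset <- function(features, labels, n_classes = max(labels)) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (anyNA(features)) {
    bad <- which(rowSums(is.na(features)) > 0)[1]
    stop(sprintf("missing value in features (first offending row: %d)", bad))
  }
  if (length(labels) != nrow(features))
    stop(sprintf("row count mismatch: %d feature rows vs %d labels",
                 nrow(features), length(labels)))
  if (any(labels != round(labels)))
    stop("labels must be integers")
  labels <- as.integer(labels)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("need at least 2 classes")
  if (any(labels < 1L | labels > n_classes)) {
    bad <- which(labels < 1L | labels > n_classes)[1]
    stop(sprintf("label out of range {1..%d} at row %d (value %d)",
                 n_classes, bad, labels[bad]))
  }
  Y <- matrix(0L, nrow(features), n_classes)
  Y[cbind(seq_along(labels), labels)] <- 1L
  structure(
    list(features = features,
         labels = labels,
         indicator = Y,
         n_classes = n_classes,
         n_samples = nrow(features),
         n_features = ncol(features)),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled ordinal dataset: N = %d, D = %d, C = %d\n",
              x$n_samples, x$n_features, x$n_classes))
  cat("  class counts:", tabulate(x$labels, x$n_classes), "\n")
  invisible(x)
}
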