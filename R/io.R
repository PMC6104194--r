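#' Read a labeled dataset from delimited text
#'
#' Features are read from a CSV with a header row (`N x D` numeric);
#' labels from a single-column CSV (header optional) of integers in
#' `{1..n_classes}`. Validation errors name the offending row.
#'
#' @param features_path path to the feature CSV.
#' @param labels_path path to the label CSV.
#' @param n_classes number of classes; defaults to the maximum label.
#' @return a [labeled_dataset()].
#' @export
read_dataset <- function(features_path, labels_path, n_classes = NULL) {
  feat <- utils::read.csv(features_path, header = TRUE)
  X <- as.matrix(feat)
  if (!is.numeric(X)) {
    bad <- which(!vapply(feat, is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric feature column '%s' in %s",
                 names(feat)[bad], features_path))
  }
  lab <- utils::read.csv(labels_path, header = TRUE)[[1]]
  if (length(lab) != nrow(X))
    stop(sprintf("row count mismatch: %d feature rows vs %d labels",
                 nrow(X), length(lab)))
  labeled_dataset(X, lab,
                  n_classes = if (is.null(n_classes)) max(lab) else n_classes)
}

#' Write a labeled dataset as delimited text
#'
#' Inverse of [read_dataset()]; round-trips exactly.
#'
#' @param data a [labeled_dataset()].
#' @param features_path,labels_path output CSV paths.
#' @return invisibly, `data`.
#' @export
write_dataset <- function(data, features_path, labels_path) {
  stopifnot(inherits(data, "labeled_dataset"))
  X <- data$features
  colnames(X) <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  utils::write.csv(as.data.frame(X), features_path, row.names = FALSE)
  utils::write.csv(data.frame(label = data$labels), labels_path,
                   row.names = FALSE)
  invisible(data)
}

.MODEL_FORMAT <- "sparseolr-model"
.MODEL_VERSION <- 1L

#' Serialize a model or fit to structured text (JSON)
#'
#' Writes a version-tagged JSON document with full double precision, so a
#' write/read round trip reproduces predictions bitwise. Accepts an
#' [ordinal_model()] or any fit object produced by this package
#' ([fit_solr()], [fit_l2olr()], [fit_elasticnet_olr()], [fit_slir()],
#' [fit_smlr()]); for fits the relevance state, objective trace and
#' selected features are included for audit.
#'
#' @param object model or fit object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_model <- function(object, path) {
  doc <- list(format = .MODEL_FORMAT, version = .MODEL_VERSION)
  if (inherits(object, "ordinal_model")) {
    doc$kind <- "ordinal_model"
    doc$model <- .model_payload(object)
  } else if (inherits(object, "olr_fit")) {
    doc$kind <- class(object)[1]
    doc$model <- .model_payload(object$model)
    if (!is.null(object$relevance)) {
      doc$relevance <- object$relevance
      doc$selected_features <- selected_features(object)
    }
    doc$alpha <- object$alpha
    doc$lambda_l1 <- object$lambda_l1
    doc$lambda_l2 <- object$lambda_l2
    doc$n_iterations <- object$n_iterations
    doc$converged <- object$converged
    doc$objective_trace <- object$objective_trace
  } else if (inherits(object, "slir_fit")) {
    doc$kind <- "slir_fit"
    doc[c("weights", "intercept", "noise_precision", "relevance",
          "n_iterations", "converged", "n_classes")] <-
      object[c("weights", "intercept", "noise_precision", "relevance",
               "n_iterations", "converged", "n_classes")]
  } else if (inherits(object, "smlr_fit")) {
    doc$kind <- "smlr_fit"
    doc[c("weight_matrix", "intercepts", "alpha", "posterior_var", "pruned",
          "n_iterations", "converged", "n_classes")] <-
      object[c("weight_matrix", "intercepts", "alpha", "posterior_var",
               "pruned", "n_iterations", "converged", "n_classes")]
  } else {
    stop("unsupported object type for write_model()")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

.model_payload <- function(model) {
  list(weights = model$weights, thresholds = model$thresholds,
       n_classes = model$n_classes, n_features = model$n_features,
       metadata = model$metadata)
}

#' Read a serialized model or fit
#'
#' Validates the format tag, version and model invariants (strictly
#' increasing thresholds) at load time.
#'
#' @param path path written by [write_model()].
#' @return the deserialized object (class restored).
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || !identical(doc$format, .MODEL_FORMAT))
    stop("not a sparseolr model file (missing or wrong format tag)")
  if (is.null(doc$version) || doc$version != .MODEL_VERSION)
    stop(sprintf("unsupported model file version '%s'", doc$version))
  if (is.null(doc$kind)) stop("model file missing 'kind' metadata")
  rebuild_model <- function(m) {
    if (is.null(m$weights) || is.null(m$thresholds))
      stop("model file missing weights/thresholds")
    ordinal_model(m$weights, m$thresholds,
                  metadata = as.list(m$metadata))
  }
  switch(doc$kind,
    ordinal_model = rebuild_model(doc$model),
    solr_fit = ,
    l2olr_fit = ,
    enet_fit = {
      out <- list(model = rebuild_model(doc$model),
                  relevance = doc$relevance,
                  alpha = doc$alpha,
                  lambda_l1 = doc$lambda_l1, lambda_l2 = doc$lambda_l2,
                  n_iterations = doc$n_iterations,
                  converged = doc$converged,
                  objective_trace = doc$objective_trace)
      class(out) <- c(doc$kind, "olr_fit")
      out
    },
    slir_fit = {
      out <- doc[c("weights", "intercept", "noise_precision", "relevance",
                   "n_iterations", "converged", "n_classes")]
      class(out) <- "slir_fit"
      out
    },
    smlr_fit = {
      out <- doc[c("weight_matrix", "intercepts", "alpha", "posterior_var",
                   "pruned", "n_iterations", "converged", "n_classes")]
      out$weight_matrix <- as.matrix(out$weight_matrix)
      out$pruned <- as.matrix(out$pruned)
      class(out) <- "smlr_fit"
      out
    },
    stop(sprintf("unknown model kind '%s'", doc$kind)))
}
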