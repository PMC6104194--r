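test_that("SLiR recovers an exact linear relation and prunes the rest", {
  set.seed(2)
  y <- rep(1:5, each = 20)
  X <- cbind((y - 2) / 3, matrix(stats::rnorm(100 * 4), 100, 4))
  fit <- fit_slir(labeled_dataset(X, y, 5))
  expect_equal(fit$weights[1], 3, tolerance = 1e-6)
  expect_identical(fit$weights[2:5], rep(0, 4))
  expect_equal(fit$intercept + X[1, ] %*% fit$weights, matrix(y[1]),
               tolerance = 1e-6)
})

test_that("SLiR on a constant response prunes everything to the intercept", {
  X <- matrix(stats::rnorm(60), 30, 2)
  fit <- fit_slir(labeled_dataset(X, rep(2, 30), n_classes = 3))
  expect_identical(fit$weights, rep(0, 2))
  expect_equal(fit$intercept, 2)
})

test_that("SLiR continuous outputs map to nearest labels with the midpoint rule", {
  fake <- structure(list(weights = 1, intercept = 0, n_classes = 5),
                    class = "slir_fit")
  expect_identical(predict_slir_ordinal(fake, matrix(c(2.4, 7.3, 2.5, 0.2))),
                   c(2L, 5L, 2L, 1L))
  expect_identical(predict_slir_ordinal(fake, matrix(c(1.5, 4.5))), c(1L, 4L))
})

test_that("two-class SMLR and SOLR agree on well-separated data", {
  set.seed(6)
  y <- rep(1:2, each = 50)
  x <- matrix(y + stats::rnorm(100, sd = 0.3), ncol = 1)
  d <- labeled_dataset(x, y, 2)
  xt <- matrix(rep(1:2, each = 100) + stats::rnorm(200, sd = 0.3), ncol = 1)
  fs <- fit_solr(d)
  fm <- fit_smlr(d)
  expect_gte(mean(predict(fs, xt) == predict(fm, xt)), 0.98)
})

test_that("SMLR ignores class order where SOLR depends on it", {
  sim <- sim_draw(17, n_features = 40, n_train = 150, n_test = 500,
                  noise_sd = 2)
  perm <- c(3, 5, 1, 4, 2)
  tr_p <- labeled_dataset(sim$train$features, perm[sim$train$labels], 5)
  te_lab_p <- perm[sim$test$labels]
  acc <- function(pred, truth) mean(pred == truth)
  sm_o <- acc(predict(fit_smlr(sim$train), sim$test$features), sim$test$labels)
  sm_p <- acc(predict(fit_smlr(tr_p), sim$test$features), te_lab_p)
  so_o <- acc(predict(fit_solr(sim$train), sim$test$features), sim$test$labels)
  so_p <- acc(predict(fit_solr(tr_p), sim$test$features), te_lab_p)
  expect_lt(abs(sm_p - sm_o), 0.08)        # label permutation leaves SMLR alone
  expect_lt(so_p, so_o - 0.1)              # ... but breaks the ordinal model
})

test_that("SMLR is sparse in its weight entries and has free boundaries", {
  sim <- sim_draw(29, n_features = 150, n_train = 100, n_test = 10)
  fit <- fit_smlr(sim$train)
  expect_lt(sum(fit$weight_matrix != 0), 150 * 5)
  expect_gt(sum(fit$weight_matrix != 0), 0)
  # per-class weight vectors are generically non-parallel (unlike OLR, whose
  # between-class boundaries all share the single normal vector w)
  w1 <- fit$weight_matrix[, 1]; w2 <- fit$weight_matrix[, 2]
  cosang <- sum(w1 * w2) / sqrt(sum(w1^2) * sum(w2^2))
  expect_lt(abs(cosang), 0.999)
})

test_that("unpenalized elastic-net OLR matches the maximum-likelihood fit", {
  skip_if_not_installed("MASS")
  sim <- sim_draw(41, n_features = 4, n_train = 300, n_test = 10,
                  n_informative = 4)
  fit <- fit_elasticnet_olr(sim$train, elasticnet_options(0, 0))
  df <- data.frame(y = factor(sim$train$labels, ordered = TRUE),
                   sim$train$features)
  polr_fit <- MASS::polr(y ~ ., data = df, method = "logistic")
  expect_equal(unname(fit$model$weights), unname(coef(polr_fit)),
               tolerance = 0.01)
  expect_equal(unname(fit$model$thresholds), unname(polr_fit$zeta),
               tolerance = 0.01)
})

test_that("a huge L1 penalty empties the weights and leaves quantile thresholds", {
  sim <- sim_draw(43, n_features = 10, n_train = 200, n_test = 10)
  fit <- fit_elasticnet_olr(sim$train, elasticnet_options(1e6, 0))
  expect_identical(fit$model$weights, rep(0, 10))
  cf <- cumsum(tabulate(sim$train$labels, 5)) / 200
  expect_equal(fit$model$thresholds, stats::qlogis(cf[1:4]), tolerance = 0.02)
})

test_that("elastic-net sparsity grows with the L1 penalty and the path is smooth", {
  sim <- sim_draw(47, n_features = 50, n_train = 150, n_test = 300)
  lams <- c(0.5, 2, 8, 32)
  fits <- lapply(lams, function(l1)
    fit_elasticnet_olr(sim$train, elasticnet_options(l1, 1)))
  nz <- vapply(fits, function(f) sum(f$model$weights != 0), numeric(1))
  expect_true(all(diff(nz) <= 0))
  preds <- vapply(fits, function(f) predict(f, sim$test$features),
                  integer(nrow(sim$test$features)))
  flips <- vapply(1:3, function(i) mean(preds[, i] != preds[, i + 1]),
                  numeric(1))
  expect_true(all(flips < 0.25))
})

test_that("all baseline predictions stay inside the label range", {
  sim <- sim_draw(53, n_features = 20, n_train = 100, n_test = 200)
  for (alg in c("slir", "smlr", "l2olr")) {
    fit <- sparseolr:::.fit_algorithm(alg, sim$train)
    pred <- sparseolr:::.predict_labels(fit, sim$test$features)
    expect_true(all(pred %in% 1:5))
  }
})
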