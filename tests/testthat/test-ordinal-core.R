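test_that("sigmoid matches the logistic CDF and its limits", {
  expect_identical(sigmoid(0), 0.5)
  expect_identical(sigmoid(Inf), 1)
  expect_identical(sigmoid(-Inf), 0)
  expect_equal(sigmoid(2), 1 / (1 + exp(-2)), tolerance = 1e-15)
  z <- seq(-10, 10, by = 0.37)
  expect_true(all(diff(sigmoid(z)) > 0))
  expect_equal(sigmoid(-z), 1 - sigmoid(z), tolerance = 1e-15)
})

test_that("class probabilities telescope to one and match the worked case", {
  m2 <- ordinal_model(rep(0, 3), 0)
  expect_equal(unname(class_probabilities(m2, rep(1, 3))), c(0.5, 0.5))
  # C = 3, mu = (-1, 1), w'x = 0: F(-1), F(1) - F(-1), 1 - F(1)
  m3 <- ordinal_model(rep(0, 2), c(-1, 1))
  expect_equal(unname(class_probabilities(m3, c(3, -2))),
               c(0.2689414213699951, 0.4621171572600098, 0.2689414213699951),
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:1000) {
    D <- sample(1:6, 1); C <- sample(2:6, 1)
    m <- rand_model(D, C)
    p <- class_probabilities(m, stats::rnorm(D, sd = 2))
    expect_true(all(p >= 0))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
})

test_that("non-increasing thresholds are rejected", {
  expect_error(ordinal_model(1, c(1, 0)), "strictly increasing")
  m <- ordinal_model(c(1, 1), c(-1, 1))
  m$thresholds <- c(1, -1)          # corrupt past the constructor
  expect_error(class_probabilities(m, c(0, 0)), "strictly increasing")
})

test_that("two-class models reduce to binary logistic regression", {
  set.seed(7)
  for (i in 1:20) {
    m <- rand_model(3, 2)
    x <- stats::rnorm(3)
    p <- class_probabilities(m, x)
    expect_equal(unname(p[2]),
                 sigmoid(sum(m$weights * x) - m$thresholds[1]),
                 tolerance = 1e-12)
  }
})

test_that("log likelihood sums per-sample log class probabilities", {
  d1 <- labeled_dataset(matrix(0, 1, 2), 1, n_classes = 2)
  m1 <- ordinal_model(rep(0, 2), 0)
  expect_equal(log_likelihood(m1, d1), log(0.5), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:10) {
    N <- sample(3:15, 1); D <- sample(1:4, 1); C <- sample(2:5, 1)
    d <- rand_dataset(N, D, C)
    m <- rand_model(D, C)
    brute <- sum(vapply(seq_len(N), function(n)
      log(class_probabilities(m, d$features[n, ])[d$labels[n]]), numeric(1)))
    expect_equal(log_likelihood(m, d), brute, tolerance = 1e-10)
    expect_lte(log_likelihood(m, d), 0)
    dd <- labeled_dataset(d$features[rep(seq_len(N), 2), ], rep(d$labels, 2), C)
    expect_equal(log_likelihood(m, dd), 2 * log_likelihood(m, d),
                 tolerance = 1e-10)
  }
})

test_that("log likelihood stays finite when a class probability underflows", {
  m <- ordinal_model(100, c(-5, 5))
  d <- labeled_dataset(matrix(10, 1, 1), 1, n_classes = 3)   # p_1 ~ 0
  ll <- log_likelihood(m, d)
  expect_true(is.finite(ll))
  expect_lt(ll, -500)
})

test_that("analytic gradients match central finite differences", {
  set.seed(23)
  for (i in 1:50) {
    N <- sample(5:20, 1); D <- sample(1:5, 1); C <- sample(2:5, 1)
    d <- rand_dataset(N, D, C)
    m <- rand_model(D, C)
    g <- log_likelihood_gradient(m, d)
    fd <- fd_gradient(m, d)
    expect_equal(g$weights, fd$weights,
                 tolerance = 1e-6)
    expect_equal(g$thresholds, fd$thresholds,
                 tolerance = 1e-6)
  }
})

test_that("threshold gradient vanishes at a symmetric balanced two-class set", {
  X <- matrix(c(1, -1), 2, 1)
  d <- labeled_dataset(X, c(2, 1), n_classes = 2)
  m <- ordinal_model(0, 0)
  g <- log_likelihood_gradient(m, d)
  expect_equal(g$thresholds, 0, tolerance = 1e-12)
})

test_that("prediction is the argmax rule with low-index tie-breaking", {
  m3 <- ordinal_model(c(1, 0), c(-1, 1))
  expect_identical(predict(m3, c(0, 5)), 2L)          # w'x = 0 -> middle class
  expect_identical(predict(m3, c(50, 0)), 3L)         # latent -> +inf
  expect_identical(predict(m3, c(-50, 0)), 1L)        # latent -> -inf
  # ties: C = 2 at z = mu gives (0.5, 0.5); lowest class index wins
  expect_identical(predict(ordinal_model(1, 0), 0), 1L)
  # monotone in the latent value; matches the threshold-segment rule away
  # from the thresholds (near a threshold the argmax switch point shifts
  # inside a finite segment; the two rules coincide only in the wide-gap
  # limit, exactly so for C = 2)
  set.seed(5)
  for (i in 1:20) {
    C <- sample(3:6, 1)
    mu <- cumsum(c(stats::rnorm(1), stats::runif(C - 2, 2, 4)))
    m <- ordinal_model(1, mu)
    z <- seq(min(mu) - 4, max(mu) + 4, length.out = 201)
    cls <- predict(m, matrix(z))
    expect_true(all(diff(cls) >= 0))
    seg <- findInterval(z, mu) + 1L
    far <- apply(abs(outer(z, mu, `-`)), 1, min) >= 0.5
    expect_equal(cls[far], seg[far])
  }
  m2 <- ordinal_model(1, 0.7)
  z <- seq(-3, 3, length.out = 101)
  expect_equal(predict(m2, matrix(z)), findInterval(z, 0.7) + 1L)
})

test_that("decision value is the linear predictor", {
  m <- ordinal_model(c(0, 0, 0), 0)
  expect_equal(decision_value(m, c(5, -2, 1)), 0)
  e2 <- ordinal_model(c(0, 1, 0), 0)
  expect_equal(decision_value(e2, c(5, -2, 1)), -2)
  m2 <- ordinal_model(2 * c(0.3, -1, 2), 0)
  expect_equal(decision_value(m2, c(1, 2, 3)),
               2 * decision_value(ordinal_model(c(0.3, -1, 2), 0), c(1, 2, 3)))
  expect_error(decision_value(m, c(1, 2)), "dimension mismatch")
})

test_that("labeled datasets validate labels and build the 1-of-K indicator", {
  d <- labeled_dataset(matrix(1:12, 4, 3), c(1, 2, 2, 3))
  expect_equal(rowSums(d$indicator), rep(1, 4))
  expect_true(all(d$indicator[cbind(1:4, d$labels)] == 1L))
  expect_error(labeled_dataset(matrix(1:4, 2, 2), c(0, 1), n_classes = 2),
               "row 1")
  expect_error(labeled_dataset(matrix(1:4, 2, 2), c(1, 7), n_classes = 3),
               "out of range")
  expect_error(labeled_dataset(matrix(c(1, NA, 3, 4), 2, 2), c(1, 2)),
               "missing value")
  expect_error(labeled_dataset(matrix(1:6, 3, 2), c(1, 2)), "mismatch")
})
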