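test_that("basis enumeration reproduces the per-shape placement counts", {
  expect_equal(nrow(enumerate_bases("1x1")), 100)
  expect_equal(nrow(enumerate_bases("1x2")), 90)
  expect_equal(nrow(enumerate_bases("2x1")), 90)
  expect_equal(nrow(enumerate_bases("2x2")), 81)
  all4 <- enumerate_bases()
  expect_equal(nrow(all4), 361)
  expect_equal(unname(table(all4$shape)[c("1x1", "1x2", "2x1", "2x2")]),
               c(100L, 90L, 90L, 81L), ignore_attr = TRUE)
  # row-major order from the 0-based top-left corner, all in-grid
  b22 <- enumerate_bases("2x2")
  expect_equal(b22[1, c("row", "col")], data.frame(row = 0L, col = 0L),
               ignore_attr = TRUE)
  expect_true(all(b22$row + b22$height <= 10 & b22$col + b22$width <= 10))
  expect_true(!is.unsorted(b22$row * 10 + b22$col))
})

test_that("binary patterns collapse to the mean-contrast label cardinalities", {
  img <- matrix(0, 10, 10)
  # 2x2 patch with pixels (1,1,0,0): mean 1/2 -> class 3 of 5
  img[1, 1] <- 1; img[1, 2] <- 1
  b <- list(shape = "2x2", row = 0L, col = 0L, height = 2L, width = 2L)
  expect_identical(mean_contrast_label(img, b), 3L)
  expect_identical(mean_contrast_label(matrix(0, 10, 10), b), 1L)
  # all 16 patterns of a 2x2 patch -> 5 classes; all 4 of a 1x2 -> 3 classes
  pat22 <- expand.grid(rep(list(0:1), 4))
  lab22 <- apply(pat22, 1, function(p) {
    im <- matrix(0, 10, 10); im[1:2, 1:2] <- matrix(p, 2, 2)
    mean_contrast_label(im, b)
  })
  expect_equal(nrow(pat22), 16L)
  expect_setequal(lab22, 1:5)
  b12 <- list(shape = "1x2", row = 0L, col = 0L, height = 1L, width = 2L)
  pat12 <- expand.grid(rep(list(0:1), 2))
  lab12 <- apply(pat12, 1, function(p) {
    im <- matrix(0, 10, 10); im[1, 1:2] <- p
    mean_contrast_label(im, b12)
  })
  expect_equal(nrow(pat12), 4L)
  expect_setequal(lab12, 1:3)
  expect_identical(vapply(c("1x1", "1x2", "2x1", "2x2"), contrast_levels,
                          integer(1), USE.NAMES = FALSE),
                   c(2L, 3L, 3L, 5L))
})

test_that("synthetic sessions are seeded and the identity configuration is exact", {
  s1 <- generate_synthetic_session(voxel_config(n_voxels = 20, seed = 4), 15)
  s2 <- generate_synthetic_session(voxel_config(n_voxels = 20, seed = 4), 15)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$images, s2$images)
  ident <- identity_session(10, seed = 2)
  expect_identical(ident$responses, ident$images + 0)
})

test_that("voxel responses increase monotonically but sublinearly with mean contrast", {
  ses <- generate_synthetic_session(
    voxel_config(n_voxels = 60, noise_sd = 0.02, seed = 10), 4000)
  b <- list(shape = "2x2", row = 4L, col = 4L, height = 2L, width = 2L)
  labels <- apply(ses$images, 1, mean_contrast_label, basis = b)
  # voxel with the strongest receptive-field overlap with the basis region
  overlap <- rowSums(ses$rf_weights[, sparseolr:::.basis_pixels(b)])
  v <- which.max(overlap)
  lv <- tapply(ses$responses[, v], labels, mean)
  expect_true(all(diff(lv) > 0))
  # saturating gain: increments between successive levels shrink
  expect_lt(diff(lv)[4], diff(lv)[1])
})

test_that("stratified folds are balanced within labels and reproducible", {
  labels <- rep(c(1, 1, 1, 2, 2), 12)
  f1 <- sparseolr:::.stratified_folds(labels, 5, seed = 3)
  f2 <- sparseolr:::.stratified_folds(labels, 5, seed = 3)
  expect_identical(f1, f2)
  for (lv in 1:2) {
    counts <- tabulate(f1[labels == lv], 5)
    expect_lte(diff(range(counts)), 1)
  }
})

test_that("reconstruction identities hold for unit configurations", {
  bases <- enumerate_bases("1x1")
  W <- diag(100)
  img <- matrix(stats::rbinom(100, 1, 0.5), 10, 10)
  contrasts <- as.vector(t(img))
  expect_equal(reconstruct_image(contrasts, bases, W), img + 0)
  expect_equal(reconstruct_image(rep(0, 100), bases, W), matrix(0, 10, 10))
})

test_that("spatial correlation is plain Pearson over the 100 pixels", {
  img <- matrix(stats::rbinom(100, 1, 0.5), 10, 10)
  expect_equal(image_spatial_correlation(img, img), 1)
  expect_equal(image_spatial_correlation(1 - img, img), -1)
  set.seed(9)
  rec <- matrix(stats::rnorm(100), 10, 10)
  a <- as.vector(t(rec)); b <- as.vector(t(img))
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(image_spatial_correlation(rec, img), oracle, tolerance = 1e-12)
  expect_true(is.na(image_spatial_correlation(matrix(1, 10, 10), img)))
})

test_that("local decoders score perfectly on a noiseless identity session", {
  ses <- identity_session(40, seed = 6)
  bases <- enumerate_bases("1x1")[c(1, 34, 77), ]
  dec <- train_local_decoders(ses, bases, "solr", n_folds = 5, seed = 1)
  expect_equal(dec$scores$spearman, rep(1, 15))
  expect_equal(dec$predicted_contrasts, dec$true_contrasts)
})

test_that("constant-label bases are recorded as undecodable, not scored", {
  ses <- identity_session(30, seed = 8)
  ses$images[, 5] <- 0L
  ses$responses[, 5] <- 0
  bases <- enumerate_bases("1x1")[5, ]
  dec <- train_local_decoders(ses, bases, "solr", n_folds = 5, seed = 1)
  expect_true(all(is.na(dec$scores$spearman)))
})

test_that("pure-noise sessions decode at chance", {
  ses <- generate_synthetic_session(
    voxel_config(n_voxels = 30, noise_sd = 25, seed = 12), 60)
  bases <- enumerate_bases("2x2")[c(10, 40), ]
  dec <- train_local_decoders(ses, bases, "solr", n_folds = 5, seed = 2)
  expect_lt(abs(mean(dec$scores$spearman, na.rm = TRUE)), 0.3)
})
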