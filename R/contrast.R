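#' Enumerate local image bases on the 10 x 10 grid
#'
#' All in-grid placements of the rectangular basis shapes, addressed by
#' their 0-based top-left corner and listed shape by shape in row-major
#' order. Over the full 10 x 10 grid the four shapes yield 100 (1x1),
#' 90 (1x2), 90 (2x1) and 81 (2x2) bases, 361 in total.
#'
#' @param shapes subset of `c("1x1", "1x2", "2x1", "2x2")` (rows x cols).
#' @param grid_size side length of the square pixel grid (default 10).
#' @return a data.frame with columns `shape`, `row`, `col` (0-based
#'   top-left corner), `height`, `width`.
#' @export
enumerate_bases <- function(shapes = c("1x1", "1x2", "2x1", "2x2"),
                            grid_size = 10L) {
  shapes <- match.arg(shapes, several.ok = TRUE)
  out <- lapply(shapes, function(s) {
    hw <- as.integer(strsplit(s, "x")[[1]])
    g <- expand.grid(col = 0:(grid_size - hw[2]), row = 0:(grid_size - hw[1]))
    data.frame(shape = s, row = g$row, col = g$col,
               height = hw[1], width = hw[2])
  })
  do.call(rbind, out)
}

.basis_pixels <- function(basis, grid_size = 10L) {
  # linear (column-major over the row-major grid? keep explicit): pixel
  # index p = row * grid_size + col + 1, row-major.
  rows <- basis$row + seq_len(basis$height) - 1L
  cols <- basis$col + seq_len(basis$width) - 1L
  as.vector(outer(cols, rows, function(cc, rr) rr * grid_size + cc + 1L))
}

#' Ordinal mean-contrast label of an image under a basis
#'
#' The mean of the binary pixels inside the basis region takes
#' `height * width + 1` equally spaced values; the label is the 1-based
#' index of that value. A 1x1 basis therefore has 2 classes, 1x2/2x1 have
#' 3, and 2x2 has 5 (its 16 binary patterns collapse to 5 mean-contrast
#' levels).
#'
#' @param image a 10 x 10 matrix with entries in `{0, 1}` (1 = flickering
#'   checkerboard patch), or a length-100 row-major pixel vector.
#' @param basis one row of [enumerate_bases()] (data.frame or list).
#' @return integer class label in `{1 .. height*width + 1}`.
#' @export
mean_contrast_label <- function(image, basis) {
  px <- .image_vector(image)
  idx <- .basis_pixels(as.list(basis))
  npix <- basis$height * basis$width
  as.integer(round(mean(px[idx]) * npix)) + 1L
}

#' Number of mean-contrast classes of a basis shape
#' @param shape one of `"1x1"`, `"1x2"`, `"2x1"`, `"2x2"`.
#' @return integer class count (2, 3, 3 or 5).
#' @export
contrast_levels <- function(shape) {
  hw <- as.integer(strsplit(shape, "x")[[1]])
  hw[1] * hw[2] + 1L
}

.image_vector <- function(image) {
  if (is.matrix(image)) {
    stopifnot(nrow(image) == 10L, ncol(image) == 10L)
    as.vector(t(image))          # row-major
  } else {
    stopifnot(length(image) == 100L)
    as.vector(image)
  }
}

#' Synthetic voxel-response generator configuration
#'
#' Emulates a population of visually responsive voxels observing the
#' 10 x 10 binary stimulus grid: each voxel pools the pixels through a
#' Gaussian receptive field (RF), passes the pooled drive through a
#' monotone saturating gain, and adds Gaussian measurement noise. The
#' saturating gain makes the response increase monotonically with, but
#' not proportionally to, the local mean contrast. Voxels whose RF center
#' lies in the left half of the grid are tagged hemisphere `"R"` and vice
#' versa (contralateral mapping); the tag is metadata only.
#'
#' @param n_voxels number of voxels (default 200).
#' @param rf_sd Gaussian RF standard deviation in pixels (default 1.2);
#'   RF weights are normalized to sum to 1. `rf_type = "delta"` instead
#'   assigns voxel `v` a point RF on pixel `v` (requires
#'   `n_voxels = 100`), which together with `gain = identity` and
#'   `noise_sd = 0` is the identity configuration whose responses equal
#'   the pixel values.
#' @param rf_type `"gaussian"` or `"delta"`.
#' @param gain monotone non-decreasing gain function; the default
#'   `u / (1 + u / 2)` saturates at high drive.
#' @param noise_sd response noise standard deviation (default 0.15, about
#'   one signal SD for the best-placed voxels).
#' @param seed integer seed used when the session is generated.
#' @return a list of class `voxel_config`.
#' @export
voxel_config <- function(n_voxels = 200L, rf_sd = 1.2,
                         rf_type = c("gaussian", "delta"),
                         gain = function(u) u / (1 + u / 2),
                         noise_sd = 0.15, seed = 1L) {
  rf_type <- match.arg(rf_type)
  if (rf_type == "delta" && n_voxels != 100L)
    stop("delta receptive fields require n_voxels = 100 (one per pixel)")
  stopifnot(noise_sd >= 0, rf_sd > 0)
  structure(list(n_voxels = as.integer(n_voxels), rf_sd = rf_sd,
                 rf_type = rf_type, gain = gain, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "voxel_config")
}

#' Generate a synthetic decoding session
#'
#' Draws `n_images` random binary stimulus images (iid Bernoulli(1/2)
#' pixels) and the corresponding voxel responses under a [voxel_config()].
#' The generator parameters (RF centers, weights, hemisphere tags) are
#' returned so that ground-truth audits are possible.
#'
#' @param config a [voxel_config()].
#' @param n_images number of stimulus presentations.
#' @return a list of class `contrast_session`: `images`
#'   (`n_images x 100` row-major binary matrix), `responses`
#'   (`n_images x n_voxels`), `rf_centers` (`n_voxels x 2`, (row, col) in
#'   pixel units), `rf_weights` (`n_voxels x 100`), `hemisphere`, `config`.
#' @export
generate_synthetic_session <- function(config, n_images) {
  stopifnot(inherits(config, "voxel_config"), n_images >= 1)
  set.seed(config$seed)
  V <- config$n_voxels
  images <- matrix(stats::rbinom(n_images * 100L, 1L, 0.5), n_images, 100L)
  # pixel centers (row-major): pixel p at row (p-1) %/% 10, col (p-1) %% 10
  prow <- (seq_len(100L) - 1L) %/% 10L + 0.5
  pcol <- (seq_len(100L) - 1L) %% 10L + 0.5
  if (config$rf_type == "delta") {
    centers <- cbind(prow, pcol)
    W <- diag(100L)
  } else {
    centers <- cbind(stats::runif(V, 0, 10), stats::runif(V, 0, 10))
    W <- matrix(0, V, 100L)
    for (v in seq_len(V)) {
      d2 <- (prow - centers[v, 1])^2 + (pcol - centers[v, 2])^2
      wv <- exp(-d2 / (2 * config$rf_sd^2))
      W[v, ] <- wv / sum(wv)
    }
  }
  drive <- images %*% t(W)
  responses <- config$gain(drive) +
    matrix(stats::rnorm(n_images * V, sd = config$noise_sd), n_images, V)
  hemisphere <- ifelse(centers[, 2] < 5, "R", "L")
  structure(list(images = images, responses = responses,
                 rf_centers = centers, rf_weights = W,
                 hemisphere = hemisphere, config = config),
            class = "contrast_session")
}

#' Identity-configuration session
#'
#' Noiseless session in which the 100 voxel responses equal the 100 pixel
#' values exactly (delta receptive fields, identity gain, zero noise).
#' Decoding such a session is an end-to-end oracle check: every local
#' contrast is perfectly recoverable.
#'
#' @param n_images number of stimulus presentations.
#' @param seed integer seed for the random images.
#' @return a `contrast_session`.
#' @export
identity_session <- function(n_images, seed = 1L) {
  generate_synthetic_session(
    voxel_config(n_voxels = 100L, rf_type = "delta", gain = identity,
                 noise_sd = 0, seed = seed),
    n_images)
}

# Label-stratified fold assignment, seeded; every label value is spread
# as evenly as possible across folds.
.stratified_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Train per-basis local decoders with cross-validation
#'
#' For every image basis, derives the ordinal mean-contrast labels of the
#' session images, then runs seeded label-stratified k-fold
#' cross-validation (default five folds) with the chosen algorithm on the
#' voxel responses. Per-fold Spearman scores and out-of-fold contrast
#' predictions (class mapped back to its mean-contrast value) are
#' returned; the predictions feed [reconstruct_image()]. A basis whose
#' labels are constant across the whole session cannot be decoded and is
#' recorded with `NA` scores.
#'
#' @param session a `contrast_session`.
#' @param bases data.frame from [enumerate_bases()].
#' @param algorithm one of `"solr"`, `"l2olr"`, `"slir"`, `"smlr"`.
#' @param options [fit_options()] shared by all fits.
#' @param n_folds number of cross-validation folds (default 5).
#' @param seed seed for the fold assignment.
#' @return a list of class `local_decoding`: `scores` (data.frame basis,
#'   shape, row, col, fold, spearman), `predicted_contrasts`
#'   (`n_images x n_bases`, out-of-fold), `true_contrasts`, `bases`,
#'   `algorithm`.
#' @export
train_local_decoders <- function(session, bases, algorithm = "solr",
                                 options = fit_options(), n_folds = 5L,
                                 seed = 1L) {
  stopifnot(inherits(session, "contrast_session"))
  n_images <- nrow(session$images)
  B <- nrow(bases)
  pred_contrast <- matrix(NA_real_, n_images, B)
  true_contrast <- matrix(NA_real_, n_images, B)
  score_rows <- vector("list", B)
  for (b in seq_len(B)) {
    basis <- bases[b, ]
    C <- contrast_levels(basis$shape)
    labels <- apply(session$images, 1L, mean_contrast_label, basis = basis)
    true_contrast[, b] <- (labels - 1) / (C - 1)
    if (length(unique(labels)) < 2L) {
      score_rows[[b]] <- data.frame(basis = b, shape = basis$shape,
                                    row = basis$row, col = basis$col,
                                    fold = seq_len(n_folds),
                                    spearman = NA_real_)
      next
    }
    fold <- .stratified_folds(labels, n_folds, seed + b)
    rho <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr_idx <- fold != f
      train <- labeled_dataset(session$responses[tr_idx, , drop = FALSE],
                               labels[tr_idx], n_classes = C)
      fit <- .fit_algorithm(algorithm, train, options)
      yhat <- .predict_labels(fit, session$responses[!tr_idx, , drop = FALSE])
      pred_contrast[!tr_idx, b] <- (yhat - 1) / (C - 1)
      rho[f] <- spearman(labels[!tr_idx], yhat)
    }
    score_rows[[b]] <- data.frame(basis = b, shape = basis$shape,
                                  row = basis$row, col = basis$col,
                                  fold = seq_len(n_folds), spearman = rho)
  }
  structure(list(scores = do.call(rbind, score_rows),
                 predicted_contrasts = pred_contrast,
                 true_contrasts = true_contrast,
                 bases = bases, algorithm = algorithm),
            class = "local_decoding")
}

#' Learn basis-combination weights by per-pixel least squares
#'
#' Regresses each training-image pixel on the true contrast values of the
#' bases covering that pixel (ridge-stabilized with 1e-6 on the normal
#' equations). The resulting `n_bases x 100` weight matrix is zero wherever
#' a basis does not cover a pixel and is used to combine predicted
#' contrasts into a reconstructed image.
#'
#' @param images `n x 100` row-major binary image matrix.
#' @param bases data.frame from [enumerate_bases()].
#' @param contrasts `n x n_bases` matrix of true contrast values (as in
#'   `local_decoding$true_contrasts`).
#' @param ridge ridge stabilizer (default 1e-6).
#' @return `n_bases x 100` combination-weight matrix.
#' @export
fit_combination_weights <- function(images, bases, contrasts, ridge = 1e-6) {
  B <- nrow(bases)
  Wmat <- matrix(0, B, 100L)
  cover <- matrix(FALSE, B, 100L)
  for (b in seq_len(B))
    cover[b, .basis_pixels(as.list(bases[b, ]))] <- TRUE
  for (p in seq_len(100L)) {
    cb <- which(cover[, p])
    Z <- contrasts[, cb, drop = FALSE]
    A <- crossprod(Z) + diag(ridge, length(cb))
    Wmat[cb, p] <- solve(A, crossprod(Z, images[, p]))
  }
  Wmat
}

#' Reconstruct a stimulus image from predicted basis contrasts
#'
#' Pixel-wise weighted sum of the basis contrasts:
#' `pixel_p = sum_b weights[b, p] * contrast_b`.
#'
#' @param predicted_contrasts numeric vector, one predicted contrast value
#'   per basis.
#' @param bases data.frame from [enumerate_bases()] (checked for length
#'   agreement).
#' @param combination_weights `n_bases x 100` matrix from
#'   [fit_combination_weights()].
#' @return a 10 x 10 numeric matrix.
#' @export
reconstruct_image <- function(predicted_contrasts, bases, combination_weights) {
  stopifnot(length(predicted_contrasts) == nrow(bases),
            nrow(combination_weights) == nrow(bases),
            ncol(combination_weights) == 100L)
  v <- drop(crossprod(combination_weights, predicted_contrasts))
  matrix(v, 10L, 10L, byrow = TRUE)
}

#' Spatial correlation between a reconstruction and a presented image
#'
#' Pearson correlation over the 100 pixel pairs; `NA_real_` when either
#' image is constant.
#'
#' @param reconstructed 10 x 10 numeric matrix (or length-100 vector).
#' @param presented 10 x 10 binary matrix (or length-100 vector).
#' @return a number in `[-1, 1]`, or `NA_real_`.
#' @export
image_spatial_correlation <- function(reconstructed, presented) {
  a <- .image_vector(reconstructed)
  b <- .image_vector(presented)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}
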