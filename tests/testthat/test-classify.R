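# Feature extraction, stratified splitting, the three classifiers (with a
# brute-force Mahalanobis oracle), whole-image prediction, metrics, pooling.

test_that("hsi features are per-pixel Z-normed over the 400-750 nm bands", {
  cube <- make_test_cube(5, 6, 40, wavelengths = seq(400, 900, length.out = 40))
  lm <- label_map(matrix(sample(c(0L, 1L, 2L), 30, TRUE), 5, 6), c("a", "b"))
  ds <- extract_dataset(cube, lm, mode = "hsi")
  expect_equal(rowMeans(ds$features), rep(0, nrow(ds$features)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(apply(ds$features, 1, sd), rep(1, nrow(ds$features)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # feature count equals the brute-force band count in range
  wl <- seq(400, 900, length.out = 480)
  cube2 <- make_test_cube(2, 3, 480, wavelengths = wl)
  lm2 <- label_map(matrix(1L, 2, 3), "a")
  ds2 <- extract_dataset(cube2, lm2, mode = "hsi")
  expect_equal(ncol(ds2$features), sum(wl >= 400 & wl <= 750))
})

test_that("Z-norm is invariant to per-pixel gain and offset", {
  B <- 30
  wl <- seq(410, 740, length.out = B)
  base <- runif(B)
  vals <- array(0, c(1, 2, B))
  vals[1, 1, ] <- base
  vals[1, 2, ] <- 3.7 * base + 0.9
  cube <- spectral_cube(vals, wl)
  ds <- extract_dataset(cube, label_map(matrix(1L, 1, 2), "a"), "hsi")
  expect_equal(ds$features[1, ], ds$features[2, ], tolerance = 1e-12)
})

test_that("rgb features are raw intensities at 640/540/460 in R,G,B order", {
  wl <- c(455, 465, 535, 545, 635, 645)
  vals <- array(seq_len(2 * 2 * 6), c(2, 2, 6))
  cube <- spectral_cube(vals, wl)
  ds <- extract_dataset(cube, label_map(matrix(1L, 2, 2), "a"), "rgb")
  # nearest bands: 640 -> 635 (tie to lower), 540 -> 535, 460 -> 455
  expect_equal(ds$wavelengths, c(635, 535, 455))
  # rows follow (line, sample) scan order
  expect_equal(ds$features[, 1], as.vector(t(vals[, , 5])))
})

test_that("rows come in deterministic (line, sample) scan order", {
  cube <- make_test_cube(3, 4, 12)
  lm <- label_map(matrix(1L, 3, 4), "a")
  ds <- extract_dataset(cube, lm, "rgb")
  expect_equal(ds$provenance$line, rep(0:2, each = 4))
  expect_equal(ds$provenance$sample, rep(0:3, times = 3))
})

test_that("zero-SD pixels are excluded from datasets with a warning", {
  B <- 20
  vals <- array(runif(4 * 2 * B), c(4, 2, B))
  vals[2, 1, ] <- 0.3  # flat spectrum
  cube <- spectral_cube(vals, seq(400, 700, length.out = B))
  lm <- label_map(matrix(1L, 4, 2), "a")
  expect_warning(ds <- extract_dataset(cube, lm, "hsi"), "zero spectral SD")
  expect_equal(nrow(ds$features), 7)
  expect_equal(ds$n_excluded, 1L)
})

test_that("stratified split honours round(0.75 * N_k) per class and the seed", {
  set.seed(9)
  n <- c(a = 100, b = 37, c = 11)
  ds <- structure(list(
    features = matrix(rnorm(sum(n) * 3), sum(n), 3),
    labels = rep(names(n), n),
    provenance = data.frame(image_id = "x", line = seq_len(sum(n)),
                            sample = 0),
    mode = "rgb", band_range = c(400, 750), wavelengths = c(640, 540, 460)),
    class = "pixel_dataset")
  sp <- split_dataset(ds, 0.75, seed = 4)
  expect_equal(sum(table(sp$train$labels)), sum(round(0.75 * n)))
  for (k in names(n))
    expect_equal(unname(table(sp$train$labels)[k]), round(0.75 * n[[k]]),
                 ignore_attr = TRUE)
  # disjoint and exhaustive
  expect_equal(nrow(sp$train$features) + nrow(sp$validation$features), sum(n))
  expect_equal(sort(c(sp$train$provenance$line, sp$validation$provenance$line)),
               seq_len(sum(n)))
  # reproducible
  sp2 <- split_dataset(ds, 0.75, seed = 4)
  expect_identical(sp$train$provenance$line, sp2$train$provenance$line)
  sp3 <- split_dataset(ds, 0.75, seed = 5)
  expect_false(identical(sp$train$provenance$line, sp3$train$provenance$line))
  # minimum class size enforced
  ds_small <- ds; ds_small$labels[ds$labels == "c"] <- "a"
  ds_small$labels[1:3] <- "tiny"
  expect_error(split_dataset(ds_small, 0.75, 0), "tiny")
})

make_gaussian_ds <- function(n_per = 200, F_ = 3, sep = 10, seed = 1,
                             K = 2) {
  set.seed(seed)
  mus <- diag(sep, K, F_)
  X <- do.call(rbind, lapply(seq_len(K), function(k)
    matrix(rnorm(n_per * F_), n_per, F_) + rep(mus[k, ], each = n_per)))
  structure(list(features = X,
                 labels = rep(LETTERS[seq_len(K)], each = n_per),
                 provenance = data.frame(image_id = "g",
                                         line = seq_len(K * n_per), sample = 0),
                 mode = "rgb", band_range = c(400, 750),
                 wavelengths = seq_len(F_)),
            class = "pixel_dataset")
}

test_that("all three algorithms separate 10-SD Gaussian classes perfectly", {
  ds <- make_gaussian_ds()
  for (alg in c("perceptron", "mahalanobis", "svm_linear")) {
    m <- train_classifier(ds, alg, seed = 0)
    expect_equal(mean(predict(m, ds) == ds$labels), 1, label = alg)
  }
})

test_that("the Mahalanobis rule is exact at class means and on the oracle", {
  ds <- make_gaussian_ds(n_per = 60, F_ = 5, sep = 4, K = 3)
  m <- train_classifier(ds, "mahalanobis")
  mus <- do.call(rbind, lapply(sort(unique(ds$labels)), function(k)
    colMeans(ds$features[ds$labels == k, ])))
  expect_equal(predict(m, mus), sort(unique(ds$labels)))
  # 50 random points x 10 seeds against the explicit loop/solve oracle
  for (seed in 1:10) {
    set.seed(100 + seed)
    tr <- make_gaussian_ds(n_per = 40, F_ = 5, sep = 2, seed = seed, K = 3)
    Xt <- matrix(rnorm(50 * 5, sd = 3), 50, 5)
    model <- train_classifier(tr, "mahalanobis")
    expect_identical(predict(model, Xt),
                     brute_mahalanobis_predict(tr$features, tr$labels, Xt))
  }
})

test_that("training is deterministic for a fixed seed (perceptron)", {
  ds <- make_gaussian_ds(n_per = 50, sep = 3)
  m1 <- train_classifier(ds, "perceptron", seed = 3)
  m2 <- train_classifier(ds, "perceptron", seed = 3)
  expect_identical(m1$fit$W1, m2$fit$W1)
  m3 <- train_classifier(ds, "perceptron", seed = 4)
  expect_false(identical(m1$fit$W1, m3$fit$W1))
})

test_that("unknown algorithms and dimension mismatches are rejected", {
  ds <- make_gaussian_ds(n_per = 20)
  expect_error(train_classifier(ds, "forest"))
  m <- train_classifier(ds, "mahalanobis")
  expect_error(predict(m, matrix(0, 2, 7)), "dimension mismatch")
  one <- ds; one$labels[] <- "A"
  expect_error(train_classifier(one, "svm_linear"), ">= 2 classes")
})

test_that("noiseless simulated scene maps to 100% ground truth, all algorithms", {
  sc <- generate_scene(degenerate_scene_spec(seed = 23, board = FALSE))
  ann <- sparse_annotations(sc$truth, 0.03, seed = 2)
  lm <- rasterize_annotations(ann, dim(sc$cube$values)[1:2])
  ds <- extract_dataset(sc$cube, lm, mode = "hsi")
  truth_names <- sc$truth$legend[sc$truth$values]
  for (alg in c("perceptron", "mahalanobis", "svm_linear")) {
    m <- train_classifier(ds, alg, seed = 0)
    map <- predict_map(m, sc$cube)
    agree <- mean(map$legend[map$values] == truth_names)
    expect_equal(agree, 1, label = alg)
  }
})

test_that("predict_map assigns every pixel and falls back on flat spectra", {
  sc <- generate_scene(tiny_scene_spec(snr = 100, seed = 29))
  ann <- sparse_annotations(sc$truth, 0.03, seed = 2)
  lm <- rasterize_annotations(ann, dim(sc$cube$values)[1:2])
  ds <- extract_dataset(sc$cube, lm, mode = "hsi")
  m <- train_classifier(ds, "mahalanobis")
  cube <- sc$cube
  cube$values[3, 5, ] <- 0.7  # one flat pixel
  map <- predict_map(m, cube)
  expect_true(all(map$values >= 1))
  expect_equal(attr(map, "qc")$n_fallback, 1L)
  # constant cube -> a single deterministic class everywhere
  const <- spectral_cube(array(0.7, dim(cube$values)), cube$wavelengths)
  cmap <- predict_map(m, const)
  expect_equal(length(unique(as.vector(cmap$values))), 1)
})

test_that("metrics match hand arithmetic and the counting oracle", {
  cm <- matrix(c(8, 1, 2, 9), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  r <- confusion_metrics(cm)
  expect_equal(r$accuracy, 0.85)
  expect_equal(unname(r$precision), c(8 / 9, 9 / 11))
  expect_equal(unname(r$recall), c(0.8, 0.9))
  expect_equal(unname(r$support), c(10, 10))
  # invariants on random confusion matrices
  set.seed(12)
  for (i in 1:20) {
    K <- sample(2:6, 1)
    M <- matrix(rpois(K * K, 5), K, K,
                dimnames = list(LETTERS[1:K], LETTERS[1:K]))
    r <- confusion_metrics(M)
    expect_equal(r$accuracy, sum(diag(M)) / sum(M))
    expect_equal(unname(r$precision), unname(diag(M) / colSums(M)))
    expect_equal(unname(r$recall), unname(diag(M) / rowSums(M)))
    expect_equal(unname(r$support), unname(rowSums(M)))
  }
})

test_that("evaluate agrees with a brute-force counting oracle", {
  ds <- make_gaussian_ds(n_per = 500, sep = 1.2, K = 3, seed = 6)
  sp <- split_dataset(ds, 0.75, seed = 0)
  m <- train_classifier(sp$train, "mahalanobis")
  rep <- evaluate(m, sp$validation)
  pred <- predict(m, sp$validation)
  truth <- sp$validation$labels
  classes <- m$classes
  for (ki in seq_along(classes)) for (kj in seq_along(classes))
    expect_equal(rep$confusion[ki, kj],
                 sum(truth == classes[ki] & pred == classes[kj]),
                 ignore_attr = TRUE)
  expect_equal(rep$accuracy, mean(pred == truth))
  # classes missing from validation keep NA metrics
  sub <- sp$validation
  keep <- sub$labels != "C"
  sub <- ds_subset <- structure(
    list(features = sub$features[keep, ], labels = sub$labels[keep],
         provenance = sub$provenance[keep, ], mode = sub$mode,
         band_range = sub$band_range, wavelengths = sub$wavelengths),
    class = "pixel_dataset")
  r2 <- evaluate(m, sub)
  expect_true(is.na(r2$recall[["C"]]))
  expect_error(evaluate(m, transform_labels <- {
    bad <- sub; bad$labels[1] <- "Z"; bad
  }), "unknown")
})

test_that("pooling concatenates datasets and preserves provenance", {
  d1 <- make_gaussian_ds(n_per = 30, seed = 2)
  d2 <- make_gaussian_ds(n_per = 20, seed = 3, K = 2)
  d2$provenance$image_id <- "g2"
  pooled <- pool_datasets(list(d1, d2))
  expect_equal(nrow(pooled$features), 100)
  expect_equal(sum(pooled$provenance$image_id == "g2"), 40)
  expect_equal(pooled$features[61, ], d2$features[1, ])
  # pooling with an empty dataset is the identity
  empty <- d2
  empty$features <- d2$features[0, , drop = FALSE]
  empty$labels <- character(0)
  empty$provenance <- d2$provenance[0, ]
  expect_equal(pool_datasets(list(d1, empty))$features, d1$features)
  # mode mismatch rejected
  d3 <- d2; d3$mode <- "hsi"
  expect_error(pool_datasets(list(d1, d3)), "mode")
})
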