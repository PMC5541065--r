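# Shared fixtures: small random cubes, a compact multi-class reef scene, and
# a lazily computed cache of the full-size reference-scene experiment so the
# expensive generation + training happens once per test run.

make_test_cube <- function(L = 4, S = 6, B = 10, seed = 42,
                           wavelengths = seq(400, 700, length.out = B)) {
  set.seed(seed)
  spectral_cube(array(runif(L * S * B, 0.1, 1), c(L, S, B)), wavelengths)
}

# a compact 6-class scene (4 benthic classes + Reference board + Sediment
# background) sharing the structure of the full reference scene
tiny_scene_spec <- function(snr = 50, seed = 7, altitude = 1.0,
                            shape = c(60L, 160L), board = TRUE) {
  classes <- list(
    scene_class("CoralA", 0.28, list(c(440, 15, 0.10), c(670, 12, 0.14)),
                red_edge_slope = 0.002, n_blobs = 2L,
                blob_lines = c(5, 8), blob_samples = c(10, 18)),
    scene_class("CoralB", 0.28, list(c(440, 15, 0.10), c(580, 10, 0.07),
                                     c(670, 12, 0.11)),
                red_edge_slope = 0.0015, n_blobs = 2L,
                blob_lines = c(5, 8), blob_samples = c(10, 18)),
    scene_class("Turf", 0.18, list(c(440, 18, 0.06), c(670, 12, 0.09)),
                red_edge_slope = 0.0008, n_blobs = 2L,
                blob_lines = c(5, 8), blob_samples = c(10, 18)),
    scene_class("Reference", 0.50),
    scene_class("Sediment", 0.45, list(c(605, 12, 0.05))))
  scene_spec(shape = shape, classes = classes, background = "Sediment",
             board = if (board) list(lines = c(2L, 14L), samples = c(3L, 26L),
                                     albedo = 0.5) else NULL,
             altitude = altitude, snr = snr, seed = seed)
}

# noiseless flat-field variant: constant altitude, unit illumination, no
# attenuation -> pixel spectra equal class endmembers exactly
degenerate_scene_spec <- function(seed = 7, board = TRUE) {
  spec <- tiny_scene_spec(snr = Inf, seed = seed, board = board)
  spec$illumination <- rep(1, length(spec$wavelengths))
  spec$kd <- rep(0, length(spec$wavelengths))
  spec
}

# ---- cached full-size reference-scene experiment ---------------------------

.reef_cache <- new.env(parent = emptyenv())

reef11_experiment <- function() {
  if (!is.null(.reef_cache$res)) return(.reef_cache$res)
  spec_n <- reef11_spec()
  sc_n <- generate_scene(spec_n)
  ann_n <- sparse_annotations(sc_n$truth, 0.018, seed = 0, image_id = "normal")
  lm_n <- rasterize_annotations(ann_n, dim(sc_n$cube$values)[1:2])
  acc <- list()
  ds <- list()
  for (mode in c("hsi", "rgb")) {
    d <- extract_dataset(sc_n$cube, lm_n, mode = mode)
    sp <- split_dataset(d, 0.75, seed = 0)
    ds[[mode]] <- d
    for (alg in c("perceptron", "mahalanobis", "svm_linear")) {
      m <- train_classifier(sp$train, alg, seed = 0)
      acc[[paste(mode, alg, sep = "_")]] <-
        evaluate(m, sp$validation)$accuracy
      if (mode == "hsi" && alg == "perceptron") .reef_cache$model_n <- m
    }
  }
  spec_e <- elevate_scene(spec_n)
  sc_e <- generate_scene(spec_e)
  ann_e <- sparse_annotations(sc_e$truth, 0.015, seed = 1,
                              image_id = "elevated")
  lm_e <- rasterize_annotations(ann_e, dim(sc_e$cube$values)[1:2])
  ds_e <- extract_dataset(sc_e$cube, lm_e, mode = "hsi")
  acc$cross <- mean(predict(.reef_cache$model_n, ds_e) == ds_e$labels)
  pooled <- pool_datasets(list(ds$hsi, ds_e))
  sp_p <- split_dataset(pooled, 0.75, seed = 0)
  m_p <- train_classifier(sp_p$train, "perceptron", seed = 0)
  acc$pooled <- evaluate(m_p, sp_p$validation)$accuracy
  .reef_cache$res <- list(
    acc = acc,
    annotated_fraction = mean(lm_n$values != 0),
    n_classes = length(sc_n$truth$legend),
    track = sc_n$track,
    spec = spec_n)
  .reef_cache$res
}

# brute-force even-odd point-in-polygon (per-pixel loop), boundary-inclusive
brute_point_in_polygon <- function(l, s, poly, eps = 1e-9) {
  n <- nrow(poly)
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[j, 1]; y2 <- poly[j, 2]
    seg <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    if (seg > 0) {
      cross <- (x2 - x1) * (s - y1) - (y2 - y1) * (l - x1)
      if (abs(cross) <= eps * max(1, seg) &&
          l >= min(x1, x2) - eps && l <= max(x1, x2) + eps &&
          s >= min(y1, y2) - eps && s <= max(y1, y2) + eps)
        return(TRUE)
    }
    if ((x1 > l) != (x2 > l)) {
      ys <- y1 + (l - x1) / (x2 - x1) * (y2 - y1)
      if (s < ys) inside <- !inside
    }
  }
  inside
}

# brute-force Mahalanobis classifier: explicit loops and an explicit solve
brute_mahalanobis_predict <- function(X_train, y_train, X_test,
                                      eps_scale = 1e-6) {
  classes <- sort(unique(y_train))
  F_ <- ncol(X_train)
  pred <- character(nrow(X_test))
  stats <- lapply(classes, function(k) {
    Xk <- X_train[y_train == k, , drop = FALSE]
    S <- cov(Xk)
    eps <- eps_scale * sum(diag(S)) / F_
    if (eps <= 0) eps <- eps_scale
    list(mu = colMeans(Xk), Sinv = solve(S + diag(eps, F_)))
  })
  for (i in seq_len(nrow(X_test))) {
    d2 <- numeric(length(classes))
    for (k in seq_along(classes)) {
      v <- X_test[i, ] - stats[[k]]$mu
      d2[k] <- drop(t(v) %*% stats[[k]]$Sinv %*% v)
    }
    pred[i] <- classes[which.min(d2)]
  }
  pred
}
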