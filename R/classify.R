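# Supervised benthic pixel classification.
#
# Sparse polygon annotations -> labelled pixel datasets -> fitted classifier
# (multi-layer perceptron, Mahalanobis distance, or linear SVM) -> full-image
# benthic maps plus confusion-matrix metrics. Two feature modes: "hsi" uses
# per-pixel Z-normed spectra restricted to 400-750 nm (the infrared end of
# the axis carries no usable signal underwater), which removes brightness and
# gain differences; "rgb" uses the raw intensities of the three bands nearest
# 640/540/460 nm, emulating a plain colour camera.

# run expr with a private, restored RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Extract per-pixel feature matrices for a whole cube
#'
#' Internal workhorse shared by [extract_dataset()] and [predict_map()].
#'
#' @param cube A [spectral_cube] or reflectance cube.
#' @param mode `"hsi"` or `"rgb"`.
#' @param band_range Length-2 nm range kept in `"hsi"` mode.
#' @return List: `features` (`(L*S) x F` matrix, pixels in column-major
#'   `(line, sample)` scan order — all lines of sample 0, then sample 1, ...),
#'   `zero_sd` (logical per pixel; `"hsi"` rows that could not be Z-normed
#'   are left as zero vectors), `wavelengths` (feature band centres).
#' @keywords internal
pixel_features <- function(cube, mode = c("hsi", "rgb"),
                           band_range = c(400, 750)) {
  mode <- match.arg(mode)
  d <- dim(cube$values)
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  if (mode == "rgb") {
    bands <- vapply(c(640, 540, 460), function(w) band_index(cube, w), 1L)
    return(list(features = flat[, bands, drop = FALSE],
                zero_sd = rep(FALSE, nrow(flat)),
                wavelengths = cube$wavelengths[bands]))
  }
  keep <- which(cube$wavelengths >= band_range[1] &
                cube$wavelengths <= band_range[2])
  if (length(keep) < 2L) stop("band range leaves < 2 bands")
  X <- flat[, keep, drop = FALSE]
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1L))
  zs <- sdv <= 0
  sdv[zs] <- 1
  X <- (X - mu) / sdv
  X[zs, ] <- 0
  list(features = X, zero_sd = zs, wavelengths = cube$wavelengths[keep])
}

#' Build a labelled pixel dataset from a cube and a label map
#'
#' Collects every labelled pixel (label-map sentinel 0 excluded) in
#' deterministic `(line, sample)` scan order. In `"hsi"` mode each pixel
#' spectrum is restricted to `band_range` and Z-normed across bands
#' (mean 0, SD 1 per pixel); pixels with zero spectral SD are excluded with
#' a warning. In `"rgb"` mode the raw intensities of the bands nearest
#' 640/540/460 nm are used unnormalized.
#'
#' @param cube A [spectral_cube] or reflectance cube.
#' @param labels A [label_map] matching the cube's spatial shape.
#' @param mode `"hsi"` (default) or `"rgb"`.
#' @param band_range Length-2 nm range for `"hsi"` features.
#' @return A `pixel_dataset`: list with `features` (N x F matrix), `labels`
#'   (length-N character), `provenance` (data.frame `image_id, line, sample`,
#'   0-based), `mode`, `band_range`, `wavelengths`, `n_excluded`.
#' @export
extract_dataset <- function(cube, labels, mode = c("hsi", "rgb"),
                            band_range = c(400, 750)) {
  mode <- match.arg(mode)
  d <- dim(cube$values)
  if (!all(dim(labels$values) == d[1:2]))
    stop("label map shape does not match cube")
  lab_vec <- as.vector(labels$values)  # column-major = (line, sample) scan
  sel <- which(lab_vec != 0L)
  if (!length(sel)) stop("no labelled pixels")
  # order by (line, sample): column-major order is sample-major; reorder
  line0 <- (sel - 1L) %% d[1]
  samp0 <- (sel - 1L) %/% d[1]
  o <- order(line0, samp0)
  sel <- sel[o]; line0 <- line0[o]; samp0 <- samp0[o]
  pf <- pixel_features(cube, mode, band_range)
  feat <- pf$features[sel, , drop = FALSE]
  labs <- labels$legend[lab_vec[sel]]
  drop <- pf$zero_sd[sel]
  n_excluded <- sum(drop)
  if (n_excluded > 0L) {
    warning(n_excluded, " pixel(s) with zero spectral SD excluded from dataset")
    feat <- feat[!drop, , drop = FALSE]
    labs <- labs[!drop]
    line0 <- line0[!drop]; samp0 <- samp0[!drop]
  }
  img <- if (!is.null(attr(labels, "image_id"))) attr(labels, "image_id") else "image"
  structure(list(features = feat, labels = labs,
                 provenance = data.frame(image_id = img, line = line0,
                                         sample = samp0),
                 mode = mode, band_range = band_range,
                 wavelengths = pf$wavelengths, n_excluded = n_excluded),
            class = "pixel_dataset")
}

#' @export
print.pixel_dataset <- function(x, ...) {
  cat(sprintf("<pixel_dataset> %d pixels x %d features (mode %s)\n",
              nrow(x$features), ncol(x$features), x$mode))
  print(table(x$labels))
  invisible(x)
}

ds_subset <- function(ds, idx) {
  out <- ds
  out$features <- ds$features[idx, , drop = FALSE]
  out$labels <- ds$labels[idx]
  out$provenance <- ds$provenance[idx, , drop = FALSE]
  out
}

#' Stratified train/validation split
#'
#' Splits per class: `round(train_fraction * N_k)` rows of each class go to
#' training, the rest to validation. Reproducible for a fixed seed; the
#' split leaves the caller's RNG state untouched.
#'
#' @param ds A `pixel_dataset`.
#' @param train_fraction Fraction per class for training (default 0.75).
#' @param seed Integer seed.
#' @return List with elements `train` and `validation` (both
#'   `pixel_dataset`s; disjoint, union = `ds`).
#' @export
split_dataset <- function(ds, train_fraction = 0.75, seed = 0L) {
  counts <- table(ds$labels)
  small <- names(counts)[counts < 4L]
  if (length(small))
    stop("class(es) below the 4-row minimum: ", paste(small, collapse = ", "))
  tr_idx <- with_seed(seed, {
    unlist(lapply(names(counts), function(k) {
      rows <- which(ds$labels == k)
      sample(rows, round(train_fraction * length(rows)))
    }), use.names = FALSE)
  })
  tr_idx <- sort(tr_idx)
  va_idx <- setdiff(seq_along(ds$labels), tr_idx)
  list(train = ds_subset(ds, tr_idx), validation = ds_subset(ds, va_idx))
}

#' Pool pixel datasets from several images
#'
#' Row-concatenation preserving provenance; the class list is the union.
#' All datasets must share the feature mode and dimensionality.
#'
#' @param datasets List of `pixel_dataset`s.
#' @return A single `pixel_dataset`.
#' @export
pool_datasets <- function(datasets) {
  datasets <- Filter(function(d) nrow(d$features) > 0L, datasets)
  if (!length(datasets)) stop("no non-empty datasets to pool")
  modes <- unique(vapply(datasets, `[[`, "", "mode"))
  Fs <- unique(vapply(datasets, function(d) ncol(d$features), 1L))
  if (length(modes) != 1L || length(Fs) != 1L)
    stop("datasets differ in feature mode or dimensionality")
  out <- datasets[[1]]
  out$features <- do.call(rbind, lapply(datasets, `[[`, "features"))
  out$labels <- unlist(lapply(datasets, `[[`, "labels"), use.names = FALSE)
  out$provenance <- do.call(rbind, lapply(datasets, `[[`, "provenance"))
  out$n_excluded <- sum(vapply(datasets, function(d)
    if (is.null(d$n_excluded)) 0L else d$n_excluded, 1L))
  out
}

## ---- single-hidden-layer perceptron (softmax output, Adam) ----------------

mlp_fit <- function(X, y_int, K, hidden = 64L, maxit = 500L, lr = 0.01,
                    l2 = 1e-4, patience = 25L, tol = 1e-6, seed = 0L) {
  n <- nrow(X); F_ <- ncol(X)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y_int)] <- 1
  par <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(F_ * hidden, sd = sqrt(1 / F_)), F_, hidden),
    b1 = rep(0, hidden),
    W2 = matrix(stats::rnorm(hidden * K, sd = sqrt(1 / hidden)), hidden, K),
    b2 = rep(0, K)))
  m <- lapply(par, function(p) p * 0); v <- m
  b1t <- 1; b2t <- 1
  best <- Inf; stall <- 0L
  for (it in seq_len(maxit)) {
    H <- tanh(sweep(X %*% par$W1, 2L, par$b1, `+`))
    Z <- sweep(H %*% par$W2, 2L, par$b2, `+`)
    Z <- Z - apply(Z, 1L, max)
    P <- exp(Z); P <- P / rowSums(P)
    loss <- -mean(log(pmax(P[Y == 1], 1e-12))) +
      l2 * (sum(par$W1^2) + sum(par$W2^2)) / (2 * n)
    if (loss < best - tol) { best <- loss; stall <- 0L } else stall <- stall + 1L
    if (stall >= patience) break
    dZ <- (P - Y) / n
    g <- list(W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL)
    g$W2 <- crossprod(H, dZ) + l2 * par$W2 / n
    g$b2 <- colSums(dZ)
    dH <- tcrossprod(dZ, par$W2) * (1 - H^2)
    g$W1 <- crossprod(X, dH) + l2 * par$W1 / n
    g$b1 <- colSums(dH)
    b1t <- b1t * 0.9; b2t <- b2t * 0.999
    for (nm in names(par)) {
      m[[nm]] <- 0.9 * m[[nm]] + 0.1 * g[[nm]]
      v[[nm]] <- 0.999 * v[[nm]] + 0.001 * g[[nm]]^2
      par[[nm]] <- par[[nm]] -
        lr * (m[[nm]] / (1 - b1t)) / (sqrt(v[[nm]] / (1 - b2t)) + 1e-8)
    }
  }
  c(par, list(n_iter = it, loss = best))
}

mlp_decision <- function(fit, X) {
  H <- tanh(sweep(X %*% fit$W1, 2L, fit$b1, `+`))
  sweep(H %*% fit$W2, 2L, fit$b2, `+`)
}

## ---- Mahalanobis distance classifier (implemented from definition) --------

mahalanobis_fit <- function(X, labs, classes, eps_scale = 1e-6) {
  F_ <- ncol(X)
  fits <- lapply(classes, function(k) {
    Xk <- X[labs == k, , drop = FALSE]
    mu <- colMeans(Xk)
    S <- stats::cov(Xk)
    eps <- eps_scale * sum(diag(S)) / F_
    if (eps <= 0) eps <- eps_scale
    Sr <- S + diag(eps, F_)
    ch <- tryCatch(chol(Sr), error = function(e)
      stop("singular covariance for class '", k,
           "' despite shrinkage; increase eps_scale", call. = FALSE))
    list(mu = mu, chol = ch)
  })
  names(fits) <- classes
  fits
}

mahalanobis_scores <- function(fit, X) {
  # lower score = closer; one column per class
  vapply(fit, function(f) {
    V <- sweep(X, 2L, f$mu)
    # d^2 = || L^-T v ||^2 with chol R: solve R' z = v  => d^2 = sum z^2
    Z <- backsolve(f$chol, t(V), transpose = TRUE)
    colSums(Z^2)
  }, numeric(nrow(X)))
}

## ---- linear SVM, one-vs-rest over binary e1071 fits ------------------------

svm_ovr_fit <- function(X, labs, classes, cost = 1) {
  lapply(stats::setNames(classes, classes), function(k) {
    y <- factor(ifelse(labs == k, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
  })
}

svm_ovr_decision <- function(fit, X) {
  vapply(fit, function(f) {
    dv <- attr(stats::predict(f, X, decision.values = TRUE), "decision.values")
    # e1071 labels the column "<first>/<second>"; flip if "neg" came first
    if (grepl("^neg/", colnames(dv)[1])) -dv[, 1] else dv[, 1]
  }, numeric(nrow(X)))
}

## ---- fitting front-end -----------------------------------------------------

#' Train a benthic pixel classifier
#'
#' Fits one of three per-pixel classifiers on a labelled `pixel_dataset`:
#' \describe{
#'   \item{perceptron}{A single-hidden-layer neural network (default 64 tanh
#'     units, softmax output) trained by full-batch Adam with early stopping;
#'     implemented in the package, seeded and deterministic.}
#'   \item{mahalanobis}{Per-class mean and covariance with ridge shrinkage
#'     `Sigma_k + eps I`, `eps = eps_scale * trace(Sigma_k)/F`; prediction is
#'     the class of smallest Mahalanobis distance, ties to the
#'     lexicographically first class.}
#'   \item{svm_linear}{Linear-kernel support vector machine, one-vs-rest over
#'     binary fits; prediction by largest decision value.}
#' }
#' Perceptron and SVM features are internally standardized per column using
#' training statistics (stored in the model); the Mahalanobis rule is
#' affine-equivariant and uses the features as-is.
#'
#' @param train A `pixel_dataset` with >= 2 classes.
#' @param algorithm `"perceptron"`, `"mahalanobis"` or `"svm_linear"`.
#' @param hyperparams Named list overriding defaults: `hidden` (64), `maxit`
#'   (500), `lr` (0.01), `cost` (1), `eps_scale` (1e-6).
#' @param seed Integer seed for the stochastic initialisation (perceptron).
#' @return A `benthic_classifier` with [predict][predict.benthic_classifier],
#'   `print` and `summary` methods.
#' @export
train_classifier <- function(train, algorithm = c("perceptron", "mahalanobis",
                                                  "svm_linear"),
                             hyperparams = list(), seed = 0L) {
  algorithm <- match.arg(algorithm)
  classes <- sort(unique(train$labels))
  if (length(classes) < 2L) stop("need >= 2 classes to train")
  hp <- utils::modifyList(
    list(hidden = 64L, maxit = 500L, lr = 0.01, cost = 1, eps_scale = 1e-6),
    hyperparams)
  X <- train$features
  cm <- do.call(rbind, lapply(classes, function(k)
    colMeans(X[train$labels == k, , drop = FALSE])))
  rownames(cm) <- classes
  std <- NULL
  if (algorithm %in% c("perceptron", "svm_linear")) {
    mu <- colMeans(X)
    sdv <- apply(X, 2L, stats::sd)
    sdv[sdv <= 0] <- 1
    std <- list(mean = mu, sd = sdv)
    X <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
  }
  fit <- switch(algorithm,
    perceptron = mlp_fit(X, match(train$labels, classes), length(classes),
                         hidden = hp$hidden, maxit = hp$maxit, lr = hp$lr,
                         seed = seed),
    mahalanobis = mahalanobis_fit(X, train$labels, classes,
                                  eps_scale = hp$eps_scale),
    svm_linear = svm_ovr_fit(X, train$labels, classes, cost = hp$cost))
  structure(list(
    algorithm = algorithm, classes = classes, fit = fit,
    preprocessing = list(mode = train$mode, band_range = train$band_range,
                         normalization = if (train$mode == "hsi")
                           "per-pixel z-norm" else "none",
                         wavelengths = train$wavelengths,
                         standardize = std),
    class_means = cm, hyperparams = hp, seed = seed,
    n_train = nrow(train$features)),
    class = "benthic_classifier")
}

#' Predict classes for pixel features
#'
#' @param object A `benthic_classifier`.
#' @param newdata A `pixel_dataset` or a numeric feature matrix with the
#'   model's feature dimensionality.
#' @param ... Unused.
#' @return Character vector of predicted class names.
#' @export
predict.benthic_classifier <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "pixel_dataset")) newdata$features else
    as.matrix(newdata)
  nf <- length(object$preprocessing$wavelengths)
  if (ncol(X) != nf)
    stop("feature dimension mismatch: model expects ", nf, ", got ", ncol(X))
  if (!is.null(object$preprocessing$standardize)) {
    s <- object$preprocessing$standardize
    X <- sweep(sweep(X, 2L, s$mean), 2L, s$sd, `/`)
  }
  idx <- switch(object$algorithm,
    perceptron = max.col(mlp_decision(object$fit, X), ties.method = "first"),
    mahalanobis = apply(mahalanobis_scores(object$fit, X), 1L, which.min),
    svm_linear = max.col(svm_ovr_decision(object$fit, X),
                         ties.method = "first"))
  object$classes[idx]
}

#' @export
print.benthic_classifier <- function(x, ...) {
  cat(sprintf("<benthic_classifier> %s on %s features (%d bands), %d classes\n",
              x$algorithm, x$preprocessing$mode,
              length(x$preprocessing$wavelengths), length(x$classes)))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("  trained on %d pixels (seed %d)\n", x$n_train, x$seed))
  invisible(x)
}

#' @export
summary.benthic_classifier <- function(object, ...) {
  print(object)
  cat("  preprocessing:", object$preprocessing$normalization, "in",
      paste(object$preprocessing$band_range, collapse = "-"), "nm\n")
  cat("  hyperparameters:",
      paste(names(object$hyperparams), unlist(object$hyperparams),
            sep = "=", collapse = ", "), "\n")
  if (object$algorithm == "perceptron")
    cat(sprintf("  converged after %d epochs (loss %.4g)\n",
                object$fit$n_iter, object$fit$loss))
  invisible(object)
}

#' Classify every pixel of a cube
#'
#' Applies the model's stored preprocessing (feature mode, band range,
#' per-pixel Z-norm) to the whole image and predicts a class for every pixel
#' — no sentinel remains. Pixels whose spectrum cannot be Z-normed (zero
#' spectral SD) are assigned the class whose training mean is nearest their
#' (zero) feature vector and counted in the attached QC report.
#'
#' @param model A `benthic_classifier`.
#' @param cube A [spectral_cube] or reflectance cube covering the model's
#'   band range.
#' @return A [label_map] with the model's classes as legend; attribute `qc`
#'   holds `n_fallback`.
#' @export
predict_map <- function(model, cube) {
  d <- dim(cube$values)
  pf <- pixel_features(cube, model$preprocessing$mode,
                       model$preprocessing$band_range)
  if (ncol(pf$features) != length(model$preprocessing$wavelengths))
    stop("feature dimension mismatch: cube yields ", ncol(pf$features),
         " features, model expects ",
         length(model$preprocessing$wavelengths))
  pred <- predict(model, pf$features)
  if (any(pf$zero_sd)) {
    fb <- which.min(rowSums(model$class_means^2))  # nearest mean to 0-vector
    pred[pf$zero_sd] <- model$classes[fb]
  }
  vals <- matrix(match(pred, model$classes), d[1], d[2])
  out <- label_map(vals, model$classes)
  attr(out, "qc") <- list(n_fallback = sum(pf$zero_sd))
  out
}

## ---- metrics ---------------------------------------------------------------

#' Confusion-matrix metrics
#'
#' `confusion_metrics()` derives overall accuracy and per-class precision
#' (producer accuracy, `TP/(TP+FP)` = diagonal over column sum) and recall
#' (user accuracy, `TP/(TP+FN)` = diagonal over row sum) from a K x K
#' confusion matrix with true classes in rows and predictions in columns.
#' Classes with zero support get `NA` metrics rather than being dropped.
#'
#' @param confusion Square numeric matrix, rows = true, columns = predicted;
#'   row/column names are the class names.
#' @return A `metrics_report`: list with `confusion`, `accuracy`,
#'   `precision`, `recall`, `support`.
#' @export
confusion_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(confusion)
  colsum <- colSums(confusion)
  rowsum <- rowSums(confusion)
  precision <- ifelse(colsum > 0, tp / colsum, NA_real_)
  recall <- ifelse(rowsum > 0, tp / rowsum, NA_real_)
  cls <- rownames(confusion)
  if (!is.null(cls)) names(precision) <- names(recall) <- cls
  structure(list(confusion = confusion, accuracy = sum(tp) / total,
                 precision = precision, recall = recall, support = rowsum),
            class = "metrics_report")
}

#' Evaluate a classifier on a validation dataset
#'
#' @param model A `benthic_classifier`.
#' @param validation A `pixel_dataset`; its classes must be a subset of the
#'   model's.
#' @return A `metrics_report` over the model's full class list (classes
#'   absent from the validation set keep `NA` precision/recall).
#' @export
evaluate <- function(model, validation) {
  if (!nrow(validation$features)) stop("validation set is empty")
  unknown <- setdiff(unique(validation$labels), model$classes)
  if (length(unknown))
    stop("validation contains class(es) unknown to the model: ",
         paste(unknown, collapse = ", "))
  pred <- predict(model, validation)
  cm <- table(factor(validation$labels, levels = model$classes),
              factor(pred, levels = model$classes))
  confusion_metrics(unclass(cm))
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf("<metrics_report> accuracy %.*f over %d pixels, %d classes\n",
              digits, x$accuracy, sum(x$support), nrow(x$confusion)))
  df <- data.frame(precision = round(x$precision, digits),
                   recall = round(x$recall, digits),
                   support = as.integer(x$support))
  print(df)
  invisible(x)
}

#' Write a metrics report as JSON + CSV confusion matrix
#'
#' @param report A `metrics_report`.
#' @param path Output stem: writes `<path>.json` and `<path>_confusion.csv`.
#' @return Invisibly, the JSON path.
#' @export
write_metrics <- function(report, path) {
  utils::write.csv(as.data.frame.matrix(report$confusion),
                   paste0(path, "_confusion.csv"))
  jsonlite::write_json(
    list(accuracy = report$accuracy,
         precision = as.list(report$precision),
         recall = as.list(report$recall),
         support = as.list(report$support)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paste0(path, ".json"))
}
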