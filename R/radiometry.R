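# In-scene gray-board reference correction: radiance -> relative reflectance.
#
# A spectrally flat board of known (or assumed) albedo placed in the scene
# samples the full optical path (illumination x water-column attenuation at
# survey altitude); dividing every pixel spectrum by the board spectrum
# cancels that path under the assumption that the average light field is
# stable over the 1-2 min of a transect.

#' Mean spectrum of the in-scene reference board
#'
#' Averages the cube over the pixels inside the board polygon(s) and reports a
#' per-band coefficient of variation as a quality check (a good board region
#' is spatially homogeneous, so CV should be small and flat).
#'
#' @param cube A [spectral_cube].
#' @param board_region Either a polygon (numeric matrix of `(line, sample)`
#'   vertices, 0-based) or an [annotation_set]; for an annotation set all
#'   regions labelled `"Reference"` are pooled.
#' @param min_pixels Minimum number of rasterized board pixels (default 25,
#'   a sanity floor for a 25 x 25 cm board at survey resolution).
#' @return A list with `mean` (per-band mean spectrum), `cv` (per-band
#'   coefficient of variation), and `n_pixels`.
#' @export
board_spectrum <- function(cube, board_region, min_pixels = 25L) {
  d <- dim(cube$values)
  if (inherits(board_region, "annotation_set")) {
    regs <- Filter(function(r) identical(r$label, "Reference"),
                   board_region$regions)
    if (!length(regs))
      stop("annotation set has no region labelled 'Reference'")
    polys <- lapply(regs, `[[`, "vertices")
  } else {
    polys <- list(as.matrix(board_region))
  }
  mask <- matrix(FALSE, d[1], d[2])
  for (p in polys) mask <- mask | .polygon_mask(p, c(d[1], d[2]))
  n <- sum(mask)
  if (n == 0L) stop("board region rasterizes to no pixels")
  if (n < min_pixels)
    stop("board region rasterizes to only ", n, " pixels (< ", min_pixels, ")")
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  px <- flat[as.vector(mask), , drop = FALSE]
  mu <- colMeans(px)
  if (any(mu <= 0))
    stop("board spectrum has non-positive mean in ", sum(mu <= 0),
         " band(s); unusable as a reference")
  sdv <- sqrt(colMeans(sweep(px, 2L, mu)^2))  # population SD
  list(mean = mu, cv = sdv / mu, n_pixels = n)
}

#' Convert radiance to board-relative reflectance
#'
#' Divides every pixel spectrum by the reference-board spectrum and scales by
#' the board albedo: `R(l, s, lambda) = board_albedo * I(l, s, lambda) /
#' I_board(lambda)`. Board pixels map to approximately `board_albedo` at every
#' band. Values below 0 or above 1 (noise, shadow, specular targets) are
#' retained — clipping would bias derivative indices — but flagged in a QC
#' mask attached to the result.
#'
#' @param cube A [spectral_cube] of radiance.
#' @param board Per-band board spectrum: the `mean` element of
#'   [board_spectrum()], or the full list itself. Length must equal the band
#'   count; all entries must be positive.
#' @param board_albedo Scalar albedo assigned to the board (default 1:
#'   output is reflectance relative to the board). Set to the board's true
#'   albedo when known.
#' @param smooth_window Optional odd boxcar width (bands) applied to the
#'   board spectrum before division, for noisy boards. `NULL` (default)
#'   disables smoothing.
#' @return A `reflectance_cube` (subclass of [spectral_cube]) with fields
#'   `board_albedo` and `qc` (list: logical `[line, sample]` matrix
#'   `out_of_gamut` marking pixels with any band outside `[0, 1]`, and its
#'   count `n_out_of_gamut`).
#' @export
to_reflectance <- function(cube, board, board_albedo = 1.0,
                           smooth_window = NULL) {
  if (is.list(board)) board <- board$mean
  d <- dim(cube$values)
  if (length(board) != d[3])
    stop("board spectrum length (", length(board),
         ") does not match band count (", d[3], ")")
  if (any(board <= 0)) stop("board spectrum entries must all be positive")
  if (!is.null(smooth_window)) {
    stopifnot(smooth_window %% 2 == 1)
    k <- rep(1 / smooth_window, smooth_window)
    pad <- (smooth_window - 1L) / 2L
    padded <- c(rep(board[1], pad), board, rep(board[length(board)], pad))
    board <- as.numeric(stats::filter(padded, k, sides = 2))[pad + seq_len(d[3])]
  }
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  refl <- sweep(flat, 2L, board / board_albedo, `/`)
  oog <- matrix(rowSums(refl < 0 | refl > 1) > 0, d[1], d[2])
  out <- spectral_cube(array(refl, d), cube$wavelengths,
                       line_period = cube$line_period, meta = cube$meta)
  out$board_albedo <- board_albedo
  out$qc <- list(out_of_gamut = oog, n_out_of_gamut = sum(oog))
  class(out) <- c("reflectance_cube", class(out))
  out
}

#' True-colour rendering of a reflectance cube
#'
#' [to_rgb()] applied after reference correction: the water-column tint is
#' removed, so the gray board renders neutral (channel means over the board
#' agree within ~2%) and the scene appears colour-accurate.
#'
#' @param rcube A `reflectance_cube` from [to_reflectance()].
#' @param ... Passed to [to_rgb()] (`rgb_wavelengths`, `stretch`).
#' @return A `color_image`.
#' @export
true_color <- function(rcube, ...) {
  if (!inherits(rcube, "reflectance_cube"))
    stop("true_color() expects a reflectance cube; see to_reflectance()")
  to_rgb(rcube, ...)
}
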