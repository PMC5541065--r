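# Hyperspectral cube container and ENVI header/binary I/O.
#
# Axis convention used throughout the package: values[line, sample, band],
# image coordinates 0-based (line, sample). ENVI files store the same data in
# one of three interleaves (bil/bsq/bip); the in-memory order never changes.

#' Construct a hyperspectral transect cube
#'
#' A `spectral_cube` holds push-broom transect radiance (or reflectance) as a
#' three-axis array `[line, sample, band]` together with its wavelength axis
#' in nanometres and free-form acquisition metadata (altitude, swim speed,
#' gain, timestamps, ...).
#'
#' @param values Numeric array with dimensions `c(lines, samples, bands)`.
#'   A matrix is accepted for a single line and reshaped to `c(1, nrow, ncol)`
#'   only when explicitly three-dimensional input is impossible; normally pass
#'   an array.
#' @param wavelengths Strictly increasing numeric vector of band-centre
#'   wavelengths (nm); its length must equal `dim(values)[3]`.
#' @param line_period Optional seconds between successive line acquisitions.
#' @param meta Named list of free-form acquisition metadata.
#' @return An object of class `spectral_cube`.
#' @examples
#' cube <- spectral_cube(array(runif(2 * 3 * 4), c(2, 3, 4)),
#'                       wavelengths = c(450, 550, 650, 750))
#' dim(cube$values)
#' @export
spectral_cube <- function(values, wavelengths, line_period = NULL, meta = list()) {
  if (is.matrix(values)) values <- array(values, c(1L, dim(values)))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-axis array [line, sample, band]")
  storage.mode(values) <- "double"
  cube <- structure(
    list(values = values, wavelengths = as.numeric(wavelengths),
         line_period = line_period, meta = meta),
    class = "spectral_cube")
  validate_cube(cube)
  cube
}

validate_cube <- function(cube) {
  d <- dim(cube$values)
  if (d[1] < 1L || d[2] < 1L || d[3] < 2L)
    stop("cube must have L >= 1, S >= 1, B >= 2 (got ",
         paste(d, collapse = " x "), ")")
  wl <- cube$wavelengths
  if (length(wl) != d[3])
    stop("wavelength axis length (", length(wl),
         ") does not match band axis length (", d[3], ")")
  if (any(diff(wl) <= 0)) stop("wavelengths must be strictly increasing")
  if (!all(is.finite(cube$values))) stop("cube values must all be finite")
  invisible(cube)
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d lines x %d samples x %d bands, %.1f-%.1f nm\n",
              class(x)[1], d[1], d[2], d[3],
              min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$line_period))
    cat(sprintf("  line period: %g s\n", x$line_period))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$values)

# ENVI numeric data-type codes <-> R read/write parameters
.envi_dtypes <- list(
  `2`  = list(what = "integer", size = 2L, signed = TRUE,  name = "int16"),
  `4`  = list(what = "double",  size = 4L, signed = TRUE,  name = "float32"),
  `5`  = list(what = "double",  size = 8L, signed = TRUE,  name = "float64"),
  `12` = list(what = "integer", size = 2L, signed = FALSE, name = "uint16"))

.envi_dtype_code <- function(name) {
  code <- names(.envi_dtypes)[vapply(.envi_dtypes, function(d) d$name == name, TRUE)]
  if (!length(code)) stop("unsupported ENVI data type '", name,
                          "'; supported: int16, uint16, float32, float64")
  as.integer(code)
}

# Parse an ENVI header into a named list; `{ ... }` blocks may span lines.
.parse_envi_header <- function(path) {
  txt <- readLines(path, warn = FALSE)
  full <- paste(txt, collapse = "\n")
  full <- sub("^\\s*ENVI\\s*", "", full)
  out <- list()
  # tokenize into key = value entries, where value is either till end-of-line
  # or a brace block
  pos <- 1L
  n <- nchar(full)
  while (pos <= n) {
    rest <- substring(full, pos)
    m <- regexpr("^\\s*([A-Za-z][A-Za-z0-9 _]*?)\\s*=\\s*", rest, perl = TRUE)
    if (m == -1L) break
    key.len <- attr(m, "match.length")
    key <- sub("^\\s*([A-Za-z][A-Za-z0-9 _]*?)\\s*=\\s*$",
               "\\1", substring(rest, 1, key.len), perl = TRUE)
    pos <- pos + key.len
    rest <- substring(full, pos)
    if (substring(rest, 1, 1) == "{") {
      close <- regexpr("\\}", rest)
      if (close == -1L) stop("unterminated '{' block for key '", key, "' in ", path)
      val <- substring(rest, 2, close - 1L)
      pos <- pos + close
    } else {
      eol <- regexpr("\n", rest)
      if (eol == -1L) eol <- nchar(rest) + 1L
      val <- substring(rest, 1, eol - 1L)
      pos <- pos + eol
    }
    out[[tolower(trimws(key))]] <- trimws(val)
  }
  out
}

#' Read an ENVI header/binary cube pair
#'
#' Reads standard ENVI raster pairs (keys: `samples`, `lines`, `bands`,
#' `interleave`, `data type`, `byte order`, `wavelength`) into a
#' [spectral_cube] with axes ordered `[line, sample, band]` regardless of the
#' on-disk interleave. Wavelengths are taken from the header's `wavelength`
#' block and interpreted as nanometres.
#'
#' @param header_path Path to the `.hdr` file. The binary is looked up by
#'   dropping the `.hdr` extension, or at `<stem>.dat`/`<stem>.img`.
#' @return A [spectral_cube]; header keys other than the structural ones are
#'   kept in `$meta`.
#' @seealso [write_envi()]
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) stop("header not found: ", header_path)
  h <- .parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "interleave", "data type")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("ENVI header missing required key(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(h$wavelength))
    stop("ENVI header has no 'wavelength' block; a wavelength list is required")
  S <- as.integer(h$samples); L <- as.integer(h$lines); B <- as.integer(h$bands)
  interleave <- tolower(h$interleave)
  if (!interleave %in% c("bil", "bsq", "bip"))
    stop("unsupported interleave '", interleave, "'")
  dt <- .envi_dtypes[[h$`data type`]]
  if (is.null(dt))
    stop("unsupported ENVI data type code ", h$`data type`,
         " (supported: 2 int16, 4 float32, 5 float64, 12 uint16)")
  wl <- as.numeric(strsplit(h$wavelength, "[,\n]")[[1]])
  wl <- wl[!is.na(wl)]
  if (length(wl) != B)
    stop("header declares bands=", B, " but lists ", length(wl), " wavelengths")
  big <- identical(h[["byte order"]], "1")

  stem <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  bin <- c(stem, paste0(stem, ".dat"), paste0(stem, ".img"))
  bin <- bin[file.exists(bin)][1]
  if (is.na(bin)) stop("binary file for ", header_path, " not found")
  con <- file(bin, "rb")
  on.exit(close(con))
  offset <- if (!is.null(h$`header offset`)) as.integer(h$`header offset`) else 0L
  if (offset > 0L) readBin(con, "raw", offset)
  ntot <- as.double(L) * S * B
  v <- readBin(con, dt$what, n = ntot, size = dt$size, signed = dt$signed,
               endian = if (big) "big" else "little")
  if (length(v) != ntot)
    stop("binary file truncated: expected ", ntot, " samples, got ", length(v))
  a <- switch(interleave,
    bil = aperm(array(v, c(S, B, L)), c(3L, 1L, 2L)),
    bsq = aperm(array(v, c(S, L, B)), c(2L, 1L, 3L)),
    bip = aperm(array(v, c(B, S, L)), c(3L, 2L, 1L)))
  meta <- h[setdiff(names(h), c(need, "wavelength", "byte order",
                                "header offset", "file type",
                                "wavelength units"))]
  meta <- lapply(meta, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  lp <- if (!is.null(meta$line_period)) as.numeric(meta$line_period) else NULL
  meta$line_period <- NULL
  spectral_cube(a, wl, line_period = lp, meta = meta)
}

#' Write a cube as an ENVI header/binary pair
#'
#' @param cube A [spectral_cube].
#' @param path Output path; `.hdr` is appended for the header and the binary
#'   is written at `path` itself (so `write_envi(cube, "x.dat")` produces
#'   `x.dat` + `x.dat.hdr`). Passing a `.hdr` path writes the binary at the
#'   stem.
#' @param interleave One of `"bil"` (default; native for push-broom
#'   acquisition), `"bsq"`, `"bip"`.
#' @param data_type Sample encoding: `"float32"` (default), `"float64"`,
#'   `"uint16"` or `"int16"`. Integer encodings round; reflectance data should
#'   stay in float.
#' @return Invisibly, the header path.
#' @export
write_envi <- function(cube, path, interleave = "bil", data_type = "float32") {
  validate_cube(cube)
  interleave <- match.arg(tolower(interleave), c("bil", "bsq", "bip"))
  code <- .envi_dtype_code(data_type)
  dt <- .envi_dtypes[[as.character(code)]]
  if (grepl("\\.hdr$", path, ignore.case = TRUE)) {
    hdr <- path
    bin <- sub("\\.hdr$", "", path, ignore.case = TRUE)
  } else {
    bin <- path
    hdr <- paste0(path, ".hdr")
  }
  d <- dim(cube$values)
  lines <- c(
    "ENVI",
    "file type = ENVI Standard",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    sprintf("data type = %d", code),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {\n%s\n}",
            paste(strwrap(paste(format(cube$wavelengths, digits = 17,
                                       trim = TRUE, scientific = FALSE),
                                collapse = ", "), width = 76),
                  collapse = "\n")))
  if (!is.null(cube$line_period))
    lines <- c(lines, sprintf("line_period = %s",
                              format(cube$line_period, digits = 17)))
  for (k in names(cube$meta)) {
    v <- cube$meta[[k]]
    if (is.atomic(v) && length(v) == 1L && !is.na(v))
      lines <- c(lines, sprintf("%s = %s", k, format(v, digits = 17)))
  }
  writeLines(lines, hdr)

  v <- switch(interleave,
    bil = aperm(cube$values, c(2L, 3L, 1L)),
    bsq = aperm(cube$values, c(2L, 1L, 3L)),
    bip = aperm(cube$values, c(3L, 2L, 1L)))
  con <- file(bin, "wb")
  on.exit(close(con))
  if (dt$what == "integer") {
    vi <- as.integer(round(as.vector(v)))
    if (dt$name == "uint16" && (any(vi < 0L) || any(vi > 65535L)))
      stop("values out of uint16 range; use a float data type")
    # writeBin() has no unsigned 16-bit mode; values 32768..65535 are stored
    # via their signed two's-complement image, which readBin(signed = FALSE)
    # inverts exactly.
    if (dt$name == "uint16") vi <- ifelse(vi > 32767L, vi - 65536L, vi)
    writeBin(vi, con, size = 2L, endian = "little")
  } else {
    writeBin(as.vector(v), con, size = dt$size, endian = "little")
  }
  invisible(hdr)
}

#' Find the band nearest a wavelength
#'
#' Returns the 1-based position along the band axis of the band centre
#' closest to `wavelength`; ties resolve to the lower wavelength.
#'
#' @param cube A [spectral_cube] (or anything with a `$wavelengths` field).
#' @param wavelength Query wavelength in nm. Must lie within the cube's
#'   wavelength range extended by half the mean band spacing.
#' @return Integer band position.
#' @export
band_index <- function(cube, wavelength) {
  wl <- if (is.numeric(cube)) cube else cube$wavelengths
  half <- mean(diff(wl)) / 2
  lo <- min(wl) - half; hi <- max(wl) + half
  if (wavelength < lo || wavelength > hi)
    stop(sprintf("wavelength %.6g nm outside valid range [%.6g, %.6g] nm",
                 wavelength, lo, hi))
  # which.min returns the first (= lower-wavelength) minimiser on ties
  which.min(abs(wl - wavelength))
}

#' Render a cube as a colour image
#'
#' Extracts the nearest bands to the requested red/green/blue wavelengths and
#' percentile-stretches them to `[0, 1]`. The default band triple
#' (640, 540, 460 nm) picks representative red, green and blue regions of a
#' 400-900 nm axis. With the default `"joint"` stretch the percentiles are
#' computed over the three planes pooled and one affine map is applied to all
#' channels, so relative band brightness — e.g. the blue-green water tint of
#' uncorrected radiance — is preserved in the rendering; `"per_channel"`
#' stretches each channel independently (maximum contrast, but any per-band
#' gain, tint included, cancels). The raw cube planes are never modified.
#'
#' @param cube A [spectral_cube] or [reflectance_cube][to_reflectance].
#' @param rgb_wavelengths Length-3 numeric, nm, in R, G, B order.
#' @param stretch Length-2 percentile pair (lower, upper) for the contrast
#'   stretch, in percent.
#' @param stretch_mode `"joint"` (default) or `"per_channel"`.
#' @return A `color_image`: numeric array `[line, sample, 3]` in `[0, 1]`,
#'   channels ordered R, G, B.
#' @export
to_rgb <- function(cube, rgb_wavelengths = c(640, 540, 460),
                   stretch = c(2, 98),
                   stretch_mode = c("joint", "per_channel")) {
  stopifnot(length(rgb_wavelengths) == 3L, length(stretch) == 2L)
  stretch_mode <- match.arg(stretch_mode)
  d <- dim(cube$values)
  img <- array(0, c(d[1], d[2], 3L))
  planes <- lapply(1:3, function(ch)
    matrix(cube$values[, , band_index(cube, rgb_wavelengths[ch]), drop = TRUE],
           d[1], d[2]))
  if (stretch_mode == "joint") {
    q <- stats::quantile(unlist(planes), stretch / 100, names = FALSE)
    if (q[2] <= q[1]) {
      warning("image is constant after stretch; rendered black")
    } else {
      for (ch in 1:3)
        img[, , ch] <- pmin(1, pmax(0, (planes[[ch]] - q[1]) / (q[2] - q[1])))
    }
  } else {
    for (ch in 1:3) {
      q <- stats::quantile(planes[[ch]], stretch / 100, names = FALSE)
      if (q[2] <= q[1]) {
        warning(sprintf(
          "channel %d (%g nm) is constant after stretch; mapped to 0",
          ch, rgb_wavelengths[ch]))
        next
      }
      img[, , ch] <- pmin(1, pmax(0, (planes[[ch]] - q[1]) / (q[2] - q[1])))
    }
  }
  structure(img, class = "color_image",
            rgb_wavelengths = rgb_wavelengths, stretch = stretch,
            stretch_mode = stretch_mode)
}

#' Resample an image so displayed pixels are square
#'
#' Push-broom transect pixels are strongly anisotropic (e.g. 0.2 cm across
#' the line of view by 2 cm along the swim direction at 1 m altitude and
#' 20 m/min); this stretches the image so both axes share the finer pixel
#' size. Colour images are linearly interpolated; label maps use
#' nearest-neighbour so no new labels appear.
#'
#' @param image A `color_image`, a plain matrix, or a [label_map].
#' @param pixel_size Length-2 numeric `(transverse, lateral)` in any common
#'   unit (cm): transverse = along-track line spacing (line axis), lateral =
#'   across-track size (sample axis).
#' @return Resampled object of the same kind.
#' @export
rectify_aspect <- function(image, pixel_size) {
  stopifnot(length(pixel_size) == 2L, all(pixel_size > 0))
  target <- min(pixel_size)
  f <- pixel_size / target  # (line factor, sample factor), >= 1
  is_label <- inherits(image, "label_map")
  vals <- if (is_label) image$values else unclass(image)
  d <- dim(vals)
  L2 <- max(1L, as.integer(round(d[1] * f[1])))
  S2 <- max(1L, as.integer(round(d[2] * f[2])))
  # output pixel centres mapped back into input index space (extent preserved)
  src_l <- (seq_len(L2) - 0.5) * d[1] / L2 + 0.5
  src_s <- (seq_len(S2) - 0.5) * d[2] / S2 + 0.5
  resample1 <- function(m, idx, nearest) {
    # interpolate rows of matrix m at fractional row positions idx
    if (nearest) return(m[pmin(nrow(m), pmax(1L, round(idx))), , drop = FALSE])
    i0 <- pmin(nrow(m) - 1L, pmax(1L, floor(idx)))
    w <- pmin(1, pmax(0, idx - i0))
    m[i0, , drop = FALSE] * (1 - w) + m[i0 + 1L, , drop = FALSE] * w
  }
  rs2d <- function(m, nearest) {
    m2 <- resample1(m, src_l, nearest)
    t(resample1(t(m2), src_s, nearest))
  }
  if (is_label) {
    out <- image
    out$values <- rs2d(vals, nearest = TRUE)
    return(out)
  }
  if (length(d) == 3L) {
    out <- array(0, c(L2, S2, d[3]))
    for (ch in seq_len(d[3])) out[, , ch] <- rs2d(vals[, , ch], nearest = FALSE)
    attrs <- attributes(image)
    return(structure(out, class = attr(image, "class"),
                     rgb_wavelengths = attrs$rgb_wavelengths,
                     stretch = attrs$stretch,
                     stretch_mode = attrs$stretch_mode))
  }
  rs2d(vals, nearest = FALSE)
}

#' Export a colour image as PNG
#'
#' @param image A `color_image` from [to_rgb()] or [true_color()].
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_color_png <- function(image, path) {
  png::writePNG(unclass(image), path)
  invisible(path)
}
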