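# Sparse polygon annotations and their per-pixel rasterization.
#
# Annotations mark small scene regions with a benthic class (coral genus,
# sediment, turf, the reference board, ...). Image coordinates are 0-based
# (line, sample); a pixel is labelled when its centre (integer coordinates)
# falls inside the polygon under the even-odd rule, boundary included.

#' Construct an annotation set
#'
#' @param regions List of regions; each region is a list with `label`
#'   (non-empty class name) and `vertices` (numeric matrix, >= 3 rows, of
#'   `(line, sample)` 0-based coordinates).
#' @param image_id Identifier of the source image.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(regions, image_id = "image") {
  regions <- lapply(regions, function(r) {
    v <- as.matrix(r$vertices)
    storage.mode(v) <- "double"
    if (nrow(v) < 3L) stop("polygon must have >= 3 vertices")
    if (is.null(r$label) || !nzchar(r$label)) stop("region label must be non-empty")
    list(label = as.character(r$label), vertices = v)
  })
  structure(list(regions = regions, image_id = as.character(image_id)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  labs <- vapply(x$regions, `[[`, "", "label")
  cat(sprintf("<annotation_set> image '%s': %d regions, %d classes\n",
              x$image_id, length(labs), length(unique(labs))))
  if (length(labs)) print(table(labs))
  invisible(x)
}

#' Read / write annotation JSON
#'
#' Schema: `{"image_id": ..., "regions": [{"label": ..., "vertices":
#' [[line, sample], ...]}, ...]}` with 0-based image coordinates.
#'
#' @param path JSON file path.
#' @return `read_annotations` returns an [annotation_set];
#'   `write_annotations` invisibly returns `path`.
#' @export
read_annotations <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  regions <- lapply(j$regions, function(r) {
    v <- do.call(rbind, lapply(r$vertices, function(p) as.numeric(unlist(p))))
    list(label = r$label, vertices = v)
  })
  annotation_set(regions, image_id = if (is.null(j$image_id)) "image" else j$image_id)
}

#' @rdname read_annotations
#' @param annotations An [annotation_set].
#' @export
write_annotations <- function(annotations, path) {
  out <- list(
    image_id = annotations$image_id,
    regions = lapply(annotations$regions, function(r)
      list(label = r$label,
           vertices = lapply(seq_len(nrow(r$vertices)),
                             function(i) as.numeric(r$vertices[i, ])))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a label map
#'
#' @param values Integer matrix `[line, sample]` of class indices; 0 is the
#'   reserved sentinel for unlabeled pixels.
#' @param legend Character vector mapping index `i` to `legend[i]`.
#' @return An object of class `label_map`.
#' @export
label_map <- function(values, legend) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  present <- setdiff(unique(as.vector(values)), 0L)
  if (length(present) && max(present) > length(legend))
    stop("label index ", max(present), " missing from legend")
  structure(list(values = values, legend = as.character(legend)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d, %d classes, %.1f%% labelled\n",
              nrow(x$values), ncol(x$values), length(x$legend),
              100 * mean(x$values != 0L)))
  invisible(x)
}

# Even-odd point-in-polygon over the pixel grid, boundary-inclusive.
# poly: matrix of (line, sample) vertices; shape: c(L, S). Pixel centres sit
# at integer 0-based (line, sample). Returns logical [L, S] mask.
.polygon_mask <- function(poly, shape, eps = 1e-9) {
  L <- shape[1]; S <- shape[2]
  lr <- range(poly[, 1]); sr <- range(poly[, 2])
  l0 <- max(0L, floor(lr[1])); l1 <- min(L - 1L, ceiling(lr[2]))
  s0 <- max(0L, floor(sr[1])); s1 <- min(S - 1L, ceiling(sr[2]))
  mask <- matrix(FALSE, L, S)
  if (l0 > l1 || s0 > s1) return(mask)
  gl <- rep(l0:l1, times = s1 - s0 + 1L)
  gs <- rep(s0:s1, each = l1 - l0 + 1L)
  inside <- rep(FALSE, length(gl))
  onedge <- rep(FALSE, length(gl))
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[j, 1]; y2 <- poly[j, 2]
    # boundary test: collinear and within the segment's bounding box
    cross <- (x2 - x1) * (gs - y1) - (y2 - y1) * (gl - x1)
    seglen <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    if (seglen > 0) {
      coll <- abs(cross) <= eps * max(1, seglen) &
        gl >= min(x1, x2) - eps & gl <= max(x1, x2) + eps &
        gs >= min(y1, y2) - eps & gs <= max(y1, y2) + eps
      onedge <- onedge | coll
    }
    # even-odd ray crossing in +sample direction
    crosses <- ((x1 > gl) != (x2 > gl))
    if (any(crosses)) {
      ys <- y1 + (gl - x1) / (x2 - x1) * (y2 - y1)
      inside <- xor(inside, crosses & (gs < ys))
    }
  }
  mask[cbind(gl + 1L, gs + 1L)] <- inside | onedge
  mask
}

.polygon_area <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1L)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

#' Rasterize polygon annotations to a label map
#'
#' Pixel centres inside any polygon (even-odd rule, boundary-inclusive)
#' receive that polygon's class index; where polygons overlap, the
#' last-listed polygon wins. All other pixels carry the unlabeled sentinel 0.
#' Zero-area polygons are skipped with a warning.
#'
#' @param annotations An [annotation_set].
#' @param shape Length-2 integer `(lines, samples)`.
#' @return A [label_map]; the legend lists classes in order of first
#'   appearance in `annotations`.
#' @export
rasterize_annotations <- function(annotations, shape) {
  stopifnot(length(shape) == 2L)
  labs <- vapply(annotations$regions, `[[`, "", "label")
  legend <- unique(labs)
  vals <- matrix(0L, shape[1], shape[2])
  for (r in annotations$regions) {
    if (.polygon_area(r$vertices) == 0) {
      warning("degenerate (zero-area) polygon for class '", r$label,
              "' skipped")
      next
    }
    m <- .polygon_mask(r$vertices, shape)
    vals[m] <- match(r$label, legend)
  }
  out <- label_map(vals, legend)
  attr(out, "image_id") <- annotations$image_id
  out
}

#' Export a label map as an indexed PNG plus JSON legend
#'
#' @param labels A [label_map].
#' @param path Output PNG path; the legend is written beside it as
#'   `<path>.legend.json`.
#' @param palette Optional vector of colours, one per legend entry; defaults
#'   to `grDevices::hcl.colors`. Sentinel pixels render black.
#' @return Invisibly, `path`.
#' @export
write_label_png <- function(labels, path, palette = NULL) {
  k <- length(labels$legend)
  if (is.null(palette)) palette <- grDevices::hcl.colors(max(k, 2L), "Spectral")
  cols <- rbind(c(0, 0, 0), t(grDevices::col2rgb(palette[seq_len(k)]) / 255))
  idx <- labels$values + 1L
  d <- dim(labels$values)
  img <- array(0, c(d[1], d[2], 3L))
  for (ch in 1:3) img[, , ch] <- matrix(cols[idx, ch], d[1], d[2])
  png::writePNG(img, path)
  jsonlite::write_json(
    list(legend = as.list(stats::setNames(seq_len(k), labels$legend)),
         sentinel = 0L),
    paste0(path, ".legend.json"), auto_unbox = TRUE)
  invisible(path)
}
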