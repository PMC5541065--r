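# Synthetic underwater transect scene simulator.
#
# Generates hyperspectral transect cubes with known ground truth so that
# every stage of the pipeline — reference correction, derivative indices,
# topography, classification — can be validated without field data. The
# forward model per pixel p of class c at line altitude h is
#
#   I(p, lambda) = E(lambda) * exp(-2 * Kd(lambda) * h) * R_c(lambda) * (1 + eps)
#
# with downwelling illumination E, diffuse attenuation Kd (the factor 2
# approximates the down-and-back path of bottom-reflected light), class
# endmember reflectance R_c, and multiplicative Gaussian noise
# eps ~ N(0, 1/SNR) (shot-noise-like proportionality). The gray board is a
# spectrally flat region of known albedo. A matching 1 Hz sensor track is
# derived from the prescribed seafloor function and altitude profile.
# Deliberately omitted: surface glint, inter-pixel scattering, bidirectional
# reflectance.

#' Define a synthetic benthic class
#'
#' The endmember reflectance is a smooth baseline minus Gaussian absorption
#' features plus a red-edge ramp:
#' `R(lambda) = baseline - sum(depth * exp(-(lambda-center)^2 / (2*width^2)))
#' + slope * max(0, lambda - 690)`, clipped to >= 0.001.
#'
#' @param name Class name.
#' @param baseline Featureless reflectance level (0-1).
#' @param features List of length-3 vectors `(center_nm, width_nm, depth)`;
#'   depths must lie in `[0, baseline]`.
#' @param red_edge_slope Reflectance increase per nm beyond 690 nm.
#' @param n_blobs,blob_lines,blob_samples Layout parameters: number of
#'   elliptical patches and their semi-axis ranges (pixels) along the line and
#'   sample axes. Ignored for the background class.
#' @return A `scene_class` list.
#' @export
scene_class <- function(name, baseline, features = list(),
                        red_edge_slope = 0, n_blobs = 3L,
                        blob_lines = c(8, 16), blob_samples = c(20, 45)) {
  for (f in features)
    if (f[3] < 0 || f[3] > baseline)
      stop("feature depth must lie in [0, baseline] for class '", name, "'")
  structure(list(name = name, baseline = baseline, features = features,
                 red_edge_slope = red_edge_slope, n_blobs = as.integer(n_blobs),
                 blob_lines = blob_lines, blob_samples = blob_samples),
            class = "scene_class")
}

#' Endmember reflectance spectrum of a scene class
#'
#' @param cls A [scene_class].
#' @param wavelengths Band centres, nm.
#' @return Numeric reflectance spectrum, clipped to >= 0.001.
#' @export
build_endmember <- function(cls, wavelengths) {
  r <- rep(cls$baseline, length(wavelengths))
  for (f in cls$features)
    r <- r - f[3] * exp(-(wavelengths - f[1])^2 / (2 * f[2]^2))
  r <- r + cls$red_edge_slope * pmax(0, wavelengths - 690)
  pmax(r, 0.001)
}

#' Default diffuse attenuation spectrum
#'
#' A smooth clear-water-like Kd(lambda) curve rising from 0.03 m^-1 at
#' 400 nm through 0.5 m^-1 at 700 nm to 2.5 m^-1 at 900 nm (monotone spline
#' through fixed anchors; fixture constants, not a claim about any site).
#'
#' @param wavelengths Band centres, nm.
#' @return Kd per band, 1/m.
#' @export
default_kd <- function(wavelengths) {
  anchors_wl <- c(400, 500, 600, 700, 800, 900)
  anchors_kd <- c(0.03, 0.06, 0.18, 0.5, 1.3, 2.5)
  stats::splinefun(anchors_wl, anchors_kd, method = "hyman")(wavelengths)
}

#' Default downwelling illumination spectrum
#'
#' A broad daylight-like curve peaking in the blue-green (arbitrary linear
#' radiance units).
#'
#' @param wavelengths Band centres, nm.
#' @return Relative spectral irradiance per band.
#' @export
default_illumination <- function(wavelengths) {
  1.0 * exp(-((wavelengths - 520) / 260)^2) + 0.1
}

#' Parameterize a synthetic transect scene
#'
#' @param shape `(lines, samples)`.
#' @param wavelengths Band centres, nm (default 480 bands over 400-900 nm).
#' @param classes List of [scene_class] objects; must include `background`.
#' @param background Name of the class filling unoccupied pixels.
#' @param board List `list(lines = c(l0, l1), samples = c(s0, s1), albedo)`
#'   defining the gray reference board rectangle (0-based, inclusive) and its
#'   albedo; `NULL` for no board.
#' @param illumination Per-band downwelling spectrum (vector) or function of
#'   wavelengths.
#' @param kd Per-band diffuse attenuation, 1/m (vector or function).
#' @param altitude Per-line imaging altitude, m: scalar, vector of length
#'   `lines`, or function of the 0-1 along-track fraction.
#' @param seafloor Function mapping along-track distance (m) to bottom depth
#'   (m, positive down).
#' @param transect_length Transect length, m.
#' @param line_period Seconds between lines.
#' @param snr Signal-to-noise ratio of the multiplicative noise; `Inf`
#'   disables noise.
#' @param seed Integer seed (mandatory; layout, noise and the sensor track
#'   are all reproducible from it).
#' @param layout_map Optional explicit [label_map] bypassing blob placement
#'   (its legend must name the classes).
#' @param layout_polygons Optional [annotation_set] of explicit class
#'   polygons drawn over the background (alternative to blobs).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(shape, wavelengths = seq(400, 900, length.out = 480),
                       classes, background, board = NULL,
                       illumination = default_illumination,
                       kd = default_kd,
                       altitude = 1.0,
                       seafloor = function(x) rep(5, length(x)),
                       transect_length = shape[1] * 0.02,
                       line_period = 0.06, snr = 50, seed,
                       layout_map = NULL, layout_polygons = NULL) {
  if (missing(seed)) stop("a seed is mandatory for a scene spec")
  nms <- vapply(classes, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate class names")
  if (!background %in% nms) stop("background class '", background,
                                 "' not among the classes")
  if (is.function(illumination)) illumination <- illumination(wavelengths)
  if (is.function(kd)) kd <- kd(wavelengths)
  if (any(kd < 0)) stop("Kd must be >= 0")
  L <- shape[1]
  alt <- if (is.function(altitude)) altitude(seq(0, 1, length.out = L))
         else if (length(altitude) == 1L) rep(altitude, L)
         else altitude
  if (length(alt) != L) stop("altitude profile length must equal lines")
  structure(list(shape = as.integer(shape), wavelengths = wavelengths,
                 classes = classes, background = background, board = board,
                 illumination = illumination, kd = kd, altitude = alt,
                 seafloor = seafloor, transect_length = transect_length,
                 line_period = line_period, snr = snr,
                 seed = as.integer(seed), layout_map = layout_map,
                 layout_polygons = layout_polygons),
            class = "scene_spec")
}

# place non-background classes as non-overlapping axis-aligned ellipses
.place_layout <- function(spec) {
  L <- spec$shape[1]; S <- spec$shape[2]
  nms <- vapply(spec$classes, `[[`, "", "name")
  vals <- matrix(match(spec$background, nms), L, S)
  free <- matrix(TRUE, L, S)
  if (!is.null(spec$board)) {
    bl <- spec$board$lines; bs <- spec$board$samples
    vals[(bl[1]:bl[2]) + 1L, (bs[1]:bs[2]) + 1L] <- match("Reference", nms)
    free[(bl[1]:bl[2]) + 1L, (bs[1]:bs[2]) + 1L] <- FALSE
  }
  if (!is.null(spec$layout_polygons)) {
    for (r in spec$layout_polygons$regions) {
      m <- .polygon_mask(r$vertices, c(L, S))
      vals[m & free] <- match(r$label, nms)
      free <- free & !m
    }
    return(label_map(vals, nms))
  }
  for (ci in seq_along(spec$classes)) {
    cls <- spec$classes[[ci]]
    if (cls$name == spec$background || cls$name == "Reference") next
    for (b in seq_len(cls$n_blobs)) {
      placed <- FALSE
      for (try in 1:300) {
        rl <- stats::runif(1, cls$blob_lines[1], cls$blob_lines[2])
        rs <- stats::runif(1, cls$blob_samples[1], cls$blob_samples[2])
        cl <- stats::runif(1, rl, L - 1 - rl)
        cs <- stats::runif(1, rs, S - 1 - rs)
        ll <- max(0, floor(cl - rl)):min(L - 1, ceiling(cl + rl))
        ss <- max(0, floor(cs - rs)):min(S - 1, ceiling(cs + rs))
        gl <- rep(ll, times = length(ss)); gs <- rep(ss, each = length(ll))
        inside <- ((gl - cl) / rl)^2 + ((gs - cs) / rs)^2 <= 1
        px <- cbind(gl[inside] + 1L, gs[inside] + 1L)
        if (all(free[px])) {
          vals[px] <- ci
          free[px] <- FALSE
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("layout overflow: could not place blob ", b, " of class '",
             cls$name, "' without overlap")
    }
  }
  label_map(vals, nms)
}

#' Generate a synthetic transect scene
#'
#' Runs the forward model for a [scene_spec]: class layout (or the explicit
#' one in the spec), per-line illumination x attenuation, endmember
#' reflectances, multiplicative noise, plus the matching 1 Hz sensor track.
#' Bit-identical for a fixed seed.
#'
#' @param spec A [scene_spec].
#' @return List with `cube` ([spectral_cube], radiance), `truth`
#'   ([label_map] of true classes, no sentinel), `track` ([sensor_track]),
#'   `board_region` (rectangle polygon, or `NULL`), `endmembers`
#'   (class x band reflectance matrix), and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  L <- spec$shape[1]; S <- spec$shape[2]; B <- length(spec$wavelengths)
  nms <- vapply(spec$classes, `[[`, "", "name")
  with_seed(spec$seed, {
    truth <- if (!is.null(spec$layout_map)) spec$layout_map else .place_layout(spec)
    EM <- t(vapply(spec$classes, build_endmember, numeric(B),
                   wavelengths = spec$wavelengths))
    rownames(EM) <- nms
    if (!is.null(spec$board) && "Reference" %in% nms)
      EM["Reference", ] <- spec$board$albedo
    # atten[l, b] = E(b) * exp(-2 * Kd(b) * h_l)
    atten <- exp(outer(-2 * spec$altitude, spec$kd))
    atten <- sweep(atten, 2L, spec$illumination, `*`)
    vals <- array(0, c(L, S, B))
    cls_idx <- truth$values
    for (l in seq_len(L)) {
      refl <- EM[cls_idx[l, ], , drop = FALSE]        # S x B
      vals[l, , ] <- refl * rep(atten[l, ], each = S)
    }
    if (is.finite(spec$snr))
      vals <- vals * (1 + stats::rnorm(length(vals), sd = 1 / spec$snr))
    cube <- spectral_cube(vals, spec$wavelengths,
                          line_period = spec$line_period,
                          meta = list(scene_seed = spec$seed,
                                      snr = spec$snr,
                                      mean_altitude_m = mean(spec$altitude)))
    duration <- L * spec$line_period
    t_s <- if (duration >= 1) seq(0, floor(duration)) else c(0, duration)
    x <- spec$transect_length * t_s / max(t_s)
    frac <- t_s / max(t_s)
    alt_t <- stats::approx(seq(0, 1, length.out = L), spec$altitude,
                           xout = frac)$y
    bottom <- spec$seafloor(x)
    track <- sensor_track(
      t_s, depth = bottom - alt_t, altitude = alt_t,
      par = 1500 * exp(-0.08 * pmax(bottom - alt_t, 0)),
      o2 = 6.8 + 0.1 * sin(2 * pi * frac),
      ph = 8.1 + 0.02 * sin(2 * pi * frac + 1))
    board_region <- NULL
    if (!is.null(spec$board)) {
      bl <- spec$board$lines; bs <- spec$board$samples
      board_region <- cbind(c(bl[1], bl[1], bl[2], bl[2]),
                            c(bs[1], bs[2], bs[2], bs[1]))
    }
    list(cube = cube, truth = truth, track = track,
         board_region = board_region, endmembers = EM, spec = spec)
  })
}

#' Sample sparse rectangular annotations from a truth map
#'
#' Emulates a sparse manual annotation effort: small rectangles strictly
#' inside each class's true region, totalling approximately
#' `per_class_fraction` of the scene's pixels, with every class represented
#' (the board class carries the reserved label `"Reference"`). Deterministic
#' for a fixed seed.
#'
#' @param truth A [label_map] with no sentinel pixels.
#' @param per_class_fraction Target annotated fraction of total pixels
#'   (default 0.018).
#' @param seed Integer seed.
#' @param image_id Image identifier recorded in the annotation set.
#' @param rect_lines,rect_samples Rectangle side ranges, pixels.
#' @param allocation `"equal"` (default) divides the pixel budget evenly
#'   over the classes present — emulating an annotator aiming for broad,
#'   balanced coverage — while `"proportional"` allocates by class area.
#' @return An [annotation_set].
#' @export
sparse_annotations <- function(truth, per_class_fraction = 0.018, seed = 0L,
                               image_id = "synthetic",
                               rect_lines = c(3, 6), rect_samples = c(4, 10),
                               allocation = c("equal", "proportional")) {
  allocation <- match.arg(allocation)
  vals <- truth$values
  L <- nrow(vals); S <- ncol(vals); total <- L * S
  counts <- table(factor(vals, levels = seq_along(truth$legend)))
  small <- truth$legend[counts < 50L & counts > 0L]
  if (length(small))
    stop("class(es) too small to annotate (< 50 pixels): ",
         paste(small, collapse = ", "))
  present <- which(counts > 0L)
  min_area <- (rect_lines[1] + 1L) * (rect_samples[1] + 1L)
  regions <- list()
  with_seed(seed, {
    for (ci in present) {
      target <- if (allocation == "equal")
        per_class_fraction * total / length(present)
      else per_class_fraction * as.integer(counts[ci])
      got <- 0L
      cls_px <- which(vals == ci)
      taken <- matrix(FALSE, L, S)
      attempts <- 0L
      while (got < target && attempts < 4000L) {
        attempts <- attempts + 1L
        # shrink to the minimum rectangle near the budget to limit overshoot
        near_budget <- (target - got) < 2L * min_area
        hl <- if (near_budget) rect_lines[1] else
          sample(rect_lines[1]:rect_lines[2], 1L)
        ws <- if (near_budget) rect_samples[1] else
          sample(rect_samples[1]:rect_samples[2], 1L)
        p <- cls_px[sample.int(length(cls_px), 1L)]
        l0 <- (p - 1L) %% L; s0 <- (p - 1L) %/% L
        if (l0 + hl > L - 1L || s0 + ws > S - 1L) next
        block <- vals[(l0:(l0 + hl)) + 1L, (s0:(s0 + ws)) + 1L]
        if (!all(block == ci)) next
        if (any(taken[(l0:(l0 + hl)) + 1L, (s0:(s0 + ws)) + 1L])) next
        taken[(l0:(l0 + hl)) + 1L, (s0:(s0 + ws)) + 1L] <- TRUE
        regions[[length(regions) + 1L]] <- list(
          label = truth$legend[ci],
          vertices = cbind(c(l0, l0, l0 + hl, l0 + hl),
                           c(s0, s0 + ws, s0 + ws, s0)))
        got <- got + (hl + 1L) * (ws + 1L)
      }
      if (got == 0L)
        stop("could not place any annotation inside class '",
             truth$legend[ci], "'")
    }
  })
  annotation_set(regions, image_id = image_id)
}

#' The reference 11-class synthetic reef scene
#'
#' A 200 x 640 x 480-band transect emulating a shallow reef survey at ~1 m
#' altitude: ten benthic classes on a sediment background plus the gray
#' reference board ("Reference"), SNR 50, seed 0. Massive corals carry a
#' 580 nm chromoprotein dip; sediment carries the 605 nm phycoerythrin
#' feature; all photosynthetic classes share chlorophyll absorption at
#' 670 nm (and 440 nm) with class-specific depths and red-edge slopes, so
#' several corals are nearly indistinguishable in broadband colour but
#' separable at full spectral resolution.
#'
#' @param snr Signal-to-noise ratio (default 50).
#' @param seed Scene seed (default 0).
#' @param shape Scene shape (default `c(200, 640)`).
#' @return A [scene_spec].
#' @export
reef11_spec <- function(snr = 50, seed = 0L, shape = c(200L, 640L)) {
  # the seven coral classes share one broadband "chassis" (baseline 0.28,
  # 440 nm Soret-band dip 0.10) and differ only in narrow features — 670 nm
  # chlorophyll depth, the 580 nm chromoprotein (massive corals), red-edge
  # slope — so broadband colour barely separates them while the full
  # spectrum does, as observed on real reef transects
  coral <- function(name, d670, slope, extra = list(), w670 = 12)
    scene_class(name, 0.28,
                c(list(c(440, 15, 0.10), c(670, w670, d670)), extra),
                red_edge_slope = slope, n_blobs = 3L)
  classes <- list(
    coral("Acropora",    0.12, 0.0020),
    coral("Briareum",    0.10, 0.0012, list(c(500, 20, 0.04))),
    coral("Echinopora",  0.14, 0.0018),
    coral("Goniopora",   0.16, 0.0022, w670 = 14),
    coral("Isopora",     0.11, 0.0016, w670 = 10),
    coral("Pocillopora", 0.13, 0.0019, list(c(580, 10, 0.06))),
    coral("Porites",     0.15, 0.0021, list(c(580, 10, 0.08))),
    scene_class("Reference",   0.50),
    scene_class("Sediment",    0.45, list(c(605, 12, 0.05), c(670, 15, 0.04))),
    coral("Seriatopora", 0.10, 0.0024),
    scene_class("Turf",        0.18, list(c(440, 18, 0.06), c(620, 15, 0.05),
                                          c(670, 12, 0.09)),
                red_edge_slope = 0.0008, n_blobs = 4L))
  scene_spec(
    shape = shape,
    classes = classes,
    background = "Sediment",
    board = list(lines = c(5L, 34L), samples = c(10L, 49L), albedo = 0.5),
    altitude = function(f) 1 + 0.15 * sin(2 * pi * 2 * f),
    seafloor = function(x) 5 + 0.4 * sin(2 * pi * 1.5 * x / 4) +
      0.15 * sin(2 * pi * x / 1.3),
    transect_length = shape[1] * 0.02,
    line_period = 0.06,
    snr = snr, seed = seed)
}

#' Derive the elevated-altitude twin of a scene
#'
#' Re-imaging the same seafloor from a higher altitude widens the swath, so
#' the same content occupies a narrower central strip of the 640-sample line
#' (the margins image previously unseen background) and the water column
#' attenuates the spectra more strongly. This helper rebuilds the spec with
#' the altitude profile scaled by `altitude_factor`, the true layout
#' laterally compressed by `swath_factor` around the centre, and a distinct
#' noise seed — the physical scene is unchanged, only the acquisition.
#'
#' @param spec The normal-altitude [scene_spec].
#' @param altitude_factor Multiplier on the altitude profile (default 2).
#' @param swath_factor Swath widening factor (default 1.5).
#' @param seed Seed for the elevated acquisition's noise (default
#'   `spec$seed + 1`).
#' @return A [scene_spec] with an explicit `layout_map`.
#' @export
elevate_scene <- function(spec, altitude_factor = 2, swath_factor = 1.5,
                          seed = spec$seed + 1L) {
  base <- generate_scene(spec)   # deterministic layout from spec$seed
  vals <- base$truth$values
  L <- nrow(vals); S <- ncol(vals)
  nms <- base$truth$legend
  bg <- match(spec$background, nms)
  out <- matrix(bg, L, S)
  # output sample s maps to source sample (s - centre)/ (1/swath) + centre
  centre <- (S - 1) / 2
  src <- round((seq_len(S) - 1 - centre) * swath_factor + centre)
  ok <- src >= 0 & src <= S - 1
  out[, ok] <- vals[, src[ok] + 1L]
  # the board is re-deployed for the second pass at the same location in the
  # compressed frame: keep whatever the compression maps there
  spec2 <- spec
  spec2$altitude <- spec$altitude * altitude_factor
  spec2$seed <- as.integer(seed)
  spec2$layout_map <- label_map(out, nms)
  spec2$board <- .board_from_map(spec2$layout_map, spec$board)
  spec2
}

# recover the (rectangular) board bounding box after lateral resampling
.board_from_map <- function(lmap, board) {
  if (is.null(board)) return(NULL)
  ref <- match("Reference", lmap$legend)
  px <- which(lmap$values == ref, arr.ind = TRUE)
  if (!nrow(px)) return(NULL)
  list(lines = c(min(px[, 1]) - 1L, max(px[, 1]) - 1L),
       samples = c(min(px[, 2]) - 1L, max(px[, 2]) - 1L),
       albedo = board$albedo)
}

#' Write all artifacts of a synthetic scene to disk
#'
#' Persists the scene in the same formats the real pipeline reads: ENVI cube,
#' annotation JSON (from [sparse_annotations()]), sensor-track CSV, and a
#' truth-map PNG + legend.
#'
#' @param scene Result of [generate_scene()].
#' @param dir Output directory (created if needed).
#' @param annotation_fraction Fraction for [sparse_annotations()].
#' @return Invisibly, a named list of file paths.
#' @export
write_scene <- function(scene, dir, annotation_fraction = 0.018) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    cube = file.path(dir, "scene.dat"),
    annotations = file.path(dir, "annotations.json"),
    track = file.path(dir, "track.csv"),
    truth = file.path(dir, "truth.png"))
  write_envi(scene$cube, paths$cube, data_type = "float32")
  ann <- sparse_annotations(scene$truth, annotation_fraction,
                            seed = scene$spec$seed,
                            image_id = basename(dir))
  write_annotations(ann, paths$annotations)
  write_sensor_track(scene$track, paths$track)
  write_label_png(scene$truth, paths$truth)
  invisible(paths)
}
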