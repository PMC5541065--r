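# The scene simulator: endmember construction, forward model, determinism,
# sensor tracks, sparse annotation sampling.

test_that("endmember construction matches its closed form", {
  wl <- seq(400, 900, length.out = 480)
  flat <- scene_class("flat", 0.4)
  expect_equal(build_endmember(flat, wl), rep(0.4, 480))
  dip <- scene_class("dip", 0.5, list(c(670, 10, 0.2)))
  em <- build_endmember(dip, wl)
  i <- band_index(list(wavelengths = wl), 670)
  expect_equal(min(em), em[i])
  expect_equal(em[i], 0.5 - 0.2 * exp(-(wl[i] - 670)^2 / 200),
               tolerance = 1e-12)
  # value at centre +/- width equals baseline - depth * exp(-1/2) on a grid
  # holding those wavelengths exactly
  wl10 <- seq(400, 900, by = 10)
  em10 <- build_endmember(dip, wl10)
  for (w in c(660, 680))
    expect_equal(em10[match(w, wl10)], 0.5 - 0.2 * exp(-1 / 2),
                 tolerance = 1e-12)
  # and off-centre bands follow the same closed form
  j <- band_index(list(wavelengths = wl), 660)
  expect_equal(em[j], 0.5 - 0.2 * exp(-(wl[j] - 670)^2 / 200),
               tolerance = 1e-12)
  # red edge ramp and floor clipping
  ramp <- scene_class("r", 0.1, list(c(500, 30, 0.1)), red_edge_slope = 0.002)
  emr <- build_endmember(ramp, wl)
  expect_equal(emr[480], 0.1 + 0.002 * (900 - 690), tolerance = 1e-12)
  expect_true(all(emr >= 0.001))
  expect_error(scene_class("bad", 0.2, list(c(500, 10, 0.5))),
               "\\[0, baseline\\]")
})

test_that("the forward model applies illumination x attenuation x reflectance", {
  spec <- tiny_scene_spec(snr = Inf, seed = 5, altitude = 1.3)
  sc <- generate_scene(spec)
  # pick a sediment pixel and verify against direct evaluation
  ci <- match("Sediment", sc$truth$legend)
  px <- which(sc$truth$values == ci, arr.ind = TRUE)[1, ]
  expected <- spec$illumination * exp(-2 * spec$kd * 1.3) *
    sc$endmembers["Sediment", ]
  expect_equal(as.vector(sc$cube$values[px[1], px[2], ]), expected,
               tolerance = 1e-12)
  # doubling altitude multiplies radiance by exp(-2 Kd h) per band
  spec2 <- tiny_scene_spec(snr = Inf, seed = 5, altitude = 2.6)
  sc2 <- generate_scene(spec2)
  ratio <- sc2$cube$values[px[1], px[2], ] / sc$cube$values[px[1], px[2], ]
  expect_equal(as.vector(ratio), exp(-2 * spec$kd * 1.3), tolerance = 1e-10)
})

test_that("degenerate forward model returns exact endmembers; seeds reproduce", {
  sc <- generate_scene(degenerate_scene_spec(seed = 3))
  for (k in c("CoralA", "Sediment")) {
    ci <- match(k, sc$truth$legend)
    px <- which(sc$truth$values == ci, arr.ind = TRUE)[1, ]
    expect_equal(as.vector(sc$cube$values[px[1], px[2], ]),
                 unname(sc$endmembers[k, ]), tolerance = 1e-14)
  }
  a <- generate_scene(tiny_scene_spec(snr = 30, seed = 9))
  b <- generate_scene(tiny_scene_spec(snr = 30, seed = 9))
  expect_identical(a$cube$values, b$cube$values)
  expect_identical(a$truth$values, b$truth$values)
  c2 <- generate_scene(tiny_scene_spec(snr = 30, seed = 10))
  expect_false(identical(a$cube$values, c2$cube$values))
})

test_that("generated tracks are valid and consistent with the seafloor", {
  sc <- generate_scene(tiny_scene_spec(seed = 2))
  tr <- sc$track
  expect_s3_class(tr, "sensor_track")
  expect_true(all(diff(tr$t_s) > 0))
  expect_true(all(tr$altitude_m > 0))
  expect_true(all(c("par", "o2", "ph") %in% names(tr)))
  expect_equal(tr$depth_m + tr$altitude_m,
               sc$spec$seafloor(sc$spec$transect_length * tr$t_s / max(tr$t_s)),
               tolerance = 1e-12)
})

test_that("pipeline closure: corrected class means match endmembers within 3/SNR", {
  for (snr in c(25, 100)) {
    sc <- generate_scene(tiny_scene_spec(snr = snr, seed = 19))
    rc <- to_reflectance(sc$cube, board_spectrum(sc$cube, sc$board_region),
                         board_albedo = 0.5)
    d <- dim(rc$values)
    flat <- matrix(rc$values, d[1] * d[2], d[3])
    for (k in rownames(sc$endmembers)) {
      sel <- as.vector(sc$truth$values == match(k, sc$truth$legend))
      mu <- colMeans(flat[sel, , drop = FALSE])
      rel_rms <- sqrt(mean((mu / sc$endmembers[k, ] - 1)^2))
      expect_lt(rel_rms, 3 / snr, label = sprintf("%s at SNR %d", k, snr))
    }
  }
})

test_that("sparse annotations stay inside their class and near the target fraction", {
  sc <- generate_scene(tiny_scene_spec(seed = 4))
  ann <- sparse_annotations(sc$truth, 0.018, seed = 5)
  lm <- rasterize_annotations(ann, dim(sc$truth$values))
  frac <- mean(lm$values != 0)
  expect_gte(frac, 0.015)
  expect_lte(frac, 0.021)
  # every class present and 100% agreement with the truth map
  expect_setequal(unique(vapply(ann$regions, `[[`, "", "label")),
                  sc$truth$legend)
  sel <- lm$values != 0
  expect_equal(mean(lm$legend[lm$values[sel]] ==
                      sc$truth$legend[sc$truth$values[sel]]), 1)
  # determinism
  ann2 <- sparse_annotations(sc$truth, 0.018, seed = 5)
  expect_identical(ann, ann2)
  # a class smaller than 50 pixels is refused by name
  tiny_truth <- label_map(matrix(c(rep(1L, 395), rep(2L, 5)), 20, 20),
                          c("big", "tiny"))
  expect_error(sparse_annotations(tiny_truth, 0.018, 0), "tiny")
})

test_that("elevated twin compresses the layout and doubles the altitude", {
  spec <- tiny_scene_spec(seed = 6)
  spec_e <- elevate_scene(spec)
  expect_equal(spec_e$altitude, 2 * spec$altitude)
  sc <- generate_scene(spec)
  sc_e <- generate_scene(spec_e)
  # same classes, content compressed toward the centre: foreground occupies
  # fewer samples in the elevated frame
  fg_n <- match(spec$background, sc$truth$legend)
  expect_lt(sum(sc_e$truth$values != fg_n), sum(sc$truth$values != fg_n))
  expect_identical(sc_e$truth$legend, sc$truth$legend)
  # the centre of the frame maps onto itself (compression is about the centre)
  expect_identical(sc_e$truth$values[, 81], sc$truth$values[, 81])
})

test_that("scene artifacts round-trip through the on-disk formats", {
  sc <- generate_scene(tiny_scene_spec(seed = 8))
  dir <- file.path(tempdir(), "scene-out")
  paths <- write_scene(sc, dir, annotation_fraction = 0.02)
  back <- read_envi(paste0(paths$cube, ".hdr"))
  expect_equal(dim(back$values), dim(sc$cube$values))
  expect_lt(max(abs(back$values - sc$cube$values)), 1e-6)  # float32 storage
  ann <- read_annotations(paths$annotations)
  expect_true("Reference" %in% vapply(ann$regions, `[[`, "", "label"))
  tr <- read_sensor_track(paths$track)
  expect_equal(nrow(tr), nrow(sc$track))
  expect_true(file.exists(paths$truth))
})
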