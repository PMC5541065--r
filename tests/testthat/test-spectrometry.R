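# Savitzky-Golay derivative operators against closed forms, and the four
# pigment/substrate index maps on simulated scenes.

wl480 <- seq(400, 900, length.out = 480)

test_that("derivatives reproduce polynomial closed forms", {
  interior <- 10:470
  lin <- 0.002 * wl480 + 0.1
  d1 <- smooth_derivative(lin, wl480, order = 1)
  expect_equal(d1[interior], rep(0.002, length(interior)), tolerance = 1e-9)
  d2 <- smooth_derivative(lin, wl480, order = 2)
  expect_equal(d2[interior], rep(0, length(interior)), tolerance = 1e-9,
               ignore_attr = TRUE)
  quad <- 1e-4 * (wl480 - 650)^2
  d2q <- smooth_derivative(quad, wl480, order = 2)
  expect_equal(d2q[interior], rep(2e-4, length(interior)), tolerance = 1e-9)
  # edges come from one-sided fits of the same polynomial -> still exact
  expect_equal(d2q[1], 2e-4, tolerance = 1e-9)
  expect_equal(d2q[480], 2e-4, tolerance = 1e-9)
})

test_that("Gaussian dip curvature at the centre matches d/sigma^2 within 2%", {
  d <- 0.2; s <- 10
  dip <- 0.5 - d * exp(-(wl480 - 670)^2 / (2 * s^2))
  d2 <- smooth_derivative(dip, wl480, order = 2)
  i <- band_index(list(wavelengths = wl480), 670)
  expect_lt(abs(d2[i] - d / s^2) / (d / s^2), 0.02)
})

test_that("derivative operator is linear to machine precision", {
  set.seed(21)
  r1 <- runif(480); r2 <- runif(480)
  for (ord in 1:2) {
    lhs <- smooth_derivative(3.2 * r1 - 1.7 * r2, wl480, ord)
    rhs <- 3.2 * smooth_derivative(r1, wl480, ord) -
      1.7 * smooth_derivative(r2, wl480, ord)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("uneven wavelength grids are rejected with advice, resampling works", {
  wl_bad <- c(seq(400, 500, by = 1), seq(502, 600, by = 2))
  expect_error(smooth_derivative(runif(length(wl_bad)), wl_bad, 1),
               "resampl")
  rs <- resample_wavelengths(0.001 * wl_bad, wl_bad)
  expect_lt(max(abs(diff(diff(rs$wavelengths)))), 1e-12)
  expect_equal(rs$spectrum, 0.001 * rs$wavelengths, tolerance = 1e-12)
})

test_that("precondition checks on window and polyorder", {
  expect_error(smooth_derivative(runif(480), wl480, 1, window = 6), "odd")
  expect_error(smooth_derivative(runif(480), wl480, 2, window = 7,
                                 polyorder = 1), "polyorder")
  expect_error(smooth_derivative(runif(5), seq(400, 500, length.out = 5), 1,
                                 window = 7), "at least 7 bands")
})

test_that("index_map equals smooth_derivative at the target band", {
  set.seed(31)
  cube <- spectral_cube(array(runif(6 * 5 * 480), c(6, 5, 480)), wl480)
  for (nm in names(index_registry())) {
    spec <- index_registry()[[nm]]
    im <- index_map(cube, nm)
    i <- band_index(cube, spec$wavelength)
    manual <- apply(cube$values, c(1, 2), function(s)
      smooth_derivative(s, wl480, spec$derivative_order)[i])
    if (spec$rectify) manual <- pmax(manual, 0)
    expect_equal(im$values, manual, tolerance = 1e-10, label = nm)
  }
})

test_that("flat-spectrum scene yields identically zero index maps", {
  cube <- spectral_cube(array(0.4, c(4, 6, 480)), wl480)
  for (nm in names(index_registry()))
    expect_equal(max(abs(index_map(cube, nm)$values)), 0, tolerance = 1e-12)
})

test_that("red-edge index separates coral from sediment on a simulated scene", {
  # clean-signal regime: this checks the index contrast itself; noise
  # behaviour is covered by the SNR-monotonicity test in test-radiometry.R
  sc <- generate_scene(tiny_scene_spec(snr = 200, seed = 13))
  rc <- to_reflectance(sc$cube, board_spectrum(sc$cube, sc$board_region), 0.5)
  im <- index_map(rc, "coral_rededge_700")
  coral <- as.vector(sc$truth$values %in%
                       match(c("CoralA", "CoralB"), sc$truth$legend))
  sed <- as.vector(sc$truth$values == match("Sediment", sc$truth$legend))
  v <- as.vector(im$values)
  pooled_sd <- sqrt((var(v[coral]) + var(v[sed])) / 2)
  expect_gt(mean(v[coral]) - mean(v[sed]), 5 * pooled_sd)
  expect_true(all(v >= 0))  # rectified
})

test_that("chlorophyll index is linear in dip depth (2x depth -> 2x index)", {
  depth_index <- function(d) {
    cls <- list(scene_class("X", 0.5, list(c(670, 10, d))),
                scene_class("Bg", 0.5))
    spec <- scene_spec(shape = c(8L, 20L), classes = cls, background = "Bg",
                       layout_polygons = annotation_set(list(list(
                         label = "X",
                         vertices = cbind(c(0, 0, 7, 7), c(0, 9, 9, 0))))),
                       illumination = rep(1, 480), kd = rep(0, 480),
                       snr = Inf, seed = 1)
    sc <- generate_scene(spec)
    im <- index_map(spectral_cube(sc$cube$values, sc$cube$wavelengths),
                    "chl_670")
    xm <- as.vector(sc$truth$values == match("X", sc$truth$legend))
    mean(im$values[matrix(xm, 8, 20)])
  }
  i1 <- depth_index(0.1); i2 <- depth_index(0.2)
  expect_equal(i2 / i1, 2, tolerance = 0.05)
  # monotone in depth over 20 depths
  idx <- vapply(seq(0.01, 0.4, length.out = 20), depth_index, numeric(1))
  expect_true(all(diff(idx) > 0))
})

test_that("index maps are invariant to per-band illumination before correction", {
  sc <- generate_scene(degenerate_scene_spec(seed = 17))
  # two illuminations of the same reflectance scene
  gain <- exp(-((wl480 - 520) / 150)^2) + 0.2
  cube1 <- sc$cube
  cube2 <- spectral_cube(sweep(cube1$values, 3, gain, `*`), wl480)
  rc1 <- to_reflectance(cube1, board_spectrum(cube1, sc$board_region), 0.5)
  rc2 <- to_reflectance(cube2, board_spectrum(cube2, sc$board_region), 0.5)
  im1 <- index_map(rc1, "chl_670"); im2 <- index_map(rc2, "chl_670")
  expect_lt(max(abs(im1$values - im2$values)), 1e-9)
})

test_that("the index registry holds the four documented indices", {
  reg <- index_registry()
  expect_setequal(names(reg),
                  c("chl_670", "coral_rededge_700", "chromo_580", "phyco_605"))
  expect_equal(reg$chl_670$derivative_order, 2L)
  expect_equal(reg$coral_rededge_700$derivative_order, 1L)
  expect_true(reg$coral_rededge_700$rectify)
  expect_false(reg$chl_670$rectify)
  # user extension via config
  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(list(list(name = "peridinin_490", order = 2,
                                 wavelength = 490)),
                       cfg, auto_unbox = TRUE)
  reg2 <- index_registry(cfg)
  expect_equal(reg2$peridinin_490$wavelength, 490)
})
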