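test_that("pixel-integrated Gaussian masses match numerical integration", {
  f <- spaintr:::gauss_pixel_mass
  for (mu in c(4.0, 4.3)) {
    for (s in c(0.6, 1.7)) {
      for (k in 2:7) {
        want <- stats::integrate(stats::dnorm, k - 0.5, k + 0.5,
                                 mean = mu, sd = s)$value
        expect_equal(f(k, mu, s), want, tolerance = 1e-9)
      }
    }
  }
  # the full pixel lattice carries (almost) unit mass
  expect_equal(sum(f(-50:50, 0.3, 2)), 1, tolerance = 1e-12)
})

test_that("every rendered localization deposits unit mass", {
  tab <- tibble::tibble(frame = 1:7,
                        x_px = c(5, 5.2, 8, 3.3, 6.6, 4.4, 7.1),
                        y_px = c(5, 4.8, 2, 6.1, 3.3, 5.5, 4.2),
                        photons = 1000,
                        precision_nm = c(7, 12, 20, 9, 15, 30, 11))
  img <- render_density(tab, render_config(), camera_model(),
                        extent_px = c(12, 12))
  expect_s3_class(img, "spaint_image")
  expect_equal(sum(img$density), nrow(tab), tolerance = 1e-3)
  expect_equal(img$n_localizations, nrow(tab))
})

test_that("a perfectly precise localization collapses to one output pixel", {
  tab <- tibble::tibble(frame = 1L, x_px = 5, y_px = 5, photons = 1000,
                        precision_nm = 1e-9)
  img <- render_density(tab, render_config(), camera_model(),
                        extent_px = c(10, 10))
  expect_equal(max(img$density), sum(img$density), tolerance = 1e-9)
  expect_equal(sum(img$density), 1, tolerance = 1e-6)
})

test_that("rendered wavelengths never leave the range of their inputs", {
  set.seed(41)
  tab <- tibble::tibble(frame = 1:200,
                        x_px = runif(200, 2, 10),
                        y_px = runif(200, 2, 10),
                        photons = runif(200, 500, 3000),
                        precision_nm = runif(200, 8, 25),
                        wavelength_nm = runif(200, 575, 655))
  ren <- render_spaint(tab, render_config(), camera_model(),
                       extent_px = c(12, 12))
  lam <- ren$wavelength[!is.na(ren$wavelength)]
  expect_gt(length(lam), 100)
  # a weighted mean is convex: bounded by the extremes of its inputs
  expect_gte(min(lam), 575)
  expect_lte(max(lam), 655)
  expect_true(all(dim(ren$rgb) == c(dim(ren$density), 3)))
  expect_true(all(ren$rgb >= 0 & ren$rgb <= 1))
})

test_that("per-pixel wavelength is the photon-weighted mean", {
  # two coincident localizations, 3:1 photon weights at 580 and 620 nm:
  # (3*580 + 620)/4 = 590 everywhere both deposit mass
  tab <- tibble::tibble(frame = 1:2, x_px = 5, y_px = 5,
                        photons = c(3000, 1000), precision_nm = 15,
                        wavelength_nm = c(580, 620))
  ren <- render_spaint(tab, render_config(), camera_model(),
                       extent_px = c(10, 10))
  lam <- ren$wavelength[!is.na(ren$wavelength)]
  expect_equal(lam, rep(590, length(lam)), tolerance = 1e-9)
})

test_that("a spectra-free table cannot be false-coloured", {
  tab <- tibble::tibble(frame = 1L, x_px = 5, y_px = 5, photons = 1000,
                        precision_nm = 10, wavelength_nm = NA_real_)
  expect_error(render_spaint(tab), "no assigned wavelengths")
})

test_that("smoothing a constant wavelength field returns that constant", {
  set.seed(42)
  tab <- tibble::tibble(frame = sample(1:200, 300, replace = TRUE),
                        x_px = runif(300, 1, 9),
                        y_px = runif(300, 1, 9),
                        wavelength_nm = 600)
  tm <- temporal_hydrophobicity_map(tab, render_config(), camera_model(),
                                    n_frames = 200, extent_px = c(10, 10))
  m <- tm$maps[[1]]
  vals <- m[!is.na(m)]
  expect_gt(length(vals), 50)
  expect_equal(vals, rep(600, length(vals)), tolerance = 1e-9)
})

test_that("the moving window advances by 0.8 s over a long acquisition", {
  set.seed(43)
  tab <- tibble::tibble(frame = sample(1:3000, 600, replace = TRUE),
                        x_px = runif(600, 1, 5), y_px = runif(600, 1, 5),
                        wavelength_nm = rnorm(600, 620, 10))
  tm <- temporal_hydrophobicity_map(tab, render_config(), camera_model(),
                                    n_frames = 3000, extent_px = c(6, 6))
  # (3000 - 200)/16 + 1 = 176 windows
  expect_equal(length(tm$maps), 176)
  expect_equal(unique(diff(tm$times$start_frame)), 16)
  expect_equal(unique(round(diff(tm$times$mid_time_s), 10)), 0.8)
  expect_equal(tm$times$mid_time_s[1], (200 / 2) / 20)
})

test_that("a window longer than the acquisition is refused", {
  tab <- tibble::tibble(frame = 1:50, x_px = 1, y_px = 1,
                        wavelength_nm = 600)
  expect_error(temporal_hydrophobicity_map(tab, render_config(),
                                           n_frames = 50),
               "larger than the acquisition")
})

test_that("kernel regression is invariant to duplicating every observation", {
  set.seed(44)
  tab <- tibble::tibble(frame = rep(1:100, 2),
                        x_px = runif(200, 1, 9), y_px = runif(200, 1, 9),
                        wavelength_nm = runif(200, 580, 660))
  tm1 <- temporal_hydrophobicity_map(tab, render_config(window_frames = 100L),
                                     camera_model(), n_frames = 100,
                                     extent_px = c(10, 10))
  tm2 <- temporal_hydrophobicity_map(dplyr::bind_rows(tab, tab),
                                     render_config(window_frames = 100L),
                                     camera_model(), n_frames = 100,
                                     extent_px = c(10, 10))
  expect_equal(tm1$maps[[1]], tm2$maps[[1]], tolerance = 1e-12)
})

test_that("a lone localization imprints its wavelength on the local map", {
  tab <- tibble::tibble(frame = 1:200, x_px = 5, y_px = 5,
                        wavelength_nm = 645)
  tm <- temporal_hydrophobicity_map(tab, render_config(), camera_model(),
                                    n_frames = 200, extent_px = c(10, 10))
  m <- tm$maps[[1]]
  vals <- m[!is.na(m)]
  expect_equal(vals, rep(645, length(vals)), tolerance = 1e-9)
  # support is local: far corners carry no estimate
  expect_true(is.na(m[1, 1]))
})

test_that("rendered images and temporal maps are written to disk", {
  dir <- withr::local_tempdir()
  tab <- tibble::tibble(frame = rep(1:200, length.out = 50),
                        x_px = runif(50, 1, 9), y_px = runif(50, 1, 9),
                        photons = 1000, precision_nm = 12,
                        wavelength_nm = rnorm(50, 620, 8))
  img <- render_density(tab, extent_px = c(10, 10))
  p1 <- file.path(dir, "density.tif")
  write_image(img, p1)
  expect_true(file.exists(p1))
  ren <- render_spaint(tab, extent_px = c(10, 10))
  p2 <- file.path(dir, "render.tif")
  write_image(ren, p2)
  expect_true(file.exists(p2))
  tm <- temporal_hydrophobicity_map(tab, n_frames = 200,
                                    extent_px = c(10, 10))
  p3 <- file.path(dir, "maps.tif")
  write_temporal_maps(tm, p3)
  expect_true(file.exists(p3))
  expect_true(file.exists(file.path(dir, "maps_times.csv")))
})
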