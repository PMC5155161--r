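test_that("a fixed seed reproduces a calibration stack bit for bit", {
  s1 <- simulate_calibration_stack(n_beads = 5, n_frames = 3, seed = 42)
  s2 <- simulate_calibration_stack(n_beads = 5, n_frames = 3, seed = 42)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$truth, s2$truth)
})

test_that("an empty bead field gives pure noise frames and empty truth", {
  s <- simulate_calibration_stack(n_beads = 0, n_frames = 2, seed = 1)
  expect_equal(nrow(s$truth), 0)
  # no structure: every pixel is background + noise, far below a bead peak
  cam <- camera_model()
  bg_adu <- cam$baseline_adu + 2 * gain_total(cam)
  expect_lt(max(s$frames[[1]]), bg_adu + 40 * gain_total(cam))
})

test_that("camera ADU counts account for every detected photon", {
  # readout of a bright uniform field: (ADU - baseline) / GainTotal
  # must return the emitted photons (QE is part of the total gain)
  set.seed(5)
  cam <- camera_model()
  img <- matrix(100, 64, 64)
  adu <- spaintr:::camera_readout(img, cam)
  est <- (mean(adu) - cam$baseline_adu) / gain_total(cam)
  expect_equal(est, 100, tolerance = 0.05)
  # a pathologically bright field clips at the 16-bit ceiling instead of
  # wrapping around
  bright <- spaintr:::camera_readout(matrix(1e4, 8, 8), cam)
  expect_lte(max(bright), 65535)
  expect_gt(min(bright), 60000)
})

test_that("the dispersed blob lands exactly at the grating-equation distance", {
  # one bead, zero aberration: the measured spectral peak position must
  # match the injected dispersion model to sub-pixel accuracy
  disp <- dispersion_from_geometry()
  s <- simulate_calibration_stack(n_beads = 1, n_frames = 20,
                                  dispersion = disp, seed = 9)
  avg <- Reduce(`+`, s$frames) / s$n_frames
  bead <- s$truth[1, ]
  z_true <- spaintr:::dispersion_distance(disp$beta, 581.5,
                                          bead$x_px, bead$y_px)
  prof <- extract_profile(avg, bead$x_px, bead$y_px, z_true)
  pk <- fit_peak(prof)
  expect_true(pk$qc_pass)
  expect_lt(abs(pk$center_px - z_true), 0.2)
})

test_that("binding events arrive at the configured Poisson rate", {
  set.seed(3)
  sites <- tibble::tibble(x_px = rep(seq(5, 45, by = 10), 5),
                          y_px = rep(seq(5, 45, by = 10), each = 5),
                          wavelength_nm = 620)
  sam <- site_field(sites, binding_rate_hz = 0.2, field_px = 50)
  stk <- simulate_spaint_stack(sam, n_frames = 200, seed = 3)
  ev <- attr(stk, "events")
  # 25 sites * 0.2 Hz * 10 s = 50 expected events
  expect_lt(abs(nrow(ev) - 50), 3 * sqrt(50))
})

test_that("a zero binding rate yields no events", {
  sites <- tibble::tibble(x_px = 10, y_px = 10, wavelength_nm = 620)
  sam <- site_field(sites, binding_rate_hz = 0, field_px = 30)
  stk <- simulate_spaint_stack(sam, n_frames = 5, seed = 1)
  expect_equal(nrow(attr(stk, "events")), 0)
  expect_equal(nrow(stk$truth), 0)
})

test_that("short on-times mostly span a single frame", {
  # tau = 25 ms against 50 ms frames: P(span = 1) = 1 - exp(-2) = 0.86
  set.seed(8)
  cam <- camera_model(frame_rate_hz = 20)
  sites <- tibble::tibble(x_px = rep(seq(5, 45, by = 10), 5),
                          y_px = rep(seq(5, 45, by = 10), each = 5),
                          wavelength_nm = 620)
  sam <- site_field(sites, binding_rate_hz = 0.5, mean_on_time_s = 0.025,
                    field_px = 50)
  stk <- simulate_spaint_stack(sam, camera = cam, n_frames = 300, seed = 8)
  ev <- attr(stk, "events")
  expect_gt(nrow(ev), 100)
  expect_gt(mean(ev$span_frames == 1), 0.75)
})

test_that("an empty binding-site map warns and produces a noise-only stack", {
  sam <- site_field(tibble::tibble(x_px = numeric(), y_px = numeric(),
                                   wavelength_nm = numeric()),
                    field_px = 20)
  expect_warning(stk <- simulate_spaint_stack(sam, n_frames = 2, seed = 1),
                 "noise-only")
  expect_equal(nrow(stk$truth), 0)
})

test_that("a stack survives the TIFF round trip losslessly", {
  dir <- withr::local_tempdir()
  s <- simulate_calibration_stack(n_beads = 3, n_frames = 2, seed = 13)
  p <- file.path(dir, "stack.tif")
  write_stack(s, p)
  r <- read_stack(p)
  expect_identical(r$frames, s$frames)
  expect_equal(r$truth$x_px, s$truth$x_px)
  expect_equal(r$camera$gain_em, s$camera$gain_em)
  expect_equal(r$dispersion$beta, s$dispersion$beta)
  expect_identical(r$spatial_rows, s$spatial_rows)
})

test_that("the ground-truth side-car keeps its column contract", {
  dir <- withr::local_tempdir()
  s <- simulate_calibration_stack(n_beads = 2, n_frames = 1, seed = 2)
  p <- file.path(dir, "stack.tif")
  write_stack(s, p)
  header <- readLines(file.path(dir, "stack_truth.csv"), n = 1)
  expect_equal(header, "frame,x_px,y_px,photons,wavelength_nm")
})

test_that("an empty stack cannot be written", {
  s <- simulate_calibration_stack(n_beads = 1, n_frames = 1, seed = 1)
  s$frames <- list(); s$n_frames <- 0L
  expect_error(write_stack(s, tempfile(fileext = ".tif")), "empty")
})

test_that("a corrupted TIFF is reported with a format error", {
  p <- tempfile(fileext = ".tif")
  writeLines("this is not a TIFF", p)
  expect_error(read_stack(p), "malformed TIFF")
})

test_that("vesicle binding sites sit on the configured ring", {
  set.seed(4)
  sam <- luv_field(n_luv = 10, diameter_nm = 110)
  r_px <- 55 / camera_model()$effective_pixel_nm
  radii <- sam$sites |>
    dplyr::group_by(structure_id) |>
    dplyr::summarise(r = sqrt(mean((x_px - mean(x_px))^2 +
                                   (y_px - mean(y_px))^2)))
  expect_equal(radii$r, rep(r_px, 10), tolerance = 1e-6)
})

test_that("overlapping spatial and spectral regions are a configuration error", {
  # a tall spatial field leaves no room for the dispersed spectra
  expect_error(
    simulate_calibration_stack(n_beads = 1, n_frames = 1,
                               field_px = c(512, 400), seed = 1),
    "overlap")
})
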