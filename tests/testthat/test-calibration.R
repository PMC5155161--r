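test_that("the profile window is centred where the user points it", {
  # a Gaussian ridge placed exactly at the estimated distance peaks at
  # offset 0; displacing the ridge moves the fitted centre accordingly
  frame <- matrix(0, 300, 21)
  z_blob <- 240
  for (dy in -10:10) {
    frame[z_blob + dy + 1, ] <- 1000 * exp(-dy^2 / (2 * 4^2))
  }
  prof <- extract_profile(frame, anchor_x = 10, anchor_y = 0,
                          estimated_distance_px = 240)
  expect_s3_class(prof, "spaint_profile")
  expect_equal(prof$offset_px[which.max(prof$intensity)], 0)
  pk0 <- fit_peak(prof)
  expect_true(pk0$qc_pass)
  expect_equal(pk0$center_px, 240, tolerance = 0.05)

  prof3 <- extract_profile(frame, 10, 0, 237)   # user guesses 3 px short
  pk3 <- fit_peak(prof3)
  expect_equal(pk3$center_offset_px, 3, tolerance = 0.05)
  expect_equal(pk3$center_px, 240, tolerance = 0.05)
})

test_that("a window that leaves the detector is reported as such", {
  frame <- matrix(0, 100, 21)
  expect_null(extract_profile(frame, 10, 0, 95))
  expect_null(extract_profile(frame, 0, 0, 50))   # transverse off the edge
})

test_that("pure noise fails peak quality control", {
  set.seed(2)
  prof <- tibble::tibble(offset_px = -15:15, intensity = rnorm(31))
  pk <- fit_peak(prof)
  expect_false(pk$qc_pass)
})

test_that("too narrow a peak is discarded, a plausible one kept", {
  mk <- function(w) {
    tibble::tibble(offset_px = -15:15,
                   intensity = 500 * exp(-(-15:15)^2 / (2 * w^2)))
  }
  narrow <- fit_peak(mk(1.0))
  expect_false(narrow$qc_pass)
  expect_equal(narrow$qc_reason, "width_too_small")
  good <- fit_peak(mk(5))
  expect_true(good$qc_pass)
  expect_equal(good$width_px, 5, tolerance = 0.05)
  expect_equal(good$center_offset_px, 0, tolerance = 0.2)
})

test_that("an inverted (negative-amplitude) profile is discarded", {
  prof <- tibble::tibble(offset_px = -15:15,
                         intensity = -500 * exp(-(-15:15)^2 / 18))
  pk <- fit_peak(prof)
  expect_false(pk$qc_pass)
  expect_equal(pk$qc_reason, "negative_amplitude")
})

test_that("noise-free distances return the generating coefficients exactly", {
  set.seed(6)
  truth <- c(50, 0.4, 0.001, 0.002)
  m <- tidyr::expand_grid(wavelength_nm = c(512.7, 581.5, 676.5),
                          bead_id = 1:20)
  m$x_px <- runif(nrow(m), 0, 500)
  m$y_px <- runif(nrow(m), 0, 90)
  m$z0z1_px <- truth[1] + truth[2] * m$wavelength_nm +
    truth[3] * m$x_px + truth[4] * m$y_px
  # noiseless data makes summary.lm warn about a perfect fit; that is the
  # point of the test
  fit <- suppressWarnings(fit_calibration(m))
  expect_equal(unname(fit$beta), truth, tolerance = 1e-10)
  expect_equal(fit$n_beads, 20)
})

test_that("0.1 px of measurement noise leaves the dispersion slope within 1%", {
  set.seed(16)
  truth <- c(-7.4647, 0.39392, 0.003, 0.004)
  m <- tidyr::expand_grid(wavelength_nm = c(512.7, 581.5, 676.5),
                          bead_id = 1:50)
  m$x_px <- runif(nrow(m), 0, 500)
  m$y_px <- runif(nrow(m), 0, 90)
  m$z0z1_px <- truth[1] + truth[2] * m$wavelength_nm +
    truth[3] * m$x_px + truth[4] * m$y_px + rnorm(nrow(m), sd = 0.1)
  fit <- fit_calibration(m)
  expect_lt(abs(fit$beta[["beta1"]] / truth[2] - 1), 0.01)
})

test_that("beads stacked at one position cannot identify the aberration", {
  m <- tidyr::expand_grid(wavelength_nm = c(512.7, 581.5, 676.5),
                          bead_id = 1:15)
  m$x_px <- 100; m$y_px <- 50
  m$z0z1_px <- -7.46 + 0.394 * m$wavelength_nm
  expect_error(fit_calibration(m), "rank deficient")
})

test_that("the forward and inverse wavelength mappings are exact inverses", {
  model <- calibration_from_coefficients(50, 0.4, 0.001, 0.002)
  # hand calculation: Z = 50 + 0.4*600 + 0.001*100 + 0.002*200 = 290.5
  z <- predict_distance(model, 600, 100, 200)
  expect_equal(z, 290.5)
  lam <- wavelength_from_distance(290.5, 100, 200, model)
  expect_equal(as.numeric(lam), 600)
  expect_true(attr(lam, "in_passband"))
  # round trip over a grid is exact to machine precision
  grid <- tidyr::expand_grid(l = seq(490, 750, by = 20),
                             x = c(0, 250, 500), y = c(0, 45, 90))
  back <- wavelength_from_distance(
    predict_distance(model, grid$l, grid$x, grid$y), grid$x, grid$y, model)
  expect_equal(as.numeric(back), grid$l, tolerance = 1e-12)
})

test_that("wavelengths outside the detection passband are flagged", {
  model <- calibration_from_coefficients(-7.46, 0.394)
  lam <- wavelength_from_distance(c(100, 230), 0, 0, model)
  expect_equal(attr(lam, "in_passband"), c(FALSE, TRUE))
})

test_that("the full bead-stack calibration recovers the injected optics", {
  model <- fx_cal_model()
  truth <- fx_true_dispersion()$beta
  expect_equal(unname(model$beta[["beta1"]]), truth[["beta1"]],
               tolerance = 0.01)
  expect_lt(abs(model$beta[["beta2"]] - 0.003), 0.002)
  expect_lt(abs(model$beta[["beta3"]] - 0.004), 0.002)
  expect_lt(model$residual_sd, 1)
  rec <- model$recovered
  expect_equal(rec$mean_recovered_nm, c(512.7, 581.5, 676.5), tolerance = 2)
})

test_that("a calibration survives its coefficient-file round trip", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cal.txt")
  model <- fx_cal_model()
  write_calibration(model, p)
  back <- read_calibration(p)
  expect_equal(back$beta, model$beta)
  expect_equal(back$passband_nm, model$passband_nm)
  z <- predict_distance(back, 620, 50, 40)
  expect_equal(as.numeric(wavelength_from_distance(z, 50, 40, back)), 620)
})

test_that("tidy and glance expose the calibration fit", {
  model <- fx_cal_model()
  td <- tidy(model)
  expect_equal(td$term, c("beta0", "beta1", "beta2", "beta3"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(model)
  expect_equal(gl$n_beads, model$n_beads)
})
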