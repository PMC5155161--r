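test_that("grid-bucketed DBSCAN agrees with a brute-force reference", {
  set.seed(21)
  centers <- tibble::tibble(cx = runif(15, 5, 95), cy = runif(15, 5, 95))
  pts <- purrr::pmap_dfr(centers, function(cx, cy) {
    tibble::tibble(x_px = cx + rnorm(25, sd = 0.12),
                   y_px = cy + rnorm(25, sd = 0.12))
  })
  pts <- dplyr::bind_rows(pts, tibble::tibble(x_px = runif(5, 0, 100),
                                              y_px = runif(5, 0, 100)))
  ref <- dbscan_reference(pts$x_px, pts$y_px, eps = 0.5, min_pts = 10)
  got <- cluster_localizations(dplyr::mutate(pts, frame = 1L),
                               eps_px = 0.5, min_points = 10)
  expect_true(same_partition(got$cluster_id, ref))
  expect_gt(max(ref), 10)   # the reference itself found real clusters
})

test_that("sparse uniform points are all labelled noise", {
  set.seed(22)
  pts <- tibble::tibble(frame = 1L, x_px = runif(20, 0, 500),
                        y_px = runif(20, 0, 500))
  got <- cluster_localizations(pts, eps_px = 0.5, min_points = 10)
  expect_true(all(got$cluster_id == -1L))
})

test_that("with a minimum cluster size of one, nothing is noise", {
  set.seed(23)
  pts <- tibble::tibble(frame = 1L, x_px = runif(30, 0, 50),
                        y_px = runif(30, 0, 50))
  got <- cluster_localizations(pts, eps_px = 0.5, min_points = 1)
  expect_true(all(got$cluster_id > 0))
})

test_that("clustering is invariant to row order and translation", {
  set.seed(24)
  pts <- dplyr::bind_rows(
    tibble::tibble(x_px = 10 + rnorm(40, sd = 0.15),
                   y_px = 10 + rnorm(40, sd = 0.15)),
    tibble::tibble(x_px = 30 + rnorm(40, sd = 0.15),
                   y_px = 12 + rnorm(40, sd = 0.15)),
    tibble::tibble(x_px = runif(8, 0, 40), y_px = runif(8, 0, 40)))
  pts$frame <- 1L
  base <- cluster_localizations(pts, eps_px = 0.5, min_points = 10)

  perm <- sample(nrow(pts))
  shuffled <- cluster_localizations(pts[perm, ], eps_px = 0.5,
                                    min_points = 10)
  expect_true(same_partition(shuffled$cluster_id, base$cluster_id[perm]))

  moved <- cluster_localizations(
    dplyr::mutate(pts, x_px = x_px + 123.4, y_px = y_px + 56.7),
    eps_px = 0.5, min_points = 10)
  expect_true(same_partition(moved$cluster_id, base$cluster_id))
})

test_that("spectral assignment recovers the emitter wavelength from a stack", {
  stk <- fx_luv_stack()
  locs <- fx_luv_locs()
  model <- fx_cal_model()
  out <- assign_spectra(locs, stk, model, anchor_nm = 635)
  ok <- out$wavelength_nm[!is.na(out$wavelength_nm)]
  expect_gt(length(ok), 100)
  expect_gt(attr(out, "fraction_assigned"), 0.5)
  # sites emit at 635 nm; the assigned mean must land near it
  expect_lt(abs(mean(ok) - 635), 4)
  expect_lt(sd(ok), 15)
})

test_that("spectral windows that leave the detector are flagged, not guessed", {
  stk <- fx_single_emitter_stack(photons = 2000, n_frames = 3)
  locs <- localize_stack(stk)
  expect_gt(nrow(locs), 0)
  model <- calibration_from_coefficients(-7.4647, 0.39392)
  out <- assign_spectra(locs, stk, model, anchor_nm = 620)
  # the 24-px frames cannot contain a window ~240 px away
  expect_true(all(is.na(out$wavelength_nm)))
  expect_true(all(out$qc_reason == "window_oob"))
})

test_that("three consecutive appearances become one 0.15 s binding event", {
  locs <- tibble::tibble(frame = c(1L, 2L, 3L, 10L),
                         x_px = c(5, 5.05, 4.95, 20),
                         y_px = c(5, 5.02, 5.01, 20),
                         photons = 1000)
  ev <- compute_on_times(locs, frame_rate_hz = 20)
  expect_equal(nrow(ev), 2)
  ev1 <- ev[ev$start_frame == 1L, ]
  expect_equal(ev1$n_frames, 3L)
  expect_equal(ev1$on_time_s, 0.15)
  expect_equal(ev1$n_localizations, 3L)
})

test_that("frame-linked event durations match the censored exponential model", {
  # mean on-time 60 ms against 50 ms frames: a binding event is seen in
  # 1/(1 - exp(-dt/tau)) = 1.77 frames on average
  set.seed(31)
  sites <- tibble::tibble(x_px = rep(seq(6, 66, by = 12), 6),
                          y_px = rep(seq(6, 66, by = 12), each = 6),
                          wavelength_nm = 620)
  sam <- site_field(sites, binding_rate_hz = 0.4, mean_on_time_s = 0.06,
                    field_px = 72)
  stk <- simulate_spaint_stack(sam, n_frames = 400, seed = 31)
  ev <- attr(stk, "events")
  # 36 sites * 0.4 Hz * 20 s = 288 expected events
  expect_lt(abs(nrow(ev) - 288), 3 * sqrt(288))
  expected_span <- 1 / (1 - exp(-0.05 / 0.06))
  expect_lt(abs(mean(ev$span_frames) / expected_span - 1), 0.15)

  # and the event linker applied to the ground-truth table agrees
  linked <- compute_on_times(stk$truth, frame_rate_hz = 20)
  expect_lt(abs(mean(linked$n_frames) / expected_span - 1), 0.2)
})

test_that("localization density is events per area and time", {
  locs <- tibble::tibble(frame = 1:100, x_px = 1, y_px = 1, photons = 1)
  d <- localization_density(locs, area_um2 = 50, duration_s = 10)
  expect_equal(d$density_per_um2_s, 100 / 50 / 10)
  d2 <- localization_density(locs[1:50, ], area_um2 = 50, duration_s = 10)
  expect_equal(d$density_per_um2_s / d2$density_per_um2_s, 2)
  expect_error(localization_density(locs, area_um2 = 0, duration_s = 10),
               "positive")
})

test_that("a spectral histogram summarises assigned wavelengths faithfully", {
  h <- spectral_histogram(rep(602, 50))
  expect_equal(h$mean_nm, 602)
  expect_equal(h$sd_nm, 0)
  expect_equal(h$n, 50)

  set.seed(33)
  lam <- rnorm(2000, 602, 5.5)
  h2 <- spectral_histogram(lam, bin_width_nm = 1)
  expect_equal(h2$mean_nm, 602, tolerance = 0.5)
  expect_equal(h2$sd_nm, 5.5, tolerance = 0.5)
  expect_equal(sum(h2$histogram$count), 2000)

  expect_error(spectral_histogram(numeric()), "no assigned wavelengths")
})

test_that("a two-dye mixture separates into its component wavelengths", {
  set.seed(34)
  lam <- c(rnorm(800, 600, 6), rnorm(800, 650, 6))
  km <- stats::kmeans(lam, centers = c(590, 660))
  mus <- sort(km$centers[, 1])
  expect_lt(abs(mus[1] - 600), 3)
  expect_lt(abs(mus[2] - 650), 3)
  # the histogram over the mixture spans both modes
  h <- spectral_histogram(lam)
  expect_gt(h$sd_nm, 20)
})

test_that("cluster summaries report per-vesicle geometry and spectra", {
  locs <- fx_luv_locs()
  stk <- fx_luv_stack()
  locs <- assign_spectra(locs, stk, fx_cal_model(), anchor_nm = 635)
  cs <- cluster_summaries(locs, camera_model(), n_frames = stk$n_frames)
  expect_gt(nrow(cs), 10)
  expect_true(all(cs$n >= 10))
  expect_true(all(cs$diameter_um > 0))
  # assigned spectra propagate into the per-cluster means
  with_spec <- cs[cs$n_spectra > 5, ]
  expect_gt(nrow(with_spec), 5)
  expect_lt(abs(mean(with_spec$mean_wavelength_nm) - 635), 5)
})
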