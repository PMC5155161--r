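# Shared fixtures, memoized per test session. Everything is generated in
# code with fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, make) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- make()
  .fixture_cache[[name]]
}

# the dispersion injected into synthetic calibration stacks: the optics
# prediction linearised through the three reference dyes, plus small
# linear field aberration
fx_true_dispersion <- function() {
  dispersion_from_geometry(grating_geometry(), camera_model(),
                           beta2 = 0.003, beta3 = 0.004)
}

# a moderate calibration bead stack and its fitted calibration
fx_cal_stack <- function() memo("cal_stack", function() {
  simulate_calibration_stack(n_beads = 30, n_frames = 15,
                             dispersion = fx_true_dispersion(),
                             seed = 101)
})

fx_cal_model <- function() memo("cal_model", function() {
  calibrate_stack(fx_cal_stack())
})

# a small vesicle acquisition plus its localizations (no clustering)
fx_luv_stack <- function() memo("luv_stack", function() {
  set.seed(7)
  simulate_spaint_stack(luv_field(n_luv = 20, spacing_px = 14),
                        n_frames = 150,
                        dispersion = fx_true_dispersion(), seed = 7)
})

fx_luv_locs <- function() memo("luv_locs", function() {
  cluster_localizations(localize_stack(fx_luv_stack()))
})

# a single bright emitter rendered into a small stack, for localization
# accuracy tests: one spot per frame at a fixed sub-pixel position
fx_single_emitter_stack <- function(photons, n_frames = 40, seed = 11,
                                    x0 = 10.3, y0 = 9.6) {
  set.seed(seed)
  cam <- camera_model()
  geom <- grating_geometry()
  # the frame must be large enough that the spot does not dominate the
  # detector's noise estimate (a robust MAD over the whole frame)
  base <- matrix(2, 48, 48)
  img <- spaintr:::add_spot(base, x0, y0, 1.2, 1.2, photons)
  frames <- replicate(n_frames, spaintr:::camera_readout(img, cam),
                      simplify = FALSE)
  truth <- tibble::tibble(frame = seq_len(n_frames), x_px = x0, y_px = y0,
                          photons = photons, wavelength_nm = NA_real_)
  spaintr:::new_spaint_stack(frames, cam, geom, fx_true_dispersion(),
                             c(0L, 48L), truth, 2)
}

# brute-force DBSCAN reference used as an oracle for the grid-bucketed
# implementation
dbscan_reference <- function(x, y, eps, min_pts) {
  n <- length(x)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    if (length(nb[[i]]) < min_pts) { labels[i] <- -1L; next }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb[[i]], i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == -1L) labels[j] <- cl
      if (labels[j] != 0L) next
      labels[j] <- cl
      if (length(nb[[j]]) >= min_pts) {
        queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

# compare two clusterings up to label permutation (noise must match
# exactly)
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == -1L, b == -1L)) return(FALSE)
  ok <- a != -1L
  length(unique(paste(a[ok], b[ok]))) ==
    length(unique(a[ok])) &&
    length(unique(a[ok])) == length(unique(b[ok]))
}
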