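# ---- frame painting -------------------------------------------------------

# add `photons` worth of a pixel-integrated 2D Gaussian centred at the
# 0-based detector position (x0, y0) to the expected-photon image `img`
# (matrix indexed [y + 1, x + 1]); truncated at 5 sigma.
add_spot <- function(img, x0, y0, sigma_x, sigma_y, photons) {
  nr <- nrow(img); nc <- ncol(img)
  xs <- max(0L, floor(x0 - 5 * sigma_x)):min(nc - 1L, ceiling(x0 + 5 * sigma_x))
  ys <- max(0L, floor(y0 - 5 * sigma_y)):min(nr - 1L, ceiling(y0 + 5 * sigma_y))
  if (length(xs) == 0L || length(ys) == 0L || xs[1] > xs[length(xs)] ||
      ys[1] > ys[length(ys)]) return(img)
  mx <- gauss_pixel_mass(xs, x0, sigma_x)
  my <- gauss_pixel_mass(ys, y0, sigma_y)
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + photons * (my %o% mx)
  img
}

# EMCCD readout: expected photons/pixel -> integer ADU frame.
# Poisson photo-electrons -> Gamma approximation of the EM register ->
# Gaussian read noise -> baseline, rounding, clipping to 16 bits.
camera_readout <- function(expected_photons, camera) {
  ne <- rpois(length(expected_photons),
              as.vector(expected_photons) * camera$quantum_efficiency)
  amp <- numeric(length(ne))
  pos <- ne > 0L
  amp[pos] <- rgamma(sum(pos), shape = ne[pos], scale = camera$gain_em)
  adu <- amp * camera$gain_camera +
    rnorm(length(ne), sd = camera$read_noise_adu) + camera$baseline_adu
  out <- pmin(pmax(round(adu), 0), 65535)
  matrix(as.integer(out), nrow = nrow(expected_photons))
}

new_spaint_stack <- function(frames, camera, geometry, dispersion,
                             spatial_rows, truth, background_photons) {
  structure(
    list(frames = frames,
         n_frames = length(frames),
         camera = camera, geometry = geometry, dispersion = dispersion,
         spatial_rows = spatial_rows,   # 0-based [min, max) y range
         background_photons = background_photons,
         truth = truth),
    class = "spaint_stack")
}

#' @export
print.spaint_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<spaint_stack> %d frame(s) of %d x %d px; spatial rows [%d, %d); %d ground-truth rows\n",
    x$n_frames, d[1], d[2], x$spatial_rows[1], x$spatial_rows[2],
    nrow(x$truth)))
  invisible(x)
}

# image height needed so that the reddest spectral blob fits below the
# spatial region, with margin
stack_height <- function(field_px, dispersion, max_lambda, margin = 20L) {
  zmax <- dispersion_distance(dispersion$beta, max_lambda,
                              field_px, field_px)
  as.integer(ceiling(field_px + zmax + margin))
}

empty_truth <- function() {
  tibble::tibble(frame = integer(), x_px = numeric(), y_px = numeric(),
                 photons = numeric(), wavelength_nm = numeric())
}

# ---- calibration stacks ---------------------------------------------------

#' Simulate a spectral-calibration bead stack
#'
#' Generates camera frames of multi-dye calibration beads: each bead shows
#' one zeroth-order PSF in the spatial region and one first-order spectral
#' blob per dye, displaced along +y by the `dispersion` model. Poisson
#' photo-electron statistics, stochastic EM gain and Gaussian read noise
#' are applied per pixel.
#'
#' @param n_beads Number of beads, placed uniformly at random in the
#'   spatial sub-region with a minimum pairwise separation. As in a real
#'   calibration field the beads are spatially isolated: two beads are not
#'   allowed to share a spectral column (within `column_exclusion_px` in x)
#'   unless their dispersed spectra cannot overlap in y.
#' @param species A list of [emitter_species()], one per dye; defaults to
#'   the three reference dyes via [calibration_species()].
#' @param camera A [camera_model()].
#' @param geometry A [grating_geometry()].
#' @param dispersion A [linear_dispersion()] giving the true Z0Z1 distance
#'   per wavelength and field position.
#' @param n_frames Frames to simulate (100 by default, matching a standard
#'   calibration acquisition).
#' @param field_px Spatial sub-region size `c(width, height)` in pixels
#'   (a single value gives a square); the default is a wide strip of a
#'   512-px chip, leaving the rows below it for the dispersed spectra.
#' @param min_separation_px Minimum bead separation.
#' @param column_exclusion_px Beads closer than this in x must have their
#'   spectral bands fully separated in y.
#' @param background_photons Uniform background, photons/pixel/frame.
#' @param edge_margin_px Keep beads this far from the field edge.
#' @param seed Optional integer seed; fixed seeds give bit-identical stacks.
#' @return A `spaint_stack` whose `truth` table holds one row per bead and
#'   frame (photons = expected zeroth-order photons per frame;
#'   `wavelength_nm` is `NA` because beads carry several dyes).
#' @export
simulate_calibration_stack <- function(n_beads = 50,
                                       species = calibration_species(),
                                       camera = camera_model(),
                                       geometry = grating_geometry(),
                                       dispersion = dispersion_from_geometry(
                                         geometry, camera),
                                       n_frames = 100,
                                       field_px = c(512, 96),
                                       min_separation_px = 8,
                                       column_exclusion_px = 4,
                                       background_photons = 2,
                                       edge_margin_px = 6,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(field_px) == 1) field_px <- c(field_px, field_px)
  width <- field_px[1]; height <- field_px[2]
  peaks <- vapply(species, `[[`, numeric(1), "peak_wavelength_nm")
  sigmas <- vapply(species, `[[`, numeric(1), "spectral_sigma_nm")
  zmin <- dispersion_distance(dispersion$beta, min(peaks) - 4 * max(sigmas),
                              0, 0)
  if (zmin <= height) {
    stop("spatial and spectral regions overlap; reduce the field height or ",
         "increase the dispersion intercept", call. = FALSE)
  }
  h <- stack_height(height, dispersion, max(peaks) + 4 * max(sigmas))

  # beads sharing an x-column would stack their dispersed spectra on top of
  # each other, so draw x from separated columns (random slots with jitter)
  # and y uniformly, keeping the Euclidean minimum separation
  slots <- seq(edge_margin_px, width - edge_margin_px,
               by = column_exclusion_px + 1)
  if (length(slots) < n_beads) {
    stop("could not place ", n_beads, " beads with isolated spectral ",
         "columns; widen the field or reduce column_exclusion_px",
         call. = FALSE)
  }
  xs <- sort(sample(slots, n_beads)) + runif(n_beads, -0.5, 0.5)
  ys <- numeric(n_beads)
  for (b in seq_len(n_beads)) {
    for (try in 1:500) {
      cy <- runif(1, edge_margin_px, height - edge_margin_px)
      prev <- seq_len(b - 1L)
      if (b == 1 || min((xs[prev] - xs[b])^2 + (ys[prev] - cy)^2) >=
            min_separation_px^2) break
      if (try == 500) stop("could not place beads with the requested ",
                           "separation", call. = FALSE)
    }
    ys[b] <- cy
  }

  split0 <- geometry$zeroth_order_fraction
  split1 <- (1 - split0) * (1 - geometry$transmission_loss)
  psf <- vapply(species, `[[`, numeric(1), "psf_sigma_px")
  phot <- vapply(species, `[[`, numeric(1), "mean_photons")
  zero_photons <- sum(phot) * split0

  base <- matrix(background_photons, nrow = h, ncol = width)
  if (n_beads > 0) {
    for (b in seq_len(n_beads)) {
      base <- add_spot(base, xs[b], ys[b], psf[1], psf[1], zero_photons)
      for (k in seq_along(species)) {
        z <- dispersion_distance(dispersion$beta, peaks[k], xs[b], ys[b])
        sy <- sqrt(psf[k]^2 + (sigmas[k] * dispersion$beta[["beta1"]])^2)
        base <- add_spot(base, xs[b], ys[b] + z, psf[k], sy, phot[k] * split1)
      }
    }
  }
  frames <- replicate(n_frames, camera_readout(base, camera),
                      simplify = FALSE)

  truth <- if (n_beads == 0) empty_truth() else
    tidyr::expand_grid(frame = seq_len(n_frames), bead = seq_len(n_beads)) |>
    dplyr::transmute(frame = .data$frame,
                     x_px = xs[.data$bead], y_px = ys[.data$bead],
                     photons = zero_photons, wavelength_nm = NA_real_)
  new_spaint_stack(frames, camera, geometry, dispersion,
                   c(0L, as.integer(height)), truth, background_photons)
}

# ---- sample geometries ----------------------------------------------------

new_spaint_sample <- function(sites, kind, binding_rate_hz, mean_on_time_s,
                              field_px, extra = list()) {
  stopifnot(mean_on_time_s > 0, binding_rate_hz >= 0)
  structure(c(list(sites = sites, kind = kind,
                   binding_rate_hz = binding_rate_hz,
                   mean_on_time_s = mean_on_time_s,
                   field_px = field_px), extra),
            class = "spaint_sample")
}

#' Generic binding-site field
#'
#' @param sites A tibble/data frame with columns `x_px`, `y_px`,
#'   `wavelength_nm` and optionally `structure_id`.
#' @param binding_rate_hz Dye binding rate per site, events/s.
#' @param mean_on_time_s Mean bound duration (exponential), s.
#' @param field_px Side of the square spatial field containing the sites.
#' @return A `spaint_sample`.
#' @export
site_field <- function(sites, binding_rate_hz = 0.1, mean_on_time_s = 0.06,
                       field_px = 102) {
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("x_px", "y_px", "wavelength_nm") %in% names(sites)))
  if (!"structure_id" %in% names(sites)) {
    sites$structure_id <- seq_len(nrow(sites))
  }
  if (nrow(sites) > 0 &&
      (any(sites$x_px < 0 | sites$x_px >= field_px) ||
       any(sites$y_px < 0 | sites$y_px >= field_px))) {
    stop("all sites must lie inside the field of view", call. = FALSE)
  }
  new_spaint_sample(sites, "site_field", binding_rate_hz, mean_on_time_s,
                    field_px)
}

#' Field of large unilamellar vesicles (LUVs)
#'
#' Spatially isolated ~110 nm vesicles laid out on a jittered grid; the dye
#' binding sites of each vesicle sit evenly spaced (with a random phase) on
#' the projected equatorial ring of the vesicle.
#'
#' @param n_luv Number of vesicles.
#' @param diameter_nm Vesicle diameter (monodisperse, 110 nm by default,
#'   the mean diameter of extruded LUVs).
#' @param sites_per_luv Binding sites per vesicle ring.
#' @param wavelength_nm Peak emission wavelength reported by the dye in
#'   this lipid environment (one value, or one per vesicle).
#' @param spacing_px Grid spacing between vesicle centres, pixels.
#' @param jitter_px Uniform jitter applied to each centre.
#' @param binding_rate_hz Binding rate per site, events/s.
#' @param mean_on_time_s Mean bound duration, s.
#' @param camera A [camera_model()] (for the nm-to-pixel conversion).
#' @return A `spaint_sample` with per-site rows and a `structure_id` per
#'   vesicle; the true diameter is stored in `$diameter_nm`.
#' @export
luv_field <- function(n_luv = 100, diameter_nm = 110, sites_per_luv = 12,
                      wavelength_nm = 635, spacing_px = 10, jitter_px = 1,
                      binding_rate_hz = 0.12, mean_on_time_s = 0.06,
                      camera = camera_model()) {
  stopifnot(n_luv >= 1, diameter_nm > 0, sites_per_luv >= 3)
  ncol_grid <- ceiling(sqrt(n_luv))
  field_px <- ncol_grid * spacing_px + 2
  idx <- seq_len(n_luv) - 1L
  cx <- (idx %% ncol_grid) * spacing_px + spacing_px / 2 +
    runif(n_luv, -jitter_px, jitter_px) + 1
  cy <- (idx %/% ncol_grid) * spacing_px + spacing_px / 2 +
    runif(n_luv, -jitter_px, jitter_px) + 1
  r_px <- diameter_nm / 2 / camera$effective_pixel_nm
  lam <- rep_len(wavelength_nm, n_luv)
  sites <- purrr::map_dfr(seq_len(n_luv), function(i) {
    th <- 2 * pi * (seq_len(sites_per_luv) - 1) / sites_per_luv +
      runif(1, 0, 2 * pi)
    tibble::tibble(x_px = cx[i] + r_px * cos(th),
                   y_px = cy[i] + r_px * sin(th),
                   wavelength_nm = lam[i], structure_id = i)
  })
  new_spaint_sample(sites, "luv_field", binding_rate_hz, mean_on_time_s,
                    field_px, extra = list(diameter_nm = diameter_nm,
                                           sites_per_luv = sites_per_luv))
}

#' Fibril-like binding-site field
#'
#' Sites along a straight segment, emulating an amyloid fibril.
#'
#' @param length_px Fibril length in pixels.
#' @param n_sites Number of sites along the fibril.
#' @param wavelength_nm Site emission wavelength(s); recycled.
#' @param field_px Field side, pixels.
#' @inheritParams site_field
#' @return A `spaint_sample`.
#' @export
fibril_field <- function(length_px = 40, n_sites = 60, wavelength_nm = 610,
                         field_px = 64, binding_rate_hz = 0.1,
                         mean_on_time_s = 0.06) {
  t <- seq(0, 1, length.out = n_sites)
  sites <- tibble::tibble(
    x_px = field_px / 2 + (t - 0.5) * length_px / sqrt(2),
    y_px = field_px / 2 + (t - 0.5) * length_px / sqrt(2),
    wavelength_nm = rep_len(wavelength_nm, n_sites),
    structure_id = 1L)
  new_spaint_sample(sites, "fibril", binding_rate_hz, mean_on_time_s,
                    field_px)
}

#' Membrane-patch binding-site field
#'
#' Sites scattered uniformly over a rectangle with a smooth left-to-right
#' wavelength gradient; useful for exercising the spatio-temporal
#' hydrophobicity maps.
#'
#' @param n_sites Number of sites.
#' @param field_px Field side, pixels.
#' @param wavelength_range_nm Wavelengths at the left and right edges.
#' @inheritParams site_field
#' @return A `spaint_sample`.
#' @export
membrane_patch <- function(n_sites = 200, field_px = 64,
                           wavelength_range_nm = c(596, 608),
                           binding_rate_hz = 0.05, mean_on_time_s = 0.06) {
  x <- runif(n_sites, 1, field_px - 1)
  sites <- tibble::tibble(
    x_px = x, y_px = runif(n_sites, 1, field_px - 1),
    wavelength_nm = wavelength_range_nm[1] +
      (x / field_px) * diff(wavelength_range_nm),
    structure_id = seq_len(n_sites))
  new_spaint_sample(sites, "membrane_patch", binding_rate_hz, mean_on_time_s,
                    field_px)
}

# ---- sPAINT experiment stacks --------------------------------------------

#' Simulate an sPAINT acquisition
#'
#' Draws PAINT binding events per site as a Poisson process, holds each
#' event for `ceiling(tau / dt)` frames with `tau` exponential, and renders
#' for every bound frame one zeroth-order PSF plus one first-order spectral
#' blob at the dispersion-model displacement of the site's emission
#' wavelength. The photon budget is split
#' `zeroth_order_fraction : (1 - fraction) * (1 - transmission_loss)`
#' between the orders.
#'
#' @param sample A `spaint_sample` (e.g. [luv_field()]).
#' @param species An [emitter_species()] providing the per-frame photon
#'   budget, PSF width and spectral width; the peak wavelength is overridden
#'   per site.
#' @inheritParams simulate_calibration_stack
#' @return A `spaint_stack`; `truth` has one row per event-frame and an
#'   `events` attribute with one row per binding event (site, start frame,
#'   frame span, true on-time).
#' @export
simulate_spaint_stack <- function(sample,
                                  species = emitter_species(),
                                  camera = camera_model(),
                                  geometry = grating_geometry(),
                                  dispersion = dispersion_from_geometry(
                                    geometry, camera),
                                  n_frames = 1000,
                                  background_photons = 2,
                                  seed = NULL) {
  stopifnot(inherits(sample, "spaint_sample"), n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  field_px <- as.integer(ceiling(sample$field_px))
  sites <- sample$sites
  lam_max <- if (nrow(sites)) max(sites$wavelength_nm) else 700
  h <- stack_height(field_px, dispersion,
                    lam_max + 4 * species$spectral_sigma_nm)
  dt <- 1 / camera$frame_rate_hz
  duration <- n_frames * dt

  if (nrow(sites) == 0 || sample$binding_rate_hz == 0) {
    if (nrow(sites) == 0) warning("empty binding-site map: noise-only stack")
    events <- tibble::tibble(event_id = integer(), site = integer(),
                             start_frame = integer(), span_frames = integer(),
                             true_on_time_s = numeric())
  } else {
    n_ev <- rpois(nrow(sites), sample$binding_rate_hz * duration)
    events <- purrr::map_dfr(which(n_ev > 0), function(s) {
      tibble::tibble(site = s,
                     start_s = runif(n_ev[s], 0, duration),
                     tau = rexp(n_ev[s], rate = 1 / sample$mean_on_time_s))
    })
    if (nrow(events)) {
      events <- events |>
        dplyr::mutate(start_frame = pmin(floor(.data$start_s / dt), n_frames - 1) + 1L,
                      span_frames = pmax(1L, as.integer(ceiling(.data$tau / dt)))) |>
        dplyr::arrange(.data$start_frame, .data$site) |>
        dplyr::mutate(event_id = dplyr::row_number(),
                      true_on_time_s = .data$tau) |>
        dplyr::select("event_id", "site", "start_frame", "span_frames",
                      "true_on_time_s")
    } else {
      events <- tibble::tibble(event_id = integer(), site = integer(),
                               start_frame = integer(), span_frames = integer(),
                               true_on_time_s = numeric())
    }
  }

  split0 <- geometry$zeroth_order_fraction
  split1 <- (1 - split0) * (1 - geometry$transmission_loss)
  sy_spec <- sqrt(species$psf_sigma_px^2 +
                  (species$spectral_sigma_nm * dispersion$beta[["beta1"]])^2)

  truth <- if (nrow(events) == 0) empty_truth() else
    events |>
    dplyr::rowwise() |>
    dplyr::reframe(frame = seq(.data$start_frame,
                               min(.data$start_frame + .data$span_frames - 1L,
                                   n_frames)),
                   site = .data$site, event_id = .data$event_id) |>
    dplyr::mutate(x_px = sites$x_px[.data$site],
                  y_px = sites$y_px[.data$site],
                  photons = species$mean_photons * split0,
                  wavelength_nm = sites$wavelength_nm[.data$site]) |>
    dplyr::arrange(.data$frame, .data$y_px, .data$x_px) |>
    dplyr::select("frame", "x_px", "y_px", "photons", "wavelength_nm",
                  "site", "event_id")

  bg <- matrix(background_photons, nrow = h, ncol = field_px)
  by_frame <- if (nrow(truth)) split(truth, truth$frame) else list()
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    exp_img <- bg
    rows <- by_frame[[as.character(f)]]
    if (!is.null(rows)) {
      for (i in seq_len(nrow(rows))) {
        z <- dispersion_distance(dispersion$beta, rows$wavelength_nm[i],
                                 rows$x_px[i], rows$y_px[i])
        exp_img <- add_spot(exp_img, rows$x_px[i], rows$y_px[i],
                            species$psf_sigma_px, species$psf_sigma_px,
                            species$mean_photons * split0)
        exp_img <- add_spot(exp_img, rows$x_px[i], rows$y_px[i] + z,
                            species$psf_sigma_px, sy_spec,
                            species$mean_photons * split1)
      }
    }
    frames[[f]] <- camera_readout(exp_img, camera)
  }

  stack <- new_spaint_stack(frames, camera, geometry, dispersion,
                            c(0L, field_px), truth, background_photons)
  attr(stack, "events") <- events
  attr(stack, "sample") <- sample
  stack
}

# ---- fiducial localization tables ----------------------------------------

#' Simulate fiducial localizations for instrument-stability analysis
#'
#' Generates the localization table of an instrument-stability acquisition
#' directly at the localization level: immobilised beads imaged over many
#' frames, each localization scattered around the true bead position by
#' photon shot noise (standard deviation \eqn{c/\sqrt{N}} per axis)
#' combined in quadrature with the instrument-instability floor.
#' Instability in a sampled-stage microscope is drift/vibration along a
#' stage axis, so the spatial floor is applied as a uniaxial jitter along
#' the camera x axis -- the axis-wise "wider of the two" convention of the
#' downstream stability analysis exists precisely to capture this
#' drift-dominant direction. Per-frame fitted spectral centres are
#' generated the same way around the bead's reference emission peak, with
#' the (one-dimensional) spectral floor in quadrature.
#'
#' Defaults place the spatial floor at 6.6 nm and the spectral floor at
#' 1.3 nm. The spatial shot-noise coefficient is the PSF standard
#' deviation in nm (1.2 px x 106.67 nm/px = 128 nm sqrt(photon)), i.e.
#' the photon-counting-limited centroid precision \eqn{\sigma_{PSF}/\sqrt{N}}.
#' The spectral coefficient combines the first-order profile width
#' (PSF plus a 15 nm emission linewidth through the 0.394 px/nm
#' dispersion, about 6 px), the smaller first-order photon share
#' (0.4 x 0.7 of the total versus 0.6 in the zeroth order), and the
#' px-to-nm dispersion conversion, giving about 22 nm sqrt(photon) in
#' terms of the zeroth-order photon count.
#'
#' @param n_beads Number of beads (laid out on a grid, >= 8 px apart).
#' @param frames_per_bead Frames in which each bead is localized.
#' @param photon_range Range of mean detected photons per bead; bead means
#'   are log-spaced over this range, per-frame counts Poisson.
#' @param sigma_floor_xy_nm Spatial instability floor, nm.
#' @param sigma_floor_lambda_nm Spectral instability floor, nm.
#' @param shot_coef_xy_nm Spatial shot-noise coefficient c (nm sqrt(photon)).
#' @param shot_coef_lambda_nm Spectral shot-noise coefficient.
#' @param lambda_nm Reference spectral peak of the beads (~580 nm, the
#'   'orange' dye).
#' @param camera A [camera_model()] for the nm/pixel conversion.
#' @param seed Optional seed.
#' @return A localization tibble with columns `frame`, `x_px`, `y_px`,
#'   `photons`, `lambda_nm` and the true `bead_id`.
#' @export
simulate_fiducial_localizations <- function(n_beads = 40,
                                            frames_per_bead = 50,
                                            photon_range = c(100, 10000),
                                            sigma_floor_xy_nm = 6.6,
                                            sigma_floor_lambda_nm = 1.3,
                                            shot_coef_xy_nm = 128,
                                            shot_coef_lambda_nm = 22,
                                            lambda_nm = 580,
                                            camera = camera_model(),
                                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ncol_grid <- ceiling(sqrt(n_beads))
  idx <- seq_len(n_beads) - 1L
  bead <- tibble::tibble(
    bead_id = seq_len(n_beads),
    x0 = (idx %% ncol_grid) * 8 + 4 + runif(n_beads, -1, 1),
    y0 = (idx %/% ncol_grid) * 8 + 4 + runif(n_beads, -1, 1),
    # log-spaced levels guarantee the whole range is spanned; per-frame
    # counts are Poisson around each level
    mean_photons = exp(seq(log(photon_range[1]), log(photon_range[2]),
                           length.out = n_beads)))
  px <- camera$effective_pixel_nm
  purrr::map_dfr(seq_len(n_beads), function(b) {
    n <- frames_per_bead
    N <- pmax(1, rpois(n, bead$mean_photons[b]))
    s_shot <- shot_coef_xy_nm / sqrt(N)
    # drift jitter acts along the camera x axis; y is shot-noise limited
    s_x <- sqrt(sigma_floor_xy_nm^2 + s_shot^2)
    s_l <- sqrt(sigma_floor_lambda_nm^2 + shot_coef_lambda_nm^2 / N)
    tibble::tibble(frame = seq_len(n),
                   x_px = bead$x0[b] + rnorm(n, sd = s_x) / px,
                   y_px = bead$y0[b] + rnorm(n, sd = s_shot) / px,
                   photons = N,
                   lambda_nm = lambda_nm + rnorm(n, sd = s_l),
                   bead_id = b)
  }) |>
    dplyr::arrange(.data$frame, .data$y_px, .data$x_px)
}

# ---- stack I/O ------------------------------------------------------------

#' Write / read a frame stack
#'
#' Frames are written as a 16-bit grayscale multi-page TIFF; the ground
#' truth goes to a CSV side-car (`<stem>_truth.csv`, columns
#' `frame,x_px,y_px,photons,wavelength_nm`) and the instrument metadata to
#' a flat key-value text side-car (`<stem>_meta.txt`). The round trip is
#' lossless for the pixel data.
#'
#' @param stack A `spaint_stack`.
#' @param path Path of the TIFF file.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   the reconstructed `spaint_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "spaint_stack"))
  if (stack$n_frames == 0) stop("cannot write an empty stack", call. = FALSE)
  tiff::writeTIFF(lapply(stack$frames, function(f) f / 65535), path,
                  bits.per.sample = 16L, compression = "none")
  stem <- tools::file_path_sans_ext(path)
  readr::write_csv(stack$truth[, c("frame", "x_px", "y_px", "photons",
                                   "wavelength_nm")],
                   paste0(stem, "_truth.csv"))
  meta <- c(
    n_frames = stack$n_frames,
    spatial_row_min = stack$spatial_rows[1],
    spatial_row_max = stack$spatial_rows[2],
    background_photons = stack$background_photons,
    pixel_size_um = stack$camera$pixel_size_um,
    magnification = stack$camera$magnification,
    gain_camera = stack$camera$gain_camera,
    gain_em = stack$camera$gain_em,
    quantum_efficiency = stack$camera$quantum_efficiency,
    baseline_adu = stack$camera$baseline_adu,
    read_noise_adu = stack$camera$read_noise_adu,
    frame_rate_hz = stack$camera$frame_rate_hz,
    groove_spacing_nm = stack$geometry$groove_spacing_nm,
    blaze_angle_deg = stack$geometry$blaze_angle_deg,
    grating_to_detector_mm = stack$geometry$grating_to_detector_mm,
    order = stack$geometry$order,
    zeroth_order_fraction = stack$geometry$zeroth_order_fraction,
    transmission_loss = stack$geometry$transmission_loss,
    beta0 = stack$dispersion$beta[["beta0"]],
    beta1 = stack$dispersion$beta[["beta1"]],
    beta2 = stack$dispersion$beta[["beta2"]],
    beta3 = stack$dispersion$beta[["beta3"]])
  writeLines(paste0(names(meta), " = ", format(meta, digits = 17,
                                               scientific = FALSE,
                                               trim = TRUE)),
             paste0(stem, "_meta.txt"))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  img <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                  error = function(e)
                    stop("malformed TIFF '", path, "': ", conditionMessage(e),
                         call. = FALSE))
  frames <- lapply(seq_along(img), function(i) {
    f <- img[[i]]
    if (!is.matrix(f)) stop("malformed TIFF: frame ", i,
                            " is not single-channel grayscale", call. = FALSE)
    matrix(as.integer(f), nrow = nrow(f))
  })
  stem <- tools::file_path_sans_ext(path)
  kv <- read_key_values(paste0(stem, "_meta.txt"))
  truth <- readr::read_csv(paste0(stem, "_truth.csv"),
                           show_col_types = FALSE)
  camera <- camera_model(
    pixel_size_um = kv$pixel_size_um, magnification = kv$magnification,
    gain_camera = kv$gain_camera, gain_em = kv$gain_em,
    quantum_efficiency = kv$quantum_efficiency,
    baseline_adu = kv$baseline_adu, read_noise_adu = kv$read_noise_adu,
    frame_rate_hz = kv$frame_rate_hz)
  geometry <- grating_geometry(
    groove_spacing_nm = kv$groove_spacing_nm,
    blaze_angle_deg = kv$blaze_angle_deg,
    grating_to_detector_mm = kv$grating_to_detector_mm,
    order = as.integer(kv$order),
    zeroth_order_fraction = kv$zeroth_order_fraction,
    transmission_loss = kv$transmission_loss)
  dispersion <- linear_dispersion(kv$beta0, kv$beta1, kv$beta2, kv$beta3)
  new_spaint_stack(frames, camera, geometry, dispersion,
                   c(as.integer(kv$spatial_row_min),
                     as.integer(kv$spatial_row_max)),
                   truth, kv$background_photons)
}

# flat "key = value" files used for metadata and calibration coefficients
read_key_values <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(parts, function(p) {
    v <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  setNames(vals, trimws(vapply(parts, `[[`, character(1), 1)))
}

write_key_values <- function(x, path, header = NULL) {
  vals <- vapply(x, function(v)
    if (is.numeric(v)) format(v, digits = 17, scientific = FALSE, trim = TRUE)
    else as.character(v), character(1))
  writeLines(c(if (!is.null(header)) paste0("# ", header),
               paste0(names(x), " = ", vals)), path)
  invisible(path)
}
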