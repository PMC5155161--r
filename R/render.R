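# ---- configuration --------------------------------------------------------

#' Rendering configuration
#'
#' @param output_pixel_nm Super-resolved output pixel, nm (10 nm default,
#'   well below the ~106.7 nm camera pixel).
#' @param colormap Colour scale for wavelength; `"jet"` only.
#' @param wavelength_range_nm Wavelengths mapped to the colour-scale ends
#'   (560-700 nm, the dynamic range of the solvatochromic dye).
#' @param kernel_bandwidth_nm Gaussian bandwidth of the Nadaraya-Watson
#'   smoother, nm in the sample plane.
#' @param window_frames Temporal moving-box length, frames (200).
#' @param shift_frames Moving-box shift, frames (16; 0.8 s at 20 Hz).
#' @param nw_pixel_nm Evaluation-grid pixel of the Nadaraya-Watson maps.
#' @param truncation_sigma Gaussian truncation radius for rendering, in
#'   sigmas.
#' @return An object of class `render_config`.
#' @export
render_config <- function(output_pixel_nm = 10, colormap = "jet",
                          wavelength_range_nm = c(560, 700),
                          kernel_bandwidth_nm = 100,
                          window_frames = 200L, shift_frames = 16L,
                          nw_pixel_nm = 50, truncation_sigma = 4) {
  stopifnot(output_pixel_nm > 0, window_frames >= shift_frames,
            shift_frames >= 1, kernel_bandwidth_nm > 0)
  structure(list(output_pixel_nm = output_pixel_nm, colormap = colormap,
                 wavelength_range_nm = wavelength_range_nm,
                 kernel_bandwidth_nm = kernel_bandwidth_nm,
                 window_frames = as.integer(window_frames),
                 shift_frames = as.integer(shift_frames),
                 nw_pixel_nm = nw_pixel_nm,
                 truncation_sigma = truncation_sigma),
            class = "render_config")
}

# jet colour scale: value in [0, 1] -> n x 3 RGB matrix
jet_rgb <- function(v) {
  anchors <- c(0, 0.125, 0.375, 0.625, 0.875, 1)
  r <- c(0, 0, 0, 1, 1, 0.5)
  g <- c(0, 0, 1, 1, 0, 0)
  b <- c(0.5, 1, 1, 0, 0, 0)
  v <- pmin(pmax(v, 0), 1)
  cbind(approx(anchors, r, v)$y, approx(anchors, g, v)$y,
        approx(anchors, b, v)$y)
}

# ---- density rendering ----------------------------------------------------

# accumulate per-localization data onto the output grid.
# Returns list(density, wsum, wlsum) matrices.
accumulate_render <- function(table, config, camera, extent_px) {
  scale <- camera$effective_pixel_nm / config$output_pixel_nm
  nx <- as.integer(ceiling(extent_px[1] * scale))
  ny <- as.integer(ceiling(extent_px[2] * scale))
  dens <- matrix(0, ny, nx)
  wsum <- matrix(0, ny, nx)
  wlsum <- matrix(0, ny, nx)
  has_lambda <- "wavelength_nm" %in% names(table)
  trunc <- config$truncation_sigma
  for (i in seq_len(nrow(table))) {
    u <- table$x_px[i] * scale
    v <- table$y_px[i] * scale
    s <- max(table$precision_nm[i] / config$output_pixel_nm, 1e-6)
    xs <- max(0L, floor(u - trunc * s)):min(nx - 1L, ceiling(u + trunc * s))
    ys <- max(0L, floor(v - trunc * s)):min(ny - 1L, ceiling(v + trunc * s))
    if (xs[1] > xs[length(xs)] || ys[1] > ys[length(ys)]) next
    mass <- gauss_pixel_mass(ys, v, s) %o% gauss_pixel_mass(xs, u, s)
    dens[ys + 1L, xs + 1L] <- dens[ys + 1L, xs + 1L] + mass
    if (has_lambda && !is.na(table$wavelength_nm[i])) {
      w <- table$photons[i] * mass
      wsum[ys + 1L, xs + 1L] <- wsum[ys + 1L, xs + 1L] + w
      wlsum[ys + 1L, xs + 1L] <- wlsum[ys + 1L, xs + 1L] +
        w * table$wavelength_nm[i]
    }
  }
  list(density = dens, wsum = wsum, wlsum = wlsum)
}

#' Render a super-resolved localization density image
#'
#' Each localization deposits a discretized 2D Gaussian whose per-pixel
#' mass is the product over the axes of half the difference of error
#' functions across the pixel edges, normalised to unit integral, with
#' width set by that localization's precision. The total image mass equals
#' the number of localizations up to the truncation error.
#'
#' @param table Localization tibble with `precision_nm`.
#' @param config A [render_config()].
#' @param camera A [camera_model()].
#' @param extent_px Field extent `c(x, y)` in camera pixels (defaults to
#'   the bounding box of the table).
#' @return An object of class `spaint_image`: list with the `density`
#'   matrix (row = y), `pixel_nm` and `n_localizations`.
#' @export
render_density <- function(table, config = render_config(),
                           camera = camera_model(), extent_px = NULL) {
  stopifnot("precision_nm" %in% names(table))
  if (is.null(extent_px)) {
    extent_px <- c(max(table$x_px) + 2, max(table$y_px) + 2)
  }
  acc <- accumulate_render(table, config, camera, extent_px)
  structure(list(density = acc$density,
                 pixel_nm = config$output_pixel_nm,
                 n_localizations = nrow(table)),
            class = "spaint_image")
}

#' Render a false-coloured sPAINT hydrophobicity map
#'
#' The wavelength at each output pixel is the average of the wavelengths
#' observed there, weighted by localization intensity (photons) times each
#' localization's Gaussian mass in the pixel; the result is jet-coloured
#' and overlaid on the localization density image (density sets
#' brightness; pixels without spectral mass are rendered density-only in
#' grey).
#'
#' @inheritParams render_density
#' @return An object of class `spaint_render`: list with `density`,
#'   `wavelength` (per-pixel mean wavelength, `NA` where no spectral
#'   mass), `rgb` (ny x nx x 3 array in [0, 1]), `pixel_nm`, `config`.
#' @export
render_spaint <- function(table, config = render_config(),
                          camera = camera_model(), extent_px = NULL) {
  stopifnot("wavelength_nm" %in% names(table))
  if (!any(!is.na(table$wavelength_nm))) {
    stop("no assigned wavelengths to render", call. = FALSE)
  }
  if (is.null(extent_px)) {
    extent_px <- c(max(table$x_px) + 2, max(table$y_px) + 2)
  }
  acc <- accumulate_render(table, config, camera, extent_px)
  lam <- acc$wlsum / acc$wsum
  lam[acc$wsum <= 0] <- NA_real_
  bright <- acc$density / max(quantile(acc$density[acc$density > 0], 0.999),
                              .Machine$double.eps)
  bright <- pmin(bright, 1)
  rng <- config$wavelength_range_nm
  hue <- jet_rgb((as.vector(lam) - rng[1]) / (rng[2] - rng[1]))
  hue[is.na(hue)] <- 1   # spectra-free pixels: grey (density-only)
  rgb_arr <- array(0, dim = c(nrow(lam), ncol(lam), 3))
  for (k in 1:3) {
    rgb_arr[, , k] <- matrix(hue[, k], nrow(lam)) * bright
  }
  structure(list(density = acc$density, wavelength = lam, rgb = rgb_arr,
                 pixel_nm = config$output_pixel_nm, config = config),
            class = "spaint_render")
}

# ---- spatio-temporal hydrophobicity maps ---------------------------------

#' Nadaraya-Watson spatio-temporal hydrophobicity maps
#'
#' Smooths the per-localization wavelengths onto a spatial grid with
#' Nadaraya-Watson kernel regression (Gaussian kernel), inside a moving
#' temporal box: a window of `window_frames` frames advances by
#' `shift_frames` per map, so a 3,000-frame acquisition with a 200-frame
#' window and 16-frame shift yields 176 maps with a temporal resolution of
#' 0.8 s at 20 Hz.
#'
#' @param table Localization tibble with assigned `wavelength_nm`.
#' @param config A [render_config()] (`window_frames`, `shift_frames`,
#'   `kernel_bandwidth_nm`, `nw_pixel_nm`).
#' @param camera A [camera_model()].
#' @param n_frames Total acquisition frames (defaults to `max(frame)`).
#' @param extent_px Field extent in camera pixels.
#' @return An object of class `spaint_temporal_map`: list with `maps`
#'   (list of wavelength matrices, `NA` beyond the kernel support),
#'   `times` (tibble `window`, `start_frame`, `mid_time_s`), `pixel_nm`,
#'   `config`.
#' @export
temporal_hydrophobicity_map <- function(table, config = render_config(),
                                        camera = camera_model(),
                                        n_frames = max(table$frame),
                                        extent_px = NULL) {
  stopifnot("wavelength_nm" %in% names(table))
  tab <- dplyr::filter(table, !is.na(.data$wavelength_nm))
  if (n_frames < config$window_frames) {
    stop("window (", config$window_frames,
         " frames) larger than the acquisition (", n_frames, ")",
         call. = FALSE)
  }
  if (is.null(extent_px)) {
    extent_px <- c(max(tab$x_px) + 2, max(tab$y_px) + 2)
  }
  px_nm <- camera$effective_pixel_nm
  grid_nm <- config$nw_pixel_nm
  nx <- as.integer(ceiling(extent_px[1] * px_nm / grid_nm))
  ny <- as.integer(ceiling(extent_px[2] * px_nm / grid_nm))
  h <- config$kernel_bandwidth_nm
  trunc_px <- config$truncation_sigma * h / grid_nm
  starts <- seq(1L, n_frames - config$window_frames + 1L,
                by = config$shift_frames)
  maps <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    s <- starts[w]
    rows <- tab[tab$frame >= s & tab$frame <= s + config$window_frames - 1L, ]
    num <- matrix(0, ny, nx)
    den <- matrix(0, ny, nx)
    for (i in seq_len(nrow(rows))) {
      u <- rows$x_px[i] * px_nm / grid_nm
      v <- rows$y_px[i] * px_nm / grid_nm
      xs <- max(0L, floor(u - trunc_px)):min(nx - 1L, ceiling(u + trunc_px))
      ys <- max(0L, floor(v - trunc_px)):min(ny - 1L, ceiling(v + trunc_px))
      if (xs[1] > xs[length(xs)] || ys[1] > ys[length(ys)]) next
      kx <- dnorm((xs - u) * grid_nm / h)
      ky <- dnorm((ys - v) * grid_nm / h)
      K <- ky %o% kx
      num[ys + 1L, xs + 1L] <- num[ys + 1L, xs + 1L] +
        K * rows$wavelength_nm[i]
      den[ys + 1L, xs + 1L] <- den[ys + 1L, xs + 1L] + K
    }
    m <- num / den
    m[den <= 0] <- NA_real_
    maps[[w]] <- m
  }
  times <- tibble::tibble(
    window = seq_along(starts),
    start_frame = starts,
    mid_time_s = (starts - 1 + config$window_frames / 2) /
      camera$frame_rate_hz)
  structure(list(maps = maps, times = times, pixel_nm = grid_nm,
                 config = config),
            class = "spaint_temporal_map")
}

#' @export
print.spaint_temporal_map <- function(x, ...) {
  cat(sprintf(
    "<spaint_temporal_map> %d map(s), window %d frames, shift %d frames\n",
    length(x$maps), x$config$window_frames, x$config$shift_frames))
  invisible(x)
}

# ---- image output ---------------------------------------------------------

#' Write rendered images to disk
#'
#' `write_image()` writes a density or wavelength matrix as a 32-bit float
#' TIFF; `write_render_png()` writes the false-coloured RGB render as PNG
#' (via [grDevices::png()] is avoided -- the array is written directly with
#' the tiff package as an RGB TIFF when `format = "tiff"`).
#' `write_temporal_maps()` writes the per-window wavelength maps as a
#' multi-page TIFF plus a CSV of window times.
#'
#' @param x A `spaint_image`, `spaint_render` or `spaint_temporal_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  m <- if (inherits(x, "spaint_image")) x$density
       else if (inherits(x, "spaint_render")) x$rgb
       else stop("unsupported object")
  mx <- max(m, na.rm = TRUE)
  tiff::writeTIFF(if (mx > 0) m / mx else m, path,
                  bits.per.sample = 32L, compression = "none")
  invisible(path)
}

#' @rdname write_image
#' @export
write_temporal_maps <- function(x, path) {
  stopifnot(inherits(x, "spaint_temporal_map"))
  rng <- range(unlist(lapply(x$maps, function(m) m[!is.na(m)])), finite = TRUE)
  norm <- lapply(x$maps, function(m) {
    m[is.na(m)] <- rng[1]
    (m - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  })
  tiff::writeTIFF(norm, path, bits.per.sample = 32L, compression = "none")
  readr::write_csv(x$times,
                   paste0(tools::file_path_sans_ext(path), "_times.csv"))
  invisible(path)
}
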