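# ---- separable Gaussian convolution --------------------------------------

# cache of band kernel matrices keyed by "n:sigma"
.conv_cache <- new.env(parent = emptyenv())

band_kernel <- function(n, sigma) {
  key <- paste0(n, ":", signif(sigma, 8))
  if (!is.null(.conv_cache[[key]])) return(.conv_cache[[key]])
  half <- ceiling(4 * sigma)
  g <- dnorm(-half:half, sd = sigma)
  g <- g / sum(g)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - half):(j + half)
    ok <- idx >= 1 & idx <= n
    K[idx[ok], j] <- g[ok]
  }
  .conv_cache[[key]] <- K
  K
}

# zero-padded separable Gaussian smoothing of a matrix
gauss_smooth <- function(m, sigma) {
  Kr <- band_kernel(nrow(m), sigma)
  Kc <- band_kernel(ncol(m), sigma)
  t(Kr) %*% m %*% Kc
}

# ---- candidate detection --------------------------------------------------

#' Detect candidate emitters in one frame
#'
#' Band-pass filters the (spatial sub-region of the) frame with a
#' difference of Gaussians matched to the PSF, estimates the noise level
#' robustly (MAD), and returns the local maxima whose filtered amplitude
#' exceeds `threshold` times the noise. This "signal strength" --
#' band-pass amplitude over robust noise sd -- plays the role of the
#' signal-strength threshold of standard SMLM peak-fitting software
#' (default 30).
#'
#' @param frame_image Integer/numeric matrix (ADU), already restricted to
#'   the spatial sub-region.
#' @param threshold Signal-strength threshold.
#' @param psf_sigma_px Expected PSF width, pixels.
#' @return A tibble with 0-based integer `x_px`, `y_px` and `strength`,
#'   sorted by decreasing strength. Adjacent maxima within 2 px are merged,
#'   keeping the larger filtered amplitude.
#' @export
detect_candidates <- function(frame_image, threshold = 30,
                              psf_sigma_px = 1.2) {
  m <- frame_image
  storage.mode(m) <- "double"
  band <- gauss_smooth(m, psf_sigma_px) - gauss_smooth(m, 3 * psf_sigma_px)
  noise <- mad(band)
  if (noise <= 0) noise <- sd(band)
  if (!is.finite(noise) || noise <= 0) {
    return(tibble::tibble(x_px = integer(), y_px = integer(),
                          strength = numeric()))
  }
  nr <- nrow(band); nc <- ncol(band)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- band
  is_max <- matrix(TRUE, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- pad[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
    # ties between equal neighbours broken towards the earlier (upper-left)
    # pixel in scan order
    is_max <- is_max & if (dy < 0 || (dy == 0 && dx < 0)) band > nb
                       else band >= nb
  }
  keep <- which(is_max & band / noise >= threshold, arr.ind = TRUE)
  if (nrow(keep) == 0) {
    return(tibble::tibble(x_px = integer(), y_px = integer(),
                          strength = numeric()))
  }
  out <- tibble::tibble(x_px = as.integer(keep[, 2] - 1L),
                        y_px = as.integer(keep[, 1] - 1L),
                        strength = band[keep] / noise) |>
    dplyr::arrange(dplyr::desc(.data$strength))
  # merge maxima closer than 2 px, keeping the stronger
  sel <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!sel[i]) next
    close <- which(sel & abs(out$x_px - out$x_px[i]) <= 2 &
                     abs(out$y_px - out$y_px[i]) <= 2)
    sel[setdiff(close, i)] <- FALSE
  }
  out[sel, ]
}

# ---- single-spot fitting --------------------------------------------------

#' Mortensen-style localization precision estimate
#'
#' Least-squares localization precision from photons, PSF width, background
#' and pixel size, including a factor 2 excess-noise penalty for the EM
#' register.
#'
#' @param photons Detected photons in the spot.
#' @param sigma_px Fitted PSF width, pixels.
#' @param background_photons Background, photons/pixel.
#' @param pixel_nm Effective sample-plane pixel size, nm.
#' @return Estimated precision, nm.
#' @export
localization_precision <- function(photons, sigma_px, background_photons,
                                   pixel_nm) {
  s_nm <- sigma_px * pixel_nm
  sa2 <- s_nm^2 + pixel_nm^2 / 12
  v <- sa2 / photons *
    (16 / 9 + 8 * pi * sa2 * pmax(background_photons, 0) /
       (photons * pixel_nm^2))
  sqrt(2 * v)
}

#' Fit one spot with a 2D Gaussian
#'
#' Least-squares fit of amplitude, sub-pixel centre, isotropic width and
#' flat offset over a square window around the candidate, by
#' Levenberg-Marquardt. Photons are the integral of the fitted Gaussian in
#' ADU divided by the total camera gain,
#' `photons = 2 * pi * A * sigma^2 / GainTotal`.
#'
#' @param frame_image Matrix (ADU) of the spatial sub-region.
#' @param candidate One-row tibble (or list) with 0-based `x_px`, `y_px`.
#' @param camera A [camera_model()].
#' @param psf_sigma_px Initial PSF width; the fit window is
#'   `2 * ceiling(3 * psf_sigma_px) + 1` px.
#' @param frame Frame number stored in the output row.
#' @return A one-row tibble: `frame`, `x_px`, `y_px`, `photons`,
#'   `background`, `sigma_px`, `precision_nm`, `fit_ok`, `reject_reason`.
#'   Failed fits carry `fit_ok = FALSE` and a reason code
#'   (`window_clipped`, `no_convergence`, `drifted`, `nonpositive`).
#' @export
fit_spot <- function(frame_image, candidate, camera = camera_model(),
                     psf_sigma_px = 1.2, frame = 1L) {
  cx <- candidate$x_px[1]; cy <- candidate$y_px[1]
  half <- ceiling(3 * psf_sigma_px)
  fail <- function(reason) tibble::tibble(
    frame = as.integer(frame), x_px = NA_real_, y_px = NA_real_,
    photons = NA_real_, background = NA_real_, sigma_px = NA_real_,
    precision_nm = NA_real_, fit_ok = FALSE, reject_reason = reason)
  if (cx - half < 0 || cy - half < 0 ||
      cx + half > ncol(frame_image) - 1 || cy + half > nrow(frame_image) - 1) {
    return(fail("window_clipped"))
  }
  xs <- (cx - half):(cx + half)
  ys <- (cy - half):(cy + half)
  z <- as.vector(frame_image[ys + 1L, xs + 1L])
  grid <- expand.grid(Y = ys, X = xs)
  b0 <- median(z[grid$X == xs[1] | grid$X == xs[length(xs)] |
                   grid$Y == ys[1] | grid$Y == ys[length(ys)]])
  a0 <- max(z) - b0
  if (a0 <= 0) return(fail("nonpositive"))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + A * exp(-((X - x0)^2 + (Y - y0)^2) / (2 * s^2)),
      data = cbind(grid, z = z),
      start = list(A = a0, x0 = cx, y0 = cy, s = psf_sigma_px, b = b0),
      lower = c(A = 0, x0 = cx - half, y0 = cy - half, s = 0.4, b = -Inf),
      upper = c(A = Inf, x0 = cx + half, y0 = cy + half, s = 4 * psf_sigma_px,
                b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 60)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("no_convergence"))
  p <- coef(fit)
  if (p[["A"]] <= 0 || p[["s"]] <= 0) return(fail("nonpositive"))
  if (abs(p[["x0"]] - cx) > 2 || abs(p[["y0"]] - cy) > 2) {
    return(fail("drifted"))
  }
  gt <- gain_total(camera)
  photons <- 2 * pi * p[["A"]] * p[["s"]]^2 / gt
  bg <- (p[["b"]] - camera$baseline_adu) / gt
  tibble::tibble(
    frame = as.integer(frame), x_px = p[["x0"]], y_px = p[["y0"]],
    photons = photons, background = bg, sigma_px = p[["s"]],
    precision_nm = localization_precision(photons, p[["s"]], bg,
                                          camera$effective_pixel_nm),
    fit_ok = TRUE, reject_reason = NA_character_)
}

# ---- whole-stack localization --------------------------------------------

#' Localize every frame of a stack
#'
#' Runs [detect_candidates()] and [fit_spot()] on the spatial sub-region of
#' each frame and collects the successful fits.
#'
#' @param stack A `spaint_stack`.
#' @param threshold Signal-strength detection threshold.
#' @param psf_sigma_px Expected PSF width, pixels.
#' @param verbose Print a per-stack summary of detected/fitted counts.
#' @return A localization tibble sorted by `(frame, y_px, x_px)` with
#'   columns `frame`, `x_px`, `y_px`, `photons`, `background`, `sigma_px`,
#'   `precision_nm`. Duplicate identical rows are dropped. The counts per
#'   frame are attached as attribute `frame_log`.
#' @export
localize_stack <- function(stack, threshold = 30, psf_sigma_px = 1.2,
                           verbose = FALSE) {
  stopifnot(inherits(stack, "spaint_stack"))
  rows <- (stack$spatial_rows[1] + 1L):stack$spatial_rows[2]
  res <- vector("list", stack$n_frames)
  log <- integer(stack$n_frames)
  for (f in seq_len(stack$n_frames)) {
    sub <- stack$frames[[f]][rows, , drop = FALSE]
    cand <- detect_candidates(sub, threshold, psf_sigma_px)
    log[f] <- nrow(cand)
    if (nrow(cand) == 0) next
    fits <- purrr::map_dfr(seq_len(nrow(cand)), function(i)
      fit_spot(sub, cand[i, ], stack$camera, psf_sigma_px, frame = f))
    res[[f]] <- fits[fits$fit_ok, ]
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(frame = integer(), x_px = numeric(),
                          y_px = numeric(), photons = numeric(),
                          background = numeric(), sigma_px = numeric(),
                          precision_nm = numeric())
  } else {
    out$y_px <- out$y_px + stack$spatial_rows[1]
    out <- out |>
      dplyr::select(-"fit_ok", -"reject_reason") |>
      dplyr::distinct() |>
      dplyr::arrange(.data$frame, .data$y_px, .data$x_px)
  }
  if (verbose) {
    message(sprintf("localized %d spots over %d frames (median %d/frame)",
                    nrow(out), stack$n_frames, median(log)))
  }
  attr(out, "frame_log") <- log
  out
}

# ---- localization table I/O ----------------------------------------------

#' Write / read a localization table
#'
#' CSV with a mandatory header
#' `frame,x_px,y_px,photons,background,sigma_px,precision_nm` plus optional
#' `wavelength_nm`, `qc_reason` and `cluster_id` columns; `#`-prefixed
#' provenance lines are allowed before the header.
#'
#' @param table Localization tibble.
#' @param path CSV path.
#' @param provenance Optional character vector written as `#` comment
#'   lines above the header.
#' @return `write_localizations()` returns `path` invisibly;
#'   `read_localizations()` returns a tibble.
#' @export
write_localizations <- function(table, path, provenance = NULL) {
  keep <- intersect(c("frame", "x_px", "y_px", "photons", "background",
                      "sigma_px", "precision_nm", "wavelength_nm",
                      "qc_reason", "cluster_id"), names(table))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), path)
    readr::write_csv(table[, keep], path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(table[, keep], path)
  }
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
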