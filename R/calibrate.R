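# ---- spectral profile extraction -----------------------------------------

#' Extract a spectral intensity profile
#'
#' Cuts a 31-sample intensity trace from the first-order (spectral) region
#' of a full frame: 15 pixels either side of the estimated first-order
#' position along the dispersion (y) axis, averaged over 3 pixels across it
#' (the spectra are wider than one pixel). The local background, the median
#' of the five samples at each tail, is subtracted.
#'
#' @param full_frame Full detector frame (matrix, ADU).
#' @param anchor_x,anchor_y Zeroth-order position of the localization,
#'   0-based pixels.
#' @param estimated_distance_px User-estimated Z0Z1 distance at which to
#'   anchor the window.
#' @param half_width Samples either side of the anchor (15).
#' @param transverse Columns averaged across the dispersion axis (3),
#'   centred on the anchor column.
#' @return A tibble of class `spaint_profile` with columns `offset_px`
#'   (-15..15) and `intensity` (background-subtracted ADU), carrying the
#'   attribute `z_at_zero` (the absolute Z0Z1 distance of offset 0), or
#'   `NULL` when the window falls outside the frame.
#' @export
extract_profile <- function(full_frame, anchor_x, anchor_y,
                            estimated_distance_px,
                            half_width = 15L, transverse = 3L) {
  r0 <- round(anchor_y + estimated_distance_px)
  c0 <- round(anchor_x)
  halfc <- (transverse - 1L) %/% 2L
  rows <- (r0 - half_width):(r0 + half_width)
  cols <- (c0 - halfc):(c0 + halfc)
  if (rows[1] < 0 || rows[length(rows)] > nrow(full_frame) - 1 ||
      cols[1] < 0 || cols[length(cols)] > ncol(full_frame) - 1) {
    return(NULL)
  }
  trace <- rowMeans(full_frame[rows + 1L, cols + 1L, drop = FALSE])
  bg <- median(c(head(trace, 5), tail(trace, 5)))
  out <- tibble::tibble(offset_px = -half_width:half_width,
                        intensity = trace - bg)
  attr(out, "z_at_zero") <- r0 - anchor_y
  class(out) <- c("spaint_profile", class(out))
  out
}

# ---- Gaussian peak fit with quality control ------------------------------

#' Fit a Gaussian to a spectral profile
#'
#' Nonlinear least-squares (Levenberg-Marquardt) fit of a Gaussian plus
#' flat offset to an intensity profile, with the four quality-control
#' rules applied to the result: fits with negative amplitude, centre
#' outside the profile range, or width < 1.5 px or > 20 px are discarded.
#'
#' @param profile A profile from [extract_profile()].
#' @return One-row tibble: `amplitude`, `center_px` (absolute Z0Z1
#'   distance when the profile carries its anchor, otherwise the offset),
#'   `center_offset_px`, `width_px`, `offset_adu`, `qc_pass`, `qc_reason`.
#' @export
fit_peak <- function(profile) {
  stopifnot(is.data.frame(profile), all(c("offset_px", "intensity") %in%
                                          names(profile)))
  z0 <- attr(profile, "z_at_zero") %||% 0
  rng <- range(profile$offset_px)
  fail <- function(reason) tibble::tibble(
    amplitude = NA_real_, center_px = NA_real_, center_offset_px = NA_real_,
    width_px = NA_real_, offset_adu = NA_real_,
    qc_pass = FALSE, qc_reason = reason)
  a0 <- max(profile$intensity)
  if (!is.finite(a0) || a0 <= 0) return(fail("negative_amplitude"))
  mu0 <- profile$offset_px[which.max(profile$intensity)]
  try_fit <- function(start) tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      intensity ~ b + A * exp(-(offset_px - mu)^2 / (2 * w^2)),
      data = profile, start = start,
      lower = c(A = -Inf, mu = rng[1] - 10, w = 0.3, b = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 80))),
    error = function(e) NULL)
  fit <- try_fit(list(A = a0, mu = mu0, w = 3, b = 0))
  if (is.null(fit)) {
    # a start sitting exactly on a symmetry point of noiseless data can
    # make the initial Jacobian rank-deficient; retry slightly off it
    fit <- try_fit(list(A = 0.9 * a0, mu = mu0 + 0.3, w = 3.5,
                        b = min(profile$intensity)))
  }
  if (is.null(fit)) return(fail("no_convergence"))
  p <- coef(fit)
  reason <- if (p[["A"]] <= 0) "negative_amplitude"
    else if (p[["mu"]] < rng[1] || p[["mu"]] > rng[2]) "center_out_of_range"
    else if (p[["w"]] < 1.5) "width_too_small"
    else if (p[["w"]] > 20) "width_too_large"
    else NA_character_
  tibble::tibble(
    amplitude = p[["A"]], center_px = z0 + p[["mu"]],
    center_offset_px = p[["mu"]], width_px = p[["w"]],
    offset_adu = p[["b"]],
    qc_pass = is.na(reason), qc_reason = reason)
}

# ---- multiple linear regression calibration ------------------------------

#' Fit the wavelength calibration model
#'
#' Ordinary least squares of the measured Z0Z1 distances on the reference
#' wavelength and the spatial position of the emitter,
#' `Z0Z1 = beta0 + beta1 * lambda + beta2 * x + beta3 * y`,
#' which captures the linear dispersion and the field aberration of the
#' grating. (The regression response is the Z0Z1 distance; the spatial
#' coordinate `y` is a separate covariate.)
#'
#' @param measurements Tibble with columns `wavelength_nm` (reference dye
#'   wavelength), `x_px`, `y_px`, `z0z1_px`, and optionally `bead_id`.
#' @param min_rows Minimum number of rows required.
#' @param passband_nm Wavelength range over which the model is intended to
#'   be applied.
#' @return An object of class `spaint_calibration` with elements `beta`
#'   (beta0..beta3), `residual_sd`, `n`, `n_beads`, `passband_nm`,
#'   `reference_wavelengths_nm` and the underlying `lm` fit.
#' @export
fit_calibration <- function(measurements, min_rows = 30,
                            passband_nm = c(480, 760)) {
  m <- measurements
  stopifnot(all(c("wavelength_nm", "x_px", "y_px", "z0z1_px") %in% names(m)))
  if (nrow(m) < min_rows) {
    stop("calibration needs at least ", min_rows,
         " qc-passing peak measurements, got ", nrow(m), call. = FALSE)
  }
  X <- cbind(1, m$wavelength_nm, m$x_px, m$y_px)
  if (qr(X)$rank < 4 || kappa(scale(X[, -1], scale = FALSE)) > 1e10) {
    stop("calibration design is rank deficient (beads do not span ",
         "wavelength, x and y)", call. = FALSE)
  }
  fit <- lm(z0z1_px ~ wavelength_nm + x_px + y_px, data = m)
  beta <- unname(coef(fit))
  if (beta[2] == 0) stop("degenerate dispersion slope", call. = FALSE)
  structure(
    list(beta = c(beta0 = beta[1], beta1 = beta[2],
                  beta2 = beta[3], beta3 = beta[4]),
         residual_sd = summary(fit)$sigma,
         n = nrow(m),
         n_beads = if ("bead_id" %in% names(m))
           dplyr::n_distinct(m$bead_id) else NA_integer_,
         reference_wavelengths_nm = sort(unique(m$wavelength_nm)),
         passband_nm = passband_nm,
         fit = fit),
    class = "spaint_calibration")
}

#' Build a calibration object from known coefficients
#'
#' @param beta0,beta1,beta2,beta3 Model coefficients (px, px/nm, px/px,
#'   px/px).
#' @param residual_sd Residual standard deviation to record, px.
#' @param passband_nm Applicable wavelength range.
#' @return A `spaint_calibration`.
#' @export
calibration_from_coefficients <- function(beta0, beta1, beta2 = 0, beta3 = 0,
                                          residual_sd = NA_real_,
                                          passband_nm = c(480, 760)) {
  stopifnot(beta1 != 0)
  structure(
    list(beta = c(beta0 = beta0, beta1 = beta1, beta2 = beta2,
                  beta3 = beta3),
         residual_sd = residual_sd, n = NA_integer_, n_beads = NA_integer_,
         reference_wavelengths_nm = c(512.7, 581.5, 676.5),
         passband_nm = passband_nm, fit = NULL),
    class = "spaint_calibration")
}

#' Forward and inverse wavelength mapping
#'
#' `predict_distance()` evaluates the calibration model forward; the
#' inverse, `wavelength_from_distance()`, recovers the aberration-corrected
#' wavelength from a measured Z0Z1 distance:
#' `lambda = (Z0Z1 - beta0 - beta2 * x - beta3 * y) / beta1`.
#'
#' @param model A `spaint_calibration` (or [linear_dispersion()]).
#' @param z0z1_px Measured zeroth-to-first-order distance(s), px.
#' @param x_px,y_px Spatial position of the localization.
#' @param wavelength_nm Wavelength(s) for the forward prediction.
#' @return Wavelength(s) in nm (with attribute `in_passband`, a logical
#'   flagging values inside the 480-760 nm passband) or distance(s) in px.
#' @export
wavelength_from_distance <- function(z0z1_px, x_px, y_px, model) {
  b <- model$beta
  if (b[["beta1"]] == 0) stop("beta1 is zero; model not invertible",
                              call. = FALSE)
  lam <- (z0z1_px - b[["beta0"]] - b[["beta2"]] * x_px -
            b[["beta3"]] * y_px) / b[["beta1"]]
  pb <- model$passband_nm %||% c(480, 760)
  attr(lam, "in_passband") <- lam >= pb[1] & lam <= pb[2]
  lam
}

#' @rdname wavelength_from_distance
#' @export
predict_distance <- function(model, wavelength_nm, x_px, y_px) {
  dispersion_distance(model$beta, wavelength_nm, x_px, y_px)
}

#' @export
print.spaint_calibration <- function(x, ...) {
  cat("<spaint_calibration>\n")
  cat(sprintf("  Z0Z1 = %.3f + %.5f*lambda + %.5f*x + %.5f*y [px]\n",
              x$beta[1], x$beta[2], x$beta[3], x$beta[4]))
  cat(sprintf("  residual sd %.3f px over n = %s measurements (%s beads)\n",
              x$residual_sd, x$n, x$n_beads))
  invisible(x)
}

#' @export
tidy.spaint_calibration <- function(x, ...) {
  if (!is.null(x$fit)) {
    s <- summary(x$fit)$coefficients
    tibble::tibble(term = c("beta0", "beta1", "beta2", "beta3"),
                   estimate = s[, 1], std.error = s[, 2],
                   statistic = s[, 3], p.value = s[, 4])
  } else {
    tibble::tibble(term = names(x$beta), estimate = unname(x$beta),
                   std.error = NA_real_, statistic = NA_real_,
                   p.value = NA_real_)
  }
}

#' @export
glance.spaint_calibration <- function(x, ...) {
  tibble::tibble(residual_sd = x$residual_sd, n = x$n, n_beads = x$n_beads,
                 passband_min_nm = x$passband_nm[1],
                 passband_max_nm = x$passband_nm[2])
}

# ---- full Step-1 pipeline -------------------------------------------------

#' Calibrate the instrument from a bead stack
#'
#' The full spectral-calibration pipeline: localize the beads in the
#' spatial region of every frame, extract one spectral profile per
#' localization and per reference dye at the user-estimated distances, fit
#' each profile with a Gaussian, apply the quality-control rules, and
#' regress the surviving Z0Z1 distances on wavelength and field position.
#'
#' @param stack Calibration `spaint_stack`.
#' @param distances_px Approximate Z0Z1 distances of the three dye peaks,
#'   estimated by the user (defaults to the grating-equation prediction
#'   for the stack's optics).
#' @param reference_wavelengths_nm The known dye peaks (512.7, 581.5,
#'   676.5 nm).
#' @param threshold Detection signal-strength threshold.
#' @param psf_sigma_px PSF width for localization.
#' @param min_beads Minimum number of beads with all three peaks passing
#'   QC.
#' @return A `spaint_calibration` with two extra elements:
#'   `measurements` (per-profile results, including the recovered
#'   wavelength of every qc-passing peak) and `recovered` (per-dye mean
#'   and sd of the recovered wavelength).
#' @export
calibrate_stack <- function(stack,
                            distances_px = predict_first_order_displacement(
                              c(512.7, 581.5, 676.5),
                              stack$geometry, stack$camera),
                            reference_wavelengths_nm = c(512.7, 581.5, 676.5),
                            threshold = 30, psf_sigma_px = 1.2,
                            min_beads = 10) {
  stopifnot(length(distances_px) == length(reference_wavelengths_nm))
  locs <- localize_stack(stack, threshold, psf_sigma_px)
  if (nrow(locs) == 0) stop("no localizations found in the spatial region",
                            call. = FALSE)
  locs <- group_fiducials(locs, n_frames = stack$n_frames,
                          min_frames_frac = 0)
  meas <- purrr::map_dfr(seq_len(nrow(locs)), function(i) {
    frame_img <- stack$frames[[locs$frame[i]]]
    purrr::map_dfr(seq_along(distances_px), function(k) {
      prof <- extract_profile(frame_img, locs$x_px[i], locs$y_px[i],
                              distances_px[k])
      if (is.null(prof)) {
        return(tibble::tibble(amplitude = NA_real_, center_px = NA_real_,
                              center_offset_px = NA_real_,
                              width_px = NA_real_, offset_adu = NA_real_,
                              qc_pass = FALSE, qc_reason = "window_oob",
                              wavelength_nm = reference_wavelengths_nm[k]))
      }
      pk <- fit_peak(prof)
      pk$wavelength_nm <- reference_wavelengths_nm[k]
      pk
    }) |>
      dplyr::mutate(x_px = locs$x_px[i], y_px = locs$y_px[i],
                    frame = locs$frame[i], bead_id = locs$group_id[i])
  })
  ok <- meas |>
    dplyr::filter(.data$qc_pass) |>
    dplyr::rename(z0z1_px = "center_px")
  complete_beads <- ok |>
    dplyr::group_by(.data$bead_id) |>
    dplyr::summarise(dyes = dplyr::n_distinct(.data$wavelength_nm)) |>
    dplyr::filter(.data$dyes == length(reference_wavelengths_nm))
  if (nrow(complete_beads) < min_beads) {
    stop("calibration error: only ", nrow(complete_beads),
         " beads have all reference peaks passing QC (need ", min_beads,
         ")", call. = FALSE)
  }
  ok <- dplyr::semi_join(ok, complete_beads, by = "bead_id")
  model <- fit_calibration(ok)
  ok$recovered_nm <- as.numeric(wavelength_from_distance(
    ok$z0z1_px, ok$x_px, ok$y_px, model))
  model$measurements <- ok
  model$recovered <- ok |>
    dplyr::group_by(wavelength_nm = .data$wavelength_nm) |>
    dplyr::summarise(mean_recovered_nm = mean(.data$recovered_nm),
                     sd_recovered_nm = sd(.data$recovered_nm),
                     n = dplyr::n(), .groups = "drop")
  model
}

# ---- calibration file I/O -------------------------------------------------

#' Write / read a calibration coefficient file
#'
#' Flat key-value text with keys `beta0..beta3`, `residual_sd`, `n`,
#' `n_beads`, `passband_min_nm`, `passband_max_nm`.
#'
#' @param model A `spaint_calibration`.
#' @param path File path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` a `spaint_calibration`.
#' @export
write_calibration <- function(model, path) {
  write_key_values(
    list(beta0 = model$beta[["beta0"]], beta1 = model$beta[["beta1"]],
         beta2 = model$beta[["beta2"]], beta3 = model$beta[["beta3"]],
         residual_sd = model$residual_sd,
         n = model$n %||% NA, n_beads = model$n_beads %||% NA,
         passband_min_nm = model$passband_nm[1],
         passband_max_nm = model$passband_nm[2]),
    path, header = "spaintr spectral calibration")
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  kv <- read_key_values(path)
  m <- calibration_from_coefficients(kv$beta0, kv$beta1, kv$beta2, kv$beta3,
                                     residual_sd = kv$residual_sd,
                                     passband_nm = c(kv$passband_min_nm,
                                                     kv$passband_max_nm))
  m$n <- kv$n; m$n_beads <- kv$n_beads
  m
}
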