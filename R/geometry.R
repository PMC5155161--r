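#' Transmission-grating geometry
#'
#' Describes the blazed transmission diffraction grating that splits the
#' fluorescence emission into an undiffracted zeroth order (the spatial
#' image) and a dispersed first order (the spectral image) on the same
#' detector.
#'
#' @param groove_spacing_nm Grating line spacing \eqn{d} in nm. The default
#'   corresponds to 300 grooves/mm.
#' @param blaze_angle_deg Blaze angle \eqn{\gamma} in degrees; controls the
#'   efficiency split between orders (kept as metadata, the split itself is
#'   given by `zeroth_order_fraction`).
#' @param grating_to_detector_mm Grating-to-detector distance \eqn{D} in mm.
#' @param order Diffraction order \eqn{m}, 0 or 1.
#' @param zeroth_order_fraction Fraction of emitted photons diffracted into
#'   the zeroth (spatial) order; the grating used here diverts ~60%.
#' @param transmission_loss Fractional photon loss of the grating, applied
#'   to the first order only (~30% for the blazed grating modelled here).
#' @param dispersion_axis Axis/sign along which the first order is
#'   displaced; `"+y"` (default) places the spectral region below the
#'   spatial region, the only layout the analysis functions consume.
#'
#' @return An object of class `grating_geometry`.
#' @export
grating_geometry <- function(groove_spacing_nm = 1e6 / 300,
                             blaze_angle_deg = 8.6,
                             grating_to_detector_mm = 20,
                             order = 1L,
                             zeroth_order_fraction = 0.60,
                             transmission_loss = 0.30,
                             dispersion_axis = c("+y", "-y")) {
  stopifnot(groove_spacing_nm > 0, grating_to_detector_mm > 0,
            zeroth_order_fraction > 0, zeroth_order_fraction < 1,
            order %in% c(0L, 1L),
            transmission_loss >= 0, transmission_loss < 1)
  structure(
    list(groove_spacing_nm = groove_spacing_nm,
         blaze_angle_deg = blaze_angle_deg,
         grating_to_detector_mm = grating_to_detector_mm,
         order = as.integer(order),
         zeroth_order_fraction = zeroth_order_fraction,
         transmission_loss = transmission_loss,
         dispersion_axis = match.arg(dispersion_axis)),
    class = "grating_geometry")
}

#' EMCCD camera model
#'
#' @param pixel_size_um Physical pixel size on the chip, in micrometres.
#' @param magnification Total magnification between sample and chip
#'   (objective x relay; 60 x 2.5 by default), giving an effective
#'   sample-plane pixel of `pixel_size_um * 1000 / magnification` nm
#'   (~106.7 nm with the defaults).
#' @param gain_camera Conversion gain of the readout, ADU per electron.
#' @param gain_em Electron-multiplication gain (unitless).
#' @param quantum_efficiency Detector quantum efficiency in (0, 1].
#' @param baseline_adu Bias offset added to every pixel, ADU.
#' @param read_noise_adu Gaussian read noise, ADU rms.
#' @param frame_rate_hz Acquisition frame rate, Hz.
#'
#' @details The total gain used to convert a fitted Gaussian integral (ADU)
#' into photons is `GainTotal = gain_camera * gain_em * quantum_efficiency`
#' (ADU/photon). With the defaults GainTotal = 25 ADU/photon.
#'
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(pixel_size_um = 16,
                         magnification = 60 * 2.5,
                         gain_camera = 1 / 9,
                         gain_em = 250,
                         quantum_efficiency = 0.9,
                         baseline_adu = 100,
                         read_noise_adu = 10,
                         frame_rate_hz = 20) {
  stopifnot(pixel_size_um > 0, magnification > 0,
            gain_camera > 0, gain_em > 0,
            quantum_efficiency > 0, quantum_efficiency <= 1,
            read_noise_adu >= 0, frame_rate_hz > 0)
  structure(
    list(pixel_size_um = pixel_size_um,
         magnification = magnification,
         effective_pixel_nm = pixel_size_um * 1000 / magnification,
         gain_camera = gain_camera,
         gain_em = gain_em,
         quantum_efficiency = quantum_efficiency,
         baseline_adu = baseline_adu,
         read_noise_adu = read_noise_adu,
         frame_rate_hz = frame_rate_hz),
    class = "camera_model")
}

#' Total camera gain in ADU per photon
#'
#' @param camera A [camera_model()].
#' @return `gain_camera * gain_em * quantum_efficiency`, ADU/photon.
#' @export
gain_total <- function(camera) {
  camera$gain_camera * camera$gain_em * camera$quantum_efficiency
}

#' Fluorescent emitter species
#'
#' A point emitter with a Gaussian-shaped emission spectrum; the Gaussian is
#' an approximation of the peak region of the true (skewed) dye spectrum.
#'
#' @param peak_wavelength_nm Peak emission wavelength; must lie in the
#'   480-760 nm detection passband.
#' @param spectral_sigma_nm Gaussian width of the emission spectrum, nm.
#' @param mean_photons Mean emitted photons per frame (before the grating
#'   splits them between orders).
#' @param psf_sigma_px Gaussian PSF width on the detector, pixels.
#' @return An object of class `emitter_species`.
#' @export
emitter_species <- function(peak_wavelength_nm = 620,
                            spectral_sigma_nm = 15,
                            mean_photons = 1333,
                            psf_sigma_px = 1.2) {
  stopifnot(peak_wavelength_nm >= 480, peak_wavelength_nm <= 760,
            spectral_sigma_nm > 0, mean_photons >= 0, psf_sigma_px > 0)
  structure(
    list(peak_wavelength_nm = peak_wavelength_nm,
         spectral_sigma_nm = spectral_sigma_nm,
         mean_photons = mean_photons,
         psf_sigma_px = psf_sigma_px),
    class = "emitter_species")
}

#' The three multi-dye calibration bead species
#'
#' Reference emission peaks of the multi-dye calibration microspheres used
#' for spectral calibration: 512.7, 581.5 and 676.5 nm.
#'
#' @param mean_photons Mean emitted photons per dye per frame.
#' @param spectral_sigma_nm Gaussian spectral width per dye, nm.
#' @param psf_sigma_px PSF width, pixels.
#' @return A list of three [emitter_species()].
#' @export
calibration_species <- function(mean_photons = 5000,
                                spectral_sigma_nm = 10,
                                psf_sigma_px = 1.2) {
  lapply(c(512.7, 581.5, 676.5), function(l)
    emitter_species(l, spectral_sigma_nm, mean_photons, psf_sigma_px))
}

#' First-order displacement predicted by the grating equation
#'
#' Distance on the detector between an emitter's zeroth-order image and its
#' first-order spectral image, from the grating equation
#' \eqn{\sin\theta_m = m\lambda/d} followed by projection over the
#' grating-to-detector distance: displacement \eqn{= D \tan(\arcsin(m\lambda/d))},
#' converted to detector pixels.
#'
#' @param wavelength_nm Emission wavelength(s), nm.
#' @param geometry A [grating_geometry()].
#' @param camera A [camera_model()] supplying the on-chip pixel size.
#' @return Displacement(s) in detector pixels; 0 for the zeroth order.
#' @export
#' @examples
#' predict_first_order_displacement(580) # ~221 px
predict_first_order_displacement <- function(wavelength_nm,
                                             geometry = grating_geometry(),
                                             camera = camera_model()) {
  m <- geometry$order
  if (m == 0L) return(rep(0, length(wavelength_nm)))
  s <- m * wavelength_nm / geometry$groove_spacing_nm
  if (any(abs(s) >= 1)) {
    stop("no diffraction: |m * lambda / d| >= 1 for some wavelength",
         call. = FALSE)
  }
  D_nm <- geometry$grating_to_detector_mm * 1e6
  pixel_nm <- camera$pixel_size_um * 1e3
  D_nm * tan(asin(s)) / pixel_nm
}

#' Linear dispersion model
#'
#' The zeroth-to-first-order distance Z0Z1 used throughout the package is
#' modelled as linear in wavelength with small linear field aberration:
#' `Z0Z1 = beta0 + beta1 * lambda + beta2 * x + beta3 * y` (pixels).
#'
#' @param beta0 Intercept, px.
#' @param beta1 Dispersion slope, px/nm; must be non-zero.
#' @param beta2,beta3 Aberration slopes with respect to the emitter's
#'   spatial x and y position, px/px.
#' @return An object of class `dispersion_model`.
#' @export
linear_dispersion <- function(beta0, beta1, beta2 = 0, beta3 = 0) {
  stopifnot(is.finite(beta0), beta1 != 0)
  structure(list(beta = c(beta0 = beta0, beta1 = beta1,
                          beta2 = beta2, beta3 = beta3)),
            class = "dispersion_model")
}

#' Linear dispersion implied by the grating optics
#'
#' Least-squares line through the exact grating-equation displacements at
#' the three calibration reference wavelengths, plus optional aberration.
#'
#' @inheritParams predict_first_order_displacement
#' @param reference_wavelengths_nm Wavelengths anchoring the linearisation.
#' @param beta2,beta3 Aberration slopes, px/px.
#' @return A [linear_dispersion()] model.
#' @export
dispersion_from_geometry <- function(geometry = grating_geometry(),
                                     camera = camera_model(),
                                     reference_wavelengths_nm =
                                       c(512.7, 581.5, 676.5),
                                     beta2 = 0, beta3 = 0) {
  z <- predict_first_order_displacement(reference_wavelengths_nm,
                                        geometry, camera)
  co <- coef(lm(z ~ reference_wavelengths_nm))
  linear_dispersion(co[[1]], co[[2]], beta2, beta3)
}

# evaluate a dispersion (or calibration) beta vector
dispersion_distance <- function(beta, wavelength_nm, x_px, y_px) {
  beta[[1]] + beta[[2]] * wavelength_nm + beta[[3]] * x_px + beta[[4]] * y_px
}

#' @export
print.grating_geometry <- function(x, ...) {
  cat(sprintf(
    "<grating_geometry> d = %.1f nm (%d gr/mm), blaze %.1f deg, D = %g mm, m = %d\n",
    x$groove_spacing_nm, round(1e6 / x$groove_spacing_nm),
    x$blaze_angle_deg, x$grating_to_detector_mm, x$order))
  cat(sprintf("  zeroth-order fraction %.2f, first-order loss %.2f, axis %s\n",
              x$zeroth_order_fraction, x$transmission_loss, x$dispersion_axis))
  invisible(x)
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model> %g um px (%.1f nm at sample), GainTotal %.2f ADU/photon, %g Hz\n",
    x$pixel_size_um, x$effective_pixel_nm, gain_total(x), x$frame_rate_hz))
  invisible(x)
}
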