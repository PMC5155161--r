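# ---- run configuration ----------------------------------------------------

#' End-to-end run configuration
#'
#' @param out_dir Output directory for all artifacts.
#' @param calibration_stack,experiment_stack Paths to input TIFF stacks;
#'   when `NULL`, small demonstration stacks are simulated.
#' @param calibration_file Path to an existing calibration coefficient
#'   file; overrides `calibration_stack`.
#' @param distances_px User-estimated Z0Z1 distances of the three
#'   calibration peaks (`NULL`: predicted from the optics).
#' @param threshold Detection signal-strength threshold.
#' @param psf_sigma_px PSF width, px.
#' @param eps_px,min_points DBSCAN parameters.
#' @param anchor_nm Spectral-window anchor wavelength.
#' @param render Rendering configuration, a [render_config()].
#' @param camera A [camera_model()].
#' @param geometry A [grating_geometry()].
#' @param seed Integer seed recorded in every output header.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       calibration_stack = NULL, experiment_stack = NULL,
                       calibration_file = NULL, distances_px = NULL,
                       threshold = 30, psf_sigma_px = 1.2,
                       eps_px = 0.5, min_points = 10, anchor_nm = 620,
                       render = render_config(),
                       camera = camera_model(),
                       geometry = grating_geometry(),
                       seed = 1L) {
  structure(list(out_dir = out_dir,
                 calibration_stack = calibration_stack,
                 experiment_stack = experiment_stack,
                 calibration_file = calibration_file,
                 distances_px = distances_px,
                 threshold = threshold, psf_sigma_px = psf_sigma_px,
                 eps_px = eps_px, min_points = min_points,
                 anchor_nm = anchor_nm, render = render,
                 camera = camera, geometry = geometry,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config[setdiff(names(config), c("camera", "geometry", "render"))], f)
  unname(tools::md5sum(f))
}

provenance_lines <- function(config) {
  c(sprintf("spaintr %s", as.character(utils::packageVersion("spaintr"))),
    sprintf("seed = %d", config$seed),
    sprintf("config_md5 = %s", config_hash(config)))
}

# ---- end-to-end pipeline --------------------------------------------------

#' Run the full sPAINT pipeline
#'
#' Executes calibration, localization + clustering + spectral assignment,
#' and rendering in order, writing every artifact (calibration
#' coefficients, localization CSV, cluster summary CSV, density and
#' sPAINT images) under `config$out_dir`. Each CSV carries a provenance
#' header (package version, seed, configuration hash). When no input
#' stacks are configured, small synthetic demonstration stacks (a bead
#' calibration field and a vesicle field) are generated first and written
#' alongside.
#'
#' @param config A [run_config()].
#' @param verbose Print step-by-step progress.
#' @return Invisibly, a named list of artifact paths plus the calibration
#'   model, localization table and cluster summaries.
#' @export
run_end_to_end <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  prov <- provenance_lines(config)
  paths <- list()
  set.seed(config$seed)

  camera <- config$camera
  geometry <- config$geometry

  # --- step 0: inputs -------------------------------------------------
  if (is.null(config$calibration_stack) && is.null(config$calibration_file)) {
    say("simulating demonstration calibration stack")
    cal_stack <- simulate_calibration_stack(
      n_beads = 15, n_frames = 20, field_px = 96,
      camera = camera, geometry = geometry,
      dispersion = dispersion_from_geometry(geometry, camera,
                                            beta2 = 0.003, beta3 = 0.004))
    paths$calibration_stack <- file.path(config$out_dir,
                                         "calibration_stack.tif")
    write_stack(cal_stack, paths$calibration_stack)
  } else if (!is.null(config$calibration_stack)) {
    cal_stack <- read_stack(config$calibration_stack)
  } else {
    cal_stack <- NULL
  }
  if (is.null(config$experiment_stack)) {
    say("simulating demonstration vesicle stack")
    sample <- luv_field(n_luv = 12, spacing_px = 14, camera = camera)
    stack <- simulate_spaint_stack(sample, camera = camera,
                                   geometry = geometry, n_frames = 250)
    paths$experiment_stack <- file.path(config$out_dir,
                                        "experiment_stack.tif")
    write_stack(stack, paths$experiment_stack)
  } else {
    stack <- read_stack(config$experiment_stack)
  }

  # --- step 1: calibration --------------------------------------------
  if (!is.null(config$calibration_file)) {
    model <- read_calibration(config$calibration_file)
    say("loaded calibration from %s", config$calibration_file)
  } else if (!is.null(cal_stack)) {
    distances <- config$distances_px %||% predict_first_order_displacement(
      c(512.7, 581.5, 676.5), cal_stack$geometry, cal_stack$camera)
    say("calibrating from bead stack (%d frames)", cal_stack$n_frames)
    model <- calibrate_stack(cal_stack, distances,
                             threshold = config$threshold,
                             psf_sigma_px = config$psf_sigma_px,
                             min_beads = 5)
  } else {
    stop("no calibration available: supply calibration_file or ",
         "calibration_stack", call. = FALSE)
  }
  paths$calibration <- file.path(config$out_dir, "calibration.txt")
  write_calibration(model, paths$calibration)

  # --- step 2: localization, clustering, spectral assignment ----------
  say("localizing %d frames", stack$n_frames)
  locs <- localize_stack(stack, config$threshold, config$psf_sigma_px)
  say("clustering %d localizations", nrow(locs))
  locs <- cluster_localizations(locs, config$eps_px, config$min_points)
  clustered <- dplyr::filter(locs, .data$cluster_id > 0)
  say("assigning spectra to %d clustered localizations", nrow(clustered))
  clustered <- assign_spectra(clustered, stack, model, config$anchor_nm)
  say("spectral yield %.1f%%",
      100 * (attr(clustered, "fraction_assigned") %||% NA))
  paths$localizations_csv <- file.path(config$out_dir, "localizations.csv")
  write_localizations(clustered, paths$localizations_csv, provenance = prov)
  summaries <- cluster_summaries(clustered, stack$camera, stack$n_frames)
  paths$clusters_csv <- file.path(config$out_dir, "clusters.csv")
  writeLines(paste0("# ", prov), paths$clusters_csv)
  readr::write_csv(summaries, paths$clusters_csv, append = TRUE,
                   col_names = TRUE)

  # --- step 3: rendering ----------------------------------------------
  say("rendering")
  dens <- render_density(clustered, config$render, stack$camera)
  paths$density_image <- file.path(config$out_dir, "density.tif")
  write_image(dens, paths$density_image)
  if (any(!is.na(clustered$wavelength_nm))) {
    sp <- render_spaint(clustered, config$render, stack$camera)
    paths$spaint_image <- file.path(config$out_dir, "spaint.tif")
    write_image(sp, paths$spaint_image)
  }

  invisible(c(paths, list(model = model, localizations = clustered,
                          clusters = summaries)))
}
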