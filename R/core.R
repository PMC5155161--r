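# ---- DBSCAN ---------------------------------------------------------------

# grid-bucketed DBSCAN on 2D points. min_pts counts the point itself
# (the convention of the classic fpc implementation). Returns integer
# labels, noise = -1, clusters numbered 1..k in order of discovery.
dbscan_labels <- function(x, y, eps, min_pts) {
  n <- length(x)
  if (n == 0) return(integer(0))
  cx <- floor(x / eps); cy <- floor(y / eps)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  neighbours <- function(i) {
    cand <- unlist(buckets[paste(rep(cx[i] + (-1:1), each = 3),
                                 cy[i] + (-1:1))],
                   use.names = FALSE)
    cand[(x[cand] - x[i])^2 + (y[cand] - y[i])^2 <= eps^2]
  }
  labels <- rep(0L, n)   # 0 = unvisited, -1 = noise
  cluster <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    nb <- neighbours(i)
    if (length(nb) < min_pts) {
      labels[i] <- -1L
      next
    }
    cluster <- cluster + 1L
    labels[i] <- cluster
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == -1L) labels[j] <- cluster     # border point
      if (labels[j] != 0L) next
      labels[j] <- cluster
      nb_j <- neighbours(j)
      if (length(nb_j) >= min_pts) queue <- c(queue, nb_j[labels[nb_j] == 0L])
    }
  }
  labels
}

#' Cluster localizations into structures with DBSCAN
#'
#' Density-based clustering of the localization table with an epsilon
#' neighbourhood of 0.5 px and a minimum of 10 points (the point itself
#' included), the parameters used to isolate individual vesicles and
#' aggregates; sparse background localizations come out as noise
#' (`cluster_id = -1`) and are excluded from downstream spectral and
#' kinetic summaries.
#'
#' @param table Localization tibble with `x_px`, `y_px`.
#' @param eps_px Neighbourhood radius, px.
#' @param min_points Minimum points in the neighbourhood.
#' @return The table with a `cluster_id` column added.
#' @export
cluster_localizations <- function(table, eps_px = 0.5, min_points = 10) {
  stopifnot(eps_px > 0, min_points >= 1)
  table$cluster_id <- dbscan_labels(table$x_px, table$y_px,
                                    eps_px, min_points)
  table
}

# ---- spectral assignment --------------------------------------------------

#' Assign an emission wavelength to each localization
#'
#' For every localization, predicts the expected Z0Z1 distance at an
#' anchor wavelength through the calibration model, extracts the spectral
#' profile there, fits the Gaussian peak, applies the quality-control
#' rules and inverts the calibration to a corrected wavelength.
#' Localizations whose profile window leaves the frame, whose fit fails QC
#' or whose wavelength falls outside the passband keep `NA` and a reason
#' code.
#'
#' @param table Localization tibble.
#' @param stack The `spaint_stack` the table came from.
#' @param model A `spaint_calibration`.
#' @param anchor_nm Anchor wavelength at which the profile window is
#'   centred (620 nm, mid emission range of the solvatochromic dye). Only
#'   peaks within ~ `half_width / beta1` nm of the anchor fall inside the
#'   window, so choose it near the expected emission.
#' @param half_width,transverse Profile window geometry (see
#'   [extract_profile()]).
#' @param verbose Report the fraction of localizations assigned.
#' @return The table with `wavelength_nm` and `qc_reason` columns; the
#'   assigned fraction is attached as attribute `fraction_assigned`.
#' @export
assign_spectra <- function(table, stack, model, anchor_nm = 620,
                           half_width = 15L, transverse = 3L,
                           verbose = FALSE) {
  stopifnot(inherits(stack, "spaint_stack"),
            inherits(model, c("spaint_calibration", "dispersion_model")))
  n <- nrow(table)
  lam <- rep(NA_real_, n)
  reason <- character(n)
  for (i in seq_len(n)) {
    d <- predict_distance(model, anchor_nm, table$x_px[i], table$y_px[i])
    prof <- extract_profile(stack$frames[[table$frame[i]]],
                            table$x_px[i], table$y_px[i], d,
                            half_width, transverse)
    if (is.null(prof)) { reason[i] <- "window_oob"; next }
    pk <- fit_peak(prof)
    if (!pk$qc_pass) { reason[i] <- pk$qc_reason; next }
    l <- wavelength_from_distance(pk$center_px, table$x_px[i],
                                  table$y_px[i], model)
    if (!attr(l, "in_passband")) { reason[i] <- "outside_passband"; next }
    lam[i] <- as.numeric(l)
    reason[i] <- "ok"
  }
  table$wavelength_nm <- lam
  table$qc_reason <- reason
  frac <- if (n) mean(reason == "ok") else NA_real_
  if (verbose) message(sprintf("assigned spectra to %.1f%% of %d localizations",
                               100 * frac, n))
  attr(table, "fraction_assigned") <- frac
  table
}

# ---- binding kinetics -----------------------------------------------------

#' Link localizations into binding events and measure on-times
#'
#' Localizations appearing in consecutive frames within `link_radius_px`
#' of each other are merged into one binding event; the on-time of an
#' event is its frame span times the frame period. PAINT events are short
#' and sparse, so the defaults link within 1 px with no frame gaps.
#'
#' @param table Localization tibble sorted by frame.
#' @param link_radius_px Maximum displacement between consecutive frames.
#' @param max_gap_frames Allowed dark frames inside one event.
#' @param frame_rate_hz Acquisition frame rate.
#' @return A tibble with one row per event: `event_id`, `x_px`, `y_px`
#'   (mean position), `start_frame`, `n_frames` (span), `n_localizations`,
#'   `on_time_s`.
#' @export
compute_on_times <- function(table, link_radius_px = 1, max_gap_frames = 0,
                             frame_rate_hz = 20) {
  if (nrow(table) == 0) {
    return(tibble::tibble(event_id = integer(), x_px = numeric(),
                          y_px = numeric(), start_frame = integer(),
                          n_frames = integer(), n_localizations = integer(),
                          on_time_s = numeric()))
  }
  tab <- dplyr::arrange(table, .data$frame, .data$y_px, .data$x_px)
  n <- nrow(tab)
  event <- integer(n)
  next_event <- 0L
  # active events: id -> (x, y, last frame)
  act_id <- integer(0); act_x <- act_y <- numeric(0); act_f <- integer(0)
  for (i in seq_len(n)) {
    f <- tab$frame[i]
    live <- act_f >= f - 1L - max_gap_frames & act_f < f
    cand <- which(live &
                    (act_x - tab$x_px[i])^2 + (act_y - tab$y_px[i])^2 <=
                    link_radius_px^2)
    if (length(cand)) {
      j <- cand[which.min((act_x[cand] - tab$x_px[i])^2 +
                            (act_y[cand] - tab$y_px[i])^2)]
      event[i] <- act_id[j]
      act_x[j] <- tab$x_px[i]; act_y[j] <- tab$y_px[i]; act_f[j] <- f
    } else {
      next_event <- next_event + 1L
      event[i] <- next_event
      act_id <- c(act_id, next_event)
      act_x <- c(act_x, tab$x_px[i]); act_y <- c(act_y, tab$y_px[i])
      act_f <- c(act_f, f)
    }
    # drop stale events to keep the scan linear
    if (length(act_id) > 256) {
      keep <- act_f >= f - 1L - max_gap_frames
      act_id <- act_id[keep]; act_x <- act_x[keep]
      act_y <- act_y[keep]; act_f <- act_f[keep]
    }
  }
  tab$event_id <- event
  tab |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(x_px = mean(.data$x_px), y_px = mean(.data$y_px),
                     start_frame = min(.data$frame),
                     n_frames = as.integer(max(.data$frame) -
                                             min(.data$frame) + 1L),
                     n_localizations = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(on_time_s = .data$n_frames / frame_rate_hz)
}

#' Localization density
#'
#' Localizations per square micrometre per second, e.g. for the density
#' versus dye-concentration curve.
#'
#' @param table Localization tibble (or anything with rows to count).
#' @param area_um2 Imaged area, um^2.
#' @param duration_s Acquisition duration, s.
#' @param concentration_label Optional label carried through (e.g. the dye
#'   concentration).
#' @return One-row tibble: `concentration`, `n_localizations`,
#'   `density_per_um2_s`.
#' @export
localization_density <- function(table, area_um2, duration_s,
                                 concentration_label = NA) {
  if (area_um2 <= 0 || duration_s <= 0) {
    stop("area and duration must be positive", call. = FALSE)
  }
  tibble::tibble(concentration = concentration_label,
                 n_localizations = nrow(table),
                 density_per_um2_s = nrow(table) / (area_um2 * duration_s))
}

# ---- spectral histogram ---------------------------------------------------

#' Frequency histogram of emission-peak wavelengths
#'
#' @param table Localization tibble with assigned `wavelength_nm` (rows
#'   with `NA` are ignored), or a bare numeric vector of wavelengths.
#' @param bin_width_nm Bin width, nm.
#' @param passband_nm Histogram range.
#' @return An object of class `spaint_spectral_hist`: list with
#'   `histogram` (tibble `wavelength_nm`, `count`), `mean_nm`, `sd_nm`,
#'   `n`.
#' @export
spectral_histogram <- function(table, bin_width_nm = 1,
                               passband_nm = c(480, 760)) {
  lam <- if (is.numeric(table)) table else table$wavelength_nm
  lam <- lam[!is.na(lam)]
  if (length(lam) == 0) stop("no assigned wavelengths", call. = FALSE)
  breaks <- seq(passband_nm[1], passband_nm[2] + bin_width_nm, bin_width_nm)
  cut_idx <- findInterval(lam, breaks, rightmost.closed = TRUE)
  inside <- cut_idx >= 1 & cut_idx < length(breaks)
  counts <- tabulate(cut_idx[inside], nbins = length(breaks) - 1)
  structure(
    list(histogram = tibble::tibble(
           wavelength_nm = head(breaks, -1) + bin_width_nm / 2,
           count = counts),
         mean_nm = mean(lam), sd_nm = sd(lam), n = length(lam)),
    class = "spaint_spectral_hist")
}

#' @export
print.spaint_spectral_hist <- function(x, ...) {
  cat(sprintf("<spaint_spectral_hist> n = %d, mean %.1f nm, sd %.1f nm\n",
              x$n, x$mean_nm, x$sd_nm))
  invisible(x)
}

#' @export
glance.spaint_spectral_hist <- function(x, ...) {
  tibble::tibble(mean_nm = x$mean_nm, sd_nm = x$sd_nm, n = x$n)
}

# ---- per-cluster summaries ------------------------------------------------

#' Summarise clustered structures
#'
#' Per-cluster aggregates: localization count, centroid, radial extent and
#' precision-corrected diameter, spectral mean and sd over qc-passing
#' wavelengths, localization rate and mean on-time. Noise localizations
#' (`cluster_id = -1`) are excluded.
#'
#' The diameter estimator assumes localizations scattered around a ring
#' (the projected equator of a vesicle): with mean squared radial distance
#' `m2` about the centroid and mean localization precision `s` (as sd per
#' axis), the ring radius is `sqrt(m2 / (1 - 1/n) - 2 s^2)`.
#'
#' @param table Clustered localization tibble (see
#'   [cluster_localizations()]).
#' @param camera A [camera_model()] (pixel size, frame rate).
#' @param n_frames Number of frames in the acquisition.
#' @return A tibble with one row per cluster: `cluster_id`, `n`,
#'   `x_px`, `y_px`, `radius_px`, `diameter_um`, `mean_wavelength_nm`,
#'   `sd_wavelength_nm`, `n_spectra`, `locs_per_frame`, `mean_on_time_s`.
#' @export
cluster_summaries <- function(table, camera = camera_model(),
                              n_frames = max(table$frame)) {
  stopifnot("cluster_id" %in% names(table))
  px_nm <- camera$effective_pixel_nm
  clustered <- dplyr::filter(table, .data$cluster_id > 0)
  clustered |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::group_modify(function(g, key) {
      cx <- mean(g$x_px); cy <- mean(g$y_px)
      n <- nrow(g)
      m2 <- mean((g$x_px - cx)^2 + (g$y_px - cy)^2) / (1 - 1 / n)
      prec_px2 <- if ("precision_nm" %in% names(g))
        mean(g$precision_nm, na.rm = TRUE)^2 / px_nm^2 else 0
      r2 <- max(m2 - 2 * prec_px2, 0)
      lam <- if ("wavelength_nm" %in% names(g))
        g$wavelength_nm[!is.na(g$wavelength_nm)] else numeric(0)
      ev <- compute_on_times(g, frame_rate_hz = camera$frame_rate_hz)
      tibble::tibble(
        n = n, x_px = cx, y_px = cy,
        radius_px = sqrt(r2),
        diameter_um = 2 * sqrt(r2) * px_nm / 1000,
        mean_wavelength_nm = if (length(lam)) mean(lam) else NA_real_,
        sd_wavelength_nm = if (length(lam) > 1) sd(lam) else NA_real_,
        n_spectra = length(lam),
        locs_per_frame = n / n_frames,
        mean_on_time_s = mean(ev$on_time_s))
    }) |>
    dplyr::ungroup()
}
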