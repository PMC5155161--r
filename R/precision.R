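# ---- fiducial grouping ----------------------------------------------------

#' Group localizations originating from the same fiducial
#'
#' Greedy association: localizations within a 4 x 4 pixel square are
#' considered to come from the same bead/vesicle. Groups seen in fewer
#' than `min_frames_frac` of the recorded frames are dropped (fiducials
#' should be localized in at least half the frames).
#'
#' @param table Localization tibble.
#' @param box_px Side of the association square (4 px: members lie within
#'   +/- `box_px / 2` of the group seed).
#' @param min_frames_frac Minimum fraction of frames a group must appear
#'   in (0.5 by default; set 0 to keep all groups).
#' @param n_frames Total recorded frames (defaults to `max(frame)`).
#' @return The table with a `group_id` column, filtered to surviving
#'   groups; per-group mean position and mean photons are attached as
#'   attribute `groups`.
#' @export
group_fiducials <- function(table, box_px = 4, min_frames_frac = 0.5,
                            n_frames = max(table$frame)) {
  n <- nrow(table)
  if (n == 0) { table$group_id <- integer(0); return(table) }
  half <- box_px / 2
  gid <- rep(NA_integer_, n)
  g <- 0L
  ord <- order(table$y_px, table$x_px)
  for (i in ord) {
    if (!is.na(gid[i])) next
    g <- g + 1L
    members <- is.na(gid) &
      abs(table$x_px - table$x_px[i]) <= half &
      abs(table$y_px - table$y_px[i]) <= half
    gid[members] <- g
  }
  table$group_id <- gid
  keep <- table |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(n_frames_seen = dplyr::n_distinct(.data$frame),
                     .groups = "drop") |>
    dplyr::filter(.data$n_frames_seen >= min_frames_frac * n_frames)
  out <- dplyr::semi_join(table, keep, by = "group_id")
  attr(out, "groups") <- out |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(x_px = mean(.data$x_px), y_px = mean(.data$y_px),
                     mean_photons = mean(.data$photons),
                     n = dplyr::n(), .groups = "drop")
  out
}

# ---- scatter -> precision -------------------------------------------------

# fit a 1D Gaussian to the histogram of `v`; returns the fitted sigma.
# Falls back to the sample sd when the histogram fit does not converge
# (rare for well-populated groups).
hist_gaussian_sigma <- function(v) {
  s0 <- sd(v)
  if (!is.finite(s0) || s0 == 0) return(0)
  # bin at roughly half the sample sd so the Gaussian core spans several
  # bins, padding the range so the tails are represented by empty bins
  bw <- s0 / 2
  lo <- min(v) - bw; hi <- max(v) + bw
  nb <- max(8L, ceiling((hi - lo) / bw))
  breaks <- seq(lo, hi, length.out = nb + 1)
  y <- graphics::hist(v, breaks = breaks, plot = FALSE)$counts
  # maximum-likelihood Gaussian fit to the binned counts (multinomial
  # bin probabilities); near-fully efficient and bounded by construction
  nll <- function(p) {
    pr <- pmax(diff(pnorm(breaks, p[1], exp(p[2]))), 1e-12)
    -sum(y * log(pr))
  }
  o <- tryCatch(optim(c(mean(v), log(s0)), nll), error = function(e) NULL)
  if (is.null(o) || o$convergence != 0) return(s0)
  s <- exp(o$par[2])
  # reject degenerate solutions (width escaping the data range)
  if (s > hi - lo || s < bw / 10) return(s0)
  s
}

#' Spatial precision from the scatter of one fiducial
#'
#' Histograms the x and y positions of a group's localizations, fits each
#' with a 1D Gaussian and returns the wider of the two widths, converted
#' to nanometres -- the empirical localization precision of that fiducial.
#'
#' @param group Localization tibble of one fiducial group.
#' @param camera A [camera_model()] for the pixel-to-nm conversion.
#' @param min_members Minimum localizations required.
#' @return Precision in nm; 0 with a warning when the scatter is
#'   degenerate (all positions identical).
#' @export
precision_from_scatter <- function(group, camera = camera_model(),
                                   min_members = 20) {
  if (nrow(group) < min_members) {
    stop("need at least ", min_members, " localizations in the group",
         call. = FALSE)
  }
  sx <- hist_gaussian_sigma(group$x_px)
  sy <- hist_gaussian_sigma(group$y_px)
  if (sx == 0 && sy == 0) {
    warning("degenerate scatter: all positions identical")
    return(structure(0, degenerate = TRUE))
  }
  max(sx, sy) * camera$effective_pixel_nm
}

#' Spectral precision from per-frame spectral centres
#'
#' Same histogram-plus-Gaussian contract as [precision_from_scatter()],
#' applied to the per-frame fitted emission-peak wavelengths of one
#' fiducial; returns the Gaussian width in nm.
#'
#' @param lambda_nm Numeric vector of per-frame spectral centres (nm), or
#'   a group tibble with a `lambda_nm` column.
#' @param min_members Minimum values required.
#' @return Spectral precision in nm; 0 (flagged) when degenerate.
#' @export
spectral_precision_from_scatter <- function(lambda_nm, min_members = 20) {
  v <- if (is.numeric(lambda_nm)) lambda_nm else lambda_nm$lambda_nm
  v <- v[!is.na(v)]
  if (length(v) < min_members) {
    stop("need at least ", min_members, " spectral centres", call. = FALSE)
  }
  s <- hist_gaussian_sigma(v)
  if (s == 0) {
    warning("degenerate scatter: all spectral centres identical")
    return(structure(0, degenerate = TRUE))
  }
  s
}

# ---- binning and asymptote fit -------------------------------------------

#' Bin precision-photon pairs and fit the infinite-photon asymptote
#'
#' Bins the per-fiducial (mean photons, precision) pairs every 200 photons
#' below 2,000 photons and every 500 photons above (a value of exactly
#' 2,000 falls in the first 500-wide bin), then fits the binned means to a
#' single exponential decay with offset,
#' `sigma(N) = sigma_inf + A * exp(-N / k)`,
#' whose offset `sigma_inf` is the ultimate (infinite-photon) precision.
#' A physically motivated quadrature alternative,
#' `sigma(N) = sqrt(sigma_inf^2 + c / N)`, is fitted alongside for
#' comparison.
#'
#' @param pairs Tibble with columns `photons` and `sigma_nm`.
#' @param min_bins Minimum number of populated bins.
#' @return An object of class `spaint_precision_fit`: list with `curve`
#'   (tibble `bin_center`, `mean_sigma_nm`, `n`), `sigma_inf_nm`,
#'   `sigma_inf_se_nm`, `amplitude_nm`, `decay_photons`, the `fit` object,
#'   and `quadrature` (named vector with the alternative fit's
#'   `sigma_inf_nm`).
#' @export
bin_and_fit <- function(pairs, min_bins = 5) {
  stopifnot(all(c("photons", "sigma_nm") %in% names(pairs)))
  brk <- c(seq(0, 2000, by = 200),
           seq(2500, max(3000, ceiling(max(pairs$photons) / 500) * 500),
               by = 500))
  idx <- findInterval(pairs$photons, brk, left.open = FALSE)
  curve <- pairs |>
    dplyr::mutate(bin = idx) |>
    dplyr::filter(.data$bin >= 1, .data$bin < length(brk)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_sigma_nm = mean(.data$sigma_nm),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(bin_center = (brk[.data$bin] + brk[.data$bin + 1]) / 2) |>
    dplyr::select("bin_center", "mean_sigma_nm", "n") |>
    dplyr::arrange(.data$bin_center)
  if (nrow(curve) < min_bins) {
    stop("only ", nrow(curve), " populated photon bins (need ", min_bins,
         ")", call. = FALSE)
  }
  smin <- min(curve$mean_sigma_nm); smax <- max(curve$mean_sigma_nm)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      mean_sigma_nm ~ sinf + A * exp(-bin_center / k), data = curve,
      start = list(sinf = smin, A = max(smax - smin, 1e-3), k = 600),
      lower = c(sinf = 0, A = 0, k = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit) && smax - smin < 1e-3 * max(smax, 1)) {
    # a photon-independent curve has no decay to fit; report the constant
    m <- mean(curve$mean_sigma_nm)
    se <- sd(curve$mean_sigma_nm) / sqrt(nrow(curve))
    s <- rbind(sinf = c(m, se), A = c(0, NA_real_), k = c(NA_real_, NA_real_))
    colnames(s) <- c("Estimate", "Std. Error")
    return(structure(
      list(curve = curve, sigma_inf_nm = m, sigma_inf_se_nm = se,
           amplitude_nm = 0, decay_photons = NA_real_, fit = NULL,
           coef_table = s,
           quadrature = c(sigma_inf_nm = m, c = 0)),
      class = "spaint_precision_fit"))
  }
  if (is.null(fit)) {
    stop("exponential-decay fit did not converge", call. = FALSE)
  }
  s <- summary(fit)$coefficients
  quad <- tryCatch({
    qf <- minpack.lm::nlsLM(
      mean_sigma_nm ~ sqrt(sinf^2 + cc / bin_center), data = curve,
      start = list(sinf = smin, cc = max(smax^2 - smin^2, 1) * 300),
      lower = c(sinf = 0, cc = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    c(sigma_inf_nm = coef(qf)[["sinf"]], c = coef(qf)[["cc"]])
  }, error = function(e) c(sigma_inf_nm = NA_real_, c = NA_real_))
  structure(
    list(curve = curve,
         sigma_inf_nm = s["sinf", 1], sigma_inf_se_nm = s["sinf", 2],
         amplitude_nm = s["A", 1], decay_photons = s["k", 1],
         fit = fit, quadrature = quad),
    class = "spaint_precision_fit")
}

#' @export
print.spaint_precision_fit <- function(x, ...) {
  cat(sprintf(
    "<spaint_precision_fit> sigma_inf = %.2f +/- %.2f nm (A = %.1f nm, k = %.0f photons; %d bins)\n",
    x$sigma_inf_nm, x$sigma_inf_se_nm, x$amplitude_nm, x$decay_photons,
    nrow(x$curve)))
  invisible(x)
}

#' @export
tidy.spaint_precision_fit <- function(x, ...) {
  s <- if (is.null(x$fit)) x$coef_table else summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' @export
glance.spaint_precision_fit <- function(x, ...) {
  tibble::tibble(sigma_inf_nm = x$sigma_inf_nm,
                 sigma_inf_se_nm = x$sigma_inf_se_nm,
                 amplitude_nm = x$amplitude_nm,
                 decay_photons = x$decay_photons,
                 n_bins = nrow(x$curve),
                 quadrature_sigma_inf_nm = x$quadrature[["sigma_inf_nm"]])
}

# ---- full precision pipeline ----------------------------------------------

#' Empirical precision curve of a fiducial localization table
#'
#' The complete instrument-stability analysis: group localizations into
#' fiducials (4 x 4 px association, at-least-half-the-frames filter),
#' measure each group's spatial (or spectral) precision from its scatter,
#' pair it with the group's mean photon count, bin per the standard
#' scheme and fit the exponential decay to obtain the ultimate precision.
#'
#' @param table Fiducial localization tibble (e.g. from
#'   [simulate_fiducial_localizations()] or [localize_stack()]); spectral
#'   mode expects a `lambda_nm` column of per-frame spectral centres.
#' @param mode `"spatial"` or `"spectral"`.
#' @param camera A [camera_model()].
#' @param n_frames Total frames recorded.
#' @param min_members Minimum localizations per usable group.
#' @param min_frames_frac Group filter (see [group_fiducials()]).
#' @return A `spaint_precision_fit`; the per-group pairs are attached as
#'   element `pairs`.
#' @export
precision_curve <- function(table, mode = c("spatial", "spectral"),
                            camera = camera_model(),
                            n_frames = max(table$frame),
                            min_members = 20, min_frames_frac = 0.5) {
  mode <- match.arg(mode)
  grouped <- group_fiducials(table, n_frames = n_frames,
                             min_frames_frac = min_frames_frac)
  pairs <- grouped |>
    dplyr::group_by(.data$group_id) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < min_members) {
        return(tibble::tibble(photons = numeric(0), sigma_nm = numeric(0)))
      }
      s <- if (mode == "spatial") precision_from_scatter(g, camera,
                                                         min_members)
           else spectral_precision_from_scatter(g, min_members)
      tibble::tibble(photons = mean(g$photons), sigma_nm = as.numeric(s))
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$sigma_nm > 0)
  out <- bin_and_fit(pairs)
  out$pairs <- pairs
  out
}
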