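#' Volume time series container
#'
#' @param times Hours, strictly increasing, starting at 0.
#' @param volumes_nl Luminal volumes (nl), same length, `>= 0`.
#' @param surface_mm2 Luminal surface area at the first timepoint (mm²).
#' @return An object of class `volume_timeseries`.
#' @export
volume_timeseries <- function(times, volumes_nl, surface_mm2) {
  if (length(times) != length(volumes_nl)) stop("times and volumes differ in length")
  if (length(times) < 3) stop("need at least 3 timepoints")
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("times must start at 0 and be strictly increasing")
  if (any(volumes_nl < 0)) stop("volumes must be non-negative")
  if (!is.numeric(surface_mm2) || surface_mm2 <= 0)
    stop("surface_mm2 must be positive")
  structure(list(times = times, volumes_nl = volumes_nl,
                 surface_mm2 = surface_mm2),
            class = "volume_timeseries")
}

#' Absorption rate from the linear portion of a volume trajectory
#'
#' Among contiguous windows starting at the first timepoint with length at
#' least 3, the longest whose ordinary least-squares line has `R² >=
#' r2_min` is selected; if none qualifies, the length-3 window with the
#' highest `R²` is used.  Absorption slows as the lumen empties, so the
#' early prefix is the linear phase.
#'
#' @param ts A [volume_timeseries()].
#' @param r2_min Minimum `R²` for a window to count as linear, default 0.98.
#' @return An object of class `rate_estimate` with `slope_nl_per_hr`
#'   (signed), `rate_nl_per_hr = max(-slope, 0)`, `window` (index range) and
#'   `r_squared`.
#' @export
fit_absorption_rate <- function(ts, r2_min = 0.98) {
  stopifnot(inherits(ts, "volume_timeseries"))
  n <- length(ts$times)
  fit_window <- function(len) {
    t <- ts$times[1:len]; v <- ts$volumes_nl[1:len]
    f <- stats::lm.fit(cbind(1, t), v)
    ssr <- sum(f$residuals^2)
    sst <- sum((v - mean(v))^2)
    r2 <- if (sst == 0) 1 else 1 - ssr / sst
    list(slope = unname(f$coefficients[2]), r2 = r2)
  }
  chosen <- NULL
  for (len in n:3) {
    f <- fit_window(len)
    if (f$r2 >= r2_min) { chosen <- c(f, len = len); break }
  }
  if (is.null(chosen)) {
    f <- fit_window(3)
    chosen <- c(f, len = 3)
  }
  structure(list(slope_nl_per_hr = chosen$slope,
                 rate_nl_per_hr = max(-chosen$slope, 0),
                 window = c(1L, chosen$len),
                 r_squared = chosen$r2),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate_estimate: %.4g nl/hr (slope %.4g), window %d..%d, R^2 = %.4f\n",
              x$rate_nl_per_hr, x$slope_nl_per_hr, x$window[1], x$window[2],
              x$r_squared))
  invisible(x)
}

#' Normalize an absorption rate to luminal surface area
#'
#' @param rate A [rate_estimate()] or a numeric rate in nl/hr.
#' @param surface_mm2 Surface area (mm²), `> 0`.
#' @return Normalized rate in nl·hr⁻¹·mm⁻².
#' @export
normalize_rate <- function(rate, surface_mm2) {
  if (!is.numeric(surface_mm2) || length(surface_mm2) != 1 || surface_mm2 <= 0)
    stop("surface_mm2 must be a positive scalar")
  r <- if (inherits(rate, "rate_estimate")) rate$rate_nl_per_hr else rate
  if (r < 0) stop("rate must be non-negative")
  r / surface_mm2
}

#' Full volumetry-to-kinetics pipeline for one sac
#'
#' Smooths and segments each stack, counts voxels, estimates the surface
#' area from the first image's mask, fits the linear-portion rate and
#' normalizes it.
#'
#' @param stacks List of [image_stack()] over time (each carries its `time`).
#' @param smooth_width,threshold Passed to [quantify_stack()].
#' @param cap_fraction Passed to [measure_linear_dimensions()].
#' @param r2_min Passed to [fit_absorption_rate()].
#' @param surface_from `"raw"` (default) measures the linear dimensions on a
#'   segmentation of the unsmoothed first image: mean filtering erodes the
#'   high-curvature cap shoulders and would bias the end radii low.
#'   `"smoothed"` reuses the smoothed mask of the volume chain.
#' @return A list of class `sac_record` with `times`, `volumes_nl`,
#'   `surface_mm2`, `rate` ([fit_absorption_rate()] result) and
#'   `rate_norm` (nl·hr⁻¹·mm⁻²).
#' @export
quantify_timecourse <- function(stacks, smooth_width = 5, threshold = "otsu",
                                cap_fraction = 0.1, r2_min = 0.98,
                                surface_from = c("raw", "smoothed")) {
  stopifnot(is.list(stacks), length(stacks) >= 3)
  surface_from <- match.arg(surface_from)
  times <- vapply(stacks, function(s) s$time, numeric(1))
  q <- lapply(stacks, quantify_stack, smooth_width = smooth_width,
              threshold = threshold)
  vols <- vapply(q, function(x) x$volume$volume_nl, numeric(1))
  surf_mask <- if (surface_from == "raw") {
    segment_lumen(stacks[[1]], threshold)
  } else q[[1]]$mask
  meas <- measure_linear_dimensions(surf_mask, cap_fraction)
  surf <- sac_surface_area(meas)
  ts <- volume_timeseries(times, vols, surf$area_mm2)
  rate <- fit_absorption_rate(ts, r2_min)
  structure(list(times = times, volumes_nl = vols,
                 surface_mm2 = surf$area_mm2, measurements = meas,
                 rate = rate,
                 rate_norm = normalize_rate(rate, surf$area_mm2)),
            class = "sac_record")
}

#' @export
print.sac_record <- function(x, ...) {
  cat(sprintf("sac_record: %d timepoints, surface %.5f mm^2\n",
              length(x$times), x$surface_mm2))
  cat(sprintf("  volumes (nl): %s\n", paste(sprintf("%.4f", x$volumes_nl), collapse = ", ")))
  cat(sprintf("  normalized rate: %.3f nl/hr/mm^2\n", x$rate_norm))
  invisible(x)
}
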