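# Digitisation of rasterised paper-ECG pages: grid-based scale
# calibration, grid-suppressed trace extraction, and conversion to
# calibrated, uniformly sampled, band-pass-filtered mV signals.

#' Estimate grid calibration from a rasterised ECG page
#'
#' The pixel pitch of the mm grid is recovered from the dominant
#' periodicity of the row/column mean-intensity projections
#' (autocorrelation peak with parabolic sub-pixel refinement). A 5x
#' harmonic (the big box) is required for the estimate to be accepted.
#' Paper speed and amplitude scale cannot be read off a raster; they are
#' filled from configuration (clinical defaults 25 mm/s, 10 mm/mV).
#'
#' @param image grayscale matrix in `[0,1]`, 1 = white.
#' @param paper_speed,amp_scale calibration constants assumed for the page.
#' @param max_period largest candidate grid period in pixels.
#' @return object of class `grid_calibration` with fields `px_per_mm_x`,
#'   `px_per_mm_y`, `paper_speed`, `amp_scale`, `ms_per_px`, `mv_per_px`.
#' @export
calibrate_grid <- function(image, paper_speed = 25, amp_scale = 10,
                           max_period = 60) {
  stopifnot(is.matrix(image))
  est <- function(proj) {
    p <- proj - mean(proj)
    if (stats::sd(p) < 1e-6) return(NA_real_)
    lag_max <- min(length(p) - 2L, 6L * max_period)
    ac <- stats::acf(p, lag.max = lag_max, plot = FALSE,
                     demean = FALSE)$acf[, 1, 1]
    lags <- seq_along(ac) - 1L
    # first local maximum in (2, max_period] with substantial correlation
    cand <- which(diff(sign(diff(ac))) == -2) + 1L # interior local maxima (ac index)
    cand <- cand[lags[cand] >= 3 & lags[cand] <= max_period & ac[cand] > 0.2]
    if (!length(cand)) return(NA_real_)
    k <- cand[1]
    # parabolic sub-pixel refinement around integer lag
    a <- ac[k - 1]; b <- ac[k]; cc <- ac[k + 1]
    denom <- a - 2 * b + cc
    shift <- if (abs(denom) > 1e-12) 0.5 * (a - cc) / denom else 0
    period <- lags[k] + max(-0.5, min(0.5, shift))
    # validate the big-box 5x harmonic
    k5 <- round(5 * period)
    if (k5 + 2 > length(lags)) return(NA_real_)
    idx5 <- which(lags >= k5 - 2 & lags <= k5 + 2)
    if (max(ac[idx5]) < 0.15) return(NA_real_)
    # refine to sub-pixel precision using a distant harmonic: the peak
    # near m * period estimates m periods, dividing the pixel-level
    # uncertainty by m
    m_h <- floor((lag_max - 2) / period)
    if (m_h >= 2) {
      centre <- round(m_h * period)
      wlo <- max(2L, centre - ceiling(period / 3))
      whi <- min(length(ac) - 1L, centre + ceiling(period / 3))
      kk <- (wlo:whi)[which.max(ac[wlo:whi])]
      a <- ac[kk - 1]; b <- ac[kk]; cc <- ac[kk + 1]
      denom <- a - 2 * b + cc
      shift <- if (abs(denom) > 1e-12) 0.5 * (a - cc) / denom else 0
      period <- (lags[kk] + max(-0.5, min(0.5, shift))) / m_h
    }
    period
  }
  px_x <- est(colMeans(image))  # vertical grid lines -> column projection
  px_y <- est(rowMeans(image))
  if (is.na(px_x) || is.na(px_y)) {
    pb_stop("no stable grid periodicity found (grid absent or too coarse)",
            "pb_calibration_failure")
  }
  structure(list(
    px_per_mm_x = px_x, px_per_mm_y = px_y,
    paper_speed = paper_speed, amp_scale = amp_scale,
    ms_per_px = 1000 / (paper_speed * px_x),
    mv_per_px = 1 / (amp_scale * px_y)
  ), class = "grid_calibration")
}

#' Build a grid calibration from known constants
#'
#' Used when the pixel pitch is known exactly (e.g. from a render
#' manifest) rather than estimated.
#' @inheritParams calibrate_grid
#' @param px_per_mm_x,px_per_mm_y pixel pitch along x (time) and y (mV).
#' @export
grid_calibration <- function(px_per_mm_x, px_per_mm_y = px_per_mm_x,
                             paper_speed = 25, amp_scale = 10) {
  stopifnot_scalar(px_per_mm_x, "px_per_mm_x", lower = 0, strict = TRUE)
  stopifnot_scalar(px_per_mm_y, "px_per_mm_y", lower = 0, strict = TRUE)
  structure(list(
    px_per_mm_x = px_per_mm_x, px_per_mm_y = px_per_mm_y,
    paper_speed = paper_speed, amp_scale = amp_scale,
    ms_per_px = 1000 / (paper_speed * px_per_mm_x),
    mv_per_px = 1 / (amp_scale * px_per_mm_y)
  ), class = "grid_calibration")
}

#' Extract a trace polyline from a panel region
#'
#' Grid pixels are suppressed by a luminance threshold (the grid is
#' printed lighter than the trace ink); within each pixel column the
#' trace ordinate is the intensity-weighted centroid of the remaining
#' dark pixels. Columns with no trace pixel are filled by linear
#' interpolation from their neighbours.
#'
#' @param image grayscale page matrix.
#' @param region list with `rows` and `cols` (integer ranges of the panel).
#' @param lum_threshold pixels darker than this are treated as trace ink.
#' @param max_empty_frac maximum tolerated fraction of trace-free columns.
#' @return numeric vector: one row ordinate (absolute image row, possibly
#'   fractional) per panel column.
#' @export
extract_trace <- function(image, region, lum_threshold = 0.5,
                          max_empty_frac = 0.5) {
  rows <- region$rows; cols <- region$cols
  if (min(rows) < 1 || max(rows) > nrow(image) ||
      min(cols) < 1 || max(cols) > ncol(image)) {
    pb_stop("panel region outside image", "pb_input_error")
  }
  sub <- image[rows, cols, drop = FALSE]
  wts <- pmax(lum_threshold - sub, 0)      # ink weight, 0 for grid/paper
  colw <- colSums(wts)
  # vectorised centroid: sum(row * weight) / sum(weight), NA when no ink
  ord <- colSums(wts * seq_along(rows)) / ifelse(colw > 0, colw, NA)
  if (mean(is.na(ord)) > max_empty_frac) {
    pb_stop("trace extraction failed: too many empty columns",
            "pb_trace_failure")
  }
  if (anyNA(ord)) {
    idx <- seq_along(ord)
    ord <- stats::approx(idx[!is.na(ord)], ord[!is.na(ord)],
                         xout = idx, rule = 2)$y
  }
  ord + min(rows) - 1
}

#' Convert a pixel polyline to a calibrated 500 Hz signal
#'
#' Maps (column, row) to (ms, mV) using the grid calibration and a known
#' baseline row, resamples linearly to a uniform rate, and applies a
#' zero-phase 0.5--40 Hz band-pass filter.
#'
#' @param polyline row ordinates, one per pixel column.
#' @param calibration a `grid_calibration`.
#' @param baseline_row image row corresponding to 0 mV.
#' @param lead lead label carried as provenance.
#' @param fs output sampling rate, Hz.
#' @param band band-pass edges in Hz; `NULL` disables filtering.
#' @param order filter order.
#' @return object of class `calibrated_signal`: list with `samples` (mV),
#'   `t_ms`, `fs`, `lead`, `baseline_mv`.
#' @export
to_signal <- function(polyline, calibration, baseline_row, lead = "II",
                      fs = 500, band = c(0.5, 40), order = 5) {
  stopifnot(inherits(calibration, "grid_calibration"))
  if (!length(polyline)) pb_stop("empty polyline", "pb_input_error")
  t_px <- (seq_along(polyline) - 1) * calibration$ms_per_px
  mv <- (baseline_row - polyline) * calibration$mv_per_px
  dur_ms <- max(t_px)
  if (dur_ms < 2000) {
    pb_stop("digitised segment shorter than 2 s", "pb_short_signal")
  }
  t_out <- seq(0, dur_ms, by = 1000 / fs)
  y <- stats::approx(t_px, mv, xout = t_out, rule = 2)$y
  if (!is.null(band)) {
    y <- bandpass_filter(y, fs, band[1], band[2], order = order)
  }
  structure(list(samples = y, t_ms = t_out, fs = fs, lead = lead,
                 baseline_mv = 0), class = "calibrated_signal")
}

#' Per-beat isoelectric baseline from TP segments
#'
#' For each beat the baseline is the mean of the samples in the TP window
#' (from +340 ms after the current R-peak to -200 ms before the next,
#' intersected with the RR gap). When the window is empty (short RR) the
#' global median of the signal is used as a fallback.
#'
#' @param signal a `calibrated_signal` (or list with `samples`, `fs`).
#' @param r_peaks R-peak times in ms.
#' @return numeric vector of baseline levels (mV), one per peak; the last
#'   peak has no following TP segment and receives the fallback value.
#' @export
estimate_baseline <- function(signal, r_peaks) {
  if (length(r_peaks) < 2) {
    pb_stop("need at least 2 R-peaks", "pb_input_error")
  }
  x <- signal$samples; fs <- signal$fs
  fallback <- stats::median(x)
  out <- rep(fallback, length(r_peaks))
  for (i in seq_len(length(r_peaks) - 1L)) {
    lo <- r_peaks[i] + 340
    hi <- r_peaks[i + 1L] - 200
    if (hi <= lo) next
    i0 <- floor(lo / 1000 * fs) + 1L
    i1 <- ceiling(hi / 1000 * fs) + 1L
    i0 <- max(1L, i0); i1 <- min(length(x), i1)
    if (i1 >= i0) out[i] <- mean(x[i0:i1])
  }
  out
}

#' Digitise every panel of a rendered page using its manifest
#'
#' Convenience round-trip driver for synthetic pages: panel locations and
#' baselines come from the render manifest (for real pages a panel
#' configuration would be supplied instead).
#'
#' @param image page matrix.
#' @param manifest render manifest from [render_ecg_page()].
#' @param calibration optional `grid_calibration`; estimated from the
#'   image when `NULL`.
#' @param band,order band-pass settings passed to [to_signal()].
#' @return named list of `calibrated_signal` objects, one per panel.
#' @export
digitise_page <- function(image, manifest, calibration = NULL,
                          band = c(0.5, 40), order = 5) {
  if (is.null(calibration)) {
    calibration <- calibrate_grid(image,
                                  paper_speed = manifest$calibration$paper_speed,
                                  amp_scale = manifest$calibration$amp_scale)
  }
  out <- list()
  for (p in manifest$panels) {
    ncols <- floor(p$dur_ms / calibration$ms_per_px)
    region <- list(rows = p$y0:p$y1,
                   cols = p$x0:(min(ncol(image), p$x0 + ncols - 1L)))
    poly <- extract_trace(image, region)
    out[[p$lead]] <- to_signal(poly, calibration, p$baseline_row,
                               lead = p$lead, band = band, order = order)
  }
  out
}
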