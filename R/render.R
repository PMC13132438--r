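# Raster renderer for synthetic paper-ECG pages. Pages are grayscale
# matrices in [0,1] (1 = white paper), drawn with a mm grid at standard
# clinical calibration (25 mm/s, 10 mm/mV) and dark trace polylines. The
# render manifest records panel origins and calibration so a page can be
# digitised and checked against its own ground truth (round-trip oracle).

#' Rendering specification for a synthetic ECG page
#'
#' @param px_per_mm raster resolution, pixels per millimetre (>= 3).
#' @param paper_speed chart speed, mm/s (clinical standard 25).
#' @param amp_scale amplitude calibration, mm/mV (clinical standard 10).
#' @param grid_small,grid_big small/big grid box size in mm; the big box
#'   must be 5 small boxes, as on real ECG paper.
#' @param layout `"single"` (one full-width panel per trace, stacked),
#'   or `"standard"` (3x4 panel grid of the 12 leads plus a full-width
#'   lead II rhythm strip).
#' @param panel_duration seconds of signal shown per grid panel.
#' @param panel_height_mm vertical extent of one panel, mm.
#' @param grid_small_lum,grid_big_lum,trace_lum luminances of the small
#'   grid, big grid and trace ink. The grid must stay lighter than the
#'   trace by a clear margin so grid suppression is solvable.
#' @return object of class `page_render_spec`.
#' @export
page_render_spec <- function(px_per_mm = 5, paper_speed = 25, amp_scale = 10,
                             grid_small = 1, grid_big = 5,
                             layout = c("single", "standard"),
                             panel_duration = 2.5, panel_height_mm = 30,
                             grid_small_lum = 0.85, grid_big_lum = 0.7,
                             trace_lum = 0) {
  stopifnot_scalar(px_per_mm, "px_per_mm", lower = 3)
  stopifnot_scalar(paper_speed, "paper_speed", lower = 0, strict = TRUE)
  stopifnot_scalar(amp_scale, "amp_scale", lower = 0, strict = TRUE)
  if (!isTRUE(all.equal(grid_big, 5 * grid_small))) {
    pb_stop("grid_big must equal 5 * grid_small", "pb_input_error")
  }
  if (grid_big_lum - trace_lum < 0.3) {
    pb_stop("grid luminance too close to trace luminance", "pb_input_error")
  }
  structure(list(
    px_per_mm = px_per_mm, paper_speed = paper_speed, amp_scale = amp_scale,
    grid_small = grid_small, grid_big = grid_big,
    layout = match.arg(layout), panel_duration = panel_duration,
    panel_height_mm = panel_height_mm,
    grid_small_lum = grid_small_lum, grid_big_lum = grid_big_lum,
    trace_lum = trace_lum
  ), class = "page_render_spec")
}

standard_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

draw_grid <- function(img, spec) {
  h <- nrow(img); w <- ncol(img)
  small <- spec$grid_small * spec$px_per_mm
  for (axis in 1:2) {
    len <- if (axis == 1) h else w
    pos <- round(seq(1, len, by = small))
    big <- (seq_along(pos) - 1L) %% 5L == 0L
    lum <- ifelse(big, spec$grid_big_lum, spec$grid_small_lum)
    for (k in seq_along(pos)) {
      if (axis == 1) {
        img[pos[k], ] <- pmin(img[pos[k], ], lum[k])
      } else {
        img[, pos[k]] <- pmin(img[, pos[k]], lum[k])
      }
    }
  }
  img
}

# Draw one trace into a panel. Ordinates are connected column-to-column
# with vertical fills so steep slopes stay contiguous (as pen ink would).
draw_panel <- function(img, trace, spec, x0, baseline_row, t_start, dur_ms) {
  ms_per_px <- 1000 / (spec$paper_speed * spec$px_per_mm)
  ncols <- floor(dur_ms / ms_per_px)
  cols <- x0 + seq_len(ncols) - 1L
  cols <- cols[cols <= ncol(img)]
  ncols <- length(cols)
  t_q <- t_start + (seq_len(ncols) - 1L) * ms_per_px
  amp <- stats::approx(trace$t_ms, trace$signal, xout = t_q, rule = 2)$y
  rows <- round(baseline_row - amp * spec$amp_scale * spec$px_per_mm)
  rows <- pmin(nrow(img), pmax(1L, rows))
  # split steep connectors between adjacent columns (Bresenham-style),
  # so the per-column ink centroid tracks the sampled ordinate
  for (j in seq_len(ncols)) {
    img[rows[j], cols[j]] <- spec$trace_lum
    if (j < ncols && abs(rows[j + 1L] - rows[j]) > 1L) {
      mid <- round((rows[j] + rows[j + 1L]) / 2)
      seg1 <- seq(min(rows[j], mid), max(rows[j], mid))
      seg2 <- seq(min(mid, rows[j + 1L]), max(mid, rows[j + 1L]))
      img[seg1, cols[j]] <- spec$trace_lum
      img[seg2, cols[j + 1L]] <- spec$trace_lum
    }
  }
  img
}

#' Render synthetic ECG traces onto a gridded raster page
#'
#' @param traces a single trace (as returned by [gen_ecg_signal()]) or a
#'   named list of traces. With `layout = "standard"` the first 12 traces
#'   fill the 3x4 panel grid and the last is drawn as a full-width rhythm
#'   strip.
#' @param spec a [page_render_spec()].
#' @return list with `image` (grayscale matrix, 1 = white) and `manifest`
#'   (panel origins, baselines, calibration, per-panel time windows).
#' @export
render_ecg_page <- function(traces, spec = page_render_spec()) {
  stopifnot(inherits(spec, "page_render_spec"))
  if (!is.null(traces$signal)) traces <- list(II = traces)
  ppm <- spec$px_per_mm
  margin <- round(5 * ppm)
  panel_h <- round(spec$panel_height_mm * ppm)

  if (spec$layout == "single") {
    durs <- vapply(traces, function(tr) max(tr$t_ms) + 1000 / tr$fs, 0)
    widths <- round(durs / 1000 * spec$paper_speed * ppm)
    w <- max(widths) + 2 * margin
    h <- length(traces) * panel_h + 2 * margin
    img <- matrix(1, h, w)
    img <- draw_grid(img, spec)
    panels <- list()
    for (i in seq_along(traces)) {
      base <- margin + (i - 1L) * panel_h + round(panel_h / 2)
      x0 <- margin + 1L
      dur <- durs[i]
      img <- draw_panel(img, traces[[i]], spec, x0, base, 0, dur)
      panels[[i]] <- list(lead = names(traces)[i] %||% "II",
                          x0 = x0, y0 = margin + (i - 1L) * panel_h,
                          y1 = margin + i * panel_h,
                          baseline_row = base, t_start = 0, dur_ms = dur)
    }
  } else {
    if (length(traces) < 13L) {
      pb_stop("standard layout needs 13 traces (12 leads + rhythm strip)",
              "pb_input_error")
    }
    pd_ms <- spec$panel_duration * 1000
    panel_w <- round(spec$panel_duration * spec$paper_speed * ppm)
    w <- 4L * panel_w + 2L * margin
    h <- 4L * panel_h + 2L * margin
    img <- matrix(1, h, w)
    img <- draw_grid(img, spec)
    panels <- list()
    leads <- names(traces) %||% c(standard_leads(), "II-rhythm")
    for (i in 1:12) {
      rrow <- (i - 1L) %/% 4L
      ccol <- (i - 1L) %% 4L
      x0 <- margin + ccol * panel_w + 1L
      base <- margin + rrow * panel_h + round(panel_h / 2)
      t_start <- ccol * pd_ms
      img <- draw_panel(img, traces[[i]], spec, x0, base, t_start, pd_ms)
      panels[[i]] <- list(lead = leads[i], x0 = x0,
                          y0 = margin + rrow * panel_h,
                          y1 = margin + (rrow + 1L) * panel_h,
                          baseline_row = base, t_start = t_start,
                          dur_ms = pd_ms)
    }
    rs <- traces[[13]]
    base <- margin + 3L * panel_h + round(panel_h / 2)
    dur <- min(max(rs$t_ms) + 1000 / rs$fs,
               (w - 2 * margin) * 1000 / (spec$paper_speed * ppm))
    img <- draw_panel(img, rs, spec, margin + 1L, base, 0, dur)
    panels[[13]] <- list(lead = leads[13], x0 = margin + 1L,
                         y0 = margin + 3L * panel_h, y1 = h - margin,
                         baseline_row = base, t_start = 0, dur_ms = dur)
  }
  manifest <- list(
    panels = panels,
    calibration = list(px_per_mm = ppm, paper_speed = spec$paper_speed,
                       amp_scale = spec$amp_scale),
    page = list(height = nrow(img), width = ncol(img))
  )
  list(image = img, manifest = manifest)
}

#' Write a page image as PNG / read one back
#'
#' Thin wrappers over the \pkg{png} package keeping the in-memory
#' convention (grayscale matrix in `[0,1]`, 1 = white).
#' @param image grayscale matrix.
#' @param path file path.
#' @rdname page_png
#' @export
write_page_png <- function(image, path) {
  png::writePNG(image, target = path)
  invisible(path)
}

#' @rdname page_png
#' @export
read_page_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a
}
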