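# Synthetic lung mask + activation map generator with planted
# consolidation fractions (exact to within 1 pixel per lung by
# construction), used as the pixel-count oracle for the compromise-ratio
# statistic.

ellipse_mask <- function(h, w, cy, cx, ry, rx) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((rows - cy) / ry)^2 + ((cols - cx) / rx)^2 <= 1
}

#' Generate a synthetic lung mask and activation map
#'
#' The mask consists of two disjoint elliptical "lungs". The activation
#' map is strictly supra-threshold (> `threshold`) on exactly
#' `round(fraction * n_pixels)` pixels of each lung and sub-threshold
#' everywhere else (including the background), so the planted fraction
#' is recoverable by pixel counting to within one pixel.
#'
#' @param shape `c(height, width)` in pixels.
#' @param true_fraction_left,true_fraction_right planted activated
#'   fractions in `[0,1]`. "Left"/"right" follow the radiographic
#'   convention of [split_lungs()] (image-left = patient right).
#' @param threshold activation threshold the plant is built against.
#' @param seed RNG seed.
#' @return list with `mask`, `activation`, `truth` (planted fractions
#'   and pixel counts), `threshold`.
#' @export
gen_lung_activation <- function(shape = c(128, 128),
                                true_fraction_left = 0.2,
                                true_fraction_right = 0.2,
                                threshold = 0.20, seed = 1L) {
  stopifnot_scalar(true_fraction_left, "true_fraction_left", 0, 1)
  stopifnot_scalar(true_fraction_right, "true_fraction_right", 0, 1)
  h <- shape[1]; w <- shape[2]
  ry <- 0.35 * h; rx <- 0.16 * w
  lungR <- ellipse_mask(h, w, h / 2, 0.28 * w, ry, rx)  # image-left
  lungL <- ellipse_mask(h, w, h / 2, 0.72 * w, ry, rx)  # image-right
  if (any(lungR & lungL)) {
    pb_stop("lung ellipses overlap at this shape", "pb_input_error")
  }
  mask <- lungR | lungL
  with_seed(seed, {
    activation <- matrix(stats::runif(h * w, 0, threshold * 0.5), h, w)
    plant <- function(act, lung, frac) {
      px <- which(lung)
      k <- round(frac * length(px))
      act[px] <- stats::runif(length(px), 0, threshold * 0.95)
      if (k > 0) {
        hot <- sample(px, k)
        act[hot] <- stats::runif(k, threshold + 1e-6, 1)
      }
      act
    }
    activation <- plant(activation, lungR, true_fraction_right)
    activation <- plant(activation, lungL, true_fraction_left)
    list(
      mask = mask, activation = activation, threshold = threshold,
      truth = list(
        fraction_left = true_fraction_left,
        fraction_right = true_fraction_right,
        n_left = sum(lungL), n_right = sum(lungR),
        act_left = round(true_fraction_left * sum(lungL)),
        act_right = round(true_fraction_right * sum(lungR))
      )
    )
  })
}
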