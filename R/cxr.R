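# CAM-based lung compromise quantification: midline/component lung
# splitting, per-lung and total compromise ratios at an activation
# threshold, and LOOCV threshold selection against gold consolidation
# masks.

# connected components of a binary matrix (4-connectivity), vectorised
# frontier flood fill -- fast enough for the image sizes used here.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nextlab <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo)) {
    nextlab <- nextlab + 1L
    frontier <- todo[1]
    lab[frontier] <- nextlab
    while (length(frontier)) {
      r <- (frontier - 1L) %% h + 1L
      cc <- (frontier - 1L) %/% h + 1L
      nb <- c(frontier[r > 1] - 1L, frontier[r < h] + 1L,
              frontier[cc > 1] - h, frontier[cc < w] + h)
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- nextlab
      frontier <- nb
    }
    todo <- which(mask & lab == 0L)
  }
  lab
}

#' Split a lung mask into right and left lungs
#'
#' With exactly two connected components, each component is one lung and
#' sides are assigned by centroid column (radiographic convention:
#' image-left is the patient's right lung, so the smaller-column
#' component is labelled "right"). Otherwise the mask is split at its
#' bounding-box midline column, midline pixels going to the left lung.
#'
#' @param mask logical/0-1 matrix.
#' @param radiographic if `FALSE`, sides follow image coordinates
#'   instead of the patient convention.
#' @return object of class `lung_partition`: `right`, `left` (binary
#'   matrices), `split_method`.
#' @export
split_lungs <- function(mask, radiographic = TRUE) {
  mask <- mask > 0
  if (!any(mask)) pb_stop("empty lung mask", "pb_input_error")
  lab <- label_components(mask)
  ncomp <- max(lab)
  if (ncomp == 2L) {
    cent <- vapply(1:2, function(k) {
      mean(((which(lab == k) - 1L) %/% nrow(mask)) + 1L)
    }, 0)
    first <- which.min(cent)   # smaller centroid column = image-left
    a <- lab == first; b <- lab == (3L - first)
    method <- "component"
  } else {
    if (ncomp > 2L) {
      warning("more than 2 components; falling back to midline split")
    }
    cols <- ((which(mask) - 1L) %/% nrow(mask)) + 1L
    mid <- floor((min(cols) + max(cols)) / 2)
    colidx <- matrix(rep(seq_len(ncol(mask)), each = nrow(mask)),
                     nrow(mask))
    a <- mask & colidx <= mid        # image-left half (midline included)
    b <- mask & colidx > mid
    method <- "midline"
  }
  # image-left component = patient's right lung under the radiographic view
  if (radiographic) {
    right <- a; left <- b
  } else {
    left <- a; right <- b
  }
  structure(list(right = right, left = left, split_method = method),
            class = "lung_partition")
}

#' Compromise ratios from an activation map (Eq. of the CR/TCR statistic)
#'
#' A pixel is activated when its activation value strictly exceeds the
#' threshold `T`. The compromise ratio of lung L is
#' `CR_L = 100 * activated_L / pixels_L`; the total compromise ratio is
#' the same statistic over the union of both lungs.
#'
#' @param activation numeric matrix, same shape as the mask, values in
#'   `[0,1]`.
#' @param partition a `lung_partition` (or binary mask, split first).
#' @param threshold activation threshold `T` in `[0,1]` (study-style
#'   default 0.20).
#' @return object of class `compromise_result`: `cr_left`, `cr_right`,
#'   `tcr` (percent), per-side activated and total pixel counts, and
#'   `threshold`.
#' @export
compromise_ratios <- function(activation, partition, threshold = 0.20) {
  if (!inherits(partition, "lung_partition")) {
    partition <- split_lungs(partition)
  }
  if (!all(dim(activation) == dim(partition$left))) {
    pb_stop("activation map and mask shapes differ", "pb_input_error")
  }
  stopifnot_scalar(threshold, "threshold", 0, 1)
  act <- activation > threshold
  n_l <- sum(partition$left); n_r <- sum(partition$right)
  a_l <- sum(act & partition$left); a_r <- sum(act & partition$right)
  structure(list(
    cr_left = 100 * a_l / n_l,
    cr_right = 100 * a_r / n_r,
    tcr = 100 * (a_l + a_r) / (n_l + n_r),
    act_left = a_l, act_right = a_r,
    px_left = n_l, px_right = n_r,
    threshold = threshold
  ), class = "compromise_result")
}

#' Dice coefficient of two binary masks
#'
#' Empty-vs-empty is defined as 1 (both agree on absence).
#' @param a,b logical/0-1 matrices.
#' @export
dice_coef <- function(a, b) {
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# rank-based (Mann-Whitney) AUC of continuous scores vs binary labels
pixel_auroc <- function(scores, labels) {
  pos <- labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' LOOCV selection of the activation threshold
#'
#' For each held-out image the threshold maximising mean Dice (activation
#' thresholded vs gold consolidation mask, within the lung mask) over the
#' remaining images is selected, and the held-out Dice at that threshold
#' recorded. Pixelwise AUROC per image is threshold-free (raw activation
#' values vs gold labels, lung pixels only). The reported `t_star` is the
#' threshold maximising mean Dice over all images.
#'
#' @param images list of lists with elements `activation`, `mask`,
#'   `gold` (matrices of equal shape).
#' @param grid candidate thresholds in (0,1).
#' @return object of class `threshold_evaluation`: `t_star`, `dice`
#'   (held-out values), `dice_mean`, `dice_sd`, `auroc`, `auroc_mean`,
#'   `auroc_sd`, `per_threshold` mean Dice curve.
#' @export
threshold_loocv <- function(images, grid = seq(0.05, 0.95, by = 0.05)) {
  if (length(images) < 3) pb_stop("need >= 3 images", "pb_input_error")
  if (all(vapply(images, function(im) !any(im$gold > 0), TRUE))) {
    pb_stop("gold mask empty on every image", "pb_input_error")
  }
  dice_at <- function(im, t) {
    inlung <- im$mask > 0
    dice_coef((im$activation > t) & inlung, (im$gold > 0) & inlung)
  }
  # image x threshold Dice table
  dmat <- vapply(grid, function(t) {
    vapply(images, dice_at, 0, t = t)
  }, numeric(length(images)))
  dmat <- matrix(dmat, nrow = length(images))
  heldout <- numeric(length(images))
  chosen <- numeric(length(images))
  for (i in seq_along(images)) {
    mean_d <- colMeans(dmat[-i, , drop = FALSE])
    j <- which.max(mean_d)
    chosen[i] <- grid[j]
    heldout[i] <- dmat[i, j]
  }
  auroc <- vapply(images, function(im) {
    inlung <- im$mask > 0
    pixel_auroc(im$activation[inlung], im$gold[inlung])
  }, 0)
  overall <- colMeans(dmat)
  structure(list(
    t_star = grid[which.max(overall)],
    chosen = chosen,
    dice = heldout, dice_mean = mean(heldout), dice_sd = stats::sd(heldout),
    auroc = auroc, auroc_mean = mean(auroc, na.rm = TRUE),
    auroc_sd = stats::sd(auroc, na.rm = TRUE),
    grid = grid, per_threshold = overall
  ), class = "threshold_evaluation")
}
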