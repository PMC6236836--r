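#' Iterative optimal threshold (Ridler-Calvard)
#'
#' Finds the gray-level threshold separating two intensity populations
#' (structure of interest vs dark background) by the classic iterative
#' intermeans scheme: starting from the midpoint of the intensity range, the
#' threshold is repeatedly replaced by the average of the means of the two
#' classes it induces, until it moves by less than 0.5 gray level (sub-integer
#' refinement is meaningless for integer histograms) or 50 iterations.
#' Convergence typically takes well under ten iterations.
#'
#' @param pixels numeric vector or matrix with at least two distinct values.
#' @param init starting threshold; default the midpoint of the intensity
#'   range.  When the two populations are very unbalanced (a thin dark rim
#'   inside a mostly-bright contour) the midpoint can start in the basin of
#'   a bright-vs-brighter split; callers that know the dark class is the
#'   minority can start lower (see [partial_volume_correct()]).
#' @return a list of class `threshold_result` with elements `threshold`,
#'   `n_iterations`, and `history` (the successive thresholds).
#' @examples
#' optimal_threshold(c(rep(10, 50), rep(200, 50)))$threshold  # 105
#' @export
optimal_threshold <- function(pixels, init = NULL) {
  x <- as.numeric(pixels)
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2)
    stop("constant image: no threshold separates two distributions")
  t_cur <- if (is.null(init)) (min(x) + max(x)) / 2 else init
  if (t_cur >= max(x)) t_cur <- (min(x) + max(x)) / 2
  history <- t_cur
  for (k in seq_len(50)) {
    lo <- x[x <= t_cur]; hi <- x[x > t_cur]
    if (length(lo) == 0 || length(hi) == 0) break
    t_new <- (mean(lo) + mean(hi)) / 2
    history <- c(history, t_new)
    if (abs(t_new - t_cur) < 0.5) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  structure(list(threshold = t_cur, n_iterations = length(history) - 1L,
                 history = history),
            class = "threshold_result")
}

#' Partial-volume artifact correction
#'
#' Shrinks an ROI mask by removing pixels classified as background by the
#' iterative optimal threshold computed within the mask: boundary pixels whose
#' intensity is pulled toward the background by partial-volume averaging fall
#' below the threshold and are excluded from analysis.  The output is always a
#' subset of the input mask.
#'
#' @param slice an [image_slice()].
#' @param mask an [roi_mask()] (or logical matrix) on the same grid.
#' @return an [roi_mask()] containing only above-threshold pixels.
#' @export
partial_volume_correct <- function(slice, mask) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  stopifnot(all(dim(m) == dim(slice$pixels)))
  if (!any(m)) stop("empty mask")
  v <- slice$pixels[m]
  # dark-anchored start: the sub-threshold class is the minority rim, so
  # starting between the darkest pixel and the median selects the
  # dark-vs-structure split rather than a split within the bright mode
  thr <- optimal_threshold(v, init = (min(v) + stats::median(v)) / 2)$threshold
  keep <- m & (slice$pixels > thr)
  if (!any(keep)) stop("partial-volume correction removed every pixel")
  roi_mask(keep, if (inherits(mask, "roi_mask")) mask$source else "manual_file")
}

#' Global grayscale normalization
#'
#' Linearly rescales the entire image so that its global mean and standard
#' deviation equal fixed targets (defaults 250 and 30), removing overall
#' grayscale variation between images acquired under different conditions.
#' Statistics are computed over the whole image, not the ROI, and the output
#' is kept in floating point.
#'
#' @param pixels numeric matrix with positive variance.
#' @param target_mean,target_sd target global statistics (gray values).
#' @return normalized numeric matrix with mean `target_mean` and (sample)
#'   standard deviation `target_sd`.
#' @export
normalize_global <- function(pixels, target_mean = 250, target_sd = 30) {
  stopifnot(target_sd > 0)
  s <- stats::sd(pixels)
  if (!is.finite(s) || s == 0) stop("zero-variance image cannot be normalized")
  (pixels - mean(pixels)) / s * target_sd + target_mean
}

#' Preprocess one slice for feature extraction
#'
#' Applies the two-step correction protocol in order: (a) partial-volume
#' artifact correction of the mask by iterative optimal thresholding within
#' the ROI, then (b) global grayscale normalization of the whole image to
#' mean 250 / SD 30.
#'
#' @param slice an [image_slice()].
#' @param mask an [roi_mask()]; default [auto_mask()] of the slice.
#' @param target_mean,target_sd normalization targets.
#' @return list with `slice` (normalized pixels) and `mask` (corrected ROI).
#' @export
preprocess_slice <- function(slice, mask = NULL, target_mean = 250,
                             target_sd = 30) {
  if (is.null(mask)) mask <- auto_mask(slice)
  corrected <- partial_volume_correct(slice, mask)
  slice$pixels <- normalize_global(slice$pixels, target_mean, target_sd)
  list(slice = slice, mask = corrected)
}
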