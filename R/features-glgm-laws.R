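#' Gray-level gradient features
#'
#' Computes the per-pixel gradient magnitude with 3x3 Sobel operators and
#' summarizes its distribution over ROI interior pixels (pixels whose full
#' 3x3 neighbourhood lies inside the mask) with four moments: mean (MGR),
#' variance (VGR, population moment), and the standardized third and fourth
#' moments (skewness, kurtosis -- non-excess, so a Gaussian gives 3).  Zero
#' gradient variance leaves skewness and kurtosis undefined (`NaN` with a
#' warning).
#'
#' @param roi a [quantize()]d ROI (supplies the mask).
#' @param pixels the (normalized) intensity matrix.
#' @return named numeric vector: mgr, vgr, skewness, kurtosis.
#' @export
glgm_features <- function(roi, pixels) {
  interior <- mask_interior(roi$mask)
  if (!any(interior)) stop("ROI has no interior pixel with a full 3x3 neighbourhood")
  sobel_x <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  gx <- filter3x3(pixels, sobel_x)
  gy <- filter3x3(pixels, t(sobel_x))
  g <- sqrt(gx^2 + gy^2)[interior]
  mu <- mean(g)
  m2 <- mean((g - mu)^2)
  if (m2 == 0) {
    warning("zero gradient variance: GLGM skewness/kurtosis undefined")
    return(c(mgr = mu, vgr = 0, skewness = NaN, kurtosis = NaN))
  }
  c(mgr = mu, vgr = m2,
    skewness = mean((g - mu)^3) / m2^1.5,
    kurtosis = mean((g - mu)^4) / m2^2)
}

#' Laws texture energy features
#'
#' Applies the standard Laws illumination correction -- subtracting the 3x3
#' moving-average local mean, so that a flat image has zero texture energy
#' in every channel -- then convolves with the nine 3x3 Laws masks formed as
#' outer products of the 1-D kernels L3 = (1, 2, 1), E3 = (-1, 0, 1),
#' S3 = (-1, 2, -1), in the order L3L3, L3E3, L3S3, E3L3, E3E3, E3S3, S3L3,
#' S3E3, S3S3 (first kernel along dim 1).  Each feature L1..L9 is the mean
#' squared filter response over ROI interior pixels.
#'
#' @param roi a [quantize()]d ROI (supplies the mask).
#' @param pixels the (normalized) intensity matrix.
#' @return named numeric vector l1..l9.
#' @export
laws_features <- function(roi, pixels) {
  interior <- mask_interior(roi$mask)
  if (!any(interior)) stop("ROI has no interior pixel with a full 3x3 neighbourhood")
  resid <- pixels - local_mean3x3(pixels)
  k1 <- list(L3 = c(1, 2, 1), E3 = c(-1, 0, 1), S3 = c(-1, 2, -1))
  out <- numeric(9)
  idx <- 1L
  for (a in k1) for (b in k1) {
    resp <- filter3x3(resid, outer(a, b))
    out[idx] <- mean(resp[interior]^2)
    idx <- idx + 1L
  }
  names(out) <- paste0("l", 1:9)
  out
}
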