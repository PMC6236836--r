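#' Histogram (first-order and local-neighbourhood) features
#'
#' Twelve features of the masked intensity distribution:
#' mean, median, standard deviation, geometric and harmonic mean, fourth
#' central moment, interquartile range, and histogram entropy
#' (\eqn{-\sum h_k \log_2 h_k} over the G-level quantized histogram), plus
#' four local-neighbourhood statistics averaged over the ROI:
#' \describe{
#'   \item{range}{local (max - min) in the 3x3 neighbourhood}
#'   \item{second_std}{SD of the 2-pixel horizontal pair}
#'   \item{std5}{SD of the 5-pixel plus-cross neighbourhood}
#'   \item{std9}{SD of the full 3x3 neighbourhood}
#' }
#' Local statistics are mask-aware: only in-mask neighbours enter, and pixels
#' with fewer than two in-mask neighbours are skipped.  Geometric and
#' harmonic means of distributions containing nonpositive values are computed
#' on values shifted up to a minimum of 1.
#'
#' @param roi a [quantize()]d ROI (supplies the entropy histogram and mask).
#' @param pixels the (normalized) intensity matrix the ROI was cut from.
#' @return named numeric vector of 12 features.
#' @export
histogram_features <- function(roi, pixels) {
  m <- roi$mask
  x <- pixels[m]
  if (length(x) < 2) stop("histogram features need at least 2 pixels")

  xp <- if (min(x) < 1) x - min(x) + 1 else x   # for geometric/harmonic mean
  counts <- tabulate(roi$levels[m] + 1L, roi$G)
  p <- counts[counts > 0] / sum(counts)

  c(mean           = mean(x),
    median         = stats::median(x),
    std            = stats::sd(x),
    range          = local_range_mean(pixels, m),
    geometric_mean = exp(mean(log(xp))),
    harmonic_mean  = 1 / mean(1 / xp),
    second_std     = local_sd_mean(pixels, m, cbind(0, 0:1)),
    std5           = local_sd_mean(pixels, m, rbind(c(0, 0), c(-1, 0), c(1, 0),
                                                    c(0, -1), c(0, 1))),
    std9           = local_sd_mean(pixels, m, as.matrix(expand.grid(-1:1, -1:1))),
    fourth_moment  = mean((x - mean(x))^4),
    iqr            = stats::IQR(x),
    entropy        = -sum(p * log2(p)))
}

# mean over masked pixels of the sample SD of in-mask neighbours at `offsets`
# (rows of (dr, dc)); pixels with < 2 in-mask neighbours are skipped
local_sd_mean <- function(pixels, mask, offsets) {
  cnt <- 0; s <- 0; ss <- 0
  for (k in seq_len(nrow(offsets))) {
    nb <- shift_mat(pixels, offsets[k, 1], offsets[k, 2], fill = 0)
    inm <- shift_mat(mask, offsets[k, 1], offsets[k, 2], fill = FALSE)
    cnt <- cnt + inm
    s <- s + nb * inm
    ss <- ss + nb * nb * inm
  }
  ok <- mask & (cnt >= 2)
  if (!any(ok)) return(NaN)
  v <- (ss[ok] - s[ok]^2 / cnt[ok]) / (cnt[ok] - 1)
  mean(sqrt(pmax(v, 0)))
}

# mean over masked pixels of local (max - min) in the 3x3 in-mask neighbourhood
local_range_mean <- function(pixels, mask) {
  mx <- matrix(-Inf, nrow(pixels), ncol(pixels))
  mn <- matrix(Inf, nrow(pixels), ncol(pixels))
  for (dr in -1:1) for (dc in -1:1) {
    nb <- shift_mat(pixels, dr, dc, fill = NA)
    inm <- shift_mat(mask, dr, dc, fill = FALSE)
    nb[!inm] <- NA
    mx <- pmax(mx, nb, na.rm = TRUE)
    mn <- pmin(mn, nb, na.rm = TRUE)
  }
  ok <- mask & is.finite(mx) & is.finite(mn)
  mean((mx - mn)[ok])
}
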