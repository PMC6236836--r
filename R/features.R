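#' Canonical texture feature names
#'
#' The 41-feature panel: 12 histogram, 5 GLCM, 11 GLRL, 4 GLGM and 9 Laws
#' features, plus three report extras (intensity skewness/kurtosis and total
#' Laws energy) that appear in result tables but are not part of the core
#' panel.
#'
#' @return named list of character vectors: `histogram`, `glcm`, `glrl`,
#'   `glgm`, `laws`, `extras`, and `core` (the 41 core names in canonical
#'   order).
#' @export
feature_names <- function() {
  fam <- list(
    histogram = paste0("hist_", c("mean", "median", "std", "range",
                                  "geometric_mean", "harmonic_mean",
                                  "second_std", "std5", "std9",
                                  "fourth_moment", "iqr", "entropy")),
    glcm = paste0("glcm_", c("entropy", "contrast", "correlation", "energy",
                             "homogeneity")),
    glrl = paste0("glrl_", c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                             "srlge", "srhge", "lrlge", "lrhge")),
    glgm = paste0("glgm_", c("mgr", "vgr", "skewness", "kurtosis")),
    laws = paste0("laws_l", 1:9),
    extras = c("mean_skewness", "mean_kurtosis", "mean_laws"))
  fam$core <- c(fam$histogram, fam$glcm, fam$glrl, fam$glgm, fam$laws)
  fam
}

# shift a matrix by (dr, dc): out[r, c] = m[r + dr, c + dc], `fill` outside
shift_mat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r1 <- max(1, 1 - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1, 1 - dc); c2 <- min(nc, nc - dc)
  if (r1 <= r2 && c1 <= c2) {
    rs <- r1:r2; cs <- c1:c2
    out[rs, cs] <- m[rs + dr, cs + dc]
  }
  out
}

# 3x3 correlation by shift-and-add; borders use zero padding (callers only
# read pixels whose full neighbourhood is in the mask)
filter3x3 <- function(img, k) {
  out <- 0
  for (dr in -1:1) for (dc in -1:1) {
    w <- k[dr + 2, dc + 2]
    if (w != 0) out <- out + w * shift_mat(img, dr, dc, fill = 0)
  }
  out
}

# 3x3 moving average normalized by the number of in-image neighbours, so a
# flat image has an identically flat local mean right up to the borders
local_mean3x3 <- function(img) {
  s <- filter3x3(img, matrix(1, 3, 3))
  n <- filter3x3(matrix(1, nrow(img), ncol(img)), matrix(1, 3, 3))
  s / n
}

# mask eroded to pixels whose full 3x3 neighbourhood lies inside the mask
mask_interior <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0)
      out <- out & shift_mat(mask, dr, dc, fill = FALSE)
  out
}

#' Quantize masked pixels to G gray levels
#'
#' Linear binning of the masked pixel values into levels `0 .. G - 1`.  By
#' default the bin edges span the min-max range of the masked pixels; a
#' constant region maps entirely to level 0.  Supplying fixed `bounds`
#' anchors the bin width instead (values outside are clipped), which makes
#' level-unit features comparable across slices -- on normalized images the
#' pipeline anchors bins at `target_mean +/- 4 target_sd`, because the
#' min-max range of a noisy slice is an extreme-value statistic whose
#' slice-to-slice fluctuation otherwise leaks into every quantized feature.
#'
#' @param pixels numeric matrix (typically normalized intensities).
#' @param mask an [roi_mask()] or logical matrix.
#' @param G number of gray levels (default 256).
#' @param bounds optional length-2 numeric: fixed lower/upper gray bounds.
#' @return an object of class `quantized_roi` with integer `levels` matrix
#'   (`NA` outside the mask), `G`, and the logical `mask`.
#' @export
quantize <- function(pixels, mask, G = 256, bounds = NULL) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  stopifnot(is.matrix(pixels), all(dim(m) == dim(pixels)), G >= 2)
  if (!any(m)) stop("empty mask")
  v <- pixels[m]
  rng <- if (is.null(bounds)) range(v) else {
    stopifnot(length(bounds) == 2, bounds[2] > bounds[1])
    v <- pmin(pmax(v, bounds[1]), bounds[2])
    as.numeric(bounds)
  }
  lev <- matrix(NA_integer_, nrow(pixels), ncol(pixels))
  if (rng[1] == rng[2]) {
    lev[m] <- 0L
  } else {
    q <- floor((v - rng[1]) / (rng[2] - rng[1]) * G)
    q[q >= G] <- G - 1L
    lev[m] <- as.integer(q)
  }
  structure(list(levels = lev, G = as.integer(G), mask = m),
            class = "quantized_roi")
}

#' Extract the full texture feature panel from one slice
#'
#' Computes the 41 core features (12 histogram, 5 GLCM, 11 GLRL, 4 GLGM,
#' 9 Laws) plus the three report extras on a preprocessed slice: `pixels`
#' are expected to be globally normalized and `mask` partial-volume
#' corrected (see [preprocess_slice()]).
#'
#' @param slice an [image_slice()] with normalized pixels.
#' @param mask an [roi_mask()] or logical matrix.
#' @param G gray levels for quantization-based families (default 256).
#' @param quant_bounds optional fixed gray bounds passed to [quantize()].
#' @return named numeric vector of length 44 (41 core + 3 extras) in
#'   canonical order.
#' @export
extract_all <- function(slice, mask, G = 256, quant_bounds = NULL) {
  px <- if (inherits(slice, "image_slice")) slice$pixels else slice
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  roi <- quantize(px, m, G, quant_bounds)
  v <- c(histogram_features(roi, px),
         glcm_features(roi),
         glrl_features(roi),
         glgm_features(roi, px),
         laws_features(roi, px),
         intensity_extras(roi, px))
  fam <- feature_names()
  names(v) <- c(fam$core, fam$extras)
  v["mean_laws"] <- sum(v[fam$laws])
  v
}

# report extras: skewness / kurtosis of the masked intensity distribution
# ("mean skewness" / "mean kurtosis" rows) and a placeholder for total Laws
# energy, filled in by extract_all
intensity_extras <- function(roi, pixels) {
  x <- pixels[roi$mask]
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(c(NaN, NaN, 0))
  sk <- mean((x - mean(x))^3) / m2^1.5
  ku <- mean((x - mean(x))^4) / m2^2
  c(sk, ku, 0)
}
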