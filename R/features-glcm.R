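#' Gray-level co-occurrence matrix features
#'
#' Builds symmetric distance-1 GLCMs in the horizontal, 45 degree, vertical
#' and 135 degree directions (only directly adjacent pixel pairs, both pixels
#' inside the mask), normalizes each direction's matrix to sum 1, averages
#' the normalized matrices, and computes five Haralick features:
#' \deqn{contrast = \sum |i-j|^2 p(i,j)}
#' \deqn{correlation = \sum (i-\mu_i)(j-\mu_j) p(i,j) / (\sigma_i \sigma_j)}
#' \deqn{energy = \sum p(i,j)^2}
#' \deqn{homogeneity = \sum p(i,j) / (1 + |i-j|)}
#' \deqn{entropy = -\sum p(i,j) \ln p(i,j)}
#' with \eqn{0 \ln 0 := 0}.  A constant ROI has a single-cell GLCM; its
#' correlation is undefined and reported as `NaN` with a warning.
#'
#' @param roi a [quantize()]d ROI.
#' @param directions integer matrix of (dr, dc) offsets, one row per
#'   direction; default the four standard directions.
#' @return named numeric vector: entropy, contrast, correlation, energy,
#'   homogeneity.
#' @export
glcm_features <- function(roi, directions = rbind(c(0, 1), c(-1, 1),
                                                  c(1, 0), c(1, 1))) {
  p <- glcm_matrix(roi, directions)
  G <- roi$G
  nz <- which(p > 0)
  pv <- p[nz]
  i <- (nz - 1L) %/% G
  j <- (nz - 1L) %% G
  mu_i <- sum(i * pv); mu_j <- sum(j * pv)
  var_i <- sum((i - mu_i)^2 * pv); var_j <- sum((j - mu_j)^2 * pv)
  correlation <- if (var_i == 0 || var_j == 0) {
    warning("constant ROI: GLCM correlation undefined")
    NaN
  } else sum((i - mu_i) * (j - mu_j) * pv) / sqrt(var_i * var_j)
  c(entropy     = -sum(pv * log(pv)),
    contrast    = sum((i - j)^2 * pv),
    correlation = correlation,
    energy      = sum(pv^2),
    homogeneity = sum(pv / (1 + abs(i - j))))
}

# direction-averaged normalized symmetric GLCM as a G*G vector indexed
# (i * G + j + 1), i = first pixel's level, 0-based
glcm_matrix <- function(roi, directions) {
  G <- roi$G
  L <- roi$levels
  acc <- numeric(G * G)
  used <- 0L
  for (k in seq_len(nrow(directions))) {
    B <- shift_mat(L, directions[k, 1], directions[k, 2], fill = NA)
    valid <- !is.na(L) & !is.na(B)
    if (!any(valid)) next
    a <- L[valid]; b <- B[valid]
    tab <- tabulate(c(a * G + b, b * G + a) + 1L, G * G)
    acc <- acc + tab / sum(tab)
    used <- used + 1L
  }
  if (used == 0L) stop("no valid adjacent pixel pairs inside the mask")
  acc / used
}
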