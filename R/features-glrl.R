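#' Gray-level run-length features
#'
#' Enumerates maximal runs of equal gray level along the horizontal,
#' 45 degree, vertical and 135 degree directions (runs break at mask
#' boundaries), computes the eleven standard Galloway/Tang run-length
#' features per direction, and averages them over the four directions.
#' With `p(i, j)` the number of runs of (1-based) gray index `i` and length
#' `j`, `nr` the total number of runs and `np` the number of mask pixels:
#' SRE = (1/nr) sum p/j^2, LRE = (1/nr) sum p j^2,
#' GLN = (1/nr) sum_i (sum_j p)^2, RLN = (1/nr) sum_j (sum_i p)^2,
#' RP = nr/np, LGRE = (1/nr) sum p/i^2, HGRE = (1/nr) sum p i^2,
#' SRLGE = (1/nr) sum p/(i^2 j^2), SRHGE = (1/nr) sum p i^2/j^2,
#' LRLGE = (1/nr) sum p j^2/i^2, LRHGE = (1/nr) sum p i^2 j^2.
#'
#' @param roi a [quantize()]d ROI.
#' @param directions subset of `c("horizontal", "diag45", "vertical",
#'   "diag135")` to average over.
#' @return named numeric vector of 11 features.
#' @export
glrl_features <- function(roi,
                          directions = c("horizontal", "diag45", "vertical",
                                         "diag135")) {
  directions <- match.arg(directions, several.ok = TRUE)
  np <- sum(roi$mask)
  if (np < 1) stop("empty mask")
  per_dir <- lapply(directions, function(d) {
    runs <- runs_in_direction(roi, d)
    glrl_from_runs(runs$gray, runs$len, np, roi$G)
  })
  colMeans(do.call(rbind, per_dir))
}

# maximal runs along one direction; NA (out-of-mask) pixels break runs
runs_in_direction <- function(roi, direction) {
  L <- roi$levels
  nr <- nrow(L); nc <- ncol(L)
  v <- switch(direction,
    horizontal = as.vector(rbind(t(L), NA_integer_)),
    vertical   = as.vector(rbind(L, NA_integer_)),
    diag45     = {  # along (r - 1, c + 1): constant r + c
      d <- as.vector(row(L) + col(L))
      unlist(lapply(split(as.vector(L), d), function(x) c(x, NA_integer_)),
             use.names = FALSE)
    },
    diag135    = {  # along (r + 1, c + 1): constant c - r
      d <- as.vector(col(L) - row(L))
      unlist(lapply(split(as.vector(L), d), function(x) c(x, NA_integer_)),
             use.names = FALSE)
    })
  # distinct negative sentinels keep NA stretches from merging into runs
  nas <- is.na(v)
  v[nas] <- -seq_len(sum(nas))
  r <- rle(v)
  keep <- r$values >= 0
  list(gray = r$values[keep], len = r$lengths[keep])
}

glrl_from_runs <- function(gray, len, np, G) {
  nr <- length(gray)
  if (nr == 0) stop("no runs inside the mask")
  i <- gray + 1  # 1-based gray index
  j <- len
  c(sre   = mean(1 / j^2),
    lre   = mean(j^2),
    gln   = sum(tabulate(i, G)^2) / nr,
    rln   = sum(tabulate(j)^2) / nr,
    rp    = nr / np,
    lgre  = mean(1 / i^2),
    hgre  = mean(i^2),
    srlge = mean(1 / (i^2 * j^2)),
    srhge = mean(i^2 / j^2),
    lrlge = mean(j^2 / i^2),
    lrhge = mean(i^2 * j^2))
}
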