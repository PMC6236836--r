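#' Region-of-interest mask
#'
#' A logical matrix marking the analysed phantom region on a slice.  Following
#' the emulated study's contouring protocol, the default mask covers the whole
#' phantom footprint -- tubes plus the interstitial space between them -- as a
#' single contour; partial-volume correction later removes sub-threshold
#' pixels ([partial_volume_correct()]).
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @param source provenance of the mask: `"manual_file"` or `"auto_threshold"`.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(mask, source = c("manual_file", "auto_threshold")) {
  source <- match.arg(source)
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("mask has no TRUE pixels")
  structure(list(mask = mask, source = source), class = "roi_mask")
}

#' Load a region-of-interest mask from file
#'
#' Supported formats: PNG (any nonzero first-channel value is inside) and
#' JSON polygon -- an array of `[row, col]` vertices in 0-based pixel
#' coordinates which is rasterized by the even-odd rule (pixels whose centres
#' fall on the polygon boundary are inside).
#'
#' @param path path to a `.png` or `.json` file.
#' @param shape length-2 integer, expected mask dimensions.
#' @return an [roi_mask()] with source `"manual_file"`.
#' @export
load_mask <- function(path, shape) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    m <- img > 0.5
  } else if (ext == "json") {
    poly <- jsonlite::fromJSON(path)
    if (!is.matrix(poly)) poly <- do.call(rbind, poly)
    m <- rasterize_polygon(poly + 1, shape)  # 0-based -> 1-based pixel centres
  } else {
    stop("unsupported mask format: ", ext)
  }
  if (!all(dim(m) == shape))
    stop(sprintf("mask shape %dx%d does not match expected %dx%d",
                 nrow(m), ncol(m), shape[1], shape[2]))
  roi_mask(m, "manual_file")
}

#' Automatic whole-phantom mask
#'
#' Thresholds the slice with the iterative optimal threshold
#' ([optimal_threshold()]) and takes the convex hull of all above-threshold
#' pixels, expanded by a relative margin, emulating a single generous manual
#' contour drawn around the entire phantom (tubes plus interstitial space
#' plus a thin rim of background).  The rim matters: it keeps the intensity
#' distribution inside the contour bimodal, which is what the downstream
#' partial-volume threshold ([partial_volume_correct()]) assumes.
#'
#' @param slice an [image_slice()].
#' @param pad relative outward expansion of the hull about its centroid
#'   (default 0.1 = 10 percent).
#' @return an [roi_mask()] with source `"auto_threshold"`.
#' @export
auto_mask <- function(slice, pad = 0.1) {
  px <- slice$pixels
  thr <- optimal_threshold(px)$threshold
  keep <- largest_component(px > thr)  # drop stray above-threshold noise
  fg <- which(keep, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("no foreground pixels above threshold")
  hull <- fg[grDevices::chull(fg[, 1], fg[, 2]), , drop = FALSE]
  if (nrow(hull) < 3) {
    m <- matrix(FALSE, nrow(px), ncol(px))
    m[fg] <- TRUE
  } else {
    ctr <- colMeans(hull)
    hull <- sweep(sweep(hull, 2, ctr) * (1 + pad), 2, ctr, "+")
    m <- rasterize_polygon(hull, dim(px))
  }
  roi_mask(m, "auto_threshold")
}

# Largest 8-connected component of a logical matrix, via run-based
# union-find (runs of TRUE within each column, merged across columns when
# their row ranges touch or overlap).
largest_component <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  runs <- list()   # per column: matrix of (start, end, id)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  for (cc in seq_len(nc)) {
    col <- fg[, cc]
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    ids <- integer(length(sel))
    for (k in seq_along(sel)) {
      parent[length(parent) + 1L] <- length(parent) + 1L
      ids[k] <- length(parent)
    }
    cur <- cbind(start = starts[sel], end = ends[sel], id = ids)
    if (cc > 1 && nrow(cur) > 0 && nrow(runs[[cc - 1L]]) > 0) {
      prev <- runs[[cc - 1L]]
      for (k in seq_len(nrow(cur))) {
        touch <- prev[, "end"] >= cur[k, "start"] - 1L &
                 prev[, "start"] <= cur[k, "end"] + 1L
        for (j in which(touch)) {
          a <- find(cur[k, "id"]); b <- find(prev[j, "id"])
          if (a != b) parent[a] <- b
        }
      }
    }
    runs[[cc]] <- cur
  }
  if (length(parent) == 0) return(fg & FALSE)
  sizes <- numeric(length(parent))
  for (cc in seq_len(nc)) {
    cur <- runs[[cc]]
    for (k in seq_len(nrow(cur))) {
      root <- find(cur[k, "id"])
      sizes[root] <- sizes[root] + cur[k, "end"] - cur[k, "start"] + 1L
    }
  }
  best <- which.max(sizes)
  out <- matrix(FALSE, nr, nc)
  for (cc in seq_len(nc)) {
    cur <- runs[[cc]]
    for (k in seq_len(nrow(cur)))
      if (find(cur[k, "id"]) == best)
        out[cur[k, "start"]:cur[k, "end"], cc] <- TRUE
  }
  out
}

# Even-odd polygon rasterization over pixel centres (1-based coordinates,
# column 1 of `poly` = dim1/row, column 2 = dim2/col).  The polygon is
# inflated by a relative 1e-6 about its centroid so that pixel centres lying
# exactly on an edge or vertex count as inside.
rasterize_polygon <- function(poly, shape) {
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3)
  ctr <- colMeans(poly)
  poly <- sweep(sweep(poly, 2, ctr), 2, c(1 + 1e-6, 1 + 1e-6), "*")
  poly <- sweep(poly, 2, ctr, "+")
  nr <- shape[1]; nc <- shape[2]
  pr <- rep(seq_len(nr), times = nc)
  pc <- rep(seq_len(nc), each = nr)
  inside <- rep(FALSE, nr * nc)
  nv <- nrow(poly)
  j <- nv
  for (i in seq_len(nv)) {
    r1 <- poly[i, 1]; c1 <- poly[i, 2]
    r2 <- poly[j, 1]; c2 <- poly[j, 2]
    if (c1 != c2) {
      crosses <- ((c1 > pc) != (c2 > pc)) &
        (pr < (r2 - r1) * (pc - c1) / (c2 - c1) + r1)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  matrix(inside, nr, nc)
}
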