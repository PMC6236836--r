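# Brute-force reference implementations, written independently of the package
# internals (explicit loops, dense matrices), used to validate every texture
# feature family on small ROIs.

oracle_dirs <- rbind(c(0, 1), c(-1, 1), c(1, 0), c(1, 1))

# dense direction-averaged symmetric GLCM, then features by explicit loops
oracle_glcm <- function(levels, mask, G, directions = oracle_dirs) {
  nr <- nrow(levels); nc <- ncol(levels)
  acc <- matrix(0, G, G); used <- 0
  for (d in seq_len(nrow(directions))) {
    M <- matrix(0, G, G)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + directions[d, 1]; c2 <- c + directions[d, 2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          mask[r, c] && mask[r2, c2]) {
        i <- levels[r, c] + 1; j <- levels[r2, c2] + 1
        M[i, j] <- M[i, j] + 1
        M[j, i] <- M[j, i] + 1
      }
    }
    if (sum(M) > 0) { acc <- acc + M / sum(M); used <- used + 1 }
  }
  p <- acc / used
  ent <- 0; con <- 0; ene <- 0; hom <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:G) for (j in 1:G) {
    mu_i <- mu_i + (i - 1) * p[i, j]
    mu_j <- mu_j + (j - 1) * p[i, j]
  }
  v_i <- 0; v_j <- 0; cov <- 0
  for (i in 1:G) for (j in 1:G) {
    pij <- p[i, j]
    if (pij > 0) ent <- ent - pij * log(pij)
    con <- con + (i - j)^2 * pij
    ene <- ene + pij^2
    hom <- hom + pij / (1 + abs(i - j))
    v_i <- v_i + (i - 1 - mu_i)^2 * pij
    v_j <- v_j + (j - 1 - mu_j)^2 * pij
    cov <- cov + (i - 1 - mu_i) * (j - 1 - mu_j) * pij
  }
  c(entropy = ent, contrast = con,
    correlation = if (v_i > 0 && v_j > 0) cov / sqrt(v_i * v_j) else NaN,
    energy = ene, homogeneity = hom)
}

# explicit run enumeration along the 4 directions, features averaged
oracle_glrl <- function(levels, mask, G) {
  nr <- nrow(levels); nc <- ncol(levels)
  np <- sum(mask)
  line_runs <- function(vals) {
    runs <- NULL
    cur_g <- NA; cur_len <- 0
    for (v in c(vals, NA)) {
      if (!is.na(v) && !is.na(cur_g) && v == cur_g) {
        cur_len <- cur_len + 1
      } else {
        if (!is.na(cur_g)) runs <- rbind(runs, c(cur_g, cur_len))
        cur_g <- v; cur_len <- 1
      }
    }
    runs
  }
  dir_lines <- list(
    lapply(seq_len(nr), function(r) ifelse(mask[r, ], levels[r, ], NA)),
    lapply(seq_len(nc), function(c) ifelse(mask[, c], levels[, c], NA)),
    # anti-diagonals (constant r + c)
    lapply(2:(nr + nc), function(s) {
      rs <- max(1, s - nc):min(nr, s - 1)
      sapply(rs, function(r) if (mask[r, s - r]) levels[r, s - r] else NA)
    }),
    # main diagonals (constant c - r)
    lapply((1 - nr):(nc - 1), function(dd) {
      rs <- max(1, 1 - dd):min(nr, nc - dd)
      sapply(rs, function(r) if (mask[r, r + dd]) levels[r, r + dd] else NA)
    }))
  feats <- NULL
  for (lines in dir_lines) {
    runs <- do.call(rbind, lapply(lines, line_runs))
    i <- runs[, 1] + 1; j <- runs[, 2]; nruns <- nrow(runs)
    gl_counts <- sapply(1:G, function(g) sum(i == g))
    rl_counts <- sapply(1:max(j), function(l) sum(j == l))
    feats <- rbind(feats, c(
      sre = sum(1 / j^2) / nruns, lre = sum(j^2) / nruns,
      gln = sum(gl_counts^2) / nruns, rln = sum(rl_counts^2) / nruns,
      rp = nruns / np, lgre = sum(1 / i^2) / nruns,
      hgre = sum(i^2) / nruns, srlge = sum(1 / (i^2 * j^2)) / nruns,
      srhge = sum(i^2 / j^2) / nruns, lrlge = sum(j^2 / i^2) / nruns,
      lrhge = sum(i^2 * j^2) / nruns))
  }
  colMeans(feats)
}

# pixel value with zero padding outside the image
.px0 <- function(img, r, c) {
  if (r < 1 || r > nrow(img) || c < 1 || c > ncol(img)) 0 else img[r, c]
}

oracle_interior <- function(mask) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    ok <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nrow(mask) || c2 < 1 || c2 > ncol(mask) ||
          !mask[r2, c2]) ok <- FALSE
    }
    out[r, c] <- ok
  }
  out
}

oracle_glgm <- function(pixels, mask) {
  interior <- oracle_interior(mask)
  kx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  g <- c()
  for (r in seq_len(nrow(pixels))) for (c in seq_len(ncol(pixels))) {
    if (!interior[r, c]) next
    gx <- 0; gy <- 0
    for (dr in -1:1) for (dc in -1:1) {
      v <- .px0(pixels, r + dr, c + dc)
      gx <- gx + kx[dr + 2, dc + 2] * v
      gy <- gy + kx[dc + 2, dr + 2] * v
    }
    g <- c(g, sqrt(gx^2 + gy^2))
  }
  mu <- mean(g); m2 <- mean((g - mu)^2)
  c(mgr = mu, vgr = m2,
    skewness = if (m2 > 0) mean((g - mu)^3) / m2^1.5 else NaN,
    kurtosis = if (m2 > 0) mean((g - mu)^4) / m2^2 else NaN)
}

oracle_laws <- function(pixels, mask) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  resid <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    s <- 0; n <- 0
    for (dr in -1:1) for (dc in -1:1) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        s <- s + pixels[r2, c2]; n <- n + 1
      }
    }
    resid[r, c] <- pixels[r, c] - s / n
  }
  interior <- oracle_interior(mask)
  k1 <- list(c(1, 2, 1), c(-1, 0, 1), c(-1, 2, -1))
  out <- numeric(9); idx <- 1
  for (a in k1) for (b in k1) {
    kern <- outer(a, b)
    tot <- 0; n <- 0
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (!interior[r, c]) next
      resp <- 0
      for (dr in -1:1) for (dc in -1:1)
        resp <- resp + kern[dr + 2, dc + 2] * .px0(resid, r + dr, c + dc)
      tot <- tot + resp^2; n <- n + 1
    }
    out[idx] <- tot / n; idx <- idx + 1
  }
  names(out) <- paste0("l", 1:9)
  out
}

# random small ROI: values on a G-level grid plus a mask that always
# contains a solid block (so every family has interior pixels)
random_roi <- function(G = 8, max_dim = 16) {
  nr <- sample(6:max_dim, 1); nc <- sample(6:max_dim, 1)
  px <- matrix(runif(nr * nc, 0, 100), nr, nc)
  mask <- matrix(runif(nr * nc) < 0.8, nr, nc)
  mask[2:min(5, nr), 2:min(5, nc)] <- TRUE
  list(pixels = px, mask = mask, G = G)
}

# one simulated, preprocessed slice for feature-level tests
demo_roi <- function(seed = 42, matrix = c(64, 48)) {
  sl <- simulate_series(phantom_config(),
                        acquisition_params(matrix = matrix, n_slices = 1),
                        noise_model(rng_seed = seed))[[1]]
  preprocess_slice(sl)
}
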