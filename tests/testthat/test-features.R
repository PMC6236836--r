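test_that("quantization bins masked pixels linearly into G levels", {
  m <- matrix(TRUE, 2, 2)
  q <- quantize(matrix(c(0, 255, 255, 0), 2, 2), m, G = 2)
  expect_identical(sort(unique(as.vector(q$levels))), c(0L, 1L))
  # constant region degenerates to level 0
  q0 <- quantize(matrix(5, 3, 3), matrix(TRUE, 3, 3), 256)
  expect_true(all(q0$levels == 0L))
  # integer 0..255 data spanning the full range quantizes to itself at G=256
  v <- matrix(sample(0:255, 400, TRUE), 20, 20)
  v[1] <- 0; v[2] <- 255
  q256 <- quantize(v, matrix(TRUE, 20, 20), 256)
  expect_identical(q256$levels, matrix(as.integer(v), 20, 20))
  # fixed bounds clip and anchor the binning
  qb <- quantize(matrix(c(-10, 0, 50, 200), 2, 2), m, G = 100,
                 bounds = c(0, 100))
  expect_identical(as.vector(qb$levels), c(0L, 0L, 50L, 99L))
})

test_that("histogram features reproduce hand-computed values", {
  m3 <- matrix(TRUE, 1, 3)
  f <- histogram_features(quantize(matrix(1:3, 1), m3, 4), matrix(1:3, 1))
  expect_equal(unname(f["mean"]), 2)
  expect_equal(unname(f["median"]), 2)
  f2 <- histogram_features(quantize(matrix(c(1, 4), 1), matrix(TRUE, 1, 2), 4),
                           matrix(c(1, 4), 1))
  expect_equal(unname(f2["geometric_mean"]), 2)
  expect_equal(unname(f2["harmonic_mean"]), 1.6)
  # uniform histogram over all 256 levels carries exactly 8 bits
  v <- matrix(rep(0:255, 4), 32, 32)
  fu <- histogram_features(quantize(v, matrix(TRUE, 32, 32), 256), v)
  expect_equal(unname(fu["entropy"]), 8)
})

test_that("fourth central moment matches the Gaussian 3 sigma^4 identity", {
  set.seed(2024)
  v <- matrix(rnorm(300^2, 250, 30), 300, 300)
  f <- histogram_features(quantize(v, matrix(TRUE, 300, 300), 256), v)
  expect_lt(abs(f["fourth_moment"] / (3 * 30^4) - 1), 0.05)
})

test_that("constant ROI collapses the GLCM to a single cell", {
  q <- quantize(matrix(7, 6, 6), matrix(TRUE, 6, 6), 256)
  expect_warning(f <- glcm_features(q), "correlation undefined")
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f["homogeneity"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  expect_true(is.nan(f["correlation"]))
})

test_that("horizontal GLCM of a checkerboard is the two-cell chessboard matrix", {
  cb <- matrix((row(matrix(0, 4, 4)) + col(matrix(0, 4, 4))) %% 2, 4, 4)
  q <- quantize(cb, matrix(TRUE, 4, 4), 2)
  f <- glcm_features(q, directions = rbind(c(0, 1)))
  expect_equal(unname(f["contrast"]), 1)
  expect_equal(unname(f["homogeneity"]), 0.5)
  expect_equal(unname(f["energy"]), 0.5)
})

test_that("constant 4x4 ROI yields the single-run GLRL cell horizontally", {
  q <- quantize(matrix(0, 4, 4), matrix(TRUE, 4, 4), 256)
  f <- glrl_features(q, directions = "horizontal")
  expect_equal(unname(f["sre"]), 0.0625)
  expect_equal(unname(f["lre"]), 16)
  expect_equal(unname(f["rp"]), 0.25)
})

test_that("alternating sequences have unit-length runs everywhere", {
  v <- matrix(rep(c(0, 255), 8), 1, 16)
  q <- quantize(v, matrix(TRUE, 1, 16), 2)
  f <- glrl_features(q, directions = "horizontal")
  expect_equal(unname(f["sre"]), 1)
  expect_equal(unname(f["lre"]), 1)
  expect_equal(unname(f["rp"]), 1)
})

test_that("gradient features vanish on constant and linear-ramp images", {
  m <- matrix(TRUE, 8, 8)
  q <- quantize(matrix(1, 8, 8), m, 256)
  expect_warning(f <- glgm_features(q, matrix(1, 8, 8)), "zero gradient")
  expect_equal(unname(f["mgr"]), 0)
  expect_equal(unname(f["vgr"]), 0)
  ramp <- matrix(rep(3 * (1:8), each = 8), 8, 8)
  expect_warning(fr <- glgm_features(quantize(ramp, m, 256), ramp),
                 "zero gradient")
  expect_equal(unname(fr["vgr"]), 0)
  expect_equal(unname(fr["mgr"]), 3 * 8)  # Sobel row-derivative weight is 8
})

test_that("Laws energies vanish on flat images after illumination removal", {
  m <- matrix(TRUE, 10, 10)
  f <- laws_features(quantize(matrix(250, 10, 10), m, 256),
                     matrix(250, 10, 10))
  expect_equal(unname(f), rep(0, 9))
})

test_that("every quantized family matches its brute-force oracle on random ROIs", {
  set.seed(31)
  for (rep in 1:8) {
    roi <- random_roi()
    q <- quantize(roi$pixels, roi$mask, roi$G)
    expect_equal(glcm_features(q),
                 oracle_glcm(q$levels, roi$mask, roi$G), tolerance = 1e-10)
    expect_equal(glrl_features(q),
                 oracle_glrl(q$levels, roi$mask, roi$G), tolerance = 1e-10)
    expect_equal(glgm_features(q, roi$pixels),
                 oracle_glgm(roi$pixels, roi$mask), tolerance = 1e-10)
    expect_equal(laws_features(q, roi$pixels),
                 oracle_laws(roi$pixels, roi$mask), tolerance = 1e-10)
  }
})

test_that("direction-averaged GLCM is a symmetric probability distribution", {
  set.seed(5)
  roi <- random_roi()
  q <- quantize(roi$pixels, roi$mask, roi$G)
  p <- matrix(phantomtex:::glcm_matrix(q, rbind(c(0, 1), c(-1, 1), c(1, 0),
                                                c(1, 1))),
              roi$G, roi$G, byrow = TRUE)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p, t(p), tolerance = 1e-12)
  expect_true(all(p >= 0))
})

test_that("rotating a square ROI by 90 degrees leaves averaged features unchanged", {
  set.seed(17)
  px <- matrix(runif(144, 0, 10), 12, 12)
  m <- matrix(TRUE, 12, 12)
  rot <- t(px)[, 12:1]
  q1 <- quantize(px, m, 8); q2 <- quantize(rot, m, 8)
  expect_equal(glcm_features(q1), glcm_features(q2), tolerance = 1e-10)
  expect_equal(glrl_features(q1), glrl_features(q2), tolerance = 1e-10)
})

test_that("Gaussian noise raises GLCM contrast and lowers homogeneity", {
  set.seed(23)
  base <- matrix(rep(seq(100, 400, length.out = 24), each = 24), 24, 24)
  m <- matrix(TRUE, 24, 24)
  deltas <- replicate(20, {
    noisy <- base + matrix(rnorm(576, 0, 25), 24, 24)
    f0 <- glcm_features(quantize(base, m, 32, bounds = c(0, 500)))
    f1 <- glcm_features(quantize(noisy, m, 32, bounds = c(0, 500)))
    c(f1["contrast"] - f0["contrast"], f1["homogeneity"] - f0["homogeneity"])
  })
  expect_true(all(deltas[1, ] > 0))
  expect_true(all(deltas[2, ] < 0))
})

test_that("extract_all emits the 41 core features plus 3 extras deterministically", {
  pp <- demo_roi()
  fv <- extract_all(pp$slice, pp$mask)
  fam <- feature_names()
  expect_length(fam$core, 41)
  expect_identical(names(fv), c(fam$core, fam$extras))
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_all(pp$slice, pp$mask))
  expect_equal(unname(fv["mean_laws"]), sum(fv[fam$laws]))
})
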