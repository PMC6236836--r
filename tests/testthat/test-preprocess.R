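test_that("two-delta histogram converges to the midpoint of the class means", {
  res <- optimal_threshold(c(rep(10, 40), rep(200, 40)))
  expect_s3_class(res, "threshold_result")
  expect_equal(res$threshold, 105)
  expect_lte(res$n_iterations, 10)
})

test_that("constant images cannot be thresholded", {
  expect_error(optimal_threshold(rep(7, 100)), "constant image")
})

test_that("intermeans threshold agrees with the misclassification oracle on
           well-separated Gaussian mixtures", {
  set.seed(101)
  for (rep in 1:5) {
    x <- round(c(rnorm(400, 50, 10), rnorm(400, 200, 10)))
    x <- pmin(pmax(x, 0), 255)
    thr <- optimal_threshold(x)$threshold
    # brute-force oracle: integer thresholds minimizing misclassification
    # (well-separated mixtures have a plateau of equally-good thresholds)
    truth <- rep(c(0, 1), each = 400)
    err <- vapply(0:255, function(t) sum((x > t) != truth), numeric(1))
    best <- which(err == min(err)) - 1
    expect_gte(thr, min(best) - 2)
    expect_lte(thr, max(best) + 2)
  }
})

test_that("threshold history settles monotonically after the first steps", {
  set.seed(7)
  x <- c(rnorm(500, 40, 12), rnorm(300, 180, 20))
  h <- optimal_threshold(x)$history
  if (length(h) > 2) {
    steps <- abs(diff(h))
    expect_true(all(diff(steps[-1]) <= 1e-9))
  }
  expect_true(min(x) <= h[length(h)] && h[length(h)] <= max(x))
})

test_that("partial-volume correction recovers exact tube pixels on noiseless data", {
  # free-standing bright tubes on empty background
  cfg <- phantom_config(body_pd = 0,
                        tube_T1s = exp(seq(log(300), log(800), length.out = 18)))
  sl <- simulate_series(cfg, acquisition_params(matrix = c(96, 96), n_slices = 1),
                        noise_model(sigma_base = 0, pd_jitter_cv = 0))[[1]]
  lab <- render_phantom_geometry(cfg, c(96, 96))
  contour <- roi_mask(matrix(TRUE, 96, 96))  # generous whole-frame contour
  corrected <- partial_volume_correct(sl, contour)
  expect_identical(corrected$mask, lab > 0)
})

test_that("partial-volume correction only removes pixels (monotone shrinkage)", {
  sl <- simulate_series(phantom_config(),
                        acquisition_params(matrix = c(64, 48), n_slices = 1),
                        noise_model(rng_seed = 9))[[1]]
  contour <- auto_mask(sl)
  corrected <- partial_volume_correct(sl, contour)
  expect_true(all(contour$mask[corrected$mask]))       # subset of the contour
  expect_lt(sum(corrected$mask), sum(contour$mask))    # rim actually removed
})

test_that("a mask already free of background is a fixed point of the correction", {
  cfg <- phantom_config(body_pd = 0,
                        tube_T1s = exp(seq(log(300), log(800), length.out = 18)))
  sl <- simulate_series(cfg, acquisition_params(matrix = c(96, 96), n_slices = 1),
                        noise_model(sigma_base = 0, pd_jitter_cv = 0))[[1]]
  tubes <- roi_mask(render_phantom_geometry(cfg, c(96, 96)) > 0)
  again <- partial_volume_correct(sl, tubes)
  # the two classes separated by the threshold are dim vs bright tubes, but
  # every tube pixel sits above the background threshold of the first pass;
  # shrinkage can only touch class-boundary pixels, never background ones
  expect_true(all(tubes$mask[again$mask]))
})

test_that("a blurred rim at intermediate gray is excluded from the mask", {
  img <- matrix(0, 40, 40)
  xs <- row(img) - 20.5; ys <- col(img) - 20.5
  d2 <- xs^2 + ys^2
  img[d2 <= 100] <- 1000          # disc interior
  rim <- d2 > 100 & d2 <= 144     # 1-2 px rim at partial-volume gray
  img[rim] <- 400
  sl <- image_slice(img, c(1, 1), acquisition_params())
  corrected <- partial_volume_correct(sl, roi_mask(matrix(TRUE, 40, 40)))
  expect_false(any(corrected$mask[rim]))
  expect_true(all(corrected$mask[d2 <= 100]))
})

test_that("global normalization hits its targets exactly and is idempotent", {
  set.seed(11)
  img <- matrix(rexp(64 * 64, 1 / 50), 64, 64)
  out <- normalize_global(img)
  expect_equal(mean(out), 250, tolerance = 1e-10)
  expect_equal(sd(out), 30, tolerance = 1e-10)
  expect_equal(normalize_global(out), out, tolerance = 1e-10)
  # invariance to positive affine transforms of the input
  expect_equal(normalize_global(3.7 * img + 42), out, tolerance = 1e-8)
  expect_error(normalize_global(matrix(5, 8, 8)), "zero-variance")
})
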