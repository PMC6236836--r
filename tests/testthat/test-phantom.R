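test_that("default phantom rasterizes to 18 gel tubes plus one Gd tube", {
  lab <- render_phantom_geometry(phantom_config(), c(256, 192))
  labels <- setdiff(unique(as.vector(lab)), 0L)
  expect_length(labels, 19L)
  expect_setequal(labels, 1:19)
  # geometry conservation: tubes + background partition the matrix
  expect_identical(sum(tabulate(lab + 1L, 20L)), 256L * 192L)
})

test_that("degenerate phantom with no gel tubes keeps only the Gd tube", {
  lab <- render_phantom_geometry(phantom_config(n_gel_tubes = 0), c(64, 64))
  expect_identical(setdiff(unique(as.vector(lab)), 0L), 1L)
})

test_that("rasterized disc area matches the analytic area within 5%", {
  cfg <- phantom_config()
  lab <- render_phantom_geometry(cfg, c(256, 192))
  px_area <- (240 / 256) * (190 / 192)
  analytic <- pi * 12.5^2 / px_area
  for (k in 1:18)
    expect_lt(abs(sum(lab == k) - analytic) / analytic, 0.05)
})

test_that("invalid geometries are rejected with the offending tube named", {
  expect_error(phantom_config(centers = rbind(c(0, 0), c(10, 0)),
                              n_gel_tubes = 1, body_pd = 0),
               "overlap")
  expect_error(phantom_config(centers = rbind(c(130, 0), c(0, 0)),
                              n_gel_tubes = 1, body_pd = 0),
               "field of view.*|gel1")
  expect_error(render_phantom_geometry(phantom_config(), c(16, 16)), "matrix")
})

test_that("spgr_signal matches the closed-form steady-state equation", {
  p <- acquisition_params(flip_angle = 30, TR = 5, TE = 1)
  expect_equal(spgr_signal(1000, 500, 50, p), 34.1995369988, tolerance = 1e-9)
  # saturation-free limit: TR >> T1, TE << T2* -> PD sin(alpha)
  p2 <- acquisition_params(flip_angle = 30, TR = 50000, TE = 1e-6)
  expect_equal(spgr_signal(1000, 500, 50, p2), 1000 * sin(pi / 6),
               tolerance = 1e-4)
  # vanishing flip angle drives the signal to zero (S ~ PD * alpha here)
  p3 <- acquisition_params(flip_angle = 1e-6, TR = 5, TE = 1)
  expect_lt(spgr_signal(1000, 500, 50, p3), 1e-3)
  p4 <- acquisition_params(flip_angle = 1e-8, TR = 5, TE = 1)
  expect_lt(spgr_signal(1000, 500, 50, p4),
            spgr_signal(1000, 500, 50, p3))
  # monotone in proton density
  s <- spgr_signal(c(100, 200, 400), 500, 50, p)
  expect_true(all(diff(s) > 0))
  expect_error(spgr_signal(1000, -1, 50, p), "positive")
})

test_that("zero-noise simulation is noiseless and slice-replicated", {
  sl <- simulate_series(phantom_config(),
                        acquisition_params(matrix = c(64, 64), n_slices = 3),
                        noise_model(sigma_base = 0, pd_jitter_cv = 0))
  expect_length(sl, 3)
  expect_identical(sl[[1]]$pixels, sl[[2]]$pixels)
  vals <- unique(as.vector(sl[[1]]$pixels))
  expect_lte(length(vals), 21)  # 19 tubes + body + background
})

test_that("same seed and inputs reproduce the identical series", {
  cfg <- phantom_config()
  p <- acquisition_params(matrix = c(48, 48), n_slices = 2)
  nm <- noise_model(rng_seed = 77L)
  a <- simulate_series(cfg, p, nm)
  b <- simulate_series(cfg, p, nm)
  expect_identical(a, b)
})

test_that("background noise follows the 1/sqrt(NEX) averaging law", {
  cfg <- phantom_config()
  bg <- {
    dims <- c(96, 96)
    sp <- cfg$field_of_view / dims
    xs <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * sp[1]
    ys <- (seq_len(dims[2]) - (dims[2] + 1) / 2) * sp[2]
    outer(xs^2, ys^2, "+") > (cfg$body$radius + 5)^2
  }
  sd_bg <- function(nex, seed) {
    p <- acquisition_params(matrix = c(96, 96), n_slices = 3, NEX = nex)
    sl <- simulate_series(cfg, p, noise_model(rng_seed = seed))
    sd(unlist(lapply(sl, function(s) s$pixels[bg])))
  }
  # pooled over >= 10^4 background pixels
  expect_gt(sum(bg) * 3, 1e4)
  ratios <- vapply(1:20, function(s) sd_bg(4, s) / sd_bg(1, s), numeric(1))
  expect_lt(abs(mean(ratios) - 0.5), 0.05)
  # Rician floor: magnitude background has positive mean
  p <- acquisition_params(matrix = c(96, 96), n_slices = 1)
  sl <- simulate_series(cfg, p, noise_model(rng_seed = 3))
  expect_gt(mean(sl[[1]]$pixels[bg]), 0)
})
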