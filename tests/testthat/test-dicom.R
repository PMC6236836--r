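sim_small_series <- function(nex = 1L, n_slices = 3L, seed = 5L,
                             platform = "A") {
  simulate_series(phantom_config(),
                  acquisition_params(matrix = c(48, 40), NEX = nex,
                                     platform = platform,
                                     n_slices = n_slices),
                  noise_model(rng_seed = seed))
}

test_that("DICOM write/read round-trips pixels and acquisition parameters", {
  sl <- sim_small_series(nex = 4L, platform = "B")
  d <- withr::local_tempdir()
  paths <- write_dicom_series(sl, d)
  expect_length(list.files(d), 3)
  back <- read_series(d)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_identical(back[[k]]$pixels,
                     matrix(as.integer(round(sl[[k]]$pixels)), 48, 40))
    expect_equal(back[[k]]$params$NEX, 4)
    expect_equal(back[[k]]$params$flip_angle, 30)
    expect_equal(back[[k]]$params$field_strength, 1.5)
    expect_identical(back[[k]]$params$platform, "B")
    expect_equal(back[[k]]$pixel_spacing, sl[[k]]$pixel_spacing,
                 tolerance = 1e-8)
    expect_identical(back[[k]]$instance_index, k)
  }
})

test_that("slices come back sorted by instance number regardless of file order", {
  sl <- sim_small_series(n_slices = 4L)
  d <- withr::local_tempdir()
  # write with shuffled file names so directory order differs from instances
  for (k in c(3, 1, 4, 2))
    phantomtex:::write_dicom_file(sl[[k]], file.path(d, sprintf("x%d.dcm", 5 - k)))
  back <- read_series(d)
  expect_identical(vapply(back, function(s) s$instance_index, integer(1)), 1:4)
})

test_that("reader errors on empty directories and inconsistent matrices", {
  d <- withr::local_tempdir()
  expect_error(read_series(d), "no DICOM files")
  expect_error(read_series(file.path(d, "missing")), "no such directory")
  write_dicom_series(sim_small_series(n_slices = 1L), d)
  other <- simulate_series(phantom_config(),
                           acquisition_params(matrix = c(64, 64), n_slices = 1),
                           noise_model(rng_seed = 1))
  phantomtex:::write_dicom_file(other[[1]], file.path(d, "slice_999.dcm"))
  expect_error(read_series(d), "inconsistent matrix")
})

test_that("series writing is deterministic: same inputs give identical bytes", {
  sl <- sim_small_series()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dicom_series(sl, d1)
  write_dicom_series(sl, d2)
  h1 <- unname(tools::md5sum(list.files(d1, full.names = TRUE)))
  h2 <- unname(tools::md5sum(list.files(d2, full.names = TRUE)))
  expect_identical(h1, h2)
})

test_that("written files are readable by an independent DICOM implementation", {
  sl <- sim_small_series(nex = 4L, n_slices = 1L)
  d <- withr::local_tempdir()
  path <- file.path(d, "slice_001.dcm")
  phantomtex:::write_dicom_file(sl[[1]], path)
  script <- paste(
    "import sys, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "print(int(ds.NumberOfAverages), ds.Rows, ds.Columns,",
    "      int(ds.pixel_array.sum()), ds.Manufacturer)",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(path)),
                 stdout = TRUE)
  parts <- strsplit(trimws(out[length(out)]), " +")[[1]]
  expect_identical(parts[1:3], c("4", "48", "40"))
  expect_identical(parts[4], as.character(sum(round(sl[[1]]$pixels))))
  expect_identical(paste(parts[5:6], collapse = " "), "Vendor A")
})

test_that("group_by_contrast partitions slices by acquisition level", {
  slices <- c(sim_small_series(nex = 1L, seed = 1), sim_small_series(nex = 4L, seed = 2))
  g <- group_by_contrast(slices, "NEX")
  expect_named(g, c("1", "4"))
  expect_identical(lengths(g), c(`1` = 3L, `4` = 3L))
  # partition: disjoint and exhaustive
  expect_identical(sum(lengths(g)), length(slices))
  expect_error(group_by_contrast(sim_small_series(), "flip_angle"),
               "fewer than 2 levels")
  fa <- unlist(lapply(c(2, 5, 10, 15, 20, 25, 30), function(a)
    simulate_series(phantom_config(),
                    acquisition_params(flip_angle = a, matrix = c(48, 40),
                                       n_slices = 1),
                    noise_model(rng_seed = a))), recursive = FALSE)
  expect_length(group_by_contrast(fa, "flip_angle"), 7)
})
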