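#' Phantom description for synthetic MRI series
#'
#' Describes a nonanatomic quality-assurance phantom made of cylindrical
#' gel-filled tubes plus one gadolinium (Gd-DTPA) tube, in the style of the
#' EuroSpin II TO5 T1-calibration object: 18 gel tubes of 25 mm diameter and a
#' single 20 mm Gd tube, arranged as two concentric rings around the Gd tube
#' at the centre of a 240 x 190 mm field of view.
#'
#' Relaxation times for the doped gel tubes default to a log-spaced T1 ladder
#' (500-1400 ms) so that changing the flip angle re-ranks tube intensities,
#' which is the behaviour a T1-calibration object is built for.  Proton
#' densities default to a common value; T2* to a log-spaced 30-100 ms ladder.
#' The Gd tube gets a short T1 (300 ms), as expected for 0.25 mM Gd-DTPA.
#' The tubes sit in a signal-filled container body so that the contoured
#' phantom dominates the image statistics.
#'
#' @param n_gel_tubes number of gel tubes (0-18 for the built-in ring layout).
#' @param gel_tube_diameter,gd_tube_diameter tube diameters in mm.
#' @param tube_T1s,tube_T2stars,proton_densities per-gel-tube values (ms, ms,
#'   arbitrary units); recycled/validated to length `n_gel_tubes`.
#' @param gd_T1,gd_T2star,gd_pd properties of the Gd-DTPA tube.
#' @param background_value signal value outside the phantom (arbitrary units).
#' @param field_of_view length-2 numeric, mm, matched to the first and second
#'   image dimension respectively.
#' @param centers optional (n_gel_tubes + 1) x 2 matrix of tube centres in mm
#'   relative to the FOV centre (Gd tube last); overrides the ring layout.
#' @param body_radius,body_T1,body_T2star,body_pd the container body the
#'   tubes are embedded in: a centred disc of `body_radius` mm filled with a
#'   gel of its own relaxation properties.  The body is what makes the
#'   contoured phantom dominate the image statistics, as in a real
#'   tube-in-box phantom; set `body_pd = 0` for free-standing tubes on empty
#'   background.
#' @return an object of class `phantom_config` with a `tubes` data frame
#'   (one row per tube, Gd tube last).
#' @examples
#' cfg <- phantom_config()
#' nrow(cfg$tubes)  # 19 tubes
#' @export
phantom_config <- function(n_gel_tubes = 18,
                           gel_tube_diameter = 25,
                           gd_tube_diameter = 20,
                           tube_T1s = NULL,
                           tube_T2stars = NULL,
                           proton_densities = NULL,
                           gd_T1 = 300, gd_T2star = 50, gd_pd = 20000,
                           background_value = 0,
                           field_of_view = c(240, 190),
                           centers = NULL,
                           body_radius = 86, body_T1 = 800, body_T2star = 60,
                           body_pd = 28000) {
  stopifnot(n_gel_tubes >= 0, gel_tube_diameter > 0, gd_tube_diameter > 0,
            length(field_of_view) == 2, all(field_of_view > 0),
            body_radius > 0, body_T1 > 0, body_T2star > 0, body_pd >= 0)
  n <- as.integer(n_gel_tubes)
  if (is.null(tube_T1s))
    tube_T1s <- if (n > 0) exp(seq(log(500), log(1400), length.out = max(n, 2)))[seq_len(n)] else numeric(0)
  if (is.null(tube_T2stars))
    tube_T2stars <- if (n > 0) exp(seq(log(30), log(100), length.out = max(n, 2)))[seq_len(n)] else numeric(0)
  if (is.null(proton_densities)) proton_densities <- rep(20000, n)
  stopifnot(length(tube_T1s) == n, length(tube_T2stars) == n,
            length(proton_densities) == n,
            all(tube_T1s > 0), all(tube_T2stars > 0), all(proton_densities > 0))
  if (is.null(centers)) centers <- default_tube_layout(n)
  centers <- as.matrix(centers)
  if (nrow(centers) != n + 1L || ncol(centers) != 2L)
    stop("`centers` must be a (n_gel_tubes + 1) x 2 matrix (Gd tube last)")
  tubes <- data.frame(
    tube    = c(if (n > 0) paste0("gel", seq_len(n)), "gd"),
    x       = centers[, 1],
    y       = centers[, 2],
    radius  = c(rep(gel_tube_diameter / 2, n), gd_tube_diameter / 2),
    T1      = c(tube_T1s, gd_T1),
    T2star  = c(tube_T2stars, gd_T2star),
    pd      = c(proton_densities, gd_pd),
    stringsAsFactors = FALSE
  )
  cfg <- structure(list(tubes = tubes,
                        background_value = background_value,
                        field_of_view = as.numeric(field_of_view),
                        body = list(radius = body_radius, T1 = body_T1,
                                    T2star = body_T2star, pd = body_pd)),
                   class = "phantom_config")
  validate_phantom_geometry(cfg)
  cfg
}

# Ring layout: Gd tube in the centre, up to 6 gel tubes on a 38 mm ring, up to
# 12 more on a 70 mm ring.  Spacings keep 25 mm tubes pairwise disjoint and
# inside a 240 x 190 mm FOV.
default_tube_layout <- function(n_gel) {
  if (n_gel > 18)
    stop("built-in layout supports at most 18 gel tubes; supply `centers`")
  inner <- cbind(38 * cos(2 * pi * (0:5) / 6), 38 * sin(2 * pi * (0:5) / 6))
  outer <- cbind(70 * cos(2 * pi * (0:11) / 12 + pi / 12),
                 70 * sin(2 * pi * (0:11) / 12 + pi / 12))
  cand <- rbind(outer, inner)
  rbind(cand[seq_len(n_gel), , drop = FALSE], c(0, 0))
}

validate_phantom_geometry <- function(cfg) {
  t <- cfg$tubes
  half <- cfg$field_of_view / 2
  for (k in seq_len(nrow(t))) {
    if (abs(t$x[k]) + t$radius[k] > half[1] || abs(t$y[k]) + t$radius[k] > half[2])
      stop(sprintf("tube '%s' exceeds the field of view", t$tube[k]))
    if (cfg$body$pd > 0 &&
        sqrt(t$x[k]^2 + t$y[k]^2) + t$radius[k] > cfg$body$radius)
      stop(sprintf("tube '%s' extends beyond the phantom body", t$tube[k]))
  }
  if (cfg$body$pd > 0 && (cfg$body$radius > min(half)))
    stop("phantom body exceeds the field of view")
  if (nrow(t) > 1) {
    for (a in seq_len(nrow(t) - 1)) for (b in (a + 1):nrow(t)) {
      d <- sqrt((t$x[a] - t$x[b])^2 + (t$y[a] - t$y[b])^2)
      if (d < t$radius[a] + t$radius[b])
        stop(sprintf("tubes '%s' and '%s' overlap", t$tube[a], t$tube[b]))
    }
  }
  invisible(cfg)
}

#' Acquisition parameters for a simulated or real series
#'
#' @param field_strength main field in tesla (1.5 or 3.0 in the emulated study).
#' @param platform scanner platform, `"A"` or `"B"` (emulating two vendors
#'   whose reconstruction pipelines differ).
#' @param flip_angle excitation flip angle in degrees, in (0, 90].
#' @param TR,TE repetition/echo time in ms, 0 < TE < TR.  Defaults are the
#'   midpoints of the emulated protocol's ranges (TR 4.09-5.47, TE 0.90-1.35).
#' @param NEX number of excitations (signal averages), integer >= 1.
#' @param matrix length-2 integer, image matrix (dim1 x dim2).
#' @param slice_thickness mm.
#' @param n_slices number of slices in the series.
#' @return an object of class `acquisition_params`.
#' @export
acquisition_params <- function(field_strength = 1.5, platform = "A",
                               flip_angle = 30, TR = 4.78, TE = 1.12,
                               NEX = 1, matrix = c(256, 192),
                               slice_thickness = 5, n_slices = 1) {
  platform <- match.arg(platform, c("A", "B"))
  if (!is.finite(flip_angle) || flip_angle <= 0 || flip_angle > 90)
    stop("flip_angle must lie in (0, 90] degrees")
  if (!(TE > 0 && TE < TR)) stop("need 0 < TE < TR")
  if (NEX < 1 || NEX != round(NEX)) stop("NEX must be an integer >= 1")
  if (length(matrix) != 2 || any(matrix < 32)) stop("matrix must be >= 32 x 32")
  structure(list(field_strength = field_strength, platform = platform,
                 flip_angle = flip_angle, TR = TR, TE = TE,
                 NEX = as.integer(NEX), matrix = as.integer(matrix),
                 slice_thickness = slice_thickness,
                 n_slices = as.integer(n_slices)),
            class = "acquisition_params")
}

#' Noise and platform model for the simulator
#'
#' Noise is synthesized in the complex domain: each excitation adds
#' independent Gaussian noise of SD `sigma_base` to the real channel and to
#' the imaginary channel (signal is real), and the magnitude is taken before
#' averaging the NEX excitations -- the standard Rician magnitude-image model.
#' Averaging N magnitudes scales the noise SD as 1/sqrt(N).
#'
#' Platform differences are modelled as a post-reconstruction Gaussian filter
#' (FWHM in pixels, 0 = no filtering) plus a global intensity scale, one pair
#' per platform.  Field strength 3 T multiplies the noiseless signal by
#' `field_snr_gain` relative to 1.5 T.
#'
#' `pd_jitter_cv` adds a per-slice, per-tube lognormal proton-density jitter
#' (coefficient of variation) emulating slice-to-slice structural variation in
#' a real series; set to 0 for bit-identical slice geometry.
#'
#' @param sigma_base complex-channel noise SD per excitation (image units).
#' @param field_snr_gain signal multiplier at 3 T vs 1.5 T.
#' @param noise_corr_fwhm spatial correlation length (Gaussian FWHM, pixels)
#'   of the complex noise, emulating the band limit that zero-fill
#'   interpolation imposes on reconstructed MR noise.  The noise field keeps
#'   per-pixel SD `sigma_base` but loses high-frequency content; 0 gives
#'   white noise.
#' @param platform_filter_fwhm named numeric `c(A = , B = )`, Gaussian FWHM in
#'   pixels applied after reconstruction.
#' @param platform_scale named numeric `c(A = , B = )`, intensity scale.
#' @param pd_jitter_cv lognormal CV of per-slice per-tube (and body) proton
#'   density, emulating slice-to-slice structural variation.
#' @param rng_seed integer seed controlling every random draw of a simulation.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(sigma_base = 100, field_snr_gain = 2,
                        noise_corr_fwhm = 2,
                        platform_filter_fwhm = c(A = 0, B = 1.2),
                        platform_scale = c(A = 1, B = 1.15),
                        pd_jitter_cv = 0.06, rng_seed = 1L) {
  stopifnot(sigma_base >= 0, field_snr_gain > 0, noise_corr_fwhm >= 0,
            all(platform_filter_fwhm >= 0), all(platform_scale > 0),
            pd_jitter_cv >= 0)
  structure(list(sigma_base = sigma_base, field_snr_gain = field_snr_gain,
                 noise_corr_fwhm = noise_corr_fwhm,
                 platform_filter_fwhm = platform_filter_fwhm,
                 platform_scale = platform_scale,
                 pd_jitter_cv = pd_jitter_cv,
                 rng_seed = as.integer(rng_seed)),
            class = "noise_model")
}

#' One 2-D image slice with acquisition metadata
#'
#' @param pixels numeric matrix of nonnegative pixel values.
#' @param pixel_spacing length-2 numeric, mm per pixel along dim1 / dim2.
#' @param params an [acquisition_params()] object (fields may be `NA` when
#'   read from files with missing tags).
#' @param series_id character series identifier.
#' @param instance_index integer position of the slice within its series.
#' @return an object of class `image_slice`.
#' @export
image_slice <- function(pixels, pixel_spacing, params, series_id = "series",
                        instance_index = 1L) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)),
            length(pixel_spacing) == 2, all(pixel_spacing > 0))
  structure(list(pixels = pixels, pixel_spacing = as.numeric(pixel_spacing),
                 params = params, series_id = series_id,
                 instance_index = as.integer(instance_index)),
            class = "image_slice")
}

#' Rasterize the phantom tube layout
#'
#' Produces an integer label image on the acquisition grid: 0 for background,
#' 1..n for the gel tubes and n + 1 for the Gd tube, each label a filled disc
#' of the configured diameter at the pixel spacing `field_of_view / matrix`.
#'
#' @param config a [phantom_config()].
#' @param matrix length-2 integer image matrix (>= 32 x 32).
#' @return integer matrix of tube labels.
#' @examples
#' lab <- render_phantom_geometry(phantom_config(), c(256, 192))
#' length(setdiff(unique(as.vector(lab)), 0L))  # 19 tubes
#' @export
render_phantom_geometry <- function(config, matrix = c(256, 192)) {
  stopifnot(inherits(config, "phantom_config"))
  if (length(matrix) != 2 || any(matrix < 32)) stop("matrix must be >= 32 x 32")
  validate_phantom_geometry(config)
  dims <- as.integer(matrix)
  sp <- config$field_of_view / dims
  # pixel-centre physical coordinates, FOV centred on 0
  xs <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * sp[1]
  ys <- (seq_len(dims[2]) - (dims[2] + 1) / 2) * sp[2]
  lab <- base::matrix(0L, dims[1], dims[2])
  t <- config$tubes
  for (k in seq_len(nrow(t))) {
    inside <- outer((xs - t$x[k])^2, (ys - t$y[k])^2, "+") <= t$radius[k]^2
    lab[inside] <- k
  }
  lab
}

#' Steady-state spoiled gradient-echo signal
#'
#' Closed-form SPGR signal
#' \deqn{S = PD \sin\alpha \frac{1 - e^{-TR/T1}}{1 - \cos\alpha\, e^{-TR/T1}}
#'        e^{-TE/T2^*}}
#' for repetition time TR, echo time TE and flip angle \eqn{\alpha}.
#'
#' @param proton_density proton density (arbitrary units), vectorized.
#' @param T1,T2star longitudinal / effective transverse relaxation times, ms.
#' @param params an [acquisition_params()] supplying `flip_angle`, `TR`, `TE`.
#' @return noiseless signal value(s), same length as the inputs.
#' @export
spgr_signal <- function(proton_density, T1, T2star, params) {
  if (any(T1 <= 0) || any(T2star <= 0)) stop("T1 and T2star must be positive")
  if (params$flip_angle <= 0) stop("flip_angle must be positive")
  a <- params$flip_angle * pi / 180
  e1 <- exp(-params$TR / T1)
  proton_density * sin(a) * (1 - e1) / (1 - cos(a) * e1) * exp(-params$TE / T2star)
}

#' Simulate a phantom MRI series
#'
#' Renders the phantom geometry on the acquisition matrix, computes the
#' noiseless SPGR signal per tube (times the field-strength gain at 3 T),
#' corrupts every excitation with complex Gaussian noise, averages the NEX
#' magnitude images, and applies the platform filter and intensity scale.
#' Slices share geometry; per-slice tube proton densities are jittered by
#' `noise$pd_jitter_cv` and each slice draws independent noise.  The whole
#' series is reproducible from `noise$rng_seed`.
#'
#' @param config a [phantom_config()].
#' @param params an [acquisition_params()].
#' @param noise a [noise_model()].
#' @param series_id series identifier stored in each slice.
#' @return list of [image_slice()] objects of length `params$n_slices`.
#' @export
simulate_series <- function(config, params, noise, series_id = NULL) {
  stopifnot(inherits(config, "phantom_config"),
            inherits(params, "acquisition_params"),
            inherits(noise, "noise_model"))
  if (is.null(series_id))
    series_id <- sprintf("%s_%.1fT_fa%02d_nex%d", params$platform,
                         params$field_strength, round(params$flip_angle),
                         params$NEX)
  lab <- render_phantom_geometry(config, params$matrix)
  gain <- if (params$field_strength >= 3) noise$field_snr_gain else 1
  base_sig <- spgr_signal(config$tubes$pd, config$tubes$T1, config$tubes$T2star,
                          params) * gain
  body_sig <- if (config$body$pd > 0)
    spgr_signal(config$body$pd, config$body$T1, config$body$T2star,
                params) * gain else 0
  in_body <- if (config$body$pd > 0) {
    dims <- params$matrix
    sp0 <- config$field_of_view / dims
    xs <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * sp0[1]
    ys <- (seq_len(dims[2]) - (dims[2] + 1) / 2) * sp0[2]
    outer(xs^2, ys^2, "+") <= config$body$radius^2
  } else FALSE
  fwhm <- unname(noise$platform_filter_fwhm[params$platform])
  scale <- unname(noise$platform_scale[params$platform])
  sp <- config$field_of_view / params$matrix
  n_tubes <- nrow(config$tubes)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(noise$rng_seed)

  npix <- prod(params$matrix)
  lapply(seq_len(params$n_slices), function(s) {
    jit <- if (noise$pd_jitter_cv > 0)
      exp(stats::rnorm(n_tubes + 1L, 0, noise$pd_jitter_cv)) else rep(1, n_tubes + 1L)
    sig <- c(config$background_value, base_sig * jit[seq_len(n_tubes)])[lab + 1L]
    if (config$body$pd > 0) sig[in_body & lab == 0L] <- body_sig * jit[n_tubes + 1L]
    if (noise$sigma_base > 0) {
      acc <- 0
      for (e in seq_len(params$NEX)) {
        re <- sig + correlated_noise(params$matrix, noise$sigma_base,
                                     noise$noise_corr_fwhm)
        im <- correlated_noise(params$matrix, noise$sigma_base,
                               noise$noise_corr_fwhm)
        acc <- acc + sqrt(re * re + im * im)
      }
      img <- base::matrix(acc / params$NEX, params$matrix[1], params$matrix[2])
    } else {
      img <- base::matrix(sig, params$matrix[1], params$matrix[2])
    }
    if (fwhm > 0) img <- gaussian_blur(img, fwhm / (2 * sqrt(2 * log(2))))
    image_slice(img * scale, sp, params, series_id, s)
  })
}

# Band-limited Gaussian noise field: blurred white noise rescaled to keep
# per-pixel SD `sigma` (the 1/sqrt(NEX) averaging law is unaffected).
correlated_noise <- function(dims, sigma, fwhm) {
  w <- base::matrix(stats::rnorm(prod(dims)), dims[1], dims[2])
  if (fwhm > 0) {
    sd <- fwhm / (2 * sqrt(2 * log(2)))
    r <- max(1L, ceiling(3 * sd))
    k <- stats::dnorm(-r:r, sd = sd)
    k <- k / sum(k)
    w <- apply_kernel_1d(apply_kernel_1d(w, k, 1), k, 2) / sum(k^2)
  }
  as.vector(w) * sigma
}

# Separable Gaussian blur with replicated edges; sd in pixels.
gaussian_blur <- function(img, sd) {
  r <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(-r:r, sd = sd)
  k <- k / sum(k)
  img <- apply_kernel_1d(img, k, along = 1)
  apply_kernel_1d(img, k, along = 2)
}

apply_kernel_1d <- function(img, k, along) {
  r <- (length(k) - 1L) / 2L
  n <- dim(img)[along]
  idx <- function(shift) pmin(pmax(seq_len(n) + shift, 1L), n)
  out <- 0
  for (j in seq_along(k)) {
    shift <- j - r - 1L
    out <- out + k[j] * (if (along == 1) img[idx(shift), , drop = FALSE]
                         else img[, idx(shift), drop = FALSE])
  }
  out
}
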