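#' Pipeline configuration
#'
#' Collects every tunable of the simulate-extract-compare pipeline.  In
#' `"simulate"` mode the pipeline emulates the four-contrast phantom study
#' design (see [default_study_design()]); in `"dicom_dir"` mode it reads one
#' DICOM series per subdirectory of `input_dir`.
#'
#' @param mode `"simulate"` or `"dicom_dir"`.
#' @param input_dir directory of DICOM series (mode `"dicom_dir"`).
#' @param phantom a [phantom_config()].
#' @param noise a [noise_model()] (its `rng_seed` is overridden per series
#'   from `seed`).
#' @param target_mean,target_sd grayscale normalization targets.
#' @param G gray levels for quantization-based feature families.
#' @param contrasts contrasts to analyse.
#' @param alpha q-value significance threshold.
#' @param output_dir where reports are written.
#' @param seed master seed for simulate mode; per-series seeds are derived
#'   from it.
#' @param n_scale multiplier on the per-series slice counts of the emulated
#'   design (1 = the study's group sizes; smaller values give a faster,
#'   scaled-down run with at least 3 slices per series).
#' @param matrix_t1,matrix_dce acquisition matrices for the T1W and DCE
#'   series of the emulated design.
#' @param write_dicom also write each simulated series as DICOM files.
#' @param mask_path optional PNG/JSON mask applied to every series instead
#'   of the automatic whole-phantom contour.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "dicom_dir"),
                            input_dir = NULL,
                            phantom = phantom_config(),
                            noise = noise_model(),
                            target_mean = 250, target_sd = 30,
                            G = 256,
                            contrasts = c("field_strength", "flip_angle",
                                          "NEX", "platform"),
                            alpha = 0.05,
                            output_dir = tempfile("phantomtex_run_"),
                            seed = 1L,
                            n_scale = 1,
                            matrix_t1 = c(256, 192),
                            matrix_dce = c(256, 160),
                            write_dicom = FALSE,
                            mask_path = NULL) {
  mode <- match.arg(mode)
  contrasts <- match.arg(contrasts, several.ok = TRUE)
  stopifnot(alpha > 0, alpha < 1, n_scale > 0)
  if (mode == "simulate" && is.null(seed)) stop("simulate mode requires a seed")
  structure(list(mode = mode, input_dir = input_dir, phantom = phantom,
                 noise = noise, target_mean = target_mean,
                 target_sd = target_sd, G = G, contrasts = contrasts,
                 alpha = alpha, output_dir = output_dir,
                 seed = as.integer(seed), n_scale = n_scale,
                 matrix_t1 = matrix_t1, matrix_dce = matrix_dce,
                 write_dicom = write_dicom, mask_path = mask_path),
            class = "pipeline_config")
}

#' Emulated four-contrast study design
#'
#' One row per simulated series, mirroring the phantom study's structure:
#' a magnet-strength contrast (1.5 T vs 3 T, platform A, flip 30, n = 80/61
#' slices), a flip-angle contrast (platform B, seven angles 2-30 degrees,
#' n = 36 per angle and 44 at 30 degrees), a NEX contrast (platform B DCE,
#' NEX 1 vs 4, n = 36/44) and a platform contrast (A vs B DCE, n = 83/36).
#'
#' @param n_scale multiplier on slice counts (minimum 3 per series).
#' @param matrix_t1,matrix_dce acquisition matrices.
#' @return data frame with one row per series.
#' @export
default_study_design <- function(n_scale = 1, matrix_t1 = c(256, 192),
                                 matrix_dce = c(256, 160)) {
  n <- function(x) max(3L, as.integer(round(x * n_scale)))
  rows <- list(
    list("field_strength", "fs_1.5T", 1.5, "A", 30, 1L, "t1", n(80)),
    list("field_strength", "fs_3T",   3.0, "A", 30, 1L, "t1", n(61)),
    list("NEX", "nex_1", 1.5, "B", 30, 1L, "dce", n(36)),
    list("NEX", "nex_4", 1.5, "B", 30, 4L, "dce", n(44)),
    list("platform", "plat_A", 1.5, "A", 30, 1L, "dce", n(83)),
    list("platform", "plat_B", 1.5, "B", 30, 1L, "dce", n(36)))
  for (fa in c(2, 5, 10, 15, 20, 25, 30))
    rows[[length(rows) + 1L]] <-
      list("flip_angle", paste0("fa_", fa), 1.5, "B", fa, 1L, "t1",
           n(if (fa == 30) 44 else 36))
  d <- do.call(rbind, lapply(rows, function(r)
    data.frame(contrast = r[[1]], series = r[[2]], field_strength = r[[3]],
               platform = r[[4]], flip_angle = r[[5]], NEX = r[[6]],
               protocol = r[[7]], n_slices = r[[8]],
               stringsAsFactors = FALSE)))
  d$matrix1 <- ifelse(d$protocol == "t1", matrix_t1[1], matrix_dce[1])
  d$matrix2 <- ifelse(d$protocol == "t1", matrix_t1[2], matrix_dce[2])
  d
}

#' Extract the feature panel from a list of slices
#'
#' Preprocesses each slice (partial-volume correction of the series mask,
#' global normalization) and extracts the 44 named features.  One mask per
#' series: the automatic whole-phantom contour of the series' first slice,
#' unless `mask` is supplied.
#'
#' @param slices list of [image_slice()] objects (one series).
#' @param mask optional [roi_mask()] shared by all slices.
#' @param G gray levels.
#' @param target_mean,target_sd normalization targets; quantization bins are
#'   anchored at `target_mean +/- 4 target_sd` (see [quantize()]).
#' @return data frame, one row per slice: `series_id`, `instance_index`,
#'   acquisition columns, then the feature columns.
#' @export
extract_features_table <- function(slices, mask = NULL, G = 256,
                                   target_mean = 250, target_sd = 30) {
  stopifnot(length(slices) > 0)
  if (is.null(mask)) mask <- auto_mask(slices[[1]])
  qb <- target_mean + c(-4, 4) * target_sd
  rows <- lapply(slices, function(sl) {
    pp <- preprocess_slice(sl, mask, target_mean, target_sd)
    fv <- extract_all(pp$slice, pp$mask, G, quant_bounds = qb)
    meta <- data.frame(series_id = sl$series_id,
                       instance_index = sl$instance_index,
                       field_strength = sl$params$field_strength,
                       platform = sl$params$platform,
                       flip_angle = sl$params$flip_angle,
                       NEX = sl$params$NEX,
                       stringsAsFactors = FALSE)
    cbind(meta, as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}

#' Run the full pipeline
#'
#' Simulates (or reads) every series, preprocesses and extracts features,
#' tests each requested contrast, and writes per-slice features
#' (`features.csv`), per-contrast result tables (`results_<contrast>.csv`
#' and `.md`), and a YAML run log capturing every parameter value and seed
#' so a run is reproducible from its log.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `features`, `results` (one
#'   `comparison_result` per contrast), and `paths` of the written files.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$output_dir))
    stop("cannot create output directory: ", config$output_dir)

  if (config$mode == "simulate") {
    design <- default_study_design(config$n_scale, config$matrix_t1,
                                   config$matrix_dce)
    design <- design[design$contrast %in% config$contrasts, , drop = FALSE]
    feats <- list()
    for (k in seq_len(nrow(design))) {
      row <- design[k, ]
      params <- acquisition_params(field_strength = row$field_strength,
                                   platform = row$platform,
                                   flip_angle = row$flip_angle,
                                   NEX = row$NEX,
                                   matrix = c(row$matrix1, row$matrix2),
                                   n_slices = row$n_slices)
      noise <- config$noise
      noise$rng_seed <- (config$seed + 1009L * k) %% .Machine$integer.max
      slices <- tryCatch(
        simulate_series(config$phantom, params, noise, series_id = row$series),
        error = function(e) stop("stage simulate, series ", row$series, ": ",
                                 conditionMessage(e)))
      if (config$write_dicom)
        write_dicom_series(slices, file.path(config$output_dir, "dicom",
                                             row$series))
      mask <- if (!is.null(config$mask_path))
        load_mask(config$mask_path, dim(slices[[1]]$pixels)) else NULL
      tab <- tryCatch(
        extract_features_table(slices, mask, config$G, config$target_mean,
                               config$target_sd),
        error = function(e) stop("stage extract, series ", row$series, ": ",
                                 conditionMessage(e)))
      tab$contrast <- row$contrast
      feats[[k]] <- tab
    }
    features <- do.call(rbind, feats)
  } else {
    if (is.null(config$input_dir) || !dir.exists(config$input_dir))
      stop("dicom_dir mode: input directory does not exist: ",
           config$input_dir)
    sub <- list.dirs(config$input_dir, recursive = FALSE)
    if (length(sub) == 0) sub <- config$input_dir
    feats <- lapply(sub, function(d) {
      slices <- read_series(d)
      mask <- if (!is.null(config$mask_path))
        load_mask(config$mask_path, dim(slices[[1]]$pixels)) else NULL
      extract_features_table(slices, mask, config$G, config$target_mean,
                             config$target_sd)
    })
    features <- do.call(rbind, feats)
    features$contrast <- NA_character_
  }

  features_path <- file.path(config$output_dir, "features.csv")
  utils::write.csv(features, features_path, row.names = FALSE)

  results <- list()
  paths <- c(features = features_path)
  for (ct in config$contrasts) {
    sub <- if (config$mode == "simulate")
      features[features$contrast == ct, , drop = FALSE] else features
    res <- tryCatch(run_contrast(sub, ct, alpha = config$alpha),
                    error = function(e) stop("stage compare, contrast ", ct,
                                             ": ", conditionMessage(e)))
    results[[ct]] <- res
    csv <- file.path(config$output_dir, paste0("results_", ct, ".csv"))
    md <- file.path(config$output_dir, paste0("results_", ct, ".md"))
    utils::write.csv(res, csv, row.names = FALSE)
    writeLines(render_table(res, "markdown"), md)
    paths[paste0(ct, "_csv")] <- csv
    paths[paste0(ct, "_md")] <- md
  }

  log_path <- file.path(config$output_dir, "run_log.yaml")
  write_run_log(config, log_path)
  paths["log"] <- log_path

  invisible(list(features = features, results = results, paths = paths))
}

# the run log records every tunable, including defaults the original
# protocol leaves open (gray levels, kernel family, test variant), so a run
# is auditable and reproducible from its log
write_run_log <- function(config, path) {
  log <- list(
    package = "phantomtex",
    version = as.character(utils::packageVersion("phantomtex")),
    mode = config$mode,
    seed = config$seed,
    n_scale = config$n_scale,
    matrix_t1 = config$matrix_t1,
    matrix_dce = config$matrix_dce,
    gray_levels = config$G,
    normalization = list(target_mean = config$target_mean,
                         target_sd = config$target_sd),
    contrasts = config$contrasts,
    alpha = config$alpha,
    phantom = list(n_tubes = nrow(config$phantom$tubes),
                   field_of_view = config$phantom$field_of_view,
                   T1_range = range(config$phantom$tubes$T1),
                   T2star_range = range(config$phantom$tubes$T2star)),
    noise = unclass(config$noise),
    methods = list(two_group_test = "pooled-variance Student t, two-tailed",
                   multi_group_test = "one-way ANOVA (flip-angle contrast)",
                   fdr = "Benjamini-Hochberg step-up, per-contrast family",
                   laws_kernels = "3x3 (L3, E3, S3 outer products)",
                   gradient = "3x3 Sobel magnitude",
                   glcm_directions = "0/45/90/135 degrees, distance 1, symmetric",
                   threshold = "iterative intermeans (Ridler-Calvard), tol 0.5"))
  yaml::write_yaml(log, path)
  invisible(path)
}

#' Format a contrast result table
#'
#' Renders a [run_contrast()] result as Markdown lines or CSV text, with
#' per-level `mean (SD)` columns, P and Q values, and a significance flag
#' (Q below the `alpha` used in the analysis).
#'
#' @param results a `comparison_result` data frame.
#' @param style `"markdown"` or `"csv"`.
#' @return character vector of lines.
#' @export
render_table <- function(results, style = c("markdown", "csv")) {
  style <- match.arg(style)
  stopifnot(inherits(results, "comparison_result"), nrow(results) > 0)
  lev <- attr(results, "levels")
  fmt <- function(x) formatC(x, format = "fg", digits = 4, width = 1)
  cells <- lapply(lev, function(l)
    paste0(fmt(results[[paste0("mean_", l)]]), " (",
           fmt(results[[paste0("sd_", l)]]), ")"))
  names(cells) <- lev
  pq <- data.frame(P = fmt(results$p_value), Q = fmt(results$q_value),
                   significant = ifelse(results$significant, "*", ""),
                   stringsAsFactors = FALSE)
  tab <- cbind(data.frame(feature = results$feature,
                          stringsAsFactors = FALSE),
               as.data.frame(cells, check.names = FALSE), pq)
  if (style == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(tab, con, row.names = FALSE)
    close(con)
    return(out)
  }
  hdr <- paste0("| ", paste(names(tab), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
  body <- apply(tab, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(sprintf("Contrast: %s (%s; n per level: %s)", attr(results, "contrast"),
            attr(results, "test"),
            paste(results[1, paste0("n_", lev)], collapse = "/")),
    "", hdr, sep, body)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments of [pipeline_config()], [phantom_config()] and
#' [noise_model()]; `phantom:` and `noise:` sub-maps are passed through to
#' their constructors.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
         else stop("unsupported config format: ", ext)
  if (!is.null(raw$phantom)) raw$phantom <- do.call(phantom_config, raw$phantom)
  if (!is.null(raw$noise)) {
    for (f in c("platform_filter_fwhm", "platform_scale"))
      if (!is.null(raw$noise[[f]])) raw$noise[[f]] <- unlist(raw$noise[[f]])
    raw$noise <- do.call(noise_model, raw$noise)
  }
  do.call(pipeline_config, raw)
}
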