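#' @name dicom_io
#' @title Minimal single-frame DICOM reader/writer
#' @description
#' The package ships a small, self-contained DICOM codec for the single-frame
#' MR slices it works with: the writer emits Explicit VR Little Endian files
#' with 16-bit unsigned pixel data and the acquisition tags the pipeline
#' needs (flip angle, TR, TE, number of averages, magnetic field strength,
#' manufacturer, pixel spacing, slice thickness); the reader parses both
#' Explicit and Implicit VR Little Endian.  Multi-frame objects, sequences of
#' undefined length, and compressed transfer syntaxes are out of scope.
NULL

# tag dictionary: group, element, VR, name (used for implicit VR and lookup)
.dicom_dict <- local({
  d <- rbind(
    c(0x0008L, 0x0016L, "UI", "sop_class_uid"),
    c(0x0008L, 0x0018L, "UI", "sop_instance_uid"),
    c(0x0008L, 0x0060L, "CS", "modality"),
    c(0x0008L, 0x0070L, "LO", "manufacturer"),
    c(0x0008L, 0x103EL, "LO", "series_description"),
    c(0x0018L, 0x0050L, "DS", "slice_thickness"),
    c(0x0018L, 0x0080L, "DS", "repetition_time"),
    c(0x0018L, 0x0081L, "DS", "echo_time"),
    c(0x0018L, 0x0083L, "DS", "number_of_averages"),
    c(0x0018L, 0x0087L, "DS", "magnetic_field_strength"),
    c(0x0018L, 0x1314L, "DS", "flip_angle"),
    c(0x0020L, 0x000DL, "UI", "study_uid"),
    c(0x0020L, 0x000EL, "UI", "series_uid"),
    c(0x0020L, 0x0013L, "IS", "instance_number"),
    c(0x0028L, 0x0002L, "US", "samples_per_pixel"),
    c(0x0028L, 0x0004L, "CS", "photometric"),
    c(0x0028L, 0x0010L, "US", "rows"),
    c(0x0028L, 0x0011L, "US", "columns"),
    c(0x0028L, 0x0030L, "DS", "pixel_spacing"),
    c(0x0028L, 0x0100L, "US", "bits_allocated"),
    c(0x0028L, 0x0101L, "US", "bits_stored"),
    c(0x0028L, 0x0102L, "US", "high_bit"),
    c(0x0028L, 0x0103L, "US", "pixel_representation"),
    c(0x7FE0L, 0x0010L, "OW", "pixel_data"))
  data.frame(group = as.integer(d[, 1]), element = as.integer(d[, 2]),
             vr = d[, 3], name = d[, 4], stringsAsFactors = FALSE)
})

.uid_root <- "1.2.826.0.1.3680043.9.7433"

# deterministic UID component derived from a string (so that identical
# simulation inputs produce byte-identical files)
.uid_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 7
  for (x in v) h <- (h * 131 + x) %% 999999937
  as.character(h)
}

.w_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")
.w_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4, endian = "little")

.dicom_element <- function(group, element, vr, value) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  .w_u16(con, c(group, element))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    writeChar(vr, con, eos = NULL)
    .w_u16(con, 0L)
    if (vr == "OW") {
      v <- as.integer(round(value))
      v <- pmin(pmax(v, 0L), 65535L)
      .w_u32(con, 2L * length(v))
      v[v > 32767L] <- v[v > 32767L] - 65536L  # two's complement bytes
      writeBin(v, con, size = 2, endian = "little")
    } else {  # OB raw
      v <- as.raw(value)
      if (length(v) %% 2 == 1) v <- c(v, as.raw(0))
      .w_u32(con, length(v))
      writeBin(v, con)
    }
  } else if (vr %in% c("US", "UL")) {
    writeChar(vr, con, eos = NULL)
    size <- if (vr == "US") 2L else 4L
    .w_u16(con, size * length(value))
    writeBin(as.integer(value), con, size = size, endian = "little")
  } else {  # string VRs
    s <- paste(value, collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2 == 1) b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
    writeChar(vr, con, eos = NULL)
    .w_u16(con, length(b))
    writeBin(b, con)
  }
  rawConnectionValue(con)
}

.fmt_ds <- function(x) {
  s <- formatC(x, format = "fg", digits = 10, width = 1)
  substr(s, 1, 16)
}

# Write one slice as an Explicit VR Little Endian DICOM file.
write_dicom_file <- function(slice, path) {
  p <- slice$params
  sop_uid <- paste(.uid_root, .uid_hash(slice$series_id), slice$instance_index,
                   sep = ".")
  series_uid <- paste(.uid_root, .uid_hash(slice$series_id), sep = ".")
  study_uid <- paste(.uid_root, "1", sep = ".")
  mr_class <- "1.2.840.10008.5.1.4.1.1.4"

  meta <- c(
    .dicom_element(0x0002, 0x0001, "OB", c(0x00, 0x01)),
    .dicom_element(0x0002, 0x0002, "UI", mr_class),
    .dicom_element(0x0002, 0x0003, "UI", sop_uid),
    .dicom_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    .dicom_element(0x0002, 0x0012, "UI", paste(.uid_root, "0.1", sep = ".")))
  meta <- c(.dicom_element(0x0002, 0x0000, "UL", length(meta)), meta)

  manufacturer <- if (identical(p$platform, "A")) "Vendor A" else "Vendor B"
  px <- as.vector(t(slice$pixels))  # DICOM pixel order: row by row
  body <- c(
    .dicom_element(0x0008, 0x0016, "UI", mr_class),
    .dicom_element(0x0008, 0x0018, "UI", sop_uid),
    .dicom_element(0x0008, 0x0060, "CS", "MR"),
    .dicom_element(0x0008, 0x0070, "LO", manufacturer),
    .dicom_element(0x0008, 0x103E, "LO", slice$series_id),
    .dicom_element(0x0018, 0x0050, "DS", .fmt_ds(p$slice_thickness)),
    .dicom_element(0x0018, 0x0080, "DS", .fmt_ds(p$TR)),
    .dicom_element(0x0018, 0x0081, "DS", .fmt_ds(p$TE)),
    .dicom_element(0x0018, 0x0083, "DS", .fmt_ds(p$NEX)),
    .dicom_element(0x0018, 0x0087, "DS", .fmt_ds(p$field_strength)),
    .dicom_element(0x0018, 0x1314, "DS", .fmt_ds(p$flip_angle)),
    .dicom_element(0x0020, 0x000D, "UI", study_uid),
    .dicom_element(0x0020, 0x000E, "UI", series_uid),
    .dicom_element(0x0020, 0x0013, "IS", as.character(slice$instance_index)),
    .dicom_element(0x0028, 0x0002, "US", 1L),
    .dicom_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dicom_element(0x0028, 0x0010, "US", nrow(slice$pixels)),
    .dicom_element(0x0028, 0x0011, "US", ncol(slice$pixels)),
    .dicom_element(0x0028, 0x0030, "DS",
                   paste(.fmt_ds(slice$pixel_spacing[1]),
                         .fmt_ds(slice$pixel_spacing[2]), sep = "\\")),
    .dicom_element(0x0028, 0x0100, "US", 16L),
    .dicom_element(0x0028, 0x0101, "US", 16L),
    .dicom_element(0x0028, 0x0102, "US", 15L),
    .dicom_element(0x0028, 0x0103, "US", 0L),
    .dicom_element(0x7FE0, 0x0010, "OW", px))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  writeBin(c(meta, body), con)
  invisible(path)
}

# Parse one DICOM file into a named list of tag values.
read_dicom_file <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 140) stop("not a DICOM file: ", path)
  b <- readBin(path, "raw", n = n)
  if (rawToChar(b[129:132]) != "DICM") stop("not a DICOM file (no DICM marker): ", path)
  pos <- 133L
  out <- list()
  u16 <- function(at) as.integer(b[at]) + 256L * as.integer(b[at + 1L])
  u32 <- function(at) u16(at) + 65536 * u16(at + 2L)
  known_vrs <- c("AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO","LT",
                 "OB","OF","OW","PN","SH","SL","SQ","SS","ST","TM","UI","UL",
                 "UN","US","UT")
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr_chars <- rawToChar(b[(pos + 4L):(pos + 5L)])
    explicit <- vr_chars %in% known_vrs
    if (group == 0x0002L && !explicit)
      stop("malformed file meta information in ", path)
    if (explicit) {
      vr <- vr_chars
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- u32(pos + 8L); val_at <- pos + 12L
      } else {
        len <- u16(pos + 6L); val_at <- pos + 8L
      }
    } else {
      hit <- which(.dicom_dict$group == group & .dicom_dict$element == element)
      vr <- if (length(hit)) .dicom_dict$vr[hit] else "UN"
      len <- u32(pos + 4L); val_at <- pos + 8L
    }
    if (len == 4294967295) stop("undefined-length element not supported in ", path)
    pos <- val_at + len
    hit <- which(.dicom_dict$group == group & .dicom_dict$element == element)
    if (length(hit) == 1L && len > 0L) {
      name <- .dicom_dict$name[hit]
      raw_val <- b[val_at:(val_at + len - 1L)]
      out[[name]] <- switch(.dicom_dict$vr[hit],
        US = readBin(raw_val, "integer", n = len / 2, size = 2,
                     endian = "little", signed = FALSE),
        OW = readBin(raw_val, "integer", n = len / 2, size = 2,
                     endian = "little", signed = FALSE),
        DS = as.numeric(strsplit(trimws(rawToChar(raw_val)), "\\\\")[[1]]),
        IS = as.integer(trimws(rawToChar(raw_val))),
        {
          s <- rawToChar(raw_val[raw_val != as.raw(0)])
          trimws(s)
        })
    }
  }
  out
}

#' Write an image series as DICOM files
#'
#' One Explicit VR Little Endian file per slice, named `slice_###.dcm`, with
#' pixel data rounded to 16-bit unsigned integers and acquisition metadata
#' (flip angle, TR, TE, number of averages, field strength, manufacturer,
#' pixel spacing, slice thickness) populated so that [read_series()] can
#' round-trip them.
#'
#' @param slices nonempty list of [image_slice()] objects.
#' @param directory output directory, created if needed.
#' @return character vector of file paths, invisibly.
#' @export
write_dicom_series <- function(slices, directory) {
  if (length(slices) == 0) stop("no slices to write")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  paths <- vapply(seq_along(slices), function(i) {
    path <- file.path(directory, sprintf("slice_%03d.dcm", i))
    write_dicom_file(slices[[i]], path)
    path
  }, character(1))
  invisible(paths)
}

#' Read a DICOM series from a directory
#'
#' Parses every `.dcm` (or extensionless DICOM) file in `directory`, sorts
#' slices by instance number, and populates [acquisition_params()] from the
#' standard tags.  Missing optional tags are recorded as `NA` rather than
#' fabricated.  Platform is derived from the Manufacturer tag
#' (case-insensitive: anything matching "siemens" or "vendor b" maps to
#' `"B"`, otherwise `"A"`).
#'
#' @param directory directory containing at least one DICOM file.
#' @return list of [image_slice()] objects sorted by instance number.
#' @export
read_series <- function(directory) {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no DICOM files in ", directory)
  parsed <- list()
  for (f in files) {
    ds <- tryCatch(read_dicom_file(f), error = function(e) NULL)
    if (!is.null(ds)) parsed[[length(parsed) + 1L]] <- ds
  }
  if (length(parsed) == 0) stop("no DICOM files in ", directory)
  dims <- vapply(parsed, function(d) c(d$rows, d$columns), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent matrix sizes within series in ", directory)
  slices <- lapply(parsed, function(d) {
    px <- matrix(d$pixel_data, nrow = d$rows, ncol = d$columns, byrow = TRUE)
    tagnum <- function(x) if (is.null(x)) NA_real_ else as.numeric(x[1])
    manu <- if (is.null(d$manufacturer)) NA_character_ else d$manufacturer
    platform <- if (is.na(manu)) NA_character_
                else if (grepl("siemens|vendor b", manu, ignore.case = TRUE)) "B"
                else "A"
    params <- structure(list(
      field_strength = tagnum(d$magnetic_field_strength),
      platform = platform,
      flip_angle = tagnum(d$flip_angle),
      TR = tagnum(d$repetition_time),
      TE = tagnum(d$echo_time),
      NEX = tagnum(d$number_of_averages),
      matrix = c(d$rows, d$columns),
      slice_thickness = tagnum(d$slice_thickness),
      n_slices = NA_integer_,
      manufacturer = manu), class = "acquisition_params")
    spacing <- if (is.null(d$pixel_spacing)) c(1, 1) else d$pixel_spacing
    sid <- if (!is.null(d$series_description)) d$series_description
           else if (!is.null(d$series_uid)) d$series_uid else "series"
    inst <- if (is.null(d$instance_number)) NA_integer_ else d$instance_number
    image_slice(px, spacing, params, series_id = sid,
                instance_index = if (is.na(inst)) 0L else inst)
  })
  ord <- order(vapply(slices, function(s) s$instance_index, integer(1)))
  slices <- slices[ord]
  n <- length(slices)
  slices <- lapply(slices, function(s) { s$params$n_slices <- n; s })
  slices
}

#' Group slices by an acquisition contrast
#'
#' Partitions a list of slices by the level of one acquisition parameter:
#' `field_strength`, `flip_angle`, `NEX`, or `platform`.
#'
#' @param slices list of [image_slice()] objects.
#' @param contrast one of `"field_strength"`, `"flip_angle"`, `"NEX"`,
#'   `"platform"`.
#' @return named list mapping each observed level to its slices; errors if
#'   any slice lacks the grouping tag or fewer than two levels are observed.
#' @export
group_by_contrast <- function(slices,
                              contrast = c("field_strength", "flip_angle",
                                           "NEX", "platform")) {
  contrast <- match.arg(contrast)
  vals <- vapply(slices, function(s) as.character(s$params[[contrast]]),
                 character(1))
  if (any(is.na(vals) | vals == "NA"))
    stop("slices with missing '", contrast, "' tag cannot be grouped")
  lv <- unique(vals)
  if (length(lv) < 2)
    stop("fewer than 2 levels of '", contrast, "' observed; no contrast possible")
  lv <- if (contrast == "platform") sort(lv) else lv[order(as.numeric(lv))]
  out <- lapply(lv, function(l) slices[vals == l])
  names(out) <- lv
  out
}
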