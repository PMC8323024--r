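#' Grayscale CFI container
#'
#' A chlorophyll fluorescence image is a single-channel grid of non-negative
#' intensities. Pixels are stored as a numeric matrix in raster order
#' (`[row, col]`, row 1 at the top); the up-axis is decreasing row.
#'
#' @param pixels numeric matrix of intensities.
#' @param bit_depth 8 or 16; intensities must lie in `[0, 2^bit_depth - 1]`.
#' @return An object of class `gray_image` with fields `pixels` and
#'   `bit_depth`.
#' @export
gray_image <- function(pixels, bit_depth = 8L) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    cond_error("zero-size image", "input_error")
  rng <- range(pixels)
  if (rng[1L] < 0 || rng[2L] > 2^bit_depth - 1)
    cond_error("intensities outside bit depth range", "input_error")
  structure(list(pixels = pixels, bit_depth = bit_depth), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d px, %d-bit, intensity range [%g, %g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' Read a grayscale image from PNG or TIFF
#'
#' Single-channel 8- or 16-bit images are read with their intensities
#' unmodified. RGB input is converted to luminance
#' (0.299 R + 0.587 G + 0.114 B) with a warning: the fluorescence camera is
#' monochrome, so color input only arises as a fallback.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return A [gray_image].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) cond_error(paste0("cannot read image: ", path), "input_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) cond_error(conditionMessage(e), "input_error"))
    bit <- attr(arr, "info")$bit.depth
    if (is.null(bit) || !bit %in% c(8L, 16L)) bit <- 8L
    px <- round(drop_to_gray(arr) * (2^bit - 1))
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tryCatch(tiff::readTIFF(path, info = TRUE, as.is = TRUE),
                    error = function(e) cond_error(conditionMessage(e), "input_error"))
    bit <- attr(arr, "bits.per.sample")
    if (is.null(bit) || !bit %in% c(8L, 16L)) bit <- 8L
    px <- drop_to_gray(arr)
  } else {
    cond_error(paste0("unsupported image format: .", ext), "input_error")
  }
  if (length(px) == 0L) cond_error("zero-size image", "input_error")
  px <- matrix(as.numeric(px), nrow(px), ncol(px))   # drop decoder attributes
  gray_image(px, bit_depth = as.integer(bit))
}

# Collapse a decoded array to one channel; RGB(A) -> luminance with warning.
drop_to_gray <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    if (nch == 1L) return(arr[, , 1L])
    if (nch %in% c(2L, 4L)) arr <- arr[, , -nch, drop = FALSE]  # drop alpha
    if (dim(arr)[3L] == 1L) return(arr[, , 1L])
    warning("RGB input converted to luminance; CFI cameras are monochrome")
    return(0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L])
  }
  cond_error("cannot interpret decoded image dimensions", "input_error")
}

#' Write a grayscale image
#'
#' 8-bit images may be written as PNG or TIFF; 16-bit images only as TIFF
#' (PNG encoding in R is 8-bit). Read/write/read round-trips are
#' pixel-identical.
#'
#' @param image a [gray_image].
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  ext <- tolower(tools::file_ext(path))
  scaled <- image$pixels / (2^image$bit_depth - 1)
  if (ext == "png") {
    if (image$bit_depth != 8L)
      cond_error("PNG output supports 8-bit only; use TIFF for 16-bit", "io_error")
    png::writePNG(scaled, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = image$bit_depth)
  } else {
    cond_error(paste0("unsupported image format: .", ext), "io_error")
  }
  invisible(path)
}

#' Pixel-to-centimeter calibration
#'
#' The facility's vendor calibration is replaced by a single isotropic scale:
#' lengths multiply by `cm_per_px`, areas by `cm_per_px^2`.
#'
#' @param cm_per_px positive real, centimeters per pixel.
#' @param camera_id short identifier of the camera the scale belongs to.
#' @export
calibration <- function(cm_per_px = 0.2, camera_id = "side") {
  if (!is.numeric(cm_per_px) || length(cm_per_px) != 1L || cm_per_px <= 0)
    cond_error("cm_per_px must be a positive number", "config_error")
  structure(list(cm_per_px = cm_per_px, camera_id = as.character(camera_id)),
            class = "calibration")
}

#' Pipeline configuration
#'
#' Collects the tunable knobs of the trait-extraction pipeline with their
#' defaults: `morph_radius_px` (disc radius of the opening/closing cleanup),
#' `min_component_px` (connected components smaller than this are discarded),
#' `spur_length_px` (terminal skeleton branches shorter than this are
#' trimmed), `midline_tolerance_frac` (how far, as a fraction of mask width,
#' the stem-start endpoint may sit from the mask's half-area column),
#' `median_window` (odd width of the 1-D median filter applied to the stem
#' radius profile) and `connectivity` (4 or 8, for connected components).
#'
#' @param morph_radius_px non-negative integer.
#' @param min_component_px non-negative integer.
#' @param spur_length_px non-negative integer.
#' @param midline_tolerance_frac real in `[0, 1]`.
#' @param median_window odd positive integer.
#' @param connectivity 4 or 8.
#' @param calibration a [calibration].
#' @export
pipeline_config <- function(morph_radius_px = 2L,
                            min_component_px = 64L,
                            spur_length_px = 10L,
                            midline_tolerance_frac = 0.05,
                            median_window = 11L,
                            connectivity = 8L,
                            calibration = maizecfi::calibration()) {
  chk_int <- function(x, nm, min = 0L) {
    if (!is.numeric(x) || length(x) != 1L || x < min || x != round(x))
      cond_error(sprintf("%s must be an integer >= %d", nm, min), "config_error")
    as.integer(x)
  }
  morph_radius_px <- chk_int(morph_radius_px, "morph_radius_px")
  min_component_px <- chk_int(min_component_px, "min_component_px")
  spur_length_px <- chk_int(spur_length_px, "spur_length_px")
  median_window <- chk_int(median_window, "median_window", min = 1L)
  if (median_window %% 2L == 0L)
    cond_error("median_window must be odd", "config_error")
  if (!is.numeric(midline_tolerance_frac) || midline_tolerance_frac < 0 ||
      midline_tolerance_frac > 1)
    cond_error("midline_tolerance_frac must lie in [0, 1]", "config_error")
  connectivity <- chk_int(connectivity, "connectivity", min = 4L)
  if (!connectivity %in% c(4L, 8L))
    cond_error("connectivity must be 4 or 8", "config_error")
  if (!inherits(calibration, "calibration"))
    cond_error("calibration must be built with calibration()", "config_error")
  structure(list(morph_radius_px = morph_radius_px,
                 min_component_px = min_component_px,
                 spur_length_px = spur_length_px,
                 midline_tolerance_frac = midline_tolerance_frac,
                 median_window = median_window,
                 connectivity = connectivity,
                 calibration = calibration),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys: `morph_radius_px`, `min_component_px`, `spur_length_px`,
#' `midline_tolerance_frac`, `median_window`, `connectivity`, `cm_per_px`,
#' `camera_id`. Missing keys take the [pipeline_config] defaults; unknown
#' keys and invalid values are configuration errors. An empty file yields the
#' full default configuration.
#'
#' @param path path to a YAML (or flat `key: value`) file.
#' @return A [pipeline_config].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) cond_error(paste0("no such config file: ", path), "config_error")
  vals <- tryCatch(yaml::read_yaml(path),
                   error = function(e) cond_error(paste0("malformed config: ",
                                                         conditionMessage(e)),
                                                  "config_error"))
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) cond_error("malformed config: not a key-value document", "config_error")
  known <- c("morph_radius_px", "min_component_px", "spur_length_px",
             "midline_tolerance_frac", "median_window", "connectivity",
             "cm_per_px", "camera_id")
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L)
    cond_error(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
               "config_error")
  cal_args <- vals[intersect(names(vals), c("cm_per_px", "camera_id"))]
  cal <- do.call(calibration, cal_args)
  cfg_args <- vals[setdiff(names(vals), c("cm_per_px", "camera_id"))]
  cfg_args$calibration <- cal
  do.call(pipeline_config, cfg_args)
}

# Column layout of the two trait tables.
PLANT_COLUMNS <- c("plant_id", "image_path", "height_cm", "width_cm",
                   "projected_area_cm2", "stem_height_cm",
                   "vertical_stem_height_cm", "stem_path_length_cm",
                   "stem_diameter_cm", "n_leaves", "flags")
LEAF_COLUMNS <- c("plant_id", "leaf_rank", "leaf_area_cm2", "leaf_angle_deg")

#' Write plant- and leaf-level trait tables
#'
#' Writes one CSV of whole-plant records (columns `plant_id`, `image_path`,
#' `height_cm`, `width_cm`, `projected_area_cm2`, `stem_height_cm`,
#' `vertical_stem_height_cm`, `stem_path_length_cm`, `stem_diameter_cm`,
#' `n_leaves`, `flags`) and a companion long-format CSV of per-leaf traits
#' (`plant_id`, `leaf_rank`, `leaf_area_cm2`, `leaf_angle_deg`) next to it,
#' named `<stem>_leaves.csv`. Numeric values keep full precision.
#'
#' @param records list of plant records as produced by [analyze_image], or a
#'   data frame already holding the plant-level columns.
#' @param path output CSV path for the plant-level table.
#' @return Named character vector with paths `plant` and `leaf`, invisibly.
#' @export
write_traits_csv <- function(records, path) {
  if (is.data.frame(records)) {
    plant_df <- records
    leaf_df <- attr(records, "leaf_table")
    if (is.null(leaf_df)) leaf_df <- empty_leaf_table()
  } else {
    if (!is.list(records) || length(records) == 0L)
      cond_error("records must be a non-empty list", "input_error")
    plant_df <- do.call(rbind, lapply(records, plant_record_row))
    leaf_df <- do.call(rbind, c(list(empty_leaf_table()),
                                lapply(records, leaf_record_rows)))
  }
  if (nrow(plant_df) == 0L) cond_error("no records to write", "input_error")
  leaf_path <- sub("(\\.[^.]*)?$", "_leaves\\1", path)
  if (identical(leaf_path, path)) leaf_path <- paste0(path, "_leaves")
  ok <- tryCatch({
    utils::write.csv(plant_df, path, row.names = FALSE)
    utils::write.csv(leaf_df, leaf_path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) cond_error(paste0("cannot write traits to ", path), "io_error")
  invisible(c(plant = path, leaf = leaf_path))
}

empty_leaf_table <- function() {
  data.frame(plant_id = character(), leaf_rank = integer(),
              leaf_area_cm2 = numeric(), leaf_angle_deg = numeric())
}

plant_record_row <- function(rec) {
  st <- rec$stem
  data.frame(
    plant_id = rec$plant_id,
    image_path = if (is.null(rec$image_path)) NA_character_ else rec$image_path,
    height_cm = null_na(rec$height_cm),
    width_cm = null_na(rec$width_cm),
    projected_area_cm2 = null_na(rec$projected_area_cm2),
    stem_height_cm = if (is.null(st)) NA_real_ else st$stem_height_cm,
    vertical_stem_height_cm = if (is.null(st)) NA_real_ else st$vertical_stem_height_cm,
    stem_path_length_cm = if (is.null(st)) NA_real_ else st$stem_path_length_cm,
    stem_diameter_cm = if (is.null(st)) NA_real_ else st$diameter_cm,
    n_leaves = if (is.null(rec$leafset)) NA_integer_ else rec$leafset$n_leaves,
    flags = paste(rec$flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

leaf_record_rows <- function(rec) {
  if (is.null(rec$leafset) || rec$leafset$n_leaves == 0L) return(empty_leaf_table())
  do.call(rbind, lapply(rec$leafset$leaves, function(lf) {
    data.frame(plant_id = rec$plant_id, leaf_rank = lf$rank,
               leaf_area_cm2 = lf$area_cm2, leaf_angle_deg = null_na(lf$angle_deg))
  }))
}

null_na <- function(x) if (is.null(x) || length(x) == 0L) NA_real_ else x
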