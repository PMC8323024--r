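# Plant/background segmentation. Under blue-excited fluorescence the plant is
# the only bright object in the scene, so a global histogram threshold is
# sufficient and needs no per-image tuning.

#' Otsu threshold of a grayscale image
#'
#' Returns the integer threshold `t` maximizing the between-class variance of
#' the intensity histogram, with the convention that pixels `< t` are
#' background and pixels `>= t` are foreground. Ties are broken toward the
#' smallest maximizing `t`.
#'
#' @param image a [gray_image].
#' @return Integer threshold in `[1, 2^bit_depth - 1]`.
#' @export
otsu_threshold <- function(image) {
  stopifnot(inherits(image, "gray_image"))
  px <- as.integer(round(image$pixels))
  L <- 2L^image$bit_depth
  h <- tabulate(px + 1L, nbins = L)          # h[i] = count of intensity i-1
  if (sum(h > 0L) < 2L)
    cond_error("constant image: histogram is degenerate", "degenerate_histogram")
  vals <- 0:(L - 1L)
  n <- sum(h)
  w0 <- cumsum(h)                            # pixels with intensity <= t-1
  s0 <- cumsum(as.numeric(vals) * h)
  total_sum <- s0[L]
  # candidate thresholds t = 1..L-1; background class = intensities < t
  w0t <- w0[1:(L - 1L)]
  s0t <- s0[1:(L - 1L)]
  valid <- w0t > 0L & w0t < n
  # between-class variance up to the constant factor 1/n^2
  num <- (total_sum * w0t - s0t * n)^2
  den <- as.numeric(w0t) * (n - as.numeric(w0t))
  vb <- ifelse(valid, num / den, -Inf)
  # smallest t attaining the maximum; exact ties (symmetric histograms) are
  # recognized through a hair's-breadth relative window so floating-point
  # noise cannot promote a larger t
  min(which(vb >= max(vb) * (1 - 1e-9)))
}

#' Binarize an image at a threshold
#'
#' @param image a [gray_image].
#' @param threshold integer; pixels `>= threshold` become foreground.
#' @return Logical mask matrix of the same shape.
#' @export
binarize <- function(image, threshold) {
  stopifnot(inherits(image, "gray_image"))
  if (threshold < 0 || threshold > 2^image$bit_depth - 1)
    cond_error("threshold outside intensity range", "input_error")
  image$pixels >= threshold
}

#' Clean a binary plant mask
#'
#' Applies morphological opening then closing with a disc of radius
#' `morph_radius_px`, removes connected components smaller than
#' `min_component_px`, and keeps only the largest remaining component (one
#' plant per image). The result is a single connected component.
#'
#' @param mask logical matrix.
#' @param config a [pipeline_config].
#' @return Logical mask with exactly one connected component.
#' @export
clean_mask <- function(mask, config = pipeline_config()) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) cond_error("no plant detected", "no_plant")
  m <- open_close(mask, config$morph_radius_px)
  lab <- label_components(m, config$connectivity)
  if (max(lab) == 0L) cond_error("no plant detected", "no_plant")
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= config$min_component_px)
  if (length(keep) == 0L) cond_error("no plant detected", "no_plant")
  biggest <- keep[which.max(sizes[keep])]
  lab == biggest
}

#' Segment a plant from a CFI in one call
#'
#' Convenience wrapper: Otsu threshold, binarize, clean.
#'
#' @inheritParams clean_mask
#' @param image a [gray_image].
#' @return List with `mask` (logical matrix) and `threshold` (integer).
#' @export
segment_plant <- function(image, config = pipeline_config()) {
  t <- otsu_threshold(image)
  list(mask = clean_mask(binarize(image, t), config), threshold = t)
}

#' Write a binary mask as a PNG (0/255) for visual inspection
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}
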