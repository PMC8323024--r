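# Whole-plant traits from the mask, plus the top-view orientation used by
# the imaging booth to rotate each plant so its broadest side faces the
# side-view cameras.

#' Whole-plant height, width and side-projected area
#'
#' Height and width are the inclusive extents of the mask's bounding box
#' (`max - min + 1` pixels) scaled by `cm_per_px`; the side-projected area is
#' the foreground pixel count scaled by `cm_per_px^2`.
#'
#' @param mask logical plant mask.
#' @param cal a [calibration].
#' @return Named list: `height_cm`, `width_cm`, `projected_area_cm2`.
#' @export
whole_plant_traits <- function(mask, cal) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0L) cond_error("empty mask", "input_error")
  list(
    height_cm = (max(pts[, 1L]) - min(pts[, 1L]) + 1L) * cal$cm_per_px,
    width_cm = (max(pts[, 2L]) - min(pts[, 2L]) + 1L) * cal$cm_per_px,
    projected_area_cm2 = nrow(pts) * cal$cm_per_px^2
  )
}

#' Top-view plant orientation
#'
#' Angle, in `[0, 180)` degrees from the horizontal x-axis, of the longest
#' axis of the plant's convex hull in a top-view mask — the farthest pair of
#' foreground pixels (always realized on hull vertices; the hull is only a
#' speed-up). Ties between equally long axes resolve to the smaller angle. A
#' single-pixel mask returns 0 with a flag; two pixels return their
#' orientation.
#'
#' @param top_mask logical top-view mask.
#' @return List: `angle_deg` in `[0, 180)`, `flags` (character).
#' @export
top_view_orientation <- function(top_mask) {
  pts <- which(top_mask, arr.ind = TRUE)
  if (nrow(pts) == 0L) cond_error("empty top-view mask", "input_error")
  if (nrow(pts) == 1L) return(list(angle_deg = 0, flags = "single_pixel"))
  hull <- tryCatch({
    hi <- grDevices::chull(pts[, 2L], -pts[, 1L])
    pts[hi, , drop = FALSE]
  }, error = function(e) pts)
  if (nrow(hull) < 2L) hull <- pts
  ang <- farthest_pair_angle(hull)
  list(angle_deg = ang, flags = character())
}

# Angle of the farthest pair among `pts` ((row, col) rows); exact integer
# squared distances so ties are detected exactly; smallest angle wins ties.
farthest_pair_angle <- function(pts) {
  n <- nrow(pts)
  d2 <- (outer(pts[, 1L], pts[, 1L], "-"))^2 + (outer(pts[, 2L], pts[, 2L], "-"))^2
  mx <- max(d2)
  hit <- which(d2 == mx & upper.tri(d2), arr.ind = TRUE)
  angs <- vapply(seq_len(nrow(hit)), function(i) {
    a <- pts[hit[i, 1L], ]; b <- pts[hit[i, 2L], ]
    dy <- -(b[1L] - a[1L])          # up-positive
    dx <- b[2L] - a[2L]
    th <- atan2(dy, dx) * 180 / pi
    th <- th %% 180
    if (th > 180 - 1e-9) th <- 0
    th
  }, numeric(1L))
  min(angs)
}

#' Mirror an image left-right
#'
#' The facility images each plant at its estimated orientation and again
#' rotated 180 degrees, which for a symmetric plant is close to a left-right
#' mirror; the trait pipeline is expected to be invariant under this flip.
#'
#' @param image a [gray_image] (a bare matrix is also accepted and returned
#'   as a matrix).
#' @return The mirrored image.
#' @export
mirror_image <- function(image) {
  if (inherits(image, "gray_image")) {
    image$pixels <- image$pixels[, rev(seq_len(ncol(image$pixels))), drop = FALSE]
    return(image)
  }
  stopifnot(is.matrix(image))
  image[, rev(seq_len(ncol(image))), drop = FALSE]
}
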