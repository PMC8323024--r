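# Stem segmentation. The stem runs from the stem start (bottom skeleton
# endpoint on the mask midline) to the top node (branch point bearing the
# youngest fully expanded leaf). The top node is taken as the branch point
# nearest the skeleton's centre of mass; the stem path is the geodesic
# shortest path between the two on the skeleton; the stem radius comes from
# the Euclidean distance transform of the plant mask sampled along that path.

#' Locate the top node
#'
#' The branch point closest (Euclidean) to the skeleton's centre of mass.
#' Ties are broken toward the smaller row, then smaller column.
#'
#' @param poi a `points_of_interest` from [find_landmarks].
#' @return Length-2 integer vector `(row, col)`.
#' @export
find_top_node <- function(poi) {
  stopifnot(inherits(poi, "points_of_interest"))
  bp <- poi$branch_points
  if (nrow(bp) == 0L)
    cond_error("no branch points: plant has no fully expanded leaf", "no_top_node")
  d2 <- (bp[, 1L] - poi$center_of_mass[1L])^2 + (bp[, 2L] - poi$center_of_mass[2L])^2
  unname(bp[order(d2, bp[, 1L], bp[, 2L])[1L], ])
}

#' Geodesic distance along a skeleton
#'
#' For every skeleton pixel, the minimal number of 8-connected steps along
#' skeleton pixels from `source` (unit cost per step). Non-skeleton pixels
#' are `NA`; skeleton pixels in another component are `Inf`.
#'
#' @param skel logical skeleton matrix.
#' @param source length-2 `(row, col)` on the skeleton.
#' @return Numeric matrix of distances, same shape as `skel`.
#' @export
geodesic_distance <- function(skel, source) {
  stopifnot(is.matrix(skel), is.logical(skel))
  source <- as.integer(source)
  if (!skel[source[1L], source[2L]])
    cond_error("source pixel is not on the skeleton", "input_error")
  adj <- skeleton_adjacency(skel)
  dist_id <- rep(Inf, nrow(adj$coords))
  src_id <- adj$id[source[1L], source[2L]]
  dist_id[src_id] <- 0
  frontier <- src_id
  step <- 0
  while (length(frontier) > 0L) {
    step <- step + 1
    nb <- adj$nbr[frontier, , drop = FALSE]
    nb <- unique(nb[!is.na(nb)])
    frontier <- nb[is.infinite(dist_id[nb])]
    dist_id[frontier] <- step
  }
  out <- matrix(NA_real_, nrow(skel), ncol(skel))
  out[adj$coords] <- dist_id
  out
}

# Pixel-graph adjacency of a skeleton: coords (n x 2), id lookup matrix, and
# an n x 8 matrix of neighbour ids (NA where absent).
skeleton_adjacency <- function(skel) {
  coords <- which(skel, arr.ind = TRUE)
  id <- matrix(NA_integer_, nrow(skel), ncol(skel))
  id[coords] <- seq_len(nrow(coords))
  nbr <- matrix(NA_integer_, nrow(coords), 8L)
  nr <- nrow(skel); nc <- ncol(skel)
  for (k in seq_len(nrow(NEIGHBOR_OFFSETS))) {
    rr <- coords[, 1L] + NEIGHBOR_OFFSETS[k, 1L]
    cc <- coords[, 2L] + NEIGHBOR_OFFSETS[k, 2L]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    nbr[ok, k] <- id[cbind(rr[ok], cc[ok])]
  }
  list(coords = coords, id = id, nbr = nbr)
}

#' Extract the stem path between stem start and top node
#'
#' The summed field `d(., start) + d(., top)` of the two geodesic distance
#' maps attains its regional minimum exactly on the shortest start-to-top
#' paths; this function returns one such path, ordered from `start` to `top`,
#' reconstructed by stepping down the distance-from-start field (neighbours
#' scanned in fixed row-major order, so the result is deterministic).
#'
#' @param skel logical skeleton matrix.
#' @param start length-2 `(row, col)`, the stem start.
#' @param top length-2 `(row, col)`, the top node.
#' @return n x 2 integer matrix of path pixels; `path[1, ] == start`,
#'   `path[n, ] == top`.
#' @export
stem_path <- function(skel, start, top) {
  start <- as.integer(start); top <- as.integer(top)
  d1 <- geodesic_distance(skel, start)
  dt <- d1[top[1L], top[2L]]
  if (!is.finite(dt))
    cond_error("top node is unreachable from the stem start", "unreachable")
  path <- matrix(0L, dt + 1L, 2L)
  path[dt + 1L, ] <- top
  cur <- top
  for (d in rev(seq_len(dt))) {       # fill positions d, d-1, ..., 1
    found <- FALSE
    for (k in seq_len(nrow(NEIGHBOR_OFFSETS))) {
      rr <- cur[1L] + NEIGHBOR_OFFSETS[k, 1L]
      cc <- cur[2L] + NEIGHBOR_OFFSETS[k, 2L]
      if (rr < 1L || cc < 1L || rr > nrow(skel) || cc > ncol(skel)) next
      v <- d1[rr, cc]
      if (!is.na(v) && is.finite(v) && v == d - 1L) {
        cur <- c(rr, cc); path[d, ] <- cur; found <- TRUE; break
      }
    }
    if (!found) cond_error("broken distance field", "internal_error")
  }
  colnames(path) <- c("row", "col")
  path
}

#' Estimate the stem radius along the path
#'
#' The Euclidean distance transform of the plant mask (distance of each
#' foreground pixel to the nearest background pixel) is sampled along the
#' stem path, giving a per-pixel radius profile. Because the transform
#' measures pixel-centre to pixel-centre, it overshoots the geometric
#' half-width by half a pixel (the centre of a 7-px-wide bar is 4 px from
#' the first background centre but 3.5 px from the boundary), so 0.5 px is
#' subtracted from each sample. The profile is smoothed with a running
#' median of width `median_window`; the representative radius is the median
#' of the smoothed profile. If the path is shorter than the window, the
#' unfiltered median is used and the result is flagged.
#'
#' @param mask logical plant mask.
#' @param path n x 2 stem path from [stem_path].
#' @param config a [pipeline_config].
#' @return List: `radius_px` (scalar), `profile` (filtered per-pixel radii),
#'   `flags` (character).
#' @export
stem_radius <- function(mask, path, config = pipeline_config()) {
  dt <- dist_transform(mask)
  raw <- pmax(0.5, dt[path] - 0.5)
  flags <- character()
  if (length(raw) >= config$median_window) {
    prof <- stats::runmed(raw, config$median_window, endrule = "median")
  } else {
    prof <- raw
    flags <- "unfiltered_radius"
  }
  list(radius_px = stats::median(prof), profile = as.numeric(prof), flags = flags)
}

#' Build the stem mask
#'
#' Foreground pixels searched along both sides of the stem path out to the
#' stem radius, restricted to the components that touch the path (so the
#' stem mask is connected and a subset of the plant mask). `radius_px` may
#' be a single representative radius, or the per-path-pixel filtered radius
#' profile, in which case the local radius is applied at each path pixel —
#' this follows the taper of a real stalk instead of cutting a constant
#' band.
#'
#' @param mask logical plant mask.
#' @param path n x 2 stem path.
#' @param radius_px positive real, scalar or one value per path pixel.
#' @return Logical stem mask.
#' @export
build_stem_mask <- function(mask, path, radius_px) {
  stopifnot(all(radius_px > 0))
  sm <- matrix(FALSE, nrow(mask), ncol(mask))
  if (length(radius_px) == 1L) {
    pm <- sm; pm[path] <- TRUE
    sm <- dist_to_set(pm) <= radius_px | pm
  } else {
    stopifnot(length(radius_px) == nrow(path))
    nr <- nrow(sm); nc <- ncol(sm)
    for (v in sort(unique(radius_px))) {
      sel <- which(radius_px == v)
      offs <- disc_offsets(ceiling(v))
      offs <- offs[offs[, 1L]^2 + offs[, 2L]^2 <= v^2 + 1e-9, , drop = FALSE]
      rr <- rep(path[sel, 1L], each = nrow(offs)) + offs[, 1L]
      cc <- rep(path[sel, 2L], each = nrow(offs)) + offs[, 2L]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      sm[cbind(rr[ok], cc[ok])] <- TRUE
    }
  }
  sm <- mask & sm
  lab <- label_components(sm, 8L)
  keep <- unique(lab[path])
  keep <- keep[keep > 0L]
  sm & matrix(lab %in% keep, nrow(lab), ncol(lab))
}

#' Stem height from the path extremities
#'
#' Straight-line (Euclidean) distance between the stem start and the top
#' node, scaled to centimeters. The vertical drop and the arc length of the
#' path are exported alongside by [extract_stem], since it is ambiguous
#' whether a ruler measurement corresponds to the chord or the vertical.
#'
#' @param path n x 2 stem path.
#' @param cal a [calibration].
#' @return Stem height in cm.
#' @export
stem_height <- function(path, cal) {
  stopifnot(nrow(path) >= 1L)
  a <- path[1L, ]; b <- path[nrow(path), ]
  sqrt(sum((as.numeric(a) - as.numeric(b))^2)) * cal$cm_per_px
}

#' Full stem extraction
#'
#' Runs [find_top_node], [stem_path], [stem_radius], [build_stem_mask] and
#' [stem_height] and assembles the stem traits.
#'
#' @param skel trimmed skeleton.
#' @param mask plant mask.
#' @param poi landmarks from [find_landmarks].
#' @param config a [pipeline_config].
#' @return List of class `stem_traits`: `path`, `top_node`, `stem_height_cm`,
#'   `vertical_stem_height_cm`, `stem_path_length_cm`, `radius_px`,
#'   `diameter_cm`, `stem_mask`, `flags`.
#' @export
extract_stem <- function(skel, mask, poi, config = pipeline_config()) {
  top <- find_top_node(poi)
  path <- stem_path(skel, poi$stem_start, top)
  rad <- stem_radius(mask, path, config)
  cmpp <- config$calibration$cm_per_px
  steps <- diff(path)
  arc <- if (nrow(path) > 1L) sum(sqrt(rowSums(steps^2))) * cmpp else 0
  structure(list(
    path = path,
    top_node = top,
    stem_height_cm = stem_height(path, config$calibration),
    vertical_stem_height_cm = abs(path[1L, 1L] - path[nrow(path), 1L]) * cmpp,
    stem_path_length_cm = arc,
    radius_px = rad$radius_px,
    radius_profile = rad$profile,
    diameter_cm = 2 * rad$radius_px * cmpp,
    stem_mask = build_stem_mask(mask, path, rad$profile),
    flags = rad$flags
  ), class = "stem_traits")
}
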