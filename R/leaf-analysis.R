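# Leaf labeling and per-leaf traits. After the stem mask is subtracted from
# the plant mask, the remaining connected components are leaf blobs plus the
# whorl (the cluster of unexpanded leaves at the top of a vegetative corn
# plant). The whorl is removed as the highest-centre-of-mass blob; the rest
# are ranked bottom-up and measured.

#' Separate leaf blobs from the plant mask
#'
#' Connected components of `plant_mask \ stem_mask`. Components smaller than
#' `min_component_px` are discarded but counted, so exact pixel accounting
#' (`|plant| = |stem| + sum(blobs) + discarded`) remains possible.
#'
#' @param plant_mask logical plant mask.
#' @param stem_mask logical stem mask, subset of `plant_mask`.
#' @param config a [pipeline_config].
#' @return List: `blobs` (list of logical matrices), `n_discarded`,
#'   `discarded_px`.
#' @export
separate_leaves <- function(plant_mask, stem_mask, config = pipeline_config()) {
  diffm <- plant_mask & !stem_mask
  if (!any(diffm)) cond_error("no leaves after stem subtraction", "no_leaves")
  lab <- label_components(diffm, config$connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= config$min_component_px)
  blobs <- lapply(keep, function(l) lab == l)
  if (length(blobs) == 0L) cond_error("no leaves after stem subtraction", "no_leaves")
  small <- setdiff(seq_along(sizes), keep)
  list(blobs = blobs,
       n_discarded = length(small),
       discarded_px = sum(sizes[small]))
}

#' Remove the whorl blob
#'
#' The whorl is the labeled blob with the highest centre of mass (smallest
#' mean row). With a single blob, that blob is the whorl and there are zero
#' expanded leaves.
#'
#' @param blobs list of logical blob masks.
#' @return List: `whorl` (logical mask) and `leaves` (remaining blobs).
#' @export
remove_whorl <- function(blobs) {
  stopifnot(length(blobs) >= 1L)
  coms <- t(vapply(blobs, mask_com, numeric(2L)))
  wi <- order(coms[, 1L], coms[, 2L])[1L]
  list(whorl = blobs[[wi]], leaves = blobs[-wi])
}

#' Rank leaf blobs bottom-up
#'
#' Blob with the lowest centre of mass (largest mean row) is leaf 1, the next
#' lowest leaf 2, and so on, so the youngest expanded leaf always carries the
#' highest rank. Ties are broken toward the smaller mean column.
#'
#' @param blobs list of logical blob masks (whorl already removed).
#' @return List of `leaf_traits` stubs: `rank`, `blob_mask`,
#'   `center_of_mass`; areas and angles are filled by [leaf_area] and
#'   [leaf_angle].
#' @export
rank_leaves <- function(blobs) {
  stopifnot(length(blobs) >= 1L)
  coms <- t(vapply(blobs, mask_com, numeric(2L)))
  ord <- order(-coms[, 1L], coms[, 2L])
  lapply(seq_along(ord), function(i) {
    structure(list(rank = i, blob_mask = blobs[[ord[i]]],
                   center_of_mass = unname(coms[ord[i], ])),
              class = "leaf_traits")
  })
}

#' Side-projected leaf area
#'
#' @param leaf a `leaf_traits` (or bare logical mask).
#' @param cal a [calibration].
#' @return Area in cm^2 (pixel count times `cm_per_px^2`).
#' @export
leaf_area <- function(leaf, cal) {
  m <- if (inherits(leaf, "leaf_traits")) leaf$blob_mask else leaf
  stopifnot(any(m))
  sum(m) * cal$cm_per_px^2
}

#' Leaf-tip-to-stem angle
#'
#' The leaf's two extremity points are its tip (the skeleton leaf-tip
#' landmark falling inside the blob) and its attachment (the stem-path pixel
#' nearest the blob). The angle is measured at the attachment between the
#' vector to the tip and the stem's local upward direction — a least-squares
#' line fit over a `direction_window`-pixel stretch of the path centred at
#' the attachment, oriented toward the top node. Upright leaves give small
#' angles; drooping leaves exceed 90 degrees. Blobs containing zero or
#' several tips (merged, occluded leaves) get `NA` with an
#' `occluded_merged_leaf` flag instead of a wrong number.
#'
#' @param leaf a `leaf_traits` or logical blob mask.
#' @param tips n x 2 matrix of leaf-tip coordinates from [find_landmarks].
#' @param path stem path from [stem_path].
#' @param direction_window odd integer, pixels of path used for the local
#'   stem direction fit.
#' @return List: `angle_deg` (in `[0, 180]` or `NA`), `tip`, `attachment`,
#'   `flags`.
#' @export
leaf_angle <- function(leaf, tips, path, direction_window = 15L) {
  blob <- if (inherits(leaf, "leaf_traits")) leaf$blob_mask else leaf
  if (is.null(dim(tips))) tips <- matrix(tips, ncol = 2L)
  inside <- if (nrow(tips) == 0L) logical(0L) else blob[tips]
  n_tips <- sum(inside)
  if (n_tips != 1L) {
    return(list(angle_deg = NA_real_, tip = NULL, attachment = NULL,
                flags = "occluded_merged_leaf", n_tips = n_tips))
  }
  tip <- tips[which(inside)[1L], ]
  # attachment: the point of the stem path nearest the blob's collar. A hard
  # argmin over path pixels hops along the stem when the blob boundary moves
  # by a single pixel (e.g. under mirroring), so the collar is located as
  # the fat set of blob pixels within 2.5 px of the blob's closest approach
  # to the path, and the vertex is the path location at the collar's mean
  # height — sub-pixel and stable.
  pm <- matrix(FALSE, nrow(blob), ncol(blob))
  pm[path] <- TRUE
  dpath <- dist_to_set(pm)
  shell_lim <- min(dpath[blob]) + 2.5
  shell <- blob & dpath <= shell_lim
  cen <- mask_com(shell)
  d2 <- (path[, 1L] - cen[1L])^2 + (path[, 2L] - cen[2L])^2
  ai <- which.min(d2)
  attach <- c(cen[1L], path[ai, 2L])
  up <- local_stem_direction(path, ai, direction_window)
  v <- c(tip[1L] - attach[1L], tip[2L] - attach[2L])
  if (all(v == 0)) {
    return(list(angle_deg = NA_real_, tip = tip, attachment = attach,
                flags = "degenerate_leaf_vector", n_tips = 1L))
  }
  cosang <- sum(up * v) / sqrt(sum(up^2) * sum(v^2))
  list(angle_deg = acos(max(-1, min(1, cosang))) * 180 / pi,
       tip = unname(tip), attachment = unname(attach),
       flags = character(), n_tips = 1L)
}

# Unit (row, col) direction of the stem at path index `i`, pointing toward
# the top node (increasing path index). Principal-axis fit over a window
# around `i` that excludes the few pixels nearest the attachment itself —
# right at a collar the merging leaf displaces the skeleton by a pixel or
# two and those pixels would tilt the fitted axis toward the leaf. Near the
# path top the whole window shifts down for the same reason.
local_stem_direction <- function(path, i, window = 15L) {
  n <- nrow(path)
  if (n == 1L) return(c(-1, 0))       # degenerate path: straight up
  half <- (window - 1L) %/% 2L
  if (i > n - 8L && n > window + 10L) {
    idx <- (n - window - 6L):(n - 6L)
  } else {
    idx <- max(1L, i - half - 3L):min(n, i + half + 3L)
    idx <- idx[abs(idx - i) > 3L]
    if (length(idx) < 4L) idx <- max(1L, i - half):min(n, i + half)
  }
  pts <- path[idx, , drop = FALSE]
  ctr <- colMeans(pts)
  cc <- crossprod(sweep(pts, 2L, ctr))
  u <- eigen(cc, symmetric = TRUE)$vectors[, 1L]
  along <- as.numeric(path[max(idx), ] - path[min(idx), ])
  if (sum(u * along) < 0) u <- -u
  u / sqrt(sum(u^2))
}

#' Measure all leaves of a plant
#'
#' Separates, de-whorls, ranks and measures the leaf blobs.
#'
#' @param plant_mask logical plant mask.
#' @param stem stem traits from [extract_stem].
#' @param poi landmarks from [find_landmarks].
#' @param config a [pipeline_config].
#' @return List of class `leaf_set`: `leaves` (list of `leaf_traits` with
#'   `rank`, `blob_mask`, `area_cm2`, `tip`, `attachment`, `angle_deg`,
#'   `flags`), `whorl_mask`, `n_leaves`, `n_discarded`, `discarded_px`.
#' @export
extract_leaves <- function(plant_mask, stem, poi, config = pipeline_config()) {
  sep <- separate_leaves(plant_mask, stem$stem_mask, config)
  rw <- remove_whorl(sep$blobs)
  leaves <- list()
  if (length(rw$leaves) > 0L) {
    leaves <- rank_leaves(rw$leaves)
    leaves <- lapply(leaves, function(lf) {
      lf$area_cm2 <- leaf_area(lf, config$calibration)
      ang <- leaf_angle(lf, poi$leaf_tips, stem$path)
      lf$angle_deg <- ang$angle_deg
      lf$tip <- ang$tip
      lf$attachment <- ang$attachment
      lf$n_tips <- ang$n_tips
      lf$flags <- ang$flags
      lf
    })
  }
  structure(list(leaves = leaves, whorl_mask = rw$whorl,
                 n_leaves = length(leaves),
                 n_discarded = sep$n_discarded,
                 discarded_px = sep$discarded_px),
            class = "leaf_set")
}
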