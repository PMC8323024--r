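# Procedural rendering of fluorescence-like corn plant images with exact
# per-organ ground truth. A plant is a near-vertical tapered stem, a set of
# curved leaves leaving the stem at prescribed tip angles, and an apical
# whorl of short upright blades above the top node. The organ label image
# (0 = background, 1 = stem, 2.. = leaves bottom-up, 255 = whorl) is the
# ground truth; all stated areas and angles are measured on it, not taken
# from the closed-form spec, so recovery tests measure algorithm error
# rather than rendering error.

WHORL_LABEL <- 255L

#' Specification of a synthetic corn plant
#'
#' @param image_h_px,image_w_px canvas size in pixels.
#' @param cm_per_px isotropic calibration scale.
#' @param stem_base_row,stem_col base of the stem (image bottom is the large
#'   row).
#' @param stem_height_px stem length in pixels, base to apex. In vegetative
#'   maize the visible stem ends at the collar of the youngest expanded
#'   leaf, so the apex is the top node; everything above it is whorl.
#' @param stem_base_width_px,stem_top_width_px linear taper of the stem.
#' @param leaves data frame with one row per expanded leaf, columns
#'   `attach_frac` (strictly increasing heights along the stem, in (0, 1]),
#'   `length_px`, `max_width_px`, `tip_angle_deg` (angle of the
#'   attachment-to-tip chord from the upward stem direction), `side` (+1
#'   right, -1 left), `curvature` (perpendicular bow of the blade as a
#'   fraction of its chord).
#' @param whorl_n_blades,whorl_blade_length_px,whorl_blade_width_px,whorl_spread_deg
#'   apical whorl geometry; blades fan out above the stem apex.
#' @param fg_mean,fg_sd,bg_mean,bg_sd intensity model (defaults emulate the
#'   high-contrast CFI regime: bright plant, nearly black background). The
#'   contrast guarantee `fg_mean - bg_mean >= 5 max(fg_sd, bg_sd)` must hold.
#' @param blur_sigma optional Gaussian blur of the rendered intensities.
#' @param bit_depth 8 or 16.
#' @param smooth_radius_px disc radius of the morphological open-close
#'   regularization applied to the rendered silhouette, so organ outlines are
#'   smooth at the pixel scale like real blades rather than aliased strokes.
#' @param seed RNG seed; rendering is deterministic per seed.
#' @return Object of class `synthetic_plant_spec`.
#' @export
synthetic_plant_spec <- function(image_h_px = 430L, image_w_px = 640L,
                                 cm_per_px = 0.2,
                                 stem_base_row = image_h_px - 14L,
                                 stem_col = image_w_px %/% 2L,
                                 stem_height_px = 160L,
                                 stem_base_width_px = 10,
                                 stem_top_width_px = 6,
                                 leaves = default_leaf_table(stem_height_px),
                                 whorl_n_blades = 4L,
                                 whorl_blade_length_px = 0.5 * stem_height_px,
                                 whorl_blade_width_px = 8,
                                 whorl_spread_deg = 35,
                                 sheath_length_px = round(0.1 * stem_height_px),
                                 fg_mean = 200, fg_sd = 8,
                                 bg_mean = 20, bg_sd = 5,
                                 blur_sigma = 0,
                                 bit_depth = 8L,
                                 smooth_radius_px = 2L,
                                 seed = 1L) {
  stopifnot(is.data.frame(leaves))
  need <- c("attach_frac", "length_px", "max_width_px", "tip_angle_deg",
            "side", "curvature")
  if (!all(need %in% names(leaves)))
    cond_error(paste("leaves table needs columns:", paste(need, collapse = ", ")),
               "spec_error")
  if (nrow(leaves) > 0L) {
    if (any(diff(leaves$attach_frac) <= 0))
      cond_error("leaf attachments must be strictly increasing along the stem",
                 "spec_error")
    if (any(leaves$attach_frac <= 0 | leaves$attach_frac > 1))
      cond_error("attach_frac must lie in (0, 1]", "spec_error")
    if (!all(leaves$side %in% c(-1, 1)))
      cond_error("leaf side must be -1 (left) or +1 (right)", "spec_error")
  }
  if (fg_mean - bg_mean < 5 * max(fg_sd, bg_sd))
    cond_error("contrast guarantee violated: fg_mean - bg_mean < 5 sd", "spec_error")
  structure(list(image_h_px = as.integer(image_h_px),
                 image_w_px = as.integer(image_w_px),
                 cm_per_px = cm_per_px,
                 stem_base_row = as.integer(stem_base_row),
                 stem_col = as.integer(stem_col),
                 stem_height_px = as.integer(stem_height_px),
                 stem_base_width_px = stem_base_width_px,
                 stem_top_width_px = stem_top_width_px,
                 leaves = leaves,
                 whorl_n_blades = as.integer(whorl_n_blades),
                 whorl_blade_length_px = whorl_blade_length_px,
                 whorl_blade_width_px = whorl_blade_width_px,
                 whorl_spread_deg = whorl_spread_deg,
                 sheath_length_px = as.integer(sheath_length_px),
                 fg_mean = fg_mean, fg_sd = fg_sd,
                 bg_mean = bg_mean, bg_sd = bg_sd,
                 blur_sigma = blur_sigma,
                 bit_depth = as.integer(bit_depth),
                 smooth_radius_px = as.integer(smooth_radius_px),
                 seed = as.integer(seed)),
            class = "synthetic_plant_spec")
}

# A V6-like default: four expanded leaves, droop decreasing with rank, the
# youngest attached at the stem apex (the top node).
default_leaf_table <- function(stem_height_px, n_leaves = 4L,
                               angle_jitter = rep(0, n_leaves),
                               sides = rep_len(c(-1, 1), n_leaves)) {
  if (n_leaves == 0L)
    return(data.frame(attach_frac = numeric(), length_px = numeric(),
                      max_width_px = numeric(), tip_angle_deg = numeric(),
                      side = numeric(), curvature = numeric()))
  i <- seq_len(n_leaves)
  f <- 1 - (n_leaves - i) * min(0.13, 0.62 / max(1L, n_leaves - 1L))
  ang <- if (n_leaves == 1L) 80 else 105 - 39 * (i - 1) / (n_leaves - 1)
  data.frame(
    attach_frac = f,
    length_px = stem_height_px * (0.5 + 0.7 * i / n_leaves),
    max_width_px = 9 + round(4 * i / n_leaves),
    tip_angle_deg = ang + angle_jitter,
    side = sides,
    curvature = 0.07
  )
}

#' Render a synthetic plant
#'
#' Deterministic for a fixed `spec$seed`. The stem is drawn as a vertical
#' tapered bar, each leaf as a quadratic arc whose attachment-to-tip chord
#' makes `tip_angle_deg` with the upward stem direction, and the whorl as a
#' fan of upright blades above the stem apex. The silhouette is regularized
#' by an open-close disc filter (idempotent, so the segmentation cleanup of
#' the pipeline reproduces the rendered mask exactly on noiseless input),
#' and all ground truth is measured on the regularized label image.
#'
#' @param spec a [synthetic_plant_spec].
#' @return List: `image` ([gray_image]), `truth` (see Details), `spec`.
#'   `truth` holds `label` (organ label matrix), `mask`, `height_cm`,
#'   `width_cm`, `area_cm2`, `stem_start`, `top_node`, `stem_height_cm`,
#'   `mid_stem_diameter_cm`, `n_expanded_leaves` and a per-leaf data frame
#'   `leaves` (`label`, `rank`, `area_cm2`, `tip_angle_deg`,
#'   `prescribed_angle_deg`, tip and attachment coordinates).
#' @export
render_plant <- function(spec) {
  stopifnot(inherits(spec, "synthetic_plant_spec"))
  h <- spec$image_h_px; w <- spec$image_w_px
  label <- matrix(0L, h, w)
  tn_row <- spec$stem_base_row - spec$stem_height_px    # top node (apex collar)
  if (tn_row < 2L) cond_error("stem leaves the canvas", "spec_error")

  # stem: vertical tapered bar from the base to the top node, label 1.
  # A few rows of crown are drawn below the nominal soil line
  # (stem_base_row), as a plant silhouette does not end flat at the media
  # surface; heights in the ground truth are measured from the soil line.
  crown <- min(spec$image_h_px - spec$stem_base_row,
               floor(spec$stem_base_width_px / 2))
  rows <- tn_row:(spec$stem_base_row + crown)
  frac_up <- (spec$stem_base_row - rows) / spec$stem_height_px
  widths <- spec$stem_base_width_px +
    (spec$stem_top_width_px - spec$stem_base_width_px) * frac_up
  for (k in seq_along(rows)) {
    hw <- (widths[k] - 1) / 2
    cs <- max(1L, floor(spec$stem_col - hw)):min(w, ceiling(spec$stem_col + hw))
    cs <- cs[abs(cs - spec$stem_col) <= hw + 1e-9]
    label[rows[k], cs] <- 1L
  }

  # whorl, label 255: the rolled-leaf sheath continuing above the top
  # collar, plus a fan of emerging blades from the sheath top
  if (spec$whorl_n_blades > 0L) {
    sheath <- spec$sheath_length_px
    label <- stamp_stroke(label, c(tn_row, spec$stem_col),
                          c(tn_row - sheath, spec$stem_col),
                          4, value = WHORL_LABEL)
    org <- c(tn_row - sheath + 2L, spec$stem_col)
    for (a in whorl_blade_angles(spec$whorl_n_blades, spec$whorl_spread_deg)) {
      tip <- org + spec$whorl_blade_length_px *
        c(-cos(a * pi / 180), sin(a * pi / 180))
      label <- stamp_stroke(label, org, tip, spec$whorl_blade_width_px,
                            curvature = 0, value = WHORL_LABEL, taper = 0.55)
    }
  }

  # leaves, bottom-up, labels 2..n+1. Each blade starts narrow at its
  # collar on the stem axis, leaves with a horizontal tangent, and its
  # collar-to-tip chord makes the prescribed angle with the stem.
  lv <- spec$leaves
  attach_rows <- integer(nrow(lv))
  for (i in seq_len(nrow(lv))) {
    # stroke centreline starts 2 px below the collar so the blade's upper
    # edge sits at the collar rather than above it
    att_row <- spec$stem_base_row -
      round(lv$attach_frac[i] * spec$stem_height_px) + 2L
    attach_rows[i] <- att_row
    th <- lv$tip_angle_deg[i] * pi / 180
    org <- c(att_row, spec$stem_col)
    tip <- c(att_row - lv$length_px[i] * cos(th),
             spec$stem_col + lv$side[i] * lv$length_px[i] * sin(th))
    shoulder <- (0.3 + lv$curvature[i]) * lv$length_px[i]
    tip_taper <- if ("tip_taper" %in% names(lv)) lv$tip_taper[i] else 0.15
    label <- stamp_stroke(label, org, tip, lv$max_width_px[i],
                          value = 1L + i, taper = tip_taper, base_ramp = TRUE,
                          ctrl = c(att_row, spec$stem_col + lv$side[i] * shoulder))
  }

  # regularize the silhouette with the open-close filter, then keep the
  # largest component — the same semantics the segmentation cleanup applies,
  # so the ground-truth mask is exactly what a noise-free pipeline recovers.
  # Small fragments (whorl blade tips pinched off by the opening) vanish
  # from the ground truth just as they vanish from the cleaned mask.
  m0 <- label > 0L
  before <- vapply(seq_len(nrow(spec$leaves)),
                   function(i) sum(label == 1L + i), 0L)
  m <- largest_component(open_close(m0, spec$smooth_radius_px), 8L)
  label[!m] <- 0L
  label <- fill_labels(label, m)
  after <- vapply(seq_len(nrow(spec$leaves)),
                  function(i) sum(label == 1L + i), 0L)
  if (any(after < 0.7 * before))
    cond_error("a leaf became disconnected from the plant; spec invalid",
               "spec_error")

  truth <- measure_truth(label, spec, attach_rows)

  img <- with_seed(spec$seed, {
    px <- matrix(stats::rnorm(h * w, spec$bg_mean, spec$bg_sd), h, w)
    nfg <- sum(m)
    px[m] <- stats::rnorm(nfg, spec$fg_mean, spec$fg_sd)
    px
  })
  maxv <- 2^spec$bit_depth - 1
  px <- pmin(pmax(img, 0), maxv)
  if (spec$blur_sigma > 0) {
    px <- EBImage::gblur(px, sigma = spec$blur_sigma)
    px <- pmin(pmax(px, 0), maxv)
  }
  list(image = gray_image(round(px), bit_depth = spec$bit_depth),
       truth = truth, spec = spec)
}

# Draw a quadratic arc from `from` to `to` with the given maximum stroke
# width. `taper = TRUE` narrows the stroke toward `to` (a blade tip);
# `base_ramp = TRUE` additionally starts the stroke narrow (a blade is
# narrow at the ligule where it leaves the stem) and widens over the first
# ~18% of its length. The arc's control point defaults to a perpendicular
# bow of `curvature` times the chord on the droop side; an explicit `ctrl`
# overrides it (used to give leaves a horizontal initial tangent at the
# collar). Errors if the stroke leaves the canvas.
stamp_stroke <- function(label, from, to, width, curvature = 0, value = 1L,
                         taper = FALSE, base_ramp = FALSE, ctrl = NULL) {
  taper_to <- if (isTRUE(taper)) 0.15 else if (is.numeric(taper)) taper else NA
  chord <- as.numeric(to) - as.numeric(from)
  len <- sqrt(sum(chord^2))
  if (len < 1) len <- 1
  if (is.null(ctrl)) {
    perp <- c(chord[2L], -chord[1L]) / len
    if (perp[1L] < 0) perp <- -perp         # bow downward (larger row)
    ctrl <- (as.numeric(from) + as.numeric(to)) / 2 + perp * curvature * len
  }
  tt <- seq(0, 1, length.out = max(16L, ceiling(2 * len)))
  pr <- (1 - tt)^2 * from[1L] + 2 * tt * (1 - tt) * ctrl[1L] + tt^2 * to[1L]
  pc <- (1 - tt)^2 * from[2L] + 2 * tt * (1 - tt) * ctrl[2L] + tt^2 * to[2L]
  shape <- rep(1, length(tt))
  if (!is.na(taper_to)) shape <- shape * (1 - (1 - taper_to) * tt)
  if (base_ramp) shape <- shape * pmin(1, 0.22 + 0.78 * tt / 0.22)
  rad <- pmax(1, (width / 2) * shape)
  h <- nrow(label); w <- ncol(label)
  rr <- integer(0); cc <- integer(0)
  rq <- round(2 * rad) / 2                  # half-pixel radius bins
  for (r_bin in sort(unique(rq))) {
    sel <- rq == r_bin
    offs <- disc_offsets(ceiling(r_bin))
    offs <- offs[offs[, 1L]^2 + offs[, 2L]^2 <= r_bin^2 + 1e-9, , drop = FALSE]
    pr_s <- round(rep(pr[sel], each = nrow(offs)) + offs[, 1L])
    pc_s <- round(rep(pc[sel], each = nrow(offs)) + offs[, 2L])
    rr <- c(rr, pr_s); cc <- c(cc, pc_s)
  }
  if (any(rr < 1L | rr > h | cc < 1L | cc > w))
    cond_error("organ leaves the canvas; spec invalid", "spec_error")
  idx <- cbind(rr, cc)
  free <- label[idx] == 0L
  label[idx[free, , drop = FALSE]] <- value
  label
}

whorl_blade_angles <- function(n, spread) {
  if (n == 1L) return(0)
  seq(-spread, spread, length.out = n)
}

disc_offsets <- local({
  cache <- new.env(parent = emptyenv())
  function(r) {
    key <- as.character(r)
    if (!is.null(cache[[key]])) return(cache[[key]])
    g <- expand.grid(dr = -r:r, dc = -r:r)
    g <- as.matrix(g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE])
    cache[[key]] <- g
    g
  }
})

# Pixels added by the closing step carry no organ label; give them the label
# of their nearest labeled neighbour (deterministic offset scan order).
fill_labels <- function(label, mask) {
  repeat {
    hole <- mask & label == 0L
    if (!any(hole)) break
    assigned <- FALSE
    for (k in seq_len(nrow(NEIGHBOR_OFFSETS))) {
      nb <- px_shift(label, NEIGHBOR_OFFSETS[k, 1L], NEIGHBOR_OFFSETS[k, 2L],
                     fill = 0L)
      sel <- hole & label == 0L & nb > 0L
      if (any(sel)) {
        label[sel] <- nb[sel]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      label[hole] <- 1L   # isolated sliver: count it as stem
      break
    }
  }
  label
}

# Ground truth measured on the regularized label image.
measure_truth <- function(label, spec, attach_rows) {
  cmpp <- spec$cm_per_px
  mask <- label > 0L
  pts <- which(mask, arr.ind = TRUE)
  tn_row <- spec$stem_base_row - spec$stem_height_px   # apex = top node
  stem_start <- c(spec$stem_base_row, spec$stem_col)
  top_node <- c(tn_row, spec$stem_col)
  # ruler-style diameter: stem width averaged over several locations
  # (here every stem row between top node and base, crown excluded)
  stem_w <- rowSums(label[tn_row:spec$stem_base_row, , drop = FALSE] == 1L)
  mid_w <- mean(stem_w[stem_w > 0L])
  n_lv <- nrow(spec$leaves)
  leaves <- lapply(seq_len(n_lv), function(i) {
    lpx <- which(label == 1L + i, arr.ind = TRUE)
    att <- c(attach_rows[i], spec$stem_col)
    d2 <- (lpx[, 1L] - att[1L])^2 + (lpx[, 2L] - att[2L])^2
    tip <- lpx[order(-d2, lpx[, 1L], lpx[, 2L])[1L], ]
    v <- c(tip[1L] - att[1L], tip[2L] - att[2L])
    ang <- acos(max(-1, min(1, -v[1L] / sqrt(sum(v^2))))) * 180 / pi
    data.frame(label = 1L + i, rank = i,
               area_cm2 = nrow(lpx) * cmpp^2,
               tip_angle_deg = ang,
               prescribed_angle_deg = spec$leaves$tip_angle_deg[i],
               tip_row = tip[1L], tip_col = tip[2L],
               attach_row = att[1L], attach_col = att[2L])
  })
  leaves <- if (n_lv > 0L) do.call(rbind, leaves) else NULL
  list(label = label, mask = mask,
       height_cm = (max(pts[, 1L]) - min(pts[, 1L]) + 1L) * cmpp,
       width_cm = (max(pts[, 2L]) - min(pts[, 2L]) + 1L) * cmpp,
       area_cm2 = nrow(pts) * cmpp^2,
       stem_start = stem_start, top_node = top_node,
       stem_height_cm = (spec$stem_base_row - tn_row) * cmpp,
       mid_stem_diameter_cm = mid_w * cmpp,
       n_expanded_leaves = n_lv,
       leaves = leaves)
}
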