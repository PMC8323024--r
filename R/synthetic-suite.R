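# Graded suites of synthetic plants spanning vegetative stages from V4-like
# (two expanded leaves, short stem) to V10-like (eight leaves, tall stem,
# deliberately overlapping upper leaves). Tier geometry follows vegetative
# maize architecture: leaf length increases with rank, droop decreases with
# rank, and a massive apical whorl towers above the top node. The whorl is
# sized by a small fixed-point solve so that the predicted skeleton centre
# of mass sits at the top node — the architectural regime in which
# centre-of-mass top-node detection is valid, and the regime the pipeline is
# specified for.

SUITE_TIERS <- data.frame(
  tier = c("V4", "V5", "V6", "V7", "V8", "V10"),
  stem_height_px = c(90L, 115L, 140L, 170L, 200L, 230L),
  n_leaves = c(2L, 3L, 4L, 5L, 6L, 8L),
  n_blades = c(4L, 4L, 4L, 5L, 5L, 5L),
  overlap = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE
)

#' Build the spec of one suite plant
#'
#' @param tier one of `"V4" ... "V10"` (see `SUITE_TIERS`); `"V10"` renders
#'   deliberately overlapping upper leaves.
#' @param seed integer; drives the small per-plant jitter of angles and
#'   lengths and the intensity noise.
#' @return A [synthetic_plant_spec].
#' @export
tier_spec <- function(tier = "V6", seed = 1L) {
  row <- SUITE_TIERS[SUITE_TIERS$tier == tier, ]
  if (nrow(row) != 1L) cond_error(paste0("unknown tier: ", tier), "spec_error")
  H <- row$stem_height_px
  n <- row$n_leaves
  i <- seq_len(n)
  jit <- with_seed(seed, list(ang = stats::runif(n, -3, 3),
                              len = stats::runif(n, 0.97, 1.03)))
  f <- 1 - (n - i) * min(0.13, 0.62 / max(1L, n - 1L))
  ang <- (if (n == 1L) 80 else 105 - 39 * (i - 1) / (n - 1)) + jit$ang
  len <- H * (0.5 + 0.7 * i / n) * jit$len
  sides <- balance_sides(len, ang)
  curv <- rep(0.07, n)
  if (row$overlap && n >= 6L) {
    # force two same-side crossing mid-canopy leaves (a steep straight blade
    # under a much flatter one from a higher collar, so their blades cross
    # mid-blade and both tips stay distinct) and route the leaves above them
    # to the other side so the cross stays clear of the apex
    i1 <- n - 4L; i2 <- n - 3L
    sides[i2] <- sides[i1]
    ang[i1] <- 52
    ang[i2] <- 88
    curv[c(i1, i2)] <- 0.02
    sides[(i2 + 1L):n] <- -sides[i1]
  }
  leaves <- data.frame(attach_frac = f, length_px = len,
                       max_width_px = 9 + round(4 * i / n),
                       tip_angle_deg = ang, side = sides, curvature = curv)
  base_row <- 430L - 14L
  sheath <- max(12L, round(0.1 * H))
  blade_len <- balance_whorl(leaves, H, row$n_blades,
                             b_max = (base_row - H - sheath - 8L) / H,
                             sheath_px = sheath)
  base_w <- round(9 + H / 40)
  synthetic_plant_spec(
    stem_height_px = H,
    stem_base_width_px = base_w,
    stem_top_width_px = round(0.85 * base_w),
    leaves = leaves,
    whorl_n_blades = row$n_blades,
    whorl_blade_length_px = blade_len * H,
    sheath_length_px = sheath,
    seed = seed
  )
}

# Distichous side assignment: alternate in spirit, but balance the lateral
# skeleton moment (0.5 L^2 sin(theta) per leaf) greedily so the skeleton's
# column centre of mass stays on the stem.
balance_sides <- function(len, ang) {
  mom <- 0.5 * len^2 * sin(ang * pi / 180)
  sides <- integer(length(len))
  cum <- c(l = 0, r = 0)
  for (i in order(-mom)) {
    if (cum["l"] <= cum["r"]) {
      sides[i] <- -1L; cum["l"] <- cum["l"] + mom[i]
    } else {
      sides[i] <- 1L; cum["r"] <- cum["r"] + mom[i]
    }
  }
  sides
}

# Whorl sizing: blade length (in stem-height units) that places the
# predicted skeleton centre of mass just above the stem apex (the top
# node). Vegetative maize carries a massive whorl over the top collar; this
# keeps centre-of-mass top-node detection in its valid regime. Leaf skeleton
# mass is approximated by chord length; the whorl fan's skeleton moment is
# measured on a small stand-alone render (its blades merge near the origin,
# which no closed form captures well), and the blade length rescaled once.
balance_whorl <- function(leaves, H, n_blades, spread_deg = 35,
                          blade_width = 8, b_max = 0.9, target = 1.02,
                          sheath_px = round(0.1 * H)) {
  lt <- leaves$length_px / H
  hgt <- leaves$attach_frac + 0.5 * lt * cos(leaves$tip_angle_deg * pi / 180)
  num <- target * (1 + sum(lt)) - 0.5 - sum(lt * hgt)
  if (num <= 0) return(0.3)
  off <- (target - 1) * H
  sheath_moment <- sheath_px * (sheath_px / 2 - off)
  required <- num * H^2 - sheath_moment
  if (required <= 0) return(0.3)
  # closed-form start: n distinct blades at mean inclination ~ spread/2
  cosm <- cos(spread_deg / 2 * pi / 180)
  b0 <- sqrt(num / (0.85 * n_blades * 0.5 * cosm))
  b0 <- min(b_max, max(0.3, b0))
  mw <- whorl_skeleton_moment(b0 * H, n_blades, spread_deg, blade_width,
                              target_offset = off - sheath_px)
  if (mw$moment <= 0) return(min(b_max, 0.9))
  b1 <- b0 * sqrt(required / mw$moment)
  min(b_max, max(0.3, b1))
}

# Skeleton moment (px^2) of a rendered whorl fan about a point
# `target_offset` px above its origin, measured on a stand-alone render.
whorl_skeleton_moment <- function(blade_len, n_blades, spread_deg,
                                  blade_width, target_offset = 0) {
  pad <- 12L
  hh <- as.integer(ceiling(blade_len)) + 2L * pad
  ww <- 2L * as.integer(ceiling(blade_len * sin(spread_deg * pi / 180))) + 2L * pad
  lab <- matrix(0L, hh, ww)
  org <- c(hh - pad, ww %/% 2L)
  for (a in whorl_blade_angles(n_blades, spread_deg)) {
    tip <- org + blade_len * c(-cos(a * pi / 180), sin(a * pi / 180))
    lab <- stamp_stroke(lab, org, tip, blade_width, curvature = 0,
                        value = 1L, taper = 0.55)
  }
  m <- open_close(lab > 0L, 2L)
  sk <- skeletonize_mask(m)
  pts <- which(sk, arr.ind = TRUE)
  height_above <- (org[1L] - pts[, 1L]) - target_offset
  list(mass = nrow(pts), moment = sum(height_above))
}

#' Render a graded suite of synthetic plants
#'
#' Plants cycle through the tiers of `SUITE_TIERS`, small to large, so any
#' `n_plants` spans the V4-like to V10-like range. Deterministic per seed;
#' the `"V10"` tier deliberately overlaps its two uppermost leaves, all
#' other tiers are overlap-free.
#'
#' @param n_plants number of plants (>= 1).
#' @param seed integer seed.
#' @return List of class `synthetic_suite`; each element is a [render_plant]
#'   result plus `plant_id` and `tier`; `attr(, "manifest")` is a data frame
#'   of plant ids, tiers and overlap flags.
#' @export
default_suite <- function(n_plants, seed = 1L) {
  stopifnot(n_plants >= 1L)
  tiers <- SUITE_TIERS$tier[((seq_len(n_plants) - 1L) %% nrow(SUITE_TIERS)) + 1L]
  out <- lapply(seq_len(n_plants), function(i) {
    sp <- tier_spec(tiers[i], seed = seed + 101L * i)
    r <- render_plant(sp)
    r$plant_id <- sprintf("P%03d", i)
    r$tier <- tiers[i]
    r
  })
  attr(out, "manifest") <- data.frame(
    plant_id = vapply(out, `[[`, "", "plant_id"),
    tier = tiers,
    overlap = SUITE_TIERS$overlap[match(tiers, SUITE_TIERS$tier)],
    seed = seed + 101L * seq_len(n_plants),
    stringsAsFactors = FALSE
  )
  class(out) <- "synthetic_suite"
  out
}

#' A plant with prescribed leaf tip angles
#'
#' Renders a four-leaf plant whose attachment-to-tip chords make the given
#' angles with the stem, for angle-recovery checks across upright,
#' horizontal and drooping postures. The most upright angle is kept off the
#' uppermost attachment so no leaf out-tops the whorl.
#'
#' @param angles chord angles in degrees, one per leaf (construction order =
#'   attachment order bottom-up).
#' @param sides one side (+1 right, -1 left) per leaf. The default pairs the
#'   angles so same-side blades diverge rather than cross: on each side the
#'   upper blade is the steeper one.
#' @param seed integer seed.
#' @return A [render_plant] result.
#' @export
prescribed_angle_plant <- function(angles = c(90, 30, 120, 60),
                                   sides = c(-1, -1, 1, 1), seed = 1L) {
  H <- 160L
  n <- length(angles)
  i <- seq_len(n)
  f <- 1 - (n - i) * min(0.13, 0.62 / max(1L, n - 1L))
  leaves <- data.frame(attach_frac = f,
                       length_px = H * (0.5 + 0.7 * i / n),
                       max_width_px = 9 + round(4 * i / n),
                       tip_angle_deg = angles,
                       side = rep_len(sides, n),
                       curvature = 0.05)
  blade_len <- balance_whorl(leaves, H, 4L)
  sp <- synthetic_plant_spec(stem_height_px = H,
                             stem_base_width_px = 13, stem_top_width_px = 11,
                             leaves = leaves, whorl_n_blades = 4L,
                             whorl_blade_length_px = blade_len * H,
                             seed = seed)
  render_plant(sp)
}

#' Ground-truth tables of a suite
#'
#' Plant- and leaf-level data frames with the same column names the pipeline
#' CSVs use, ready for [evaluate_traits].
#'
#' @param suite a `synthetic_suite`.
#' @return List of data frames `plant` and `leaf`.
#' @export
suite_truth_tables <- function(suite) {
  man <- attr(suite, "manifest")
  plant <- do.call(rbind, lapply(suite, function(r) {
    tr <- r$truth
    data.frame(plant_id = r$plant_id, tier = r$tier,
               height_cm = tr$height_cm, width_cm = tr$width_cm,
               projected_area_cm2 = tr$area_cm2,
               stem_height_cm = tr$stem_height_cm,
               stem_diameter_cm = tr$mid_stem_diameter_cm,
               n_leaves = tr$n_expanded_leaves,
               stringsAsFactors = FALSE)
  }))
  plant$overlap <- man$overlap[match(plant$plant_id, man$plant_id)]
  leaf <- do.call(rbind, lapply(suite, function(r) {
    lv <- r$truth$leaves
    if (is.null(lv)) return(NULL)
    data.frame(plant_id = r$plant_id, leaf_rank = lv$rank,
               leaf_area_cm2 = lv$area_cm2, leaf_angle_deg = lv$tip_angle_deg,
               stringsAsFactors = FALSE)
  }))
  list(plant = plant, leaf = leaf)
}

#' Write a synthetic suite to disk
#'
#' Per plant: the CFI as PNG, the organ label image as PNG (labels scaled to
#' 0-255) and nothing else binary; plus a manifest CSV and ground-truth
#' plant/leaf CSVs for the whole suite.
#'
#' @param suite a `synthetic_suite`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_suite <- function(suite, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in suite) {
    write_gray_image(r$image, file.path(dir, paste0(r$plant_id, ".png")))
    png::writePNG(r$truth$label / 255, file.path(dir, paste0(r$plant_id, "_label.png")))
  }
  utils::write.csv(attr(suite, "manifest"), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  tt <- suite_truth_tables(suite)
  utils::write.csv(tt$plant, file.path(dir, "truth_plants.csv"), row.names = FALSE)
  utils::write.csv(tt$leaf, file.path(dir, "truth_leaves.csv"), row.names = FALSE)
  invisible(dir)
}
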