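skeleton_degrees <- function(skel) maizecfi:::neighbor_count(skel)

has_2x2_block <- function(skel) {
  any(skel & maizecfi:::px_shift(skel, 1L, 0L) &
        maizecfi:::px_shift(skel, 0L, 1L) & maizecfi:::px_shift(skel, 1L, 1L))
}

test_that("skeleton of simple shapes has the forced topology", {
  bar <- matrix(FALSE, 10, 60)
  bar[4:6, 5:54] <- TRUE
  sk <- skeletonize_mask(bar)
  deg <- skeleton_degrees(sk)
  expect_equal(sum(sk & deg == 1L), 2L)           # a line: two ends
  expect_gte(sum(sk), 44)                          # ~50 px long
  expect_false(has_2x2_block(sk))

  plus <- matrix(FALSE, 41, 41)
  plus[19:23, 6:36] <- TRUE
  plus[6:36, 19:23] <- TRUE
  skp <- skeletonize_mask(plus)
  degp <- skeleton_degrees(skp)
  expect_equal(sum(skp & degp == 1L), 4L)          # four arm tips
  bp <- maizecfi:::cluster_branch_points(skp & degp >= 3L)
  expect_equal(nrow(bp), 1L)                       # one centre junction

  expect_error(skeletonize_mask(matrix(FALSE, 8, 8)), class = "input_error")
})

test_that("skeletons are one pixel wide and stay connected", {
  for (s in 1:10) {
    blob <- random_blob(2000 + s)
    blob <- maizecfi:::largest_component(blob, 8L)
    sk <- skeletonize_mask(blob)
    expect_false(has_2x2_block(sk), label = sprintf("2x2 block, seed %d", s))
    expect_equal(max(maizecfi:::label_components(sk, 8L)), 1L,
                 label = sprintf("connectivity, seed %d", s))
  }
})

test_that("spur trimming removes short twigs and only short twigs", {
  m <- matrix(FALSE, 20, 120)
  m[10, 6:105] <- TRUE                 # 100 px line
  m[7:9, 50] <- TRUE                   # 3 px side twig
  out <- trim_spurs(m, 10L)
  deg <- skeleton_degrees(out)
  expect_equal(sum(out & deg == 1L), 2L)
  expect_false(any(out[7:9, 50]))

  expect_identical(trim_spurs(m, 0L), m)  # zero length: identity
})

test_that("after trimming no terminal branch shorter than the limit remains", {
  shortest_terminal <- function(skel) {
    deg <- skeleton_degrees(skel)
    ends <- which(skel & deg == 1L, arr.ind = TRUE)
    best <- Inf
    for (i in seq_len(nrow(ends))) {
      walk <- maizecfi:::walk_branch(skel, deg, ends[i, 1L], ends[i, 2L], 10000L)
      if (!is.null(walk)) best <- min(best, nrow(walk))
    }
    best
  }
  for (s in 1:8) {
    sk <- random_skeleton(3000 + s)
    trimmed <- trim_spurs(sk, 8L)
    expect_gte(shortest_terminal(trimmed), 8L)
  }
})

test_that("landmarks classify a plus-sign and a vertical line correctly", {
  plus <- matrix(FALSE, 41, 41)
  plus[19:23, 6:36] <- TRUE
  plus[6:36, 19:23] <- TRUE
  sk <- skeletonize_mask(plus)
  poi <- find_landmarks(sk, plus, pipeline_config())
  expect_equal(poi$stem_start[1L], max(which(sk, arr.ind = TRUE)[, 1L]))
  expect_equal(nrow(poi$leaf_tips), 3L)
  expect_length(poi$flags, 0L)

  line <- matrix(FALSE, 40, 21)
  line[5:35, 10] <- TRUE
  poi2 <- find_landmarks(line, line, pipeline_config())
  expect_equal(poi2$stem_start, c(35L, 10L))
  expect_equal(nrow(poi2$leaf_tips), 1L)
  expect_equal(poi2$leaf_tips[1L, ], c(row = 5L, col = 10L))
  expect_equal(nrow(poi2$branch_points), 0L)
})

test_that("endpoint/branch classification matches a brute-force neighbour scan", {
  for (s in 1:6) {
    sk <- random_skeleton(4000 + s)
    sk <- trim_spurs(sk, 5L)
    deg <- skeleton_degrees(sk)
    pts <- which(sk, arr.ind = TRUE)
    brute_deg <- apply(pts, 1L, function(p) {
      cnt <- 0L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- p[1L] + dr; cc <- p[2L] + dc
        if (rr >= 1L && cc >= 1L && rr <= nrow(sk) && cc <= ncol(sk) && sk[rr, cc])
          cnt <- cnt + 1L
      }
      cnt
    })
    expect_identical(deg[pts], brute_deg)
  }
})

test_that("a drooping leaf tip below the stem base stays a leaf tip", {
  # one long drooping leaf whose tip ends lower than the stem base and far
  # from the mask midline
  sp <- synthetic_plant_spec(
    stem_height_px = 120L, stem_base_width_px = 11, stem_top_width_px = 9,
    leaves = data.frame(attach_frac = c(0.7, 1), length_px = c(126, 110),
                        max_width_px = c(12, 12), tip_angle_deg = c(135, 70),
                        side = c(-1, 1), curvature = c(0.03, 0.05),
                        tip_taper = c(0.5, 0.15)),
    whorl_n_blades = 4L, whorl_blade_length_px = 70, seed = 8L)
  r <- render_plant(sp)
  rec <- analyze_image(r$image, pipeline_config(), "droop")
  tip1 <- r$truth$leaves[1L, ]
  expect_gt(tip1$tip_row, sp$stem_base_row - 10L)   # really droops low
  # the stem start is on the midline, not at the drooping tip
  expect_lt(abs(rec$poi$stem_start[2L] - sp$stem_col), 8L)
  # the drooping tip is among the leaf tips
  d <- sqrt((rec$poi$leaf_tips[, 1L] - tip1$tip_row)^2 +
              (rec$poi$leaf_tips[, 2L] - tip1$tip_col)^2)
  expect_lt(min(d), 12)
})

test_that("leaf-tip count and endpoint count agree on whorl-free renders", {
  for (k in c(2L, 4L)) {
    sp <- synthetic_plant_spec(
      stem_height_px = 140L, stem_base_width_px = 12, stem_top_width_px = 10,
      leaves = maizecfi:::default_leaf_table(140L, n_leaves = k),
      whorl_n_blades = 0L, seed = k)
    r <- render_plant(sp)
    seg <- segment_plant(r$image)
    sk <- trim_spurs(skeletonize_mask(seg$mask), 10L)
    poi <- find_landmarks(sk, seg$mask, pipeline_config())
    deg <- skeleton_degrees(sk)
    n_end <- sum(sk & deg == 1L)
    expect_equal(n_end, k + 1L, label = sprintf("k = %d endpoints", k))
    expect_equal(nrow(poi$leaf_tips), k, label = sprintf("k = %d tips", k))
    expect_equal(nrow(poi$leaf_tips) + 1L, n_end)
  }
})
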