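test_that("rendering is deterministic per seed", {
  sp <- tier_spec("V5", seed = 12)
  a <- render_plant(sp)
  b <- render_plant(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$label, b$truth$label)

  s1 <- default_suite(4L, seed = 7)
  s2 <- default_suite(4L, seed = 7)
  expect_identical(suite_truth_tables(s1), suite_truth_tables(s2))
})

test_that("a bare stem renders with no leaves and one organ class", {
  sp <- synthetic_plant_spec(
    stem_height_px = 100L,
    leaves = maizecfi:::default_leaf_table(100L, n_leaves = 0L),
    whorl_n_blades = 0L, seed = 1L)
  r <- render_plant(sp)
  expect_equal(r$truth$n_expanded_leaves, 0L)
  expect_identical(sort(unique(as.vector(r$truth$label[r$truth$label > 0]))), 1L)
})

test_that("a V6-like spec renders six organ classes", {
  r <- render_plant(tier_spec("V6", seed = 4))
  classes <- sort(unique(as.vector(r$truth$label[r$truth$label > 0])))
  expect_identical(classes, c(1L, 2L, 3L, 4L, 5L, 255L))  # stem + 4 leaves + whorl
})

test_that("the noiseless render thresholded mid-way reproduces the label mask", {
  sp <- tier_spec("V5", seed = 5)
  sp$fg_sd <- 0; sp$bg_sd <- 0; sp$blur_sigma <- 0
  r <- render_plant(sp)
  t_mid <- (sp$fg_mean + sp$bg_mean) / 2
  expect_identical(binarize(r$image, t_mid), r$truth$mask)
})

test_that("rendered leaf areas track the analytic stroke-area target", {
  # light regularization isolates rasterization fidelity from the open-close
  # smoothing (which deliberately erodes the thin collar and tip fringes)
  sp <- tier_spec("V6", seed = 19)
  sp$smooth_radius_px <- 1L
  r <- render_plant(sp)
  lv <- sp$leaves
  # analytic area of a tapered, collar-ramped rasterized stroke: integral of
  # the discrete stroke width (2 floor(r) + 1 pixels for a half-pixel radius
  # bin r) over the arc length
  tgrid <- seq(0, 1, length.out = 2001L)
  for (i in seq_len(nrow(lv))) {
    rad <- pmax(1, (lv$max_width_px[i] / 2) *
                  (1 - 0.85 * tgrid) * pmin(1, 0.22 + 0.78 * tgrid / 0.22))
    wd <- 2 * floor(round(2 * rad) / 2) + 1
    target_px <- lv$length_px[i] * mean(wd)
    got_px <- sum(r$truth$label == 1L + i)
    expect_lt(abs(got_px / target_px - 1), 0.10,
              label = sprintf("leaf %d analytic area", i))
  }
})

test_that("ground truth is measured on the label image, not the spec", {
  r <- render_plant(tier_spec("V4", seed = 3))
  expect_equal(r$truth$area_cm2,
               sum(r$truth$mask) * r$spec$cm_per_px^2)
  for (i in seq_len(nrow(r$truth$leaves))) {
    expect_equal(r$truth$leaves$area_cm2[i],
                 sum(r$truth$label == r$truth$leaves$label[i]) * r$spec$cm_per_px^2)
  }
  pts <- which(r$truth$mask, arr.ind = TRUE)
  expect_equal(r$truth$height_cm, (diff(range(pts[, 1L])) + 1L) * r$spec$cm_per_px)
})

test_that("suite tiers grade from small to large and the largest overlaps", {
  suite <- default_suite(6L, seed = 11)
  man <- attr(suite, "manifest")
  expect_equal(man$tier, c("V4", "V5", "V6", "V7", "V8", "V10"))
  expect_equal(man$overlap, c(rep(FALSE, 5L), TRUE))
  n_lv <- sapply(suite, function(r) r$truth$n_expanded_leaves)
  expect_equal(n_lv, c(2L, 3L, 4L, 5L, 6L, 8L))
  h <- sapply(suite, function(r) r$truth$stem_height_cm)
  expect_true(all(diff(h) > 0))

  one <- default_suite(1L, seed = 2)
  expect_equal(attr(one, "manifest")$tier, "V4")
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_plant_spec(
    leaves = data.frame(attach_frac = c(0.5, 0.4), length_px = 50,
                        max_width_px = 9, tip_angle_deg = 90, side = 1,
                        curvature = 0.05)), class = "spec_error")
  expect_error(synthetic_plant_spec(fg_mean = 60, bg_mean = 40, fg_sd = 10),
               class = "spec_error")
  expect_error(render_plant(synthetic_plant_spec(
    stem_height_px = 140L,
    leaves = data.frame(attach_frac = 1, length_px = 4000, max_width_px = 9,
                        tip_angle_deg = 90, side = 1, curvature = 0.05))),
    class = "spec_error")
})

test_that("a written suite can be read back and evaluated", {
  dir <- withr::local_tempdir()
  suite <- default_suite(2L, seed = 5)
  write_synthetic_suite(suite, dir)
  expect_true(file.exists(file.path(dir, "P001.png")))
  expect_true(file.exists(file.path(dir, "truth_plants.csv")))
  img <- read_gray_image(file.path(dir, "P001.png"))
  expect_equal(img$pixels, suite[[1L]]$image$pixels)
})
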