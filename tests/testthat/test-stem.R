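test_that("top node is the branch point nearest the centre of mass", {
  poi <- structure(list(
    branch_points = cbind(row = c(10L, 40L), col = c(50L, 50L)),
    center_of_mass = c(38, 50)), class = "points_of_interest")
  expect_equal(find_top_node(poi), c(40L, 50L))

  poi$branch_points <- cbind(row = 22L, col = 7L)
  expect_equal(find_top_node(poi), c(22L, 7L))

  # equidistant: smaller row, then smaller col
  poi$branch_points <- cbind(row = c(30L, 10L), col = c(20L, 20L))
  poi$center_of_mass <- c(20, 20)
  expect_equal(find_top_node(poi), c(10L, 20L))

  poi$branch_points <- matrix(integer(), 0L, 2L)
  expect_error(find_top_node(poi), class = "no_top_node")
})

test_that("geodesic distances count unit steps along the skeleton", {
  line <- matrix(FALSE, 5, 30)
  line[3, 6:25] <- TRUE
  d <- geodesic_distance(line, c(3L, 6L))
  expect_equal(d[3, 6:25], 0:19)
  expect_equal(d[3, 6], 0)
  expect_true(all(is.na(d[1, ])))
  expect_error(geodesic_distance(line, c(1L, 1L)), class = "input_error")
})

test_that("geodesic distances equal BFS on the pixel graph", {
  for (s in 1:10) {
    sk <- random_skeleton(5000 + s)
    pts <- which(sk, arr.ind = TRUE)
    src <- pts[1L, ]
    expect_equal(geodesic_distance(sk, src), oracle_geodesic(sk, src),
                 label = sprintf("seed %d", s))
  }
})

test_that("stem path takes the trunk of a Y and matches BFS lengths", {
  y <- matrix(FALSE, 40, 40)
  y[20:35, 20] <- TRUE                       # trunk
  for (i in 1:12) {
    y[20 - i, 20 - i] <- TRUE                # left arm
    y[20 - i, 20 + i] <- TRUE                # right arm
  }
  p <- stem_path(y, c(35L, 20L), c(20L, 20L))
  expect_equal(p[1L, ], c(row = 35L, col = 20L), ignore_attr = TRUE)
  expect_equal(p[nrow(p), ], c(row = 20L, col = 20L), ignore_attr = TRUE)
  expect_true(all(p[, 2L] == 20L))           # trunk only, no arm pixels

  expect_equal(nrow(stem_path(y, c(35L, 20L), c(35L, 20L))), 1L)

  for (s in 1:6) {
    sk <- random_skeleton(6000 + s)
    pts <- which(sk, arr.ind = TRUE)
    a <- pts[1L, ]; b <- pts[nrow(pts), ]
    d <- oracle_geodesic(sk, a)
    p <- stem_path(sk, a, b)
    expect_equal(nrow(p) - 1L, unname(d[b[1L], b[2L]]))
    # consecutive path pixels are 8-adjacent and unique
    expect_true(all(abs(diff(p[, 1L])) <= 1L & abs(diff(p[, 2L])) <= 1L))
    expect_equal(nrow(unique(p)), nrow(p))
  }
})

test_that("stem radius recovers the half-width of a bar", {
  bar <- matrix(FALSE, 60, 20)
  bar[6:55, 7:13] <- TRUE                    # width 7
  path <- cbind(row = 55:6, col = 10L)
  rad <- stem_radius(bar, path, pipeline_config())
  expect_lt(abs(rad$radius_px - 3.5), 0.5)
  expect_lt(abs(2 * rad$radius_px - 7), 1)

  thin <- matrix(FALSE, 30, 9)
  thin[5:25, 5] <- TRUE
  rthin <- stem_radius(thin, cbind(row = 25:5, col = 5L), pipeline_config())
  expect_lte(rthin$radius_px, 1)

  short <- stem_radius(bar, path[1:5, ], pipeline_config())
  expect_true("unfiltered_radius" %in% short$flags)
})

test_that("stem mask covers a bar at half-width radius and grows with radius", {
  bar <- matrix(FALSE, 60, 21)
  bar[6:55, 7:13] <- TRUE
  path <- cbind(row = 55:6, col = 10L)
  sm <- build_stem_mask(bar, path, 3.5)
  expect_gte(sum(sm & bar) / sum(bar), 0.95)
  expect_true(all(sm[!bar] == FALSE))

  tiny <- build_stem_mask(bar, path, 0.5)
  expect_lte(sum(tiny), 2 * nrow(path))

  sizes <- sapply(c(0.5, 1.5, 2.5, 3.5, 5), function(r)
    sum(build_stem_mask(bar, path, r)))
  expect_true(all(diff(sizes) >= 0))
})

test_that("stem height is the scaled straight-line distance", {
  cal <- calibration(cm_per_px = 0.1)
  path <- cbind(row = 199:99, col = 50L)
  expect_equal(stem_height(path, cal), 10.0)
  expect_equal(stem_height(path[1L, , drop = FALSE], cal), 0)
})

test_that("top node and stem height are recovered on a rendered plant", {
  r <- render_plant(tier_spec("V6", seed = 31))
  rec <- analyze_image(r$image, pipeline_config(), "p")
  expect_lte(sqrt(sum((rec$stem$top_node - r$truth$top_node)^2)), 5)
  expect_lt(abs(rec$stem$stem_height_cm / r$truth$stem_height_cm - 1), 0.05)
  expect_lt(abs(rec$stem$diameter_cm / r$truth$mid_stem_diameter_cm - 1), 0.15)
  # stem mask stays out of the leaves
  leaf_px <- r$truth$label >= 2L & r$truth$label != 255L
  expect_lte(sum(rec$stem$stem_mask & leaf_px) / sum(rec$stem$stem_mask), 0.1)
})
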