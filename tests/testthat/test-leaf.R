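test_that("leaf separation splits a plus into its two arms", {
  plus <- matrix(FALSE, 41, 41)
  plus[19:23, 6:36] <- TRUE
  plus[6:36, 19:23] <- TRUE
  bar <- matrix(FALSE, 41, 41)
  bar[6:36, 19:23] <- TRUE
  sep <- separate_leaves(plus, bar, pipeline_config())
  expect_length(sep$blobs, 2L)
  expect_equal(sep$discarded_px, 0L)

  expect_error(separate_leaves(bar, bar, pipeline_config()), class = "no_leaves")
})

test_that("whorl removal takes the highest blob; a lone blob is all whorl", {
  mk <- function(r0) {
    m <- matrix(FALSE, 200, 50); m[r0:(r0 + 9), 21:30] <- TRUE; m
  }
  blobs <- list(mk(100L), mk(20L), mk(180L))
  rw <- remove_whorl(blobs)
  expect_identical(rw$whorl, blobs[[2L]])
  expect_length(rw$leaves, 2L)

  one <- remove_whorl(blobs[1L])
  expect_identical(one$whorl, blobs[[1L]])
  expect_length(one$leaves, 0L)
})

test_that("leaves rank bottom-up by centre of mass", {
  mk <- function(r0) {
    m <- matrix(FALSE, 200, 50); m[r0:(r0 + 9), 21:30] <- TRUE; m
  }
  blobs <- list(mk(100L), mk(20L), mk(180L))
  ranked <- rank_leaves(blobs)
  expect_equal(sapply(ranked, `[[`, "rank"), 1:3)
  expect_equal(sapply(ranked, function(l) l$center_of_mass[1L]),
               c(184.5, 104.5, 24.5))
  expect_equal(rank_leaves(blobs[2L])[[1L]]$rank, 1L)
})

test_that("leaf area is pixel count times the squared scale", {
  m <- matrix(FALSE, 30, 30)
  m[1:10, 1:10] <- TRUE
  expect_equal(leaf_area(m, calibration(cm_per_px = 0.1)), 1.0)
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(leaf_area(one, calibration(cm_per_px = 0.05)), 0.0025)
})

test_that("leaf angle is 0 for an upright tip, 90 for a horizontal one", {
  path <- cbind(row = 100:50, col = 30L)      # vertical stem, up = -row
  blob_up <- matrix(FALSE, 120, 80)
  blob_up[25:48, 30:31] <- TRUE               # thin blob straight above the top
  tips <- cbind(row = 25L, col = 30L)
  a_up <- leaf_angle(blob_up, tips, path)
  expect_lt(abs(a_up$angle_deg - 0), 3)       # parallel to the stem

  blob_flat <- matrix(FALSE, 120, 80)
  blob_flat[73:77, 36:70] <- TRUE
  tips_flat <- cbind(row = 75L, col = 70L)
  a_flat <- leaf_angle(blob_flat, tips_flat, path)
  expect_lt(abs(a_flat$angle_deg - 90), 3)

  # two tips in one blob: flagged, no angle
  two <- leaf_angle(blob_flat, rbind(tips_flat, cbind(row = 74L, col = 69L)), path)
  expect_true(is.na(two$angle_deg))
  expect_equal(two$flags, "occluded_merged_leaf")
  none <- leaf_angle(blob_flat, cbind(row = 1L, col = 1L), path)
  expect_true(is.na(none$angle_deg))
})

test_that("leaf angle is invariant under translation and mirroring", {
  path <- cbind(row = 100:50, col = 30L)
  blob <- matrix(FALSE, 140, 100)
  blob[60:64, 36:80] <- TRUE
  tips <- cbind(row = 62L, col = 80L)
  base <- leaf_angle(blob, tips, path)$angle_deg

  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  tr <- leaf_angle(shift(blob, 20L, 10L), tips + rep(c(20L, 10L), each = 1),
                   path + rep(c(20L, 10L), each = nrow(path)))$angle_deg
  expect_equal(tr, base, tolerance = 1e-9)

  w <- ncol(blob)
  mblob <- blob[, w:1]
  mpath <- cbind(row = path[, 1L], col = w + 1L - path[, 2L])
  mtips <- cbind(row = tips[, 1L], col = w + 1L - tips[, 2L])
  mi <- leaf_angle(mblob, mtips, mpath)$angle_deg
  expect_equal(mi, base, tolerance = 1e-9)
})

test_that("pixel accounting is exact on rendered plants", {
  for (tier in c("V5", "V8")) {
    r <- render_plant(tier_spec(tier, seed = 17))
    rec <- analyze_image(r$image, pipeline_config(), "p")
    acct <- rec$accounting
    expect_identical(acct$plant_px,
                     acct$stem_px + acct$whorl_px + acct$leaf_px + acct$discarded_px)
  }
})

test_that("blob count matches the rendered organ count without overlap", {
  r <- render_plant(tier_spec("V6", seed = 23))
  rec <- analyze_image(r$image, pipeline_config(), "p")
  sep <- separate_leaves(rec$mask, rec$stem$stem_mask, pipeline_config())
  # expanded leaves + the whorl cluster
  expect_length(sep$blobs, r$truth$n_expanded_leaves + 1L)
  expect_equal(rec$leafset$n_leaves, r$truth$n_expanded_leaves)
  # whorl blob overlaps the true whorl pixels heavily
  wh <- rec$leafset$whorl_mask
  true_wh <- r$truth$label == 255L
  expect_gte(sum(wh & true_wh) / sum(true_wh), 0.8)
})
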