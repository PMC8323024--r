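# End-to-end pipeline: segmentation -> skeleton -> landmarks -> stem ->
# leaves -> whole-plant traits, with graceful degradation. A failed stage
# flags the record and later stages are skipped; one bad image never aborts
# a batch.

#' Analyze a single CFI
#'
#' Runs the full trait-extraction pipeline on one image. Stages degrade
#' gracefully: a plant with no branch point gets whole-plant traits but no
#' stem or leaf traits, and the record is flagged accordingly.
#'
#' @param image a [gray_image].
#' @param config a [pipeline_config].
#' @param plant_id identifier for the output tables.
#' @param image_path optional source path, echoed into the record.
#' @return A `plant_record` list: `plant_id`, `image_path`, `flags`,
#'   `threshold`, `mask`, `skeleton`, `poi`, `stem` (`stem_traits` or NULL),
#'   `leafset` (`leaf_set` or NULL), `height_cm`, `width_cm`,
#'   `projected_area_cm2`, and `accounting` (exact pixel bookkeeping:
#'   `plant_px = stem_px + whorl_px + leaf_px + discarded_px` whenever leaves
#'   were separated).
#' @export
analyze_image <- function(image, config = pipeline_config(), plant_id = "plant",
                          image_path = NULL) {
  rec <- list(plant_id = plant_id, image_path = image_path, flags = character(),
              stem = NULL, leafset = NULL)
  seg <- tryCatch(segment_plant(image, config), maizecfi_error = function(e) e)
  if (inherits(seg, "error")) {
    rec$flags <- "no_plant"
    class(rec) <- "plant_record"
    return(rec)
  }
  rec$threshold <- seg$threshold
  rec$mask <- seg$mask
  rec[c("height_cm", "width_cm", "projected_area_cm2")] <-
    whole_plant_traits(seg$mask, config$calibration)

  skel <- trim_spurs(skeletonize_mask(seg$mask), config$spur_length_px)
  rec$skeleton <- skel
  poi <- tryCatch(find_landmarks(skel, seg$mask, config),
                  maizecfi_error = function(e) e)
  if (inherits(poi, "error")) {
    rec$flags <- c(rec$flags, "no_landmarks")
    class(rec) <- "plant_record"
    return(rec)
  }
  rec$poi <- poi
  rec$flags <- c(rec$flags, poi$flags)

  stem <- tryCatch(extract_stem(skel, seg$mask, poi, config),
                   no_top_node = function(e) NULL,
                   maizecfi_error = function(e) e)
  if (inherits(stem, "error")) {
    rec$flags <- c(rec$flags, "stem_failed")
    stem <- NULL
  } else if (is.null(stem)) {
    rec$flags <- c(rec$flags, "no_top_node")
  }
  rec$stem <- stem
  if (!is.null(stem)) {
    rec$flags <- c(rec$flags, stem$flags)
    ls <- tryCatch(extract_leaves(seg$mask, stem, poi, config),
                   no_leaves = function(e) NULL)
    if (is.null(ls)) {
      rec$flags <- c(rec$flags, "no_leaves")
    } else {
      rec$leafset <- ls
      leaf_flags <- unique(unlist(lapply(ls$leaves, `[[`, "flags")))
      rec$flags <- c(rec$flags, leaf_flags)
      rec$accounting <- list(
        plant_px = sum(seg$mask),
        stem_px = sum(stem$stem_mask),
        whorl_px = sum(ls$whorl_mask),
        leaf_px = sum(vapply(ls$leaves, function(l) sum(l$blob_mask), 0L)),
        discarded_px = as.integer(ls$discarded_px)
      )
    }
  }
  class(rec) <- "plant_record"
  rec
}

#' @export
print.plant_record <- function(x, ...) {
  cat(sprintf("<plant_record %s: height %.1f cm, area %.1f cm2, %s leaves%s>\n",
              x$plant_id,
              null_na(x$height_cm), null_na(x$projected_area_cm2),
              if (is.null(x$leafset)) "?" else x$leafset$n_leaves,
              if (length(x$flags)) paste0(", flags: ", paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Batch pipeline over a directory of images
#'
#' Processes every PNG/TIFF in `image_dir`, writes the plant-level and
#' per-leaf trait CSVs to `out_dir`, and optionally debug PNGs (mask,
#' skeleton, labeled organs) per image. Unreadable or plant-free images are
#' logged and flagged, never fatal.
#'
#' @param image_dir directory with input images.
#' @param config a [pipeline_config].
#' @param out_dir output directory (created if needed).
#' @param debug_figures write per-image debug PNGs under `out_dir/debug`.
#' @param keep_masks keep mask/skeleton matrices in the returned records
#'   (memory-heavy for large batches).
#' @return Invisibly, a list: `records`, `n_full`, `n_partial`, `n_failed`,
#'   `paths` (the CSVs written).
#' @export
run_pipeline <- function(image_dir, config = pipeline_config(), out_dir,
                         debug_figures = FALSE, keep_masks = TRUE) {
  files <- sort(list.files(image_dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  files <- files[!grepl("_label\\.png$", files)]  # skip ground-truth labels
  if (length(files) == 0L)
    cond_error(paste0("no readable images in ", image_dir), "usage_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (debug_figures)
    dir.create(file.path(out_dir, "debug"), recursive = TRUE, showWarnings = FALSE)
  records <- list()
  n_failed <- 0L
  for (f in files) {
    pid <- tools::file_path_sans_ext(basename(f))
    rec <- tryCatch({
      img <- read_gray_image(f)
      analyze_image(img, config, plant_id = pid, image_path = f)
    }, error = function(e) {
      warning(sprintf("failed on %s: %s", f, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(rec)) {
      n_failed <- n_failed + 1L
      next
    }
    if (debug_figures) write_debug_figures(rec, file.path(out_dir, "debug"))
    if (!keep_masks)
      rec[c("mask", "skeleton")] <- NULL
    records[[pid]] <- rec
  }
  if (length(records) == 0L)
    cond_error("no image produced a record", "usage_error")
  paths <- write_traits_csv(unname(records), file.path(out_dir, "plant_traits.csv"))
  full <- vapply(records, function(r) !is.null(r$stem) && !is.null(r$leafset) &&
                   length(r$flags) == 0L, TRUE)
  invisible(list(records = records,
                 n_full = sum(full),
                 n_partial = length(records) - sum(full),
                 n_failed = n_failed,
                 paths = paths))
}

# Debug overlays: mask, skeleton with landmark markers, labeled organs.
write_debug_figures <- function(rec, dir) {
  if (!is.null(rec$mask))
    write_mask_png(rec$mask, file.path(dir, paste0(rec$plant_id, "_mask.png")))
  if (!is.null(rec$skeleton)) {
    h <- nrow(rec$skeleton); w <- ncol(rec$skeleton)
    rgb <- array(0, c(h, w, 3L))
    for (ch in 1:3) rgb[, , ch][rec$skeleton] <- 1
    mark <- function(pts, col) {
      if (is.null(pts)) return()
      pts <- matrix(pts, ncol = 2L)
      for (i in seq_len(nrow(pts))) {
        rs <- max(1L, pts[i, 1L] - 2L):min(h, pts[i, 1L] + 2L)
        cs <- max(1L, pts[i, 2L] - 2L):min(w, pts[i, 2L] + 2L)
        for (ch in 1:3) rgb[rs, cs, ch] <<- col[ch]
      }
    }
    if (!is.null(rec$poi)) {
      mark(rec$poi$leaf_tips, c(0, 0.4, 1))        # blue: leaf tips
      mark(rec$poi$branch_points, c(0, 1, 0))      # green: nodes
      mark(rec$poi$stem_start, c(1, 0, 1))         # magenta: stem start
      if (!is.null(rec$stem)) mark(rec$stem$top_node, c(0, 1, 1))  # cyan
    }
    png::writePNG(rgb, file.path(dir, paste0(rec$plant_id, "_skeleton.png")))
  }
  if (!is.null(rec$leafset) && !is.null(rec$mask)) {
    h <- nrow(rec$mask); w <- ncol(rec$mask)
    rgb <- array(0, c(h, w, 3L))
    paint <- function(m, col) for (ch in 1:3) rgb[, , ch][m] <<- col[ch]
    if (!is.null(rec$stem)) paint(rec$stem$stem_mask, c(0.8, 0.8, 0.8))
    paint(rec$leafset$whorl_mask, c(0.5, 0.5, 0))
    pal <- grDevices::rainbow(max(1L, rec$leafset$n_leaves))
    for (lf in rec$leafset$leaves)
      paint(lf$blob_mask, grDevices::col2rgb(pal[lf$rank])[, 1L] / 255)
    png::writePNG(rgb, file.path(dir, paste0(rec$plant_id, "_organs.png")))
  }
}

#' Evaluate estimated traits against ground truth
#'
#' Joins an estimated and a true trait table on `keys` and reports, per
#' shared numeric trait, the sample size, R-squared about the identity line
#' (1 - SS_res/SS_tot with residuals to y = x), the conventional regression
#' R-squared, the RMSE and the mean bias (estimate minus truth).
#'
#' @param pred data frame or CSV path of estimates.
#' @param truth data frame or CSV path of ground truth.
#' @param keys join columns (default `"plant_id"`).
#' @return Data frame of class `evaluation_report` with columns `trait`,
#'   `n`, `r2_identity`, `r2_fit`, `rmse`, `bias`.
#' @export
evaluate_traits <- function(pred, truth, keys = "plant_id") {
  if (is.character(pred)) pred <- utils::read.csv(pred, stringsAsFactors = FALSE)
  if (is.character(truth)) truth <- utils::read.csv(truth, stringsAsFactors = FALSE)
  if (!all(keys %in% names(pred)) || !all(keys %in% names(truth)))
    cond_error("join keys missing from one of the tables", "input_error")
  m <- merge(pred, truth, by = keys, suffixes = c("_est", "_true"))
  if (nrow(m) == 0L) cond_error("no records match on the join keys", "input_error")
  shared <- intersect(setdiff(names(pred), keys), setdiff(names(truth), keys))
  shared <- shared[vapply(shared, function(cn)
    is.numeric(pred[[cn]]) && is.numeric(truth[[cn]]), TRUE)]
  rows <- lapply(shared, function(cn) {
    e <- m[[paste0(cn, "_est")]]; t <- m[[paste0(cn, "_true")]]
    ok <- is.finite(e) & is.finite(t)
    if (sum(ok) < 2L) return(NULL)
    e <- e[ok]; t <- t[ok]
    ss_tot <- sum((t - mean(t))^2)
    r2_id <- if (ss_tot > 0) 1 - sum((e - t)^2) / ss_tot else NA_real_
    r2_fit <- if (stats::var(e) > 0 && stats::var(t) > 0)
      stats::cor(e, t)^2 else NA_real_
    data.frame(trait = cn, n = sum(ok),
               r2_identity = r2_id, r2_fit = r2_fit,
               rmse = sqrt(mean((e - t)^2)), bias = mean(e - t),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    cond_error("fewer than 2 matched records per trait", "input_error")
  class(out) <- c("evaluation_report", class(out))
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Trait recovery vs ground truth\n")
  df <- as.data.frame(x)
  df$r2_identity <- sprintf("%.4f", df$r2_identity)
  df$r2_fit <- sprintf("%.4f", df$r2_fit)
  df$rmse <- signif(df$rmse, 4)
  df$bias <- signif(df$bias, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
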