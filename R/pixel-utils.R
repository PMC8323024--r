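# Shared low-level helpers on (row, col) pixel grids. Masks and skeletons are
# plain logical matrices in raster order: row 1 is the top of the image, rows
# increase downward. The "height" of a pixel is (nrow - row), so smaller rows
# are higher in the scene.

# Value of the neighbour at offset (dr, dc) for every pixel; out-of-image
# neighbours are `fill`.
px_shift <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) > 0L && length(cs) > 0L)
    out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

# 8-neighbourhood offsets in a fixed scan order (row-major); all tie-breaks
# that walk neighbours rely on this order being deterministic.
NEIGHBOR_OFFSETS <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

# Number of foreground 8-neighbours of every pixel.
neighbor_count <- function(mask) {
  acc <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(NEIGHBOR_OFFSETS)))
    acc <- acc + px_shift(mask, NEIGHBOR_OFFSETS[k, 1L], NEIGHBOR_OFFSETS[k, 2L])
  acc
}

# Connected-component labels of a logical mask (0 = background). Components
# are found on the pixel adjacency graph; label ids are renumbered so that
# label 1 contains the first foreground pixel in column-major scan order,
# making the labeling deterministic.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(lab)
  id <- matrix(0L, nrow(mask), ncol(mask))
  id[idx] <- seq_along(idx)
  offs <- if (connectivity == 8L) NEIGHBOR_OFFSETS else
    NEIGHBOR_OFFSETS[NEIGHBOR_OFFSETS[, 1L] == 0L | NEIGHBOR_OFFSETS[, 2L] == 0L, , drop = FALSE]
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    nb <- px_shift(id, offs[k, 1L], offs[k, 2L], fill = 0L)
    keep <- mask & nb > 0L
    if (any(keep)) edges[[length(edges) + 1L]] <- cbind(id[keep], nb[keep])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0L)
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  memb <- igraph::components(g)$membership
  # renumber by first occurrence in scan order
  first <- !duplicated(memb)
  renum <- integer(max(memb))
  renum[memb[first]] <- seq_len(sum(first))
  lab[idx] <- renum[memb]
  lab
}

# Keep only the largest component (ties: smallest label id, i.e. first in
# scan order).
largest_component <- function(mask, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# Centre of mass (mean row, mean col) of a logical mask, real-valued.
mask_com <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  c(row = mean(pts[, 1L]), col = mean(pts[, 2L]))
}

# Pixel coordinates of a mask as an n x 2 (row, col) matrix in deterministic
# column-major scan order.
mask_coords <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  colnames(pts) <- c("row", "col")
  pts
}

disc_brush <- function(radius_px) {
  EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
}

# Morphological opening-then-closing with a disc; radius 0 is the identity.
open_close <- function(mask, radius_px) {
  if (radius_px <= 0) return(mask)
  b <- disc_brush(radius_px)
  m <- EBImage::closing(EBImage::opening(mask * 1, b), b)
  m > 0.5
}

# Euclidean distance transform: distance of each foreground pixel to the
# nearest background pixel (0 on background). The image border is not treated
# as background.
dist_transform <- function(mask) {
  EBImage::distmap(mask * 1)
}

# Distance of every pixel to the nearest TRUE pixel of `target` (0 on target).
dist_to_set <- function(target) {
  EBImage::distmap((!target) * 1)
}

# Run `expr` with a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

cond_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "maizecfi_error")))
}
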