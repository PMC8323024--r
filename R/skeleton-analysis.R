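# Skeletonization of the plant mask and classification of its topological
# landmarks. The skeleton is the one-pixel-wide wireframe from which leaf
# tips, branch points (nodes) and the stem extremities are read.

#' Skeletonize a binary mask
#'
#' Topology-preserving thinning (Zhang-Suen, with a final pass that dissolves
#' residual 2x2 blocks while keeping connectivity), yielding a one-pixel-wide
#' 8-connected skeleton of the mask.
#'
#' @param mask logical matrix, a single connected component.
#' @return Logical skeleton matrix of the same shape.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) cond_error("cannot skeletonize an empty mask", "input_error")
  m <- mask
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      del <- zs_deletable(m, phase)
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  minimal_thin(m)
}

# One Zhang-Suen sub-iteration: which pixels are deletable.
zs_deletable <- function(m, phase) {
  p2 <- px_shift(m, -1L, 0L); p3 <- px_shift(m, -1L, 1L)
  p4 <- px_shift(m, 0L, 1L);  p5 <- px_shift(m, 1L, 1L)
  p6 <- px_shift(m, 1L, 0L);  p7 <- px_shift(m, 1L, -1L)
  p8 <- px_shift(m, 0L, -1L); p9 <- px_shift(m, -1L, -1L)
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
       (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
  base <- m & b >= 2L & b <= 6L & a == 1L
  if (phase == 1L) base & !(p2 & p4 & p6) & !(p4 & p6 & p8)
  else             base & !(p2 & p4 & p8) & !(p2 & p6 & p8)
}

# Ring of 8 neighbour offsets in cyclic order N, NE, E, SE, S, SW, W, NW,
# with precomputed adjacency between ring positions (as pixels).
RING_OFFSETS <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
                      dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))
RING_ADJ8 <- outer(seq_len(8L), seq_len(8L), function(i, j)
  i != j & abs(RING_OFFSETS[i, 1L] - RING_OFFSETS[j, 1L]) <= 1L &
    abs(RING_OFFSETS[i, 2L] - RING_OFFSETS[j, 2L]) <= 1L)
RING_ADJ4 <- outer(seq_len(8L), seq_len(8L), function(i, j)
  abs(RING_OFFSETS[i, 1L] - RING_OFFSETS[j, 1L]) +
    abs(RING_OFFSETS[i, 2L] - RING_OFFSETS[j, 2L]) == 1L)
RING_IS_EDGE_NEIGHBOR <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)

# Sequential shrink of a Zhang-Suen output to a minimal 8-connected skeleton:
# deletes simple pixels (Yokoi test) that are not endpoints, removing the
# staircase corners and 2x2 blocks the parallel pass leaves behind. Scan
# order is deterministic, so the result is reproducible.
minimal_thin <- function(m) {
  repeat {
    changed <- FALSE
    pts <- which(m, arr.ind = TRUE)
    pts <- pts[order(pts[, 1L], pts[, 2L]), , drop = FALSE]
    for (i in seq_len(nrow(pts))) {
      r <- pts[i, 1L]; c <- pts[i, 2L]
      if (simple_nonend_pixel(m, r, c)) {
        m[r, c] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# TRUE when (r, c) is 8-simple (its foreground ring neighbours form one
# 8-connected set and the background 4-neighbourhood stays one piece) and
# has at least two foreground neighbours (so endpoints survive).
simple_nonend_pixel <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  rr <- r + RING_OFFSETS[, 1L]; cc <- c + RING_OFFSETS[, 2L]
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  fg <- logical(8L)
  fg[ok] <- m[cbind(rr[ok], cc[ok])]
  b <- sum(fg)
  if (b < 2L) return(FALSE)
  if (ring_components(fg, RING_ADJ8) != 1L) return(FALSE)
  bg <- !fg
  if (!any(bg & RING_IS_EDGE_NEIGHBOR)) return(FALSE)   # would create a hole
  ring_components_touching(bg, RING_ADJ4, RING_IS_EDGE_NEIGHBOR) == 1L
}

ring_components <- function(present, adj) {
  nodes <- which(present)
  if (length(nodes) == 0L) return(0L)
  seen <- logical(8L)
  ncomp <- 0L
  for (s in nodes) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    stack <- s
    while (length(stack) > 0L) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, nodes[adj[v, nodes] & !seen[nodes]])
    }
  }
  ncomp
}

# Number of 4-connected background components that contain a 4-neighbour.
ring_components_touching <- function(present, adj, is_edge) {
  nodes <- which(present)
  if (length(nodes) == 0L) return(0L)
  seen <- logical(8L)
  ncomp <- 0L
  for (s in nodes) {
    if (seen[s]) next
    comp <- integer(0)
    stack <- s
    while (length(stack) > 0L) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, nodes[adj[v, nodes] & !seen[nodes]])
    }
    if (any(is_edge[comp])) ncomp <- ncomp + 1L
  }
  ncomp
}

#' Trim short terminal branches (spurs) from a skeleton
#'
#' Thinning artifacts show up as short twigs hanging off the main wireframe.
#' Each terminal branch is walked from its endpoint to the nearest branch
#' point; branches whose pixel count (branch point excluded) is smaller than
#' `spur_length_px` are deleted. The pass repeats until no spur remains, so
#' branch points that lose all but two of their arms degrade gracefully.
#' `spur_length_px = 0` returns the skeleton unchanged; a skeleton with no
#' branch point (a bare path) is never trimmed.
#'
#' @param skel logical skeleton matrix.
#' @param spur_length_px non-negative integer.
#' @return Trimmed skeleton.
#' @export
trim_spurs <- function(skel, spur_length_px) {
  stopifnot(is.matrix(skel), is.logical(skel))
  if (spur_length_px <= 0L) return(skel)
  m <- skel
  repeat {
    deg <- neighbor_count(m)
    ends <- which(m & deg == 1L, arr.ind = TRUE)
    if (nrow(ends) == 0L) break
    ends <- ends[order(ends[, 1L], ends[, 2L]), , drop = FALSE]
    to_remove <- matrix(integer(), 0L, 2L)
    for (i in seq_len(nrow(ends))) {
      walk <- walk_branch(m, deg, ends[i, 1L], ends[i, 2L], spur_length_px)
      if (!is.null(walk)) to_remove <- rbind(to_remove, walk)
    }
    if (nrow(to_remove) == 0L) break
    m[to_remove] <- FALSE
  }
  # a removed spur can leave its base pixel as a redundant bump on the main
  # line (adjacent to 3+ line pixels); shrink back to a minimal skeleton
  minimal_thin(m)
}

# Walk from an endpoint along degree-2 pixels. Returns the branch pixels to
# delete if a branch point is reached in fewer than `limit` pixels, else NULL.
walk_branch <- function(m, deg, r, c, limit) {
  path <- matrix(c(r, c), 1L, 2L)
  prev <- c(NA_integer_, NA_integer_)
  repeat {
    if (nrow(path) >= limit) return(NULL)          # long enough: keep
    nxt <- NULL
    for (k in seq_len(nrow(NEIGHBOR_OFFSETS))) {
      rr <- r + NEIGHBOR_OFFSETS[k, 1L]; cc <- c + NEIGHBOR_OFFSETS[k, 2L]
      if (rr < 1L || cc < 1L || rr > nrow(m) || cc > ncol(m)) next
      if (!m[rr, cc]) next
      if (!is.na(prev[1L]) && rr == prev[1L] && cc == prev[2L]) next
      nxt <- c(rr, cc); break
    }
    if (is.null(nxt)) return(NULL)                 # isolated path end
    if (deg[nxt[1L], nxt[2L]] >= 3L) return(path)  # reached a branch point
    if (deg[nxt[1L], nxt[2L]] == 1L) return(NULL)  # other end of a bare path
    prev <- c(r, c); r <- nxt[1L]; c <- nxt[2L]
    path <- rbind(path, nxt)
  }
}

#' Classify skeleton landmarks
#'
#' Endpoints are skeleton pixels with exactly one neighbour; branch points
#' have three or more. Adjacent branch pixels are merged into clusters and
#' each cluster is represented by the member pixel nearest its centroid. The
#' stem start is the endpoint with the largest row (lowest in the image)
#' whose column lies within `midline_tolerance_frac` of the mask width from
#' the mask's half-area column — the column at which the cumulative
#' column-wise mask area reaches 50%. All other endpoints are leaf tips; in
#' particular a drooping tip that sits lower than the stem base but off the
#' midline stays a leaf tip. When no endpoint passes the midline test the
#' lowest endpoint is used and the record is flagged `stem_start_fallback`.
#'
#' @param skel trimmed logical skeleton.
#' @param mask the plant mask the skeleton came from.
#' @param config a [pipeline_config].
#' @return List of class `points_of_interest`: `leaf_tips` (n x 2 matrix),
#'   `branch_points` (m x 2 matrix), `stem_start` (length-2), `center_of_mass`
#'   (length-2, real), `flags` (character).
#' @export
find_landmarks <- function(skel, mask, config = pipeline_config()) {
  deg <- neighbor_count(skel)
  ends <- which(skel & deg == 1L, arr.ind = TRUE)
  colnames(ends) <- c("row", "col")
  ends <- ends[order(ends[, 1L], ends[, 2L]), , drop = FALSE]
  if (nrow(ends) == 0L)
    cond_error("skeleton has no endpoints", "no_endpoints")
  branch_px <- skel & deg >= 3L
  branch_points <- cluster_branch_points(branch_px)
  com <- mask_com(skel)
  flags <- character()

  # half-area column of the mask and tolerance band around it
  csum <- cumsum(colSums(mask))
  half_col <- which(csum >= csum[length(csum)] / 2)[1L]
  cols_present <- range(which(colSums(mask) > 0L))
  tol <- config$midline_tolerance_frac * (cols_present[2L] - cols_present[1L] + 1L)
  qualifying <- abs(ends[, 2L] - half_col) <= tol
  if (any(qualifying)) {
    q <- ends[qualifying, , drop = FALSE]
    stem_start <- q[order(-q[, 1L], q[, 2L])[1L], ]
  } else {
    stem_start <- ends[order(-ends[, 1L], ends[, 2L])[1L], ]
    flags <- c(flags, "stem_start_fallback")
  }
  start_idx <- which(ends[, 1L] == stem_start[1L] & ends[, 2L] == stem_start[2L])[1L]
  tips <- ends[-start_idx, , drop = FALSE]
  structure(list(leaf_tips = tips,
                 branch_points = branch_points,
                 stem_start = unname(stem_start),
                 center_of_mass = unname(com),
                 flags = flags),
            class = "points_of_interest")
}

# Merge 8-adjacent branch pixels; representative = member pixel nearest the
# cluster centroid (ties: smaller row, then col).
cluster_branch_points <- function(branch_px) {
  if (!any(branch_px)) return(matrix(integer(), 0L, 2L,
                                     dimnames = list(NULL, c("row", "col"))))
  lab <- label_components(branch_px, 8L)
  out <- t(vapply(seq_len(max(lab)), function(l) {
    pts <- which(lab == l, arr.ind = TRUE)
    ctr <- colMeans(pts)
    d2 <- (pts[, 1L] - ctr[1L])^2 + (pts[, 2L] - ctr[2L])^2
    pts[order(d2, pts[, 1L], pts[, 2L])[1L], ]
  }, integer(2L)))
  colnames(out) <- c("row", "col")
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

#' @export
print.points_of_interest <- function(x, ...) {
  cat(sprintf(
    "<points_of_interest: %d leaf tips, %d branch points, stem start (%d, %d)%s>\n",
    nrow(x$leaf_tips), nrow(x$branch_points), x$stem_start[1L], x$stem_start[2L],
    if (length(x$flags)) paste0(", flags: ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}
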