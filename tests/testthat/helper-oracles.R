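# Independent oracles used across the suite. Each is deliberately written as
# plain enumeration / a third-party graph library so it shares no code path
# with the implementation it checks.

# Exhaustive-search Otsu: for every candidate threshold t, split the pixels
# into {< t} and {>= t} and compute the between-class variance from raw
# class means; return the smallest maximizing t.
oracle_otsu <- function(px, bit_depth = 8L) {
  v <- as.vector(px)
  n <- length(v)
  ts <- integer(0)
  vbs <- numeric(0)
  for (t in 1:(2^bit_depth - 1L)) {
    bg <- v[v < t]
    fg <- v[v >= t]
    if (length(bg) == 0L || length(fg) == 0L) next
    w0 <- length(bg) / n
    ts <- c(ts, t)
    vbs <- c(vbs, w0 * (1 - w0) * (mean(bg) - mean(fg))^2)
  }
  # smallest t within a hair of the maximum (ties in exact arithmetic)
  min(ts[vbs >= max(vbs) * (1 - 1e-9)])
}

# Breadth-first distances on the skeleton pixel graph via igraph.
oracle_geodesic <- function(skel, source) {
  pts <- which(skel, arr.ind = TRUE)
  id <- matrix(NA_integer_, nrow(skel), ncol(skel))
  id[pts] <- seq_len(nrow(pts))
  edges <- NULL
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- pts[, 1] + dr; cc <- pts[, 2] + dc
    ok <- rr >= 1 & rr <= nrow(skel) & cc >= 1 & cc <= ncol(skel)
    nb <- rep(NA_integer_, nrow(pts))
    nb[ok] <- id[cbind(rr[ok], cc[ok])]
    keep <- !is.na(nb)
    if (any(keep)) edges <- rbind(edges, cbind(which(keep), nb[keep]))
  }
  if (is.null(edges)) {           # isolated pixel(s): no edges at all
    out <- matrix(NA_real_, nrow(skel), ncol(skel))
    out[pts] <- Inf
    out[source[1], source[2]] <- 0
    return(out)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(pts) - igraph::vcount(g)))
  d <- igraph::distances(g, v = id[source[1], source[2]])[1, ]
  out <- matrix(NA_real_, nrow(skel), ncol(skel))
  out[pts] <- d
  out
}

# Farthest-pair angle by brute force over ALL foreground pixels (not just
# hull vertices), with the same fold-into-[0,180) and min-angle tie-break.
oracle_farthest_angle <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  mx <- max(d2)
  hit <- which(d2 == mx & upper.tri(d2), arr.ind = TRUE)
  angs <- apply(hit, 1, function(ij) {
    a <- pts[ij[1], ]; b <- pts[ij[2], ]
    th <- atan2(-(b[1] - a[1]), b[2] - a[2]) * 180 / pi
    th <- th %% 180
    if (th > 180 - 1e-9) th <- 0
    th
  })
  min(angs)
}

# Random blob: union of a few random discs, guaranteed non-empty.
random_blob <- function(seed, h = 48L, w = 48L, n_disc = 5L) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, h, w)
    for (i in seq_len(n_disc)) {
      r0 <- sample(8:(h - 8), 1); c0 <- sample(8:(w - 8), 1)
      rad <- sample(2:6, 1)
      for (dr in -rad:rad) for (dc in -rad:rad)
        if (dr^2 + dc^2 <= rad^2) m[r0 + dr, c0 + dc] <- TRUE
    }
    m
  })
}

# Random small skeleton: thin the largest component of a random blob.
random_skeleton <- function(seed, h = 48L, w = 48L) {
  m <- random_blob(seed, h, w)
  lab <- maizecfi:::label_components(m, 8L)
  sizes <- tabulate(lab[lab > 0])
  skeletonize_mask(lab == which.max(sizes))
}

# Random grayscale test image mixing several intensity regimes.
random_gray <- function(seed, h = 64L, w = 64L) {
  withr::with_seed(seed, {
    kind <- sample(3, 1)
    px <- switch(kind,
      matrix(sample(0:255, h * w, replace = TRUE), h, w),
      matrix(pmin(255, pmax(0, round(c(rnorm(h * w / 2, 60, 25),
                                       rnorm(h * w / 2, 190, 20))))), h, w),
      matrix(pmin(255, pmax(0, round(rexp(h * w, 1 / 40)))), h, w))
    gray_image(px, 8L)
  })
}
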