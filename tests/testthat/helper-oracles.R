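# Independent oracles and fixture generators. These deliberately use
# different algorithms from the package internals (per-pixel ray casting
# instead of scanline, exhaustive partition search instead of hierarchical
# merging) so they can serve as cross-checks.

# Per-pixel even-odd point-in-polygon oracle with explicit boundary test:
# returns a height x width 0/1 matrix, pixel (x, y) at [y + 1, x + 1].
oracle_rasterize <- function(poly, width, height) {
  v <- unclass(herdmotion::as_polygon(poly))
  n <- nrow(v)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  on_segment <- function(px, py) {
    for (k in seq_len(n)) {
      dx <- x2[k] - x1[k]; dy <- y2[k] - y1[k]
      len2 <- dx^2 + dy^2
      if (len2 == 0) next
      t <- ((px - x1[k]) * dx + (py - y1[k]) * dy) / len2
      if (t < -1e-9 || t > 1 + 1e-9) next
      d <- abs((px - x1[k]) * dy - (py - y1[k]) * dx) / sqrt(len2)
      if (d < 1e-7) return(TRUE)
    }
    FALSE
  }
  m <- matrix(0L, nrow = height, ncol = width)
  for (py in 0:(height - 1)) {
    for (px in 0:(width - 1)) {
      crossings <- 0L
      for (k in seq_len(n)) {
        if ((y1[k] > py) != (y2[k] > py)) {
          xint <- x1[k] + (py - y1[k]) * (x2[k] - x1[k]) / (y2[k] - y1[k])
          if (px < xint) crossings <- crossings + 1L
        }
      }
      if (crossings %% 2L == 1L || on_segment(px, py)) m[py + 1, px + 1] <- 1L
    }
  }
  m
}

# Random simple (star-shaped) polygon: sorted angles, positive radii.
random_polygon <- function(n = 12, center = c(0, 0), rmin = 2, rmax = 8) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# Random convex polygon (convex hull of points in a disc of given radius).
random_convex_polygon <- function(n = 40, center = c(0, 0), radius = 10) {
  th <- stats::runif(n, 0, 2 * pi)
  r <- radius * sqrt(stats::runif(n))
  pts <- cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  pts[rev(grDevices::chull(pts)), , drop = FALSE]
}

# Exhaustive 2-partition oracle: minimizes the larger within-cluster
# diameter over all two-block partitions.
oracle_two_partition <- function(pts) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  best <- NULL; best_obj <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    lab <- c(1L, as.integer(intToBits(code))[1:(n - 1)] + 1L)
    diam <- function(g) if (sum(lab == g) < 2) 0 else max(d[lab == g, lab == g])
    obj <- max(diam(1L), diam(2L))
    if (obj < best_obj) { best_obj <- obj; best <- lab }
  }
  best
}

# Canonical form of a partition label vector: relabel clusters in order of
# first appearance, so partitions compare independently of label identity.
canonical_partition <- function(labels) {
  match(labels, unique(labels))
}

# Small in-memory recovery: spatial-moment centres -> k = 1 agglomerative
# group point -> displacement series, for a simulated scene (same math as
# the pipeline, without the file round trip).
recover_track <- function(scene) {
  W <- scene$config$width; H <- scene$config$height
  n_frames <- nrow(scene$frames)
  xs <- numeric(n_frames); ys <- numeric(n_frames); np <- integer(n_frames)
  for (t in seq_len(n_frames)) {
    ctr <- scene$centers[scene$centers$frame_id == scene$frames$frame_id[t], ]
    det <- which(ctr$detected)
    if (!length(det)) { xs[t] <- NA; ys[t] <- NA; np[t] <- 0L; next }
    pts <- t(vapply(det, function(i)
      herdmotion::centroid_spatial_moment(scene$polygons[[t]][[i]], W, H),
      numeric(2)))
    gp <- herdmotion::group_center(data.frame(x = pts[, 1], y = pts[, 2]),
                                   timestamp = scene$frames$timestamp[t],
                                   frame_id = scene$frames$frame_id[t])
    xs[t] <- gp$x; ys[t] <- gp$y; np[t] <- gp$n_pigs
  }
  data.frame(frame_id = scene$frames$frame_id,
             timestamp = scene$frames$timestamp,
             x = xs, y = ys, n_pigs = np)
}
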