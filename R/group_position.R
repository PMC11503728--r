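# One group position per frame: agglomerative clustering of per-pig centres,
# plus a runtime benchmark harness for alternative clusterers.

#' Agglomerative (bottom-up hierarchical) clustering of 2-D points
#'
#' Starts from singleton clusters and successively merges the pair of
#' clusters with the smallest linkage distance until `n_clusters` remain.
#' Distances are Euclidean; inter-cluster distances are maintained with the
#' Lance-Williams update for the chosen linkage (Ward operates on squared
#' distances). Ties are broken deterministically by the lexicographically
#' smallest pair of cluster indices (clusters are indexed by their lowest
#' original member), so a run is reproducible for a given input order.
#'
#' @param points An `n x 2` numeric matrix (or data frame with `x`, `y`).
#' @param n_clusters Number of clusters to keep, `1 <= n_clusters <= n`.
#' @param linkage One of `"ward"` (default), `"single"`, `"complete"`,
#'   `"average"`.
#' @return Integer vector of cluster labels in `1..n_clusters`; labels are
#'   assigned in order of each cluster's lowest original member index.
#' @examples
#' pts <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
#' agglomerative_cluster(pts, n_clusters = 2)
#' @export
agglomerative_cluster <- function(points,
                                  n_clusters = 1L,
                                  linkage = c("ward", "single", "complete", "average")) {
  linkage <- match.arg(linkage)
  pts <- .as_points(points)
  n <- nrow(pts)
  if (n < 1L) stop("empty point list", call. = FALSE)
  if (n_clusters < 1L || n_clusters > n)
    stop(sprintf("n_clusters must be in 1..%d", n), call. = FALSE)

  # membership: cluster id of each point; active cluster ids are the lowest
  # original member index of each live cluster
  member <- seq_len(n)
  size <- rep(1L, n)
  d <- as.matrix(stats::dist(pts))
  if (linkage == "ward") d <- d^2
  diag(d) <- Inf
  active <- rep(TRUE, n)

  n_live <- n
  while (n_live > n_clusters) {
    # smallest distance among active pairs; tie -> smallest (i, j), i < j
    ids <- which(active)
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (ai in seq_along(ids)) {
      i <- ids[ai]
      if (ai == length(ids)) break
      for (bi in (ai + 1L):length(ids)) {
        j <- ids[bi]
        if (d[i, j] < bestd - 1e-12) {
          bestd <- d[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    ni <- size[i]; nj <- size[j]
    # Lance-Williams update of d(i U j, k) for every other active cluster k
    for (k in ids) {
      if (k == i || k == j) next
      nk <- size[k]
      dik <- d[i, k]; djk <- d[j, k]
      dn <- switch(linkage,
        single   = min(dik, djk),
        complete = max(dik, djk),
        average  = (ni * dik + nj * djk) / (ni + nj),
        ward     = ((ni + nk) * dik + (nj + nk) * djk - nk * d[i, j]) /
                   (ni + nj + nk)
      )
      d[i, k] <- dn; d[k, i] <- dn
    }
    size[i] <- ni + nj
    active[j] <- FALSE
    d[j, ] <- Inf; d[, j] <- Inf
    member[member == j] <- i
    n_live <- n_live - 1L
  }
  match(member, sort(unique(member)))
}

.as_points <- function(points) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L, byrow = TRUE)
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 2L) stop("points must have two columns", call. = FALSE)
  pts
}

## ---------------------------------------------------------------------------
## Comparison clusterers (benchmark harness only; the monitoring method itself
## always uses agglomerative clustering)

# kmeans with ++-style farthest-point-probability seeding, then stats::kmeans.
.kmeanspp <- function(pts, k) {
  n <- nrow(pts)
  if (k >= n) return(seq_len(n))
  ctr_idx <- integer(k)
  ctr_idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums((pts - matrix(pts[ctr_idx[1L], ], n, 2L, byrow = TRUE))^2)
  if (k > 1L) for (m in 2L:k) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    ctr_idx[m] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, rowSums((pts - matrix(pts[ctr_idx[m], ], n, 2L, byrow = TRUE))^2))
  }
  fit <- suppressWarnings(
    stats::kmeans(pts, centers = pts[ctr_idx, , drop = FALSE], iter.max = 50L))
  fit$cluster
}

# Minimal DBSCAN for small 2-D point sets. eps defaults to 1.5x the median
# pairwise distance so a loosely gathered herd forms one cluster; noise
# points get their own singleton labels so that every point is labelled.
.dbscan_simple <- function(pts, eps = NULL, min_pts = 2L) {
  n <- nrow(pts)
  if (n == 1L) return(1L)
  dm <- as.matrix(stats::dist(pts))
  if (is.null(eps)) eps <- 1.5 * stats::median(dm[upper.tri(dm)])
  labels <- rep(0L, n)
  core <- rowSums(dm <= eps) >= min_pts  # includes self
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      q <- queue[1L]; queue <- queue[-1L]
      nb <- which(dm[q, ] <= eps)
      for (b in nb) {
        if (labels[b] == 0L) {
          labels[b] <- cl
          if (core[b]) queue <- c(queue, b)
        }
      }
    }
  }
  for (i in which(labels == 0L)) { cl <- cl + 1L; labels[i] <- cl }
  labels
}

# Minimal mean-shift with a Gaussian kernel; modes closer than bandwidth / 4
# are merged into one cluster.
.meanshift_simple <- function(pts, bandwidth = NULL, max_iter = 100L, tol = 1e-4) {
  n <- nrow(pts)
  if (n == 1L) return(1L)
  dm <- as.matrix(stats::dist(pts))
  if (is.null(bandwidth)) bandwidth <- max(stats::median(dm[upper.tri(dm)]), 1e-8)
  modes <- pts
  for (i in seq_len(n)) {
    m <- pts[i, ]
    for (it in seq_len(max_iter)) {
      w <- exp(-rowSums((pts - matrix(m, n, 2L, byrow = TRUE))^2) / (2 * bandwidth^2))
      m_new <- colSums(pts * w) / sum(w)
      if (sqrt(sum((m_new - m)^2)) < tol * bandwidth) { m <- m_new; break }
      m <- m_new
    }
    modes[i, ] <- m
  }
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    cl <- cl + 1L
    same <- sqrt(rowSums((modes - matrix(modes[i, ], n, 2L, byrow = TRUE))^2)) <
      bandwidth / 4
    labels[same & labels == 0L] <- cl
  }
  labels
}

.gmm_cluster <- function(pts, k) {
  if (!requireNamespace("mclust", quietly = TRUE))
    stop("the 'gmm' clusterer requires the mclust package", call. = FALSE)
  if (nrow(pts) <= k) return(seq_len(nrow(pts)))
  fit <- suppressWarnings(
    mclust::Mclust(pts, G = k, modelNames = "VII", verbose = FALSE))
  if (is.null(fit)) return(rep(1L, nrow(pts)))  # degenerate data; one cluster
  as.integer(fit$classification)
}

.CLUSTERERS <- c("agglomerative", "kmeans++", "dbscan", "meanshift", "gmm")

.run_clusterer <- function(method, pts, k) {
  n <- nrow(pts)
  if (n == 1L) return(1L)
  switch(method,
    "agglomerative" = agglomerative_cluster(pts, n_clusters = min(k, n)),
    "kmeans++"      = .kmeanspp(pts, min(k, n)),
    "dbscan"        = .dbscan_simple(pts),
    "meanshift"     = .meanshift_simple(pts),
    "gmm"           = .gmm_cluster(pts, min(k, n)),
    stop(sprintf("unknown clusterer id '%s'", method), call. = FALSE)
  )
}

#' Condense per-pig centres into one group position
#'
#' Clusters the per-frame pig centre points and returns a single group
#' position. With `n_clusters = 1` (the default, and the configuration used
#' for monitoring) the group point is exactly the arithmetic mean of the
#' member points; with `n_clusters > 1` it is the unweighted mean of the
#' per-cluster means. An empty frame yields a gap marker (`n_pigs = 0`,
#' coordinates `NA`).
#'
#' @param centers Data frame with columns `x`, `y` and optionally
#'   `confidence`; one row per detected pig. May have zero rows.
#' @param timestamp `POSIXct` timestamp of the frame (kept in the output).
#' @param method Clusterer id, one of
#'   `"agglomerative"`, `"kmeans++"`, `"dbscan"`, `"meanshift"`, `"gmm"`.
#' @param n_clusters Number of clusters formed before averaging (default 1).
#' @param frame_id Frame identifier carried through to the output.
#' @param confidence_weighted If `TRUE` and a `confidence` column is present,
#'   cluster means are confidence-weighted. Default `FALSE`: detections are
#'   weighted equally.
#' @return One-row data frame `frame_id, timestamp, x, y, n_pigs`.
#' @export
group_center <- function(centers, timestamp = as.POSIXct(NA),
                         method = "agglomerative", n_clusters = 1L,
                         frame_id = NA_character_,
                         confidence_weighted = FALSE) {
  if (!method %in% .CLUSTERERS)
    stop(sprintf("unknown clusterer id '%s' (choose from: %s)",
                 method, paste(.CLUSTERERS, collapse = ", ")), call. = FALSE)
  n <- if (is.null(centers)) 0L else nrow(centers)
  if (n == 0L) {
    return(data.frame(frame_id = frame_id, timestamp = timestamp,
                      x = NA_real_, y = NA_real_, n_pigs = 0L))
  }
  pts <- .as_points(centers)
  w <- if (confidence_weighted && !is.null(centers$confidence) &&
           !anyNA(centers$confidence)) centers$confidence else rep(1, n)
  labels <- .run_clusterer(method, pts, min(n_clusters, n))
  mx <- tapply(pts[, 1L] * w, labels, sum) / tapply(w, labels, sum)
  my <- tapply(pts[, 2L] * w, labels, sum) / tapply(w, labels, sum)
  data.frame(frame_id = frame_id, timestamp = timestamp,
             x = mean(mx), y = mean(my), n_pigs = n)
}

# Wall-clock timing that is guaranteed positive: the call is repeated in an
# inner loop whose length doubles until the elapsed time passes min_time,
# then the per-call time is the mean.
.time_call <- function(fn, min_time = 1e-4) {
  reps <- 1L
  repeat {
    t0 <- Sys.time()
    for (r in seq_len(reps)) fn()
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (dt >= min_time || reps >= 2^20) return(max(dt, 1e-9) / reps)
    reps <- reps * 2L
  }
}

#' Benchmark clustering algorithms on per-frame point sets
#'
#' Times each requested clusterer on each frame's point set, averaging over
#' `repetitions` passes. Intended to reproduce the shape of a
#' runtime-per-frame comparison; which algorithm wins is hardware-dependent
#' and the table makes no such claim.
#'
#' @param frames List of `n x 2` point matrices (one per frame).
#' @param algorithms Character vector drawn from
#'   `c("agglomerative", "kmeans++", "dbscan", "meanshift", "gmm")`.
#' @param repetitions Number of timing repetitions (default 30).
#' @param n_clusters Cluster count for the clusterers that take one.
#' @return Data frame with one row per `(algorithm, frame)` holding the
#'   median per-frame runtime in milliseconds across repetitions, plus one
#'   `"total"` row per algorithm with the summed runtime (mean over
#'   repetitions) across all frames.
#' @export
benchmark_clusterers <- function(frames, algorithms, repetitions = 30L,
                                 n_clusters = 1L) {
  if (length(algorithms) == 0L) stop("empty algorithm list", call. = FALSE)
  bad <- setdiff(algorithms, .CLUSTERERS)
  if (length(bad))
    stop(sprintf("unknown clusterer id(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  stopifnot(repetitions >= 1, length(frames) >= 1)
  rows <- list()
  for (alg in algorithms) {
    per_frame <- matrix(NA_real_, nrow = length(frames), ncol = repetitions)
    for (f in seq_along(frames)) {
      pts <- .as_points(frames[[f]])
      for (r in seq_len(repetitions)) {
        per_frame[f, r] <- .time_call(function() .run_clusterer(alg, pts, n_clusters))
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      algorithm = alg,
      frame = as.character(seq_along(frames)),
      runtime_ms = apply(per_frame, 1L, stats::median) * 1000
    )
    rows[[length(rows) + 1L]] <- data.frame(
      algorithm = alg,
      frame = "total",
      runtime_ms = mean(colSums(per_frame)) * 1000
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
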