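# Polygon geometry and centre-point algorithms.
#
# Coordinate convention used throughout the package: origin at the top-left
# of the image, x increases rightward, y increases downward, pixel centres sit
# at integer coordinates, 0-based. A polygon is an ordered set of vertices,
# implicitly closed (the last vertex connects back to the first).

.EPS <- 1e-9

#' Construct and validate a polygon
#'
#' A polygon is stored as an `n x 2` numeric matrix of `(x, y)` vertex
#' coordinates in pixels, implicitly closed. Validation removes consecutive
#' duplicate vertices (including the wrap-around pair) and requires at least
#' three distinct vertices and a non-zero enclosed area. The *original*
#' vertex list (duplicates included) is kept: vertex-weighted operations such
#' as [centroid_mean()] intentionally see repeated vertices.
#'
#' @param x An `n x 2` numeric matrix, a data frame with columns `x` and `y`,
#'   or a numeric vector of interleaved `x1, y1, x2, y2, ...` coordinates.
#' @return The vertex matrix with class `"polygon2d"`.
#' @examples
#' as_polygon(rbind(c(0, 0), c(4, 0), c(4, 2), c(0, 2)))
#' @export
as_polygon <- function(x) {
  if (inherits(x, "polygon2d")) return(x)
  if (is.data.frame(x)) x <- cbind(x$x, x$y)
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) %% 2L != 0L)
      stop("interleaved coordinate vector must have even length", call. = FALSE)
    x <- matrix(x, ncol = 2L, byrow = TRUE)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("polygon must have two coordinate columns", call. = FALSE)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("polygon vertices must be finite", call. = FALSE)
  dedup <- .dedup_vertices(x)
  if (nrow(dedup) < 3L)
    stop("invalid geometry: fewer than 3 distinct vertices", call. = FALSE)
  if (abs(.signed_area(dedup)) <= .EPS)
    stop("invalid geometry: polygon has zero area", call. = FALSE)
  structure(x, class = "polygon2d", dimnames = NULL)
}

# Drop consecutive duplicates, then the wrap-around duplicate if present.
.dedup_vertices <- function(v) {
  n <- nrow(v)
  if (n < 2L) return(v)
  keep <- c(TRUE, rowSums(abs(v[-1L, , drop = FALSE] - v[-n, , drop = FALSE])) > .EPS)
  v <- v[keep, , drop = FALSE]
  n <- nrow(v)
  if (n > 1L && all(abs(v[n, ] - v[1L, ]) <= .EPS)) v <- v[-n, , drop = FALSE]
  v
}

# Shoelace signed area (positive for counter-clockwise order in a y-up frame;
# with y-down image coordinates the sign flips, only |A| is used for checks).
.signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon area
#'
#' Absolute shoelace area of the closed polygon, in square pixels.
#'
#' @param poly A polygon acceptable to [as_polygon()].
#' @return A single non-negative number.
#' @export
polygon_area <- function(poly) {
  v <- .dedup_vertices(unclass(as_polygon(poly)))
  abs(.signed_area(v))
}

## ---------------------------------------------------------------------------
## Scanline rasterization
##
## Fill rule: a pixel belongs to the mask iff its centre lies inside the
## closed polygon under the even-odd rule; centres exactly on an edge count
## as inside. Implemented as a vectorized scanline: for every integer row y
## the edge crossings are computed under the half-open rule
## min(y1,y2) <= y < max(y1,y2), sorted, and consecutive pairs delimit closed
## x-intervals. Closed intervals plus two cheap extra passes (horizontal edges
## lying exactly on an integer row; vertices at exact pixel centres) realise
## the boundary-inclusive rule: any pixel centre on a non-horizontal edge is
## necessarily a crossing at its own row and therefore an interval endpoint.

# Disjoint per-row pixel intervals of the filled polygon clipped to a
# width x height frame. Returns a data.frame(y, lo, hi) of 0-based pixel
# columns lo..hi (inclusive) per 0-based row y.
.polygon_row_intervals <- function(poly, width, height) {
  v <- .dedup_vertices(unclass(as_polygon(poly)))
  n <- nrow(v)
  x1 <- v[, 1L]; y1 <- v[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])

  ylo_e <- pmin(y1, y2); yhi_e <- pmax(y1, y2)
  horiz <- abs(y1 - y2) <= .EPS

  out_y <- integer(0); out_lo <- integer(0); out_hi <- integer(0)

  ## even-odd crossings of non-horizontal edges (fully vectorized)
  e <- which(!horiz)
  if (length(e)) {
    r0 <- pmax(ceiling(ylo_e[e] - .EPS), 0)
    r1 <- pmin(ceiling(yhi_e[e] - .EPS) - 1, height - 1L)
    cnt <- pmax(r1 - r0 + 1L, 0L)
    if (sum(cnt) > 0L) {
      has <- cnt > 0L
      eid <- rep(e[has], cnt[has])
      rows <- rep(r0[has], cnt[has]) + sequence(cnt[has]) - 1
      xs <- x1[eid] + (rows - y1[eid]) * (x2[eid] - x1[eid]) / (y2[eid] - y1[eid])
      ord <- order(rows, xs)
      rows <- rows[ord]; xs <- xs[ord]
      # crossings per row are even under the half-open rule; consecutive
      # pairs delimit inside spans (rows with a numerically odd count are
      # degenerate and dropped defensively)
      rl <- rle(rows)
      len_of <- rep(rl$lengths, rl$lengths)
      pos <- sequence(rl$lengths)
      keep <- len_of %% 2L == 0L
      odd <- keep & pos %% 2L == 1L
      evn <- keep & pos %% 2L == 0L
      a <- xs[odd]; b <- xs[evn]; ry <- rows[odd]
      lo <- pmax(ceiling(a - 1e-7), 0)
      hi <- pmin(floor(b + 1e-7), width - 1L)
      ok <- hi >= lo
      out_y <- as.integer(ry[ok])
      out_lo <- as.integer(lo[ok])
      out_hi <- as.integer(hi[ok])
    }
  }

  ## horizontal edges exactly on an integer row are boundary, hence inside
  h <- which(horiz & abs(y1 - round(y1)) <= 1e-7)
  for (i in h) {
    yy <- as.integer(round(y1[i]))
    if (yy < 0L || yy > height - 1L) next
    lo <- max(ceiling(min(x1[i], x2[i]) - 1e-7), 0)
    hi <- min(floor(max(x1[i], x2[i]) + 1e-7), width - 1L)
    if (hi >= lo) {
      out_y <- c(out_y, yy); out_lo <- c(out_lo, as.integer(lo))
      out_hi <- c(out_hi, as.integer(hi))
    }
  }

  ## vertices landing exactly on a pixel centre
  vint <- which(abs(x1 - round(x1)) <= 1e-7 & abs(y1 - round(y1)) <= 1e-7)
  for (i in vint) {
    xx <- as.integer(round(x1[i])); yy <- as.integer(round(y1[i]))
    if (xx >= 0L && xx <= width - 1L && yy >= 0L && yy <= height - 1L) {
      out_y <- c(out_y, yy); out_lo <- c(out_lo, xx); out_hi <- c(out_hi, xx)
    }
  }

  if (!length(out_y)) return(data.frame(y = integer(0), lo = integer(0), hi = integer(0)))
  .merge_row_intervals(out_y, out_lo, out_hi, width)
}

# Union of possibly overlapping integer intervals, per row (vectorized).
# Rows are mapped onto one axis by a per-row offset larger than any span,
# so a single sweep merges everything; adjacency (lo == prev_hi + 1) merges
# too, which leaves the pixel set unchanged.
.merge_row_intervals <- function(y, lo, hi, width) {
  key <- as.numeric(y) * (width + 2)
  lo2 <- lo + key; hi2 <- hi + key
  ord <- order(lo2, hi2)
  lo2 <- lo2[ord]; hi2 <- hi2[ord]
  n <- length(lo2)
  cm <- cummax(hi2)
  new_grp <- c(TRUE, lo2[-1L] > cm[-n] + 1)
  ends <- c(which(new_grp)[-1L] - 1L, n)
  starts <- which(new_grp)
  lo_m <- lo2[starts]; hi_m <- cm[ends]
  y_m <- floor(lo_m / (width + 2))
  data.frame(y = as.integer(y_m),
             lo = as.integer(lo_m - y_m * (width + 2)),
             hi = as.integer(hi_m - y_m * (width + 2)))
}

#' Rasterize a polygon into a binary mask
#'
#' Fills the closed polygon onto a `width x height` pixel grid. A pixel is set
#' iff its centre (at integer coordinates, 0-based) lies inside the polygon
#' under the even-odd rule; centres exactly on an edge count as inside.
#' Vertices may lie outside the frame; the mask is clipped to the frame.
#'
#' @param poly A polygon acceptable to [as_polygon()].
#' @param width,height Frame dimensions in pixels (>= 1).
#' @return A `raster_mask` object: list with `width`, `height` and an
#'   integer `intensity` matrix of 0/1 values with `height` rows and `width`
#'   columns; `intensity[y + 1, x + 1]` is the pixel at `(x, y)`.
#' @seealso [spatial_moments()], [centroid_spatial_moment()]
#' @export
rasterize_polygon <- function(poly, width, height) {
  stopifnot(width >= 1, height >= 1)
  iv <- .polygon_row_intervals(poly, as.integer(width), as.integer(height))
  m <- matrix(0L, nrow = height, ncol = width)
  if (nrow(iv)) {
    for (k in seq_len(nrow(iv))) m[iv$y[k] + 1L, (iv$lo[k]:iv$hi[k]) + 1L] <- 1L
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 intensity = m), class = "raster_mask")
}

#' Spatial moments of a binary mask
#'
#' Computes the raw image moments `m_ji = sum_{x,y} I(x, y) * x^j * y^i` for
#' `(j, i)` in `{(0,0), (1,0), (0,1)}` over a binary raster. `m00` is the
#' number of set pixels; `m10 / m00` and `m01 / m00` give the mass centroid.
#'
#' @param mask A `raster_mask` from [rasterize_polygon()], or a plain 0/1
#'   matrix (rows = y, columns = x, 0-based pixel indices).
#' @return A list with components `m00`, `m10`, `m01`. An all-zero mask
#'   returns all-zero moments.
#' @export
spatial_moments <- function(mask) {
  m <- if (inherits(mask, "raster_mask")) mask$intensity else as.matrix(mask)
  if (!all(m %in% c(0L, 1L))) stop("mask values must be 0 or 1", call. = FALSE)
  xs <- 0:(ncol(m) - 1L); ys <- 0:(nrow(m) - 1L)
  list(m00 = sum(m),
       m10 = sum(colSums(m) * xs),
       m01 = sum(rowSums(m) * ys))
}

#' Centre point from spatial moments of the rasterized contour
#'
#' The contour is filled onto the pixel grid (see [rasterize_polygon()] for
#' the fill rule) and the centre is the mass centroid of the resulting binary
#' mask, `(m10 / m00, m01 / m00)`. Because every interior pixel carries equal
#' weight, the centre responds to the *area* of the shape rather than to the
#' placement of contour vertices, which is what makes it stable against thin
#' appendages such as the legs of a lying pig.
#'
#' For speed the moments are accumulated from the scanline spans directly;
#' the result is identical to `spatial_moments(rasterize_polygon(...))`.
#'
#' @param poly A polygon acceptable to [as_polygon()].
#' @param frame_width,frame_height Frame dimensions in pixels; the fill is
#'   clipped to the frame.
#' @return Named numeric vector `c(x = , y = )`.
#' @export
centroid_spatial_moment <- function(poly, frame_width, frame_height) {
  stopifnot(frame_width >= 1, frame_height >= 1)
  iv <- .polygon_row_intervals(poly, as.integer(frame_width), as.integer(frame_height))
  if (!nrow(iv))
    stop("empty mask: contour covers no pixel centre within the frame", call. = FALSE)
  cnt <- iv$hi - iv$lo + 1L
  m00 <- sum(cnt)
  m10 <- sum((iv$lo + iv$hi) * cnt / 2)
  m01 <- sum(iv$y * cnt)
  c(x = m10 / m00, y = m01 / m00)
}

#' Mean-coordinate centre point
#'
#' Arithmetic mean of the polygon's vertex coordinates. Duplicate vertices
#' are deliberately *not* removed: every recorded contour point carries equal
#' weight, so regions annotated with many points (for a lying pig, the legs)
#' pull the centre toward them. That sensitivity is exactly what the other
#' centre algorithms are compared against.
#'
#' @param poly A polygon acceptable to [as_polygon()].
#' @return Named numeric vector `c(x = , y = )`.
#' @export
centroid_mean <- function(poly) {
  v <- unclass(as_polygon(poly))
  c(x = mean(v[, 1L]), y = mean(v[, 2L]))
}

#' Iterative least-squares centre point
#'
#' Minimizes `sum_k || v_k - c ||^2` over candidate centres `c` by gradient
#' descent from the first vertex. The analytic minimizer of this objective is
#' the vertex mean, so the iterate converges to [centroid_mean()]; the
#' iterative form is kept because the two approaches are benchmarked as
#' distinct candidate algorithms.
#'
#' @param poly A polygon acceptable to [as_polygon()].
#' @param tol Convergence tolerance on the step length, in pixels.
#' @param max_iter Maximum number of gradient steps.
#' @param validate If `FALSE`, skip polygon validation (the objective is well
#'   defined for any vertex multiset, e.g. all-identical vertices).
#' @return Named numeric vector `c(x = , y = )` with attribute `"iterations"`.
#' @export
centroid_least_squares <- function(poly, tol = 1e-9, max_iter = 10000L,
                                   validate = TRUE) {
  stopifnot(tol > 0, max_iter >= 1)
  v <- if (validate) unclass(as_polygon(poly)) else {
    p <- poly
    if (is.data.frame(p)) p <- cbind(p$x, p$y)
    matrix(as.numeric(p), ncol = 2L)
  }
  n <- nrow(v)
  ctr <- v[1L, ]
  eta <- 0.45 / n  # objective gradient is 2n(c - mean); eta < 1/(2n) contracts
  for (it in seq_len(max_iter)) {
    grad <- 2 * (n * ctr - colSums(v))
    step <- eta * grad
    ctr <- ctr - step
    if (sqrt(sum(step^2)) < tol)
      return(structure(c(x = ctr[1L], y = ctr[2L]), iterations = it))
  }
  stop(sprintf(
    "least-squares centre did not converge within %d iterations (last iterate %.6f, %.6f)",
    max_iter, ctr[1L], ctr[2L]), call. = FALSE)
}

#' Signed-area (shoelace) centroid
#'
#' Decomposes the polygon into a fan of signed triangles and area-weights
#' their centroids:
#' `A = 1/2 sum (x_k y_{k+1} - x_{k+1} y_k)`,
#' `Cx = 1/(6A) sum (x_k + x_{k+1})(x_k y_{k+1} - x_{k+1} y_k)` and
#' analogously for `Cy`. The result is independent of vertex orientation and
#' of vertex density along the boundary.
#'
#' @param poly A polygon acceptable to [as_polygon()]; must not
#'   self-intersect.
#' @return Named numeric vector `c(x = , y = )`.
#' @export
centroid_signed_area <- function(poly) {
  v <- .dedup_vertices(unclass(as_polygon(poly)))
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) <= .EPS) stop("invalid geometry: polygon has zero area", call. = FALSE)
  c(x = sum((x + xn) * cross) / (6 * a),
    y = sum((y + yn) * cross) / (6 * a))
}

#' Compute a pig centre point by a named algorithm
#'
#' Dispatch helper used by the pipeline: `"spatial_moment"` (default
#' throughout the package), `"mean"`, `"least_squares"` or `"signed_area"`.
#'
#' @param poly A polygon acceptable to [as_polygon()].
#' @param method Centre algorithm id.
#' @param frame_width,frame_height Frame dimensions, required by
#'   `"spatial_moment"`.
#' @return Named numeric vector `c(x = , y = )`.
#' @export
pig_center <- function(poly, method = c("spatial_moment", "mean",
                                        "least_squares", "signed_area"),
                       frame_width = NULL, frame_height = NULL) {
  method <- match.arg(method)
  switch(method,
    spatial_moment = {
      if (is.null(frame_width) || is.null(frame_height))
        stop("spatial_moment centre requires frame dimensions", call. = FALSE)
      centroid_spatial_moment(poly, frame_width, frame_height)
    },
    mean          = centroid_mean(poly),
    least_squares = centroid_least_squares(poly),
    signed_area   = centroid_signed_area(poly)
  )
}
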