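# Spatial occupancy of the pen: density grid with marginal histograms and
# quadrant-region counts compared between observation periods.

#' Occupancy density grid
#'
#' Bins group positions into an `nx x ny` grid over the frame. Bins are
#' half-open, `[k * W / nx, (k + 1) * W / nx)` in x (likewise in y), except
#' the last bin in each direction which is closed so points on the far edge
#' are kept. The density is the bin count divided by the *maximum* bin count,
#' so it ranges from 0 to 1 and the darkest cell marks the most-used resting
#' spot; set `prob = TRUE` to normalize to a probability mass instead.
#'
#' @param points Data frame or matrix of `(x, y)` positions in pixels; rows
#'   with `NA` are dropped.
#' @param geom A [frame_geometry()].
#' @param nx,ny Number of bins in x and y. The default `64 x 29`
#'   approximately matches the aspect ratio of a 3632 x 1632 frame.
#' @param prob If `TRUE`, normalize density to sum to one.
#' @return An object of class `"occupancy_grid"`: list with `nx`, `ny`,
#'   `counts` (`ny x nx` integer matrix, rows = y bins top-down), `density`,
#'   `x_marginal`, `y_marginal`, `n_points`.
#' @export
density_grid <- function(points, geom, nx = 64L, ny = 29L, prob = FALSE) {
  stopifnot(inherits(geom, "frame_geometry"), nx >= 1, ny >= 1)
  pts <- .as_points(stats::na.omit(.as_points(points)))
  n <- nrow(pts)
  if (n > 0L) {
    outside <- pts[, 1L] < 0 | pts[, 1L] > geom$W | pts[, 2L] < 0 | pts[, 2L] > geom$H
    if (any(outside)) {
      warning(sprintf("%d point(s) outside the frame were clipped to it", sum(outside)))
      pts[, 1L] <- pmin(pmax(pts[, 1L], 0), geom$W)
      pts[, 2L] <- pmin(pmax(pts[, 2L], 0), geom$H)
    }
  }
  ix <- pmin(floor(pts[, 1L] * nx / geom$W), nx - 1L)
  iy <- pmin(floor(pts[, 2L] * ny / geom$H), ny - 1L)
  counts <- matrix(0L, nrow = ny, ncol = nx)
  if (n > 0L) {
    tab <- table(factor(iy, levels = 0:(ny - 1L)), factor(ix, levels = 0:(nx - 1L)))
    counts <- matrix(as.integer(tab), nrow = ny, ncol = nx)
  }
  density <- if (n == 0L) matrix(0, ny, nx)
             else if (prob) counts / n
             else counts / max(counts)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 counts = counts, density = density,
                 x_marginal = as.integer(colSums(counts)),
                 y_marginal = as.integer(rowSums(counts)),
                 n_points = n),
            class = "occupancy_grid")
}

#' Quadrant region counts
#'
#' Splits the frame into four equal regions and counts the group positions
#' falling in each. Region convention (printed in every output header):
#' `A` = top-left (`x < W/2, y < H/2`), `B` = top-right, `C` = bottom-left,
#' `D` = bottom-right; boundaries follow the half-open rule (`x >= W/2`
#' belongs to the right half, `y >= H/2` to the bottom half), so the exact
#' centre point falls in `D`.
#'
#' @param points Data frame or matrix of `(x, y)` positions; `NA` rows drop.
#' @param geom A [frame_geometry()].
#' @param period_label Label naming the observation period.
#' @return Data frame with columns `period`, `region` (`A`-`D`), `count`.
#' @export
quadrant_counts <- function(points, geom, period_label = "all") {
  stopifnot(inherits(geom, "frame_geometry"))
  pts <- .as_points(stats::na.omit(.as_points(points)))
  right <- pts[, 1L] >= geom$W / 2
  bottom <- pts[, 2L] >= geom$H / 2
  data.frame(period = period_label,
             region = c("A", "B", "C", "D"),
             count = c(sum(!right & !bottom), sum(right & !bottom),
                       sum(!right & bottom), sum(right & bottom)))
}

#' Compare region counts between two periods
#'
#' Per-region ratio of first-period to second-period counts. A zero
#' denominator yields an `NA` ratio with the `undefined` flag set (never
#' infinity).
#'
#' @param counts_p1,counts_p2 Outputs of [quadrant_counts()] over the same
#'   region scheme.
#' @return Data frame with columns `region`, `count_p1`, `count_p2`,
#'   `ratio`, `undefined`.
#' @export
period_compare <- function(counts_p1, counts_p2) {
  if (!identical(counts_p1$region, counts_p2$region))
    stop("the two periods use different region schemes", call. = FALSE)
  undef <- counts_p2$count == 0L
  ratio <- ifelse(undef, NA_real_, counts_p1$count / counts_p2$count)
  data.frame(region = counts_p1$region,
             count_p1 = counts_p1$count, count_p2 = counts_p2$count,
             ratio = ratio, undefined = undef)
}
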