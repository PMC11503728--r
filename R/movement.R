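# Scale-invariant displacement between adjacent frames and its aggregation
# into daily totals and hourly profiles.

#' Frame geometry
#'
#' @param width,height Image dimensions in pixels (>= 1).
#' @return List with components `W`, `H` and class `"frame_geometry"`.
#' @export
frame_geometry <- function(width, height) {
  if (!is.numeric(width) || !is.numeric(height) || width < 1 || height < 1)
    stop("frame dimensions must be >= 1 pixel", call. = FALSE)
  structure(list(W = as.numeric(width), H = as.numeric(height)),
            class = "frame_geometry")
}

#' Normalized displacement between two points
#'
#' The Euclidean distance between two group positions expressed as a
#' percentage of the image diagonal:
#' `D = 100 * sqrt((x_i - x_{i-1})^2 + (y_i - y_{i-1})^2) / sqrt(W^2 + H^2)`.
#' Because both the numerator and the diagonal scale linearly with image
#' size, `D` is invariant under uniform rescaling of the frames, so tracks
#' computed at different image resolutions are directly comparable.
#'
#' @param prev,curr Numeric `(x, y)` coordinate pairs in pixels.
#' @param geom A [frame_geometry()].
#' @return Displacement as a percentage (0-100 for points inside the frame).
#' @examples
#' g <- frame_geometry(3632, 1632)
#' normalized_distance(c(0, 0), c(3632, 1632), g)  # 100
#' @export
normalized_distance <- function(prev, curr, geom) {
  stopifnot(inherits(geom, "frame_geometry"))
  if (anyNA(prev) || anyNA(curr))
    stop("both points must be present", call. = FALSE)
  100 * sqrt((curr[[1]] - prev[[1]])^2 + (curr[[2]] - prev[[2]])^2) /
    sqrt(geom$W^2 + geom$H^2)
}

#' Displacement series along a track of group positions
#'
#' Forms one displacement per consecutive pair of frames. Frames with no
#' detections (gaps, `n_pigs = 0` / `NA` coordinates) are handled by the gap
#' policy: under `"skip"` (default) any pair touching a gap is recorded as
#' missing and excluded from totals — the conservative choice that never
#' invents movement; under `"bridge"` the displacement spans the gap between
#' the surrounding present frames, with `dt` accumulated across it.
#'
#' @param track Data frame with columns `frame_id`, `timestamp` (`POSIXct`),
#'   `x`, `y` (NA for gap frames), in chronological order.
#' @param geom A [frame_geometry()].
#' @param gap_policy `"skip"` or `"bridge"`.
#' @return Data frame with columns `from_frame`, `to_frame`, `t_from`,
#'   `t_to`, `dt` (seconds), `D` (percentage, `NA` for missing pairs) and
#'   `missing` (logical).
#' @export
displacement_series <- function(track, geom, gap_policy = c("skip", "bridge")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(geom, "frame_geometry"))
  n <- nrow(track)
  if (n >= 2L && any(diff(as.numeric(track$timestamp)) <= 0))
    stop("track timestamps must be strictly increasing", call. = FALSE)
  empty <- data.frame(from_frame = character(0), to_frame = character(0),
                      t_from = as.POSIXct(character(0), tz = "UTC"),
                      t_to = as.POSIXct(character(0), tz = "UTC"),
                      dt = numeric(0), D = numeric(0), missing = logical(0))
  if (n < 2L) return(empty)
  present <- !is.na(track$x) & !is.na(track$y)

  if (gap_policy == "skip") {
    i <- seq_len(n - 1L)
    ok <- present[i] & present[i + 1L]
    D <- rep(NA_real_, n - 1L)
    if (any(ok)) {
      D[ok] <- 100 * sqrt((track$x[i + 1L][ok] - track$x[i][ok])^2 +
                          (track$y[i + 1L][ok] - track$y[i][ok])^2) /
        sqrt(geom$W^2 + geom$H^2)
    }
    out <- data.frame(
      from_frame = track$frame_id[i], to_frame = track$frame_id[i + 1L],
      t_from = track$timestamp[i], t_to = track$timestamp[i + 1L],
      dt = as.numeric(difftime(track$timestamp[i + 1L], track$timestamp[i],
                               units = "secs")),
      D = D, missing = !ok)
  } else {
    idx <- which(present)
    if (length(idx) < 2L) return(empty)
    a <- idx[-length(idx)]; b <- idx[-1L]
    out <- data.frame(
      from_frame = track$frame_id[a], to_frame = track$frame_id[b],
      t_from = track$timestamp[a], t_to = track$timestamp[b],
      dt = as.numeric(difftime(track$timestamp[b], track$timestamp[a],
                               units = "secs")),
      D = 100 * sqrt((track$x[b] - track$x[a])^2 + (track$y[b] - track$y[a])^2) /
        sqrt(geom$W^2 + geom$H^2),
      missing = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Daily summed movement distance
#'
#' Sums the normalized displacements per calendar day. Each pair is assigned
#' to the day of its *destination* frame (a pair crossing midnight counts for
#' the later day). Days whose pairs are all missing are reported with a
#' total of 0 and flagged.
#'
#' @param series Output of [displacement_series()].
#' @return Data frame with columns `date`, `total_D` (summed percentage),
#'   `n_pairs` (pairs contributing), `n_missing` (gap-adjacent pairs
#'   excluded) and `flagged` (`TRUE` when a day has no usable pair).
#' @export
aggregate_daily <- function(series) {
  if (nrow(series) == 0L)
    return(data.frame(date = as.Date(character(0)), total_D = numeric(0),
                      n_pairs = integer(0), n_missing = integer(0),
                      flagged = logical(0)))
  day <- as.Date(series$t_to, tz = "UTC")
  days <- sort(unique(day))
  out <- do.call(rbind, lapply(days, function(d) {
    s <- series[day == d, , drop = FALSE]
    ok <- !s$missing
    data.frame(date = d,
               total_D = sum(s$D[ok]),
               n_pairs = sum(ok),
               n_missing = sum(!ok),
               flagged = !any(ok))
  }))
  rownames(out) <- NULL
  out
}

#' Hourly movement profile
#'
#' Bins the displacement series into the 24 hours of the day (per calendar
#' day), assigning each pair to the hour of its destination timestamp. For
#' every day all 24 bins are reported, zero-filled, so the bins of a day sum
#' exactly to that day's total in [aggregate_daily()].
#'
#' @param series Output of [displacement_series()].
#' @return Data frame with columns `date`, `hour` (0-23), `total_D`,
#'   `n_pairs`.
#' @export
hourly_profile <- function(series) {
  if (nrow(series) == 0L)
    return(data.frame(date = as.Date(character(0)), hour = integer(0),
                      total_D = numeric(0), n_pairs = integer(0)))
  day <- as.Date(series$t_to, tz = "UTC")
  hr <- as.integer(format(series$t_to, "%H", tz = "UTC"))
  days <- sort(unique(day))
  out <- do.call(rbind, lapply(days, function(d) {
    s <- series[day == d & !series$missing, , drop = FALSE]
    h <- hr[day == d & !series$missing]
    tot <- vapply(0:23, function(b) sum(s$D[h == b]), numeric(1))
    cnt <- vapply(0:23, function(b) sum(h == b), integer(1))
    data.frame(date = d, hour = 0:23, total_D = tot, n_pairs = cnt)
  }))
  rownames(out) <- NULL
  out
}
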