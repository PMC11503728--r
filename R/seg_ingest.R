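# Reading per-frame instance-segmentation polygon labels and frame
# manifests; writing tracks as CSV.
#
# Label dialect: one text file per frame, one instance per line, formatted
# as "<class_id> x1 y1 x2 y2 ... [confidence]" with coordinates normalized
# to [0, 1]. Whether a trailing confidence token is present is auto-detected
# from token-count parity (class id + an even number of coordinates leaves
# an odd total without confidence) and can be forced either way.

#' Parse one segmentation label line
#'
#' @param line A whitespace-separated label line.
#' @param image_width,image_height Frame dimensions used to denormalize the
#'   coordinates.
#' @param confidence `"auto"` (detect the trailing confidence token from
#'   token-count parity), `"always"` or `"never"`.
#' @return List with `class_id` (integer), `polygon` (a [as_polygon()]
#'   matrix in pixel coordinates) and `confidence` (number or `NA`).
#' @examples
#' parse_yolo_seg_line("0 0.0 0.0 1.0 0.0 1.0 1.0", 100, 50)
#' @export
parse_yolo_seg_line <- function(line, image_width, image_height,
                                confidence = c("auto", "always", "never")) {
  confidence <- match.arg(confidence)
  toks <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
  if (anyNA(toks)) stop("format error: non-numeric token in label line", call. = FALSE)
  if (length(toks) < 2L) stop("format error: empty label line", call. = FALSE)
  class_id <- toks[1L]
  rest <- toks[-1L]
  has_conf <- switch(confidence,
    auto   = length(rest) %% 2L == 1L,
    always = TRUE,
    never  = FALSE)
  conf <- NA_real_
  if (has_conf) {
    conf <- rest[length(rest)]
    rest <- rest[-length(rest)]
    if (conf < 0 || conf > 1)
      stop("format error: confidence outside [0, 1]", call. = FALSE)
  }
  if (length(rest) %% 2L == 1L)
    stop("format error: odd coordinate count", call. = FALSE)
  if (length(rest) < 6L)
    stop("format error: fewer than 3 vertices", call. = FALSE)
  if (any(rest < -1e-6 | rest > 1 + 1e-6))
    stop("format error: normalized coordinate outside [0, 1]", call. = FALSE)
  rest <- pmin(pmax(rest, 0), 1)
  m <- matrix(rest, ncol = 2L, byrow = TRUE)
  m[, 1L] <- m[, 1L] * image_width
  m[, 2L] <- m[, 2L] * image_height
  list(class_id = as.integer(class_id),
       polygon = as_polygon(m),
       confidence = conf)
}

#' Read all instances of one label file
#'
#' @param path Label file path; blank lines are skipped.
#' @inheritParams parse_yolo_seg_line
#' @return List of parsed instances (see [parse_yolo_seg_line()]).
#' @export
read_label_file <- function(path, image_width, image_height,
                            confidence = "auto") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, parse_yolo_seg_line, image_width = image_width,
         image_height = image_height, confidence = confidence)
}

.parse_timestamp <- function(x) {
  ts <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  bad <- is.na(ts)
  if (any(bad))
    stop(sprintf("manifest error: unparsable timestamp '%s'", x[bad][1L]),
         call. = FALSE)
  ts
}

#' Load a frame manifest and its label files
#'
#' The manifest is a CSV with columns
#' `frame_id, timestamp, label_path, width, height`; timestamps are
#' `YYYY-MM-DD HH:MM:SS` local (naive) time and must be strictly increasing;
#' `label_path` is resolved relative to the manifest's directory. A
#' referenced label file that does not exist yields a frame with zero
#' instances and a warning — the frame is kept so the downstream gap policy
#' stays explicit.
#'
#' @param path Manifest CSV path.
#' @param confidence Confidence-token dialect passed to label parsing.
#' @param min_confidence Drop instances whose confidence is below this value
#'   (instances without a confidence are always kept). Default 0.
#' @return List with `manifest` (the manifest data frame with parsed
#'   timestamps) and `frames`: a list of frame records, each a list with
#'   `frame_id`, `timestamp`, `width`, `height` and `instances`.
#' @export
load_manifest <- function(path, confidence = "auto", min_confidence = 0) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path), call. = FALSE)
  man <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("frame_id", "timestamp", "label_path", "width", "height")
  if (!all(need %in% names(man)))
    stop(sprintf("manifest error: missing column(s) %s",
                 paste(setdiff(need, names(man)), collapse = ", ")), call. = FALSE)
  if (anyDuplicated(man$frame_id))
    stop("manifest error: duplicate frame_id", call. = FALSE)
  man$timestamp <- .parse_timestamp(man$timestamp)
  man$width <- as.integer(man$width); man$height <- as.integer(man$height)
  if (any(is.na(man$width) | is.na(man$height) | man$width < 1 | man$height < 1))
    stop("manifest error: invalid image dimensions", call. = FALSE)
  if (nrow(man) > 1L && any(diff(as.numeric(man$timestamp)) <= 0))
    stop("manifest error: timestamps not strictly increasing", call. = FALSE)
  base_dir <- dirname(normalizePath(path))
  frames <- lapply(seq_len(nrow(man)), function(i) {
    lp <- man$label_path[i]
    if (!file.exists(lp)) lp <- file.path(base_dir, man$label_path[i])
    inst <- list()
    if (file.exists(lp)) {
      inst <- read_label_file(lp, man$width[i], man$height[i], confidence)
      if (min_confidence > 0) {
        keep <- vapply(inst, function(z) is.na(z$confidence) ||
                         z$confidence >= min_confidence, logical(1))
        inst <- inst[keep]
      }
    } else {
      warning(sprintf("label file missing for frame %s; treating as empty frame",
                      man$frame_id[i]), call. = FALSE)
    }
    list(frame_id = man$frame_id[i], timestamp = man$timestamp[i],
         width = man$width[i], height = man$height[i], instances = inst)
  })
  list(manifest = man, frames = frames)
}

#' Build a manifest data frame from a start time and interval
#'
#' Convenience helper for fixed-cadence recordings: timestamps are generated
#' from `start` at `interval` seconds; they are never inferred from file
#' names.
#'
#' @param label_paths Character vector of label file paths, in order.
#' @param start Start `POSIXct` (or `YYYY-MM-DD HH:MM:SS` string).
#' @param interval Seconds between frames (default 300, i.e. 5 minutes).
#' @param width,height Image dimensions in pixels.
#' @param frame_ids Optional frame ids; default `frame_000001`, ...
#' @return Manifest data frame (not yet written to disk).
#' @export
make_manifest <- function(label_paths, start, interval = 300,
                          width = 3632L, height = 1632L, frame_ids = NULL) {
  if (is.character(start)) start <- .parse_timestamp(start)
  n <- length(label_paths)
  if (is.null(frame_ids)) frame_ids <- sprintf("frame_%06d", seq_len(n))
  data.frame(frame_id = frame_ids,
             timestamp = format(start + (seq_len(n) - 1L) * interval,
                                "%Y-%m-%d %H:%M:%S", tz = "UTC"),
             label_path = label_paths,
             width = as.integer(width), height = as.integer(height),
             stringsAsFactors = FALSE)
}

#' Write a group-position track as CSV
#'
#' RFC-4180 CSV with header `frame_id,timestamp,x,y,n_pigs,D`; coordinates
#' and displacements are printed with six decimal places. `x`, `y` are empty
#' for gap frames, and `D` is empty for the first frame and for any pair
#' touching a gap.
#'
#' @param track Data frame with columns `frame_id`, `timestamp`, `x`, `y`,
#'   `n_pigs` and optionally `D` (displacement into each frame).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_track_csv <- function(track, path) {
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.6f", v))
  d <- if ("D" %in% names(track)) track$D else rep(NA_real_, nrow(track))
  lines <- c("frame_id,timestamp,x,y,n_pigs,D",
             if (nrow(track)) sprintf("%s,%s,%s,%s,%d,%s",
               track$frame_id,
               format(track$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
               fmt(track$x), fmt(track$y), as.integer(track$n_pigs), fmt(d)))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot write track CSV to %s: %s", path, conditionMessage(e)),
         call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a track CSV written by [write_track_csv()]
#'
#' @param path Track CSV path.
#' @return Data frame with parsed timestamps and numeric coordinates (`NA`
#'   for gap frames).
#' @export
read_track_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(frame_id = "character"))
  tr$timestamp <- .parse_timestamp(tr$timestamp)
  for (cc in c("x", "y", "D")) if (cc %in% names(tr)) tr[[cc]] <- as.numeric(tr[[cc]])
  tr
}
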