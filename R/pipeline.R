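# End-to-end orchestration: manifest -> per-pig centres -> group point ->
# displacement -> daily / hourly / occupancy artifacts, plus report figures.

#' Pipeline configuration
#'
#' Validates every enumeration up front, before any I/O.
#'
#' @param manifest Path to the frame manifest CSV.
#' @param out_dir Output directory for all artifacts.
#' @param center_method Pig-centre algorithm: `"spatial_moment"` (default),
#'   `"mean"`, `"least_squares"` or `"signed_area"`.
#' @param clusterer Group-point clusterer id (default `"agglomerative"`).
#' @param n_clusters Clusters formed per frame before averaging (default 1).
#' @param gap_policy `"skip"` or `"bridge"` (see [displacement_series()]).
#' @param split_date Optional `"YYYY-MM-DD"`; observations before this date
#'   form period 1, the rest period 2, for the quadrant comparison.
#' @param min_confidence Minimum detection confidence retained at ingest.
#' @param confidence Label confidence-token dialect (`"auto"`, `"always"`,
#'   `"never"`).
#' @param nx,ny Occupancy grid size.
#' @param seed Seed applied before processing (only stochastic clusterers
#'   consume randomness; the default pipeline is deterministic regardless).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(manifest, out_dir,
                            center_method = "spatial_moment",
                            clusterer = "agglomerative",
                            n_clusters = 1L,
                            gap_policy = "skip",
                            split_date = NULL,
                            min_confidence = 0,
                            confidence = "auto",
                            nx = 64L, ny = 29L,
                            seed = NULL) {
  center_method <- match.arg(center_method,
    c("spatial_moment", "mean", "least_squares", "signed_area"))
  if (!clusterer %in% .CLUSTERERS)
    stop(sprintf("unknown clusterer id '%s'", clusterer), call. = FALSE)
  gap_policy <- match.arg(gap_policy, c("skip", "bridge"))
  confidence <- match.arg(confidence, c("auto", "always", "never"))
  stopifnot(n_clusters >= 1, min_confidence >= 0, min_confidence <= 1,
            nx >= 1, ny >= 1)
  if (!is.null(split_date)) split_date <- as.Date(split_date)
  structure(list(manifest = manifest, out_dir = out_dir,
                 center_method = center_method, clusterer = clusterer,
                 n_clusters = as.integer(n_clusters), gap_policy = gap_policy,
                 split_date = split_date, min_confidence = min_confidence,
                 confidence = confidence, nx = as.integer(nx),
                 ny = as.integer(ny), seed = seed),
            class = "pipeline_config")
}

#' Run the full movement-monitoring pipeline
#'
#' Ingests the manifest and label files, condenses each pig contour to a
#' centre point, clusters the centres into one group position per frame,
#' computes the displacement series and writes every artifact as CSV into
#' `config$out_dir`: `track.csv`, `displacement.csv`, `daily.csv`,
#' `hourly.csv`, `occupancy_grid.csv`, `occupancy_marginals.csv`,
#' `regions.csv` and (when a split date is set) `region_ratios.csv`, plus a
#' `config.yaml` echo and a frame-level `run.log`. The run is deterministic
#' given config and inputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with the in-memory artifacts (`track`, `series`,
#'   `daily`, `hourly`, `grid`, `regions`, `ratios`, `geom`) and `paths` to
#'   the files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  loaded <- load_manifest(config$manifest, confidence = config$confidence,
                          min_confidence = config$min_confidence)
  frames <- loaded$frames
  if (!length(frames)) stop("manifest contains no frames", call. = FALSE)
  geom <- frame_geometry(frames[[1L]]$width, frames[[1L]]$height)

  log_lines <- character(length(frames))
  track <- do.call(rbind, lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    centers <- NULL
    if (length(fr$instances)) {
      pts <- t(vapply(fr$instances, function(inst) {
        ctr <- pig_center(inst$polygon, config$center_method,
                          frame_width = fr$width, frame_height = fr$height)
        # keep centres inside the frame (contours may poke past the edge)
        c(min(max(ctr[["x"]], 0), fr$width), min(max(ctr[["y"]], 0), fr$height))
      }, numeric(2)))
      centers <- data.frame(x = pts[, 1L], y = pts[, 2L],
                            confidence = vapply(fr$instances,
                                                function(z) z$confidence,
                                                numeric(1)))
    }
    gp <- tryCatch(
      group_center(centers, timestamp = fr$timestamp,
                   method = config$clusterer, n_clusters = config$n_clusters,
                   frame_id = fr$frame_id),
      error = function(e) stop(sprintf("group_position stage failed at frame %s: %s",
                                       fr$frame_id, conditionMessage(e)),
                               call. = FALSE))
    log_lines[i] <<- sprintf("%s instances=%d n_pigs=%d",
                             fr$frame_id, length(fr$instances), gp$n_pigs)
    gp
  }))

  series <- displacement_series(track, geom, config$gap_policy)
  daily <- aggregate_daily(series)
  hourly <- hourly_profile(series)

  # displacement into each frame, aligned by destination, for the track CSV
  track$D <- NA_real_
  if (nrow(series)) {
    idx <- match(series$to_frame[!series$missing], track$frame_id)
    track$D[idx] <- series$D[!series$missing]
  }

  pts <- track[!is.na(track$x), c("x", "y")]
  grid <- density_grid(pts, geom, nx = config$nx, ny = config$ny)
  if (!is.null(config$split_date)) {
    p1 <- track[!is.na(track$x) &
                  as.Date(track$timestamp, tz = "UTC") < config$split_date,
                c("x", "y")]
    p2 <- track[!is.na(track$x) &
                  as.Date(track$timestamp, tz = "UTC") >= config$split_date,
                c("x", "y")]
    regions <- rbind(quadrant_counts(p1, geom, "period1"),
                     quadrant_counts(p2, geom, "period2"))
    ratios <- period_compare(regions[regions$period == "period1", ],
                             regions[regions$period == "period2", ])
  } else {
    regions <- quadrant_counts(pts, geom, "all")
    ratios <- NULL
  }

  paths <- list(track = file.path(config$out_dir, "track.csv"))
  write_track_csv(track, paths$track)
  region_header <- "# region convention: A=top-left B=top-right C=bottom-left D=bottom-right (half-open split)"
  wcsv <- function(df, name, header = NULL) {
    p <- file.path(config$out_dir, name)
    con <- file(p, "w"); on.exit(close(con), add = TRUE)
    if (!is.null(header)) writeLines(header, con)
    utils::write.csv(df, con, row.names = FALSE)
    p
  }
  paths$displacement <- wcsv(series, "displacement.csv")
  paths$daily <- wcsv(daily, "daily.csv")
  paths$hourly <- wcsv(hourly, "hourly.csv")
  grid_df <- as.data.frame(as.table(grid$counts))
  names(grid_df) <- c("y_bin", "x_bin", "count")
  grid_df$y_bin <- as.integer(grid_df$y_bin) - 1L
  grid_df$x_bin <- as.integer(grid_df$x_bin) - 1L
  grid_df$density <- as.vector(grid$density)
  paths$occupancy_grid <- wcsv(grid_df, "occupancy_grid.csv")
  marg <- data.frame(axis = c(rep("x", grid$nx), rep("y", grid$ny)),
                     bin = c(seq_len(grid$nx), seq_len(grid$ny)) - 1L,
                     count = c(grid$x_marginal, grid$y_marginal))
  paths$occupancy_marginals <- wcsv(marg, "occupancy_marginals.csv")
  paths$regions <- wcsv(regions, "regions.csv", region_header)
  if (!is.null(ratios))
    paths$region_ratios <- wcsv(ratios, "region_ratios.csv", region_header)
  cfg_echo <- config
  cfg_echo$split_date <- if (is.null(config$split_date)) NULL
                         else format(config$split_date)
  yaml::write_yaml(unclass(cfg_echo), file.path(config$out_dir, "config.yaml"))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))

  n_gaps <- sum(track$n_pigs == 0L)
  message(sprintf(
    "pipeline: %d frames (%d gaps), %d displacement pairs (%d missing), %d day(s)",
    nrow(track), n_gaps, sum(!series$missing), sum(series$missing), nrow(daily)))

  invisible(list(track = track, series = series, daily = daily,
                 hourly = hourly, grid = grid, regions = regions,
                 ratios = ratios, geom = geom, paths = paths,
                 config = config))
}

#' Render report figures from pipeline artifacts
#'
#' Writes three PNG figures: the occupancy density heatmap with marginal
#' histograms, the daily summed-distance bars, and up to four within-day
#' hourly profiles (the days with maximum, minimum and median daily
#' totals). Figure captions carry the quadrant convention and the daily
#' total corresponding to each hourly panel.
#'
#' @param artifacts Result of [run_pipeline()].
#' @param out_dir Output directory for the figures.
#' @return Invisible character vector of the figure paths.
#' @export
make_report <- function(artifacts, out_dir) {
  for (need in c("track", "daily", "hourly", "grid")) {
    if (is.null(artifacts[[need]]))
      stop(sprintf("report error: missing artifact '%s'", need), call. = FALSE)
  }
  if (all(is.na(artifacts$track$x)))
    stop("report error: track contains no group positions", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  geom <- artifacts$geom
  paths <- character(0)

  # occupancy heatmap + marginals
  p <- file.path(out_dir, "occupancy_density.png")
  grDevices::png(p, width = 1000, height = 600)
  g <- artifacts$grid
  layout(matrix(c(2, 4, 1, 3), 2, 2, byrow = TRUE), widths = c(4, 1),
         heights = c(1, 3))
  op <- par(mar = c(4, 4, 0.5, 0.5))
  image(x = seq(0, geom$W, length.out = g$nx + 1L),
        y = seq(0, geom$H, length.out = g$ny + 1L),
        z = t(g$density)[, rev(seq_len(g$ny)), drop = FALSE],
        col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "x (px)", ylab = "y (px, top-down view)", useRaster = TRUE)
  par(mar = c(0.5, 4, 2, 0.5))
  barplot(g$x_marginal, space = 0, border = NA, axes = FALSE,
          main = "occupancy density (0-1, max-normalized)")
  par(mar = c(4, 0.5, 0.5, 2))
  barplot(rev(g$y_marginal), space = 0, horiz = TRUE, border = NA, axes = FALSE)
  par(op)
  grDevices::dev.off()
  paths <- c(paths, p)

  # daily totals
  p <- file.path(out_dir, "daily_distance.png")
  grDevices::png(p, width = 1000, height = 450)
  d <- artifacts$daily
  barplot(d$total_D, names.arg = format(d$date, "%d %b"), las = 2,
          ylab = "summed distance (% of diagonal)",
          main = "Daily summed movement distance")
  abline(h = mean(d$total_D), lty = 2)
  grDevices::dev.off()
  paths <- c(paths, p)

  # hourly profiles of extreme and median days
  p <- file.path(out_dir, "hourly_profiles.png")
  d_ok <- d[!d$flagged, , drop = FALSE]
  ord <- order(d_ok$total_D)
  pick <- unique(c(ord[length(ord)], ord[1L],
                   ord[ceiling(length(ord) / 2)],
                   ord[min(length(ord), ceiling(length(ord) / 2) + 1L)]))
  pick <- pick[!is.na(pick)]
  pick <- pick[seq_len(min(4L, length(pick)))]
  grDevices::png(p, width = 1000, height = 250 * length(pick))
  op <- par(mfrow = c(length(pick), 1), mar = c(3, 4, 2, 1))
  for (i in pick) {
    day <- d_ok$date[i]
    h <- artifacts$hourly[artifacts$hourly$date == day, ]
    barplot(h$total_D, names.arg = h$hour,
            ylab = "% of diagonal",
            main = sprintf("%s (daily total %.1f%%)", format(day),
                           sum(h$total_D)))
  }
  par(op)
  grDevices::dev.off()
  paths <- c(paths, p)

  invisible(paths)
}
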