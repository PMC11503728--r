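# Synthetic pen scenes: pig-shaped contours with posture, a latent two-state
# group random walk with a diurnal activity schedule, and full ground truth,
# so that every pipeline stage can be tested without any video data.

#' Pen / recording configuration for scene generation
#'
#' Defaults describe the monitored pen: a 3632 x 1632 px overhead view of a
#' room holding 7 pigs, sampled every 5 minutes.
#'
#' @param width,height Frame size in pixels.
#' @param n_pigs Number of pigs.
#' @param interval Seconds between frames.
#' @param duration Number of frames to simulate (288 = one day at 5 min).
#' @param start First-frame timestamp (`POSIXct` or `YYYY-MM-DD HH:MM:SS`).
#' @param seed Integer seed fixing every downstream draw (`NULL` = leave the
#'   RNG state alone).
#' @param body_length Mean pig body length in pixels (per-pig lengths vary
#'   by ~5%).
#' @param dispersion Herd spread: stationary standard deviation of each
#'   pig's offset from the group point, as a fraction of the image diagonal.
#' @param dropout Probability that a pig detection is missing from a frame
#'   (exercises the downstream gap policy). Default 0.
#' @return List of class `"pen_config"`.
#' @export
pen_config <- function(width = 3632L, height = 1632L, n_pigs = 7L,
                       interval = 300, duration = 288L,
                       start = "2023-05-13 00:00:00", seed = NULL,
                       body_length = 800, dispersion = 0.03, dropout = 0) {
  if (is.character(start)) start <- .parse_timestamp(start)
  stopifnot(width >= 1, height >= 1, n_pigs >= 1, interval > 0, duration >= 1,
            body_length > 0, dispersion >= 0, dropout >= 0, dropout < 1)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_pigs = as.integer(n_pigs), interval = as.numeric(interval),
                 duration = as.integer(duration), start = start,
                 seed = seed, body_length = body_length,
                 dispersion = dispersion, dropout = dropout),
            class = "pen_config")
}

#' Two-state behaviour model for the latent group walk
#'
#' The group alternates between `rest` and `move` by a per-frame Markov
#' chain. Step lengths are bivariate Gaussian with a per-axis standard
#' deviation expressed as a fraction of the image diagonal. The persistence
#' parameters `rho_rest`/`rho_move` control how strongly each pig holds its
#' offset from the group point between frames (resting pigs barely move
#' relative to the herd; moving pigs re-arrange).
#'
#' @param p_rest_to_move Baseline per-frame probability of starting to move;
#'   multiplied by the hourly activity schedule and capped at 1.
#' @param p_move_to_rest Per-frame probability of settling back to rest.
#' @param move_step Per-axis step s.d. while moving (fraction of diagonal).
#' @param rest_jitter Per-axis step s.d. while resting (fraction of
#'   diagonal).
#' @param rho_rest,rho_move AR(1) persistence of per-pig offsets in each
#'   state, in `[0, 1)`.
#' @return List of class `"behavior_state"`.
#' @export
behavior_state <- function(p_rest_to_move = 0.10, p_move_to_rest = 0.70,
                           move_step = 0.32, rest_jitter = 0.018,
                           rho_rest = 0.98, rho_move = 0.6) {
  stopifnot(p_rest_to_move >= 0, p_rest_to_move <= 1,
            p_move_to_rest >= 0, p_move_to_rest <= 1,
            move_step >= 0, rest_jitter >= 0,
            rho_rest >= 0, rho_rest < 1, rho_move >= 0, rho_move < 1)
  structure(list(p_rest_to_move = p_rest_to_move,
                 p_move_to_rest = p_move_to_rest,
                 move_step = move_step, rest_jitter = rest_jitter,
                 rho_rest = rho_rest, rho_move = rho_move),
            class = "behavior_state")
}

#' Default diurnal activity schedule
#'
#' 24 hourly multipliers for the rest-to-move probability, normalized to
#' mean 1, with sharp peaks (Gaussian bumps, s.d. 0.35 h) at the given hours.
#' The default peaks at 9 h and 21 h mirror the twice-daily feeding routine
#' of the monitored pen, which concentrates activity into short bursts.
#'
#' @param peaks Peak hours (0-23).
#' @param base Baseline multiplier before normalization.
#' @param sigma Peak width in hours.
#' @return Numeric vector of 24 multipliers with mean 1.
#' @export
default_activity_schedule <- function(peaks = c(9, 21), base = 0.1, sigma = 0.35) {
  h <- 0:23
  bump <- rowSums(vapply(peaks, function(p) {
    d <- pmin(abs(h - p), 24 - abs(h - p))  # circular hour distance
    exp(-d^2 / (2 * sigma^2))
  }, numeric(24)))
  m <- base + bump * (1 - base) * 24 / sum(bump)
  m / mean(m)
}

# Smallest circular difference between two angles.
.angdiff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Generate a pig-shaped contour polygon
#'
#' Produces a closed contour of 30-50 vertices (matching the density of a
#' hand-annotated pig outline) as a star-shaped radial perturbation of an
#' ellipse with 2.5:1 aspect ratio, so the polygon can never
#' self-intersect. Postures:
#' * `"standing"` — smooth noisy ellipse;
#' * `"sitting"` — ellipse with one flattened (rear) end;
#' * `"lying"` — ellipse plus 2-4 thin leg lobes protruding from one flank,
#'   each lobe adding at most ~5% of the body area. The lying posture is the
#'   adversarial case that separates vertex-weighted centre algorithms from
#'   area-weighted ones: the leg vertices pull the vertex mean sideways
#'   while barely moving the mass centroid.
#'
#' Draws from the current RNG state; seed upstream for determinism.
#'
#' @param center `(x, y)` position of the body-ellipse centre in pixels.
#' @param pose One of `"lying"`, `"sitting"`, `"standing"`.
#' @param body_length Tip-to-tip body length in pixels.
#' @param heading Body axis orientation in radians.
#' @return A [as_polygon()] matrix with attributes `pose` and, for lying
#'   pigs, `leg_dir`, the unit vector from the body centre toward the leg
#'   side in image coordinates.
#' @export
generate_pig_polygon <- function(center, pose = c("lying", "sitting", "standing"),
                                 body_length = 800, heading = 0) {
  pose <- match.arg(pose)
  stopifnot(body_length > 0)
  a <- body_length / 2
  b <- a / 2.5
  leg_w <- 0.055   # lobe angular half-width (rad)
  leg_amp <- 0.9   # lobe radial extension factor

  if (pose == "lying") {
    n_base <- sample(24:38, 1L)
    k <- sample(2:4, 1L)
    th_legs <- seq(55, 125, length.out = k) * pi / 180 +
      stats::runif(k, -0.04, 0.04)
    th <- seq(0, 2 * pi, length.out = n_base + 1L)[-(n_base + 1L)]
    th <- th + stats::runif(n_base, -0.3, 0.3) * (2 * pi / n_base) / 2
    th <- sort(c(th %% (2 * pi), th_legs - leg_w, th_legs, th_legs + leg_w))
  } else {
    n <- sample(30:50, 1L)
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    th <- sort((th + stats::runif(n, -0.3, 0.3) * (2 * pi / n) / 2) %% (2 * pi))
  }

  r <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)  # ellipse radius
  r <- r * (1 + stats::rnorm(length(th), 0, 0.015))     # contour noise
  if (pose == "sitting") {
    r <- r * (1 - 0.30 * exp(-.angdiff(th, pi)^2 / (2 * 0.45^2)))
  }
  if (pose == "lying") {
    for (tl in th_legs) {
      r <- r * (1 + leg_amp * exp(-.angdiff(th, tl)^2 / (2 * leg_w^2)))
    }
  }

  rot <- matrix(c(cos(heading), sin(heading), -sin(heading), cos(heading)), 2L, 2L)
  body <- cbind(r * cos(th), r * sin(th)) %*% t(rot)
  v <- sweep(body, 2L, as.numeric(center[1:2]), "+")
  poly <- as_polygon(v)
  attr(poly, "pose") <- pose
  if (pose == "lying") attr(poly, "leg_dir") <- as.numeric(rot %*% c(0, 1))
  poly
}

.reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  if (span <= 0) return(rep((lo + hi) / 2, length(x)))
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

.POSE_REST <- c(lying = 0.8, sitting = 0.15, standing = 0.05)
.POSE_MOVE <- c(lying = 0.1, sitting = 0.2, standing = 0.7)

#' Simulate a group-housed pig scene with ground truth
#'
#' The latent group point follows the two-state walk of [behavior_state()]
#' inside the pen (reflective boundaries, with a wall margin so contours
#' stay inside the frame). Each pig sits at the group point plus a
#' mean-reverting AR(1) offset whose stationary spread is the configured
#' dispersion; postures are sampled state-dependently (resting herds are
#' lying-heavy) and persist between frames. The hourly schedule multiplies
#' the rest-to-move probability, producing the configured activity peaks.
#'
#' @param config A [pen_config()].
#' @param behavior A [behavior_state()].
#' @param activity_schedule 24 hourly multipliers (default
#'   [default_activity_schedule()]); `NULL` for a flat schedule.
#' @return An object of class `"herd_scene"`: list with `config`,
#'   `behavior`, `schedule`, `frames` (latent trajectory: `frame_id`,
#'   `timestamp`, `hour`, `state`, `gx`, `gy`), `centers` (per pig and
#'   frame: true centre, pose, heading, body length, confidence, `detected`
#'   flag), `polygons` (per frame, list of contour matrices), and the
#'   ground-truth `daily` and `hourly` movement summaries of the latent
#'   trajectory.
#' @export
simulate_group_walk <- function(config = pen_config(),
                                behavior = behavior_state(),
                                activity_schedule = default_activity_schedule()) {
  stopifnot(inherits(config, "pen_config"), inherits(behavior, "behavior_state"))
  if (is.null(activity_schedule)) activity_schedule <- rep(1, 24)
  stopifnot(length(activity_schedule) == 24L, all(activity_schedule >= 0))
  if (!is.null(config$seed)) set.seed(config$seed)

  W <- config$width; H <- config$height
  diag_px <- sqrt(W^2 + H^2)
  margin <- 0.55 * config$body_length
  xlim <- c(min(margin, W / 2), max(W - margin, W / 2))
  ylim <- c(min(margin, H / 2), max(H - margin, H / 2))
  T <- config$duration
  np <- config$n_pigs

  ts <- config$start + (seq_len(T) - 1L) * config$interval
  hour <- as.integer(format(ts, "%H", tz = "UTC"))
  frame_id <- sprintf("frame_%06d", seq_len(T))

  body_len <- stats::rnorm(np, config$body_length, 0.05 * config$body_length)
  body_len <- pmax(body_len, 0.5 * config$body_length)

  state <- character(T)
  gx <- numeric(T); gy <- numeric(T)
  state[1L] <- "rest"
  gx[1L] <- stats::runif(1, xlim[1L], xlim[2L])
  gy[1L] <- stats::runif(1, ylim[1L], ylim[2L])

  offs <- matrix(stats::rnorm(np * 2L, 0, config$dispersion * diag_px), np, 2L)
  heading <- stats::runif(np, 0, 2 * pi)
  pose <- sample(names(.POSE_REST), np, replace = TRUE, prob = .POSE_REST)

  centers <- vector("list", T)
  polygons <- vector("list", T)

  for (t in seq_len(T)) {
    if (t > 1L) {
      p_rm <- min(1, behavior$p_rest_to_move * activity_schedule[hour[t] + 1L])
      state[t] <- if (state[t - 1L] == "rest") {
        if (stats::runif(1) < p_rm) "move" else "rest"
      } else {
        if (stats::runif(1) < behavior$p_move_to_rest) "rest" else "move"
      }
      sd_step <- if (state[t] == "move") behavior$move_step else behavior$rest_jitter
      gx[t] <- .reflect_into(gx[t - 1L] + stats::rnorm(1, 0, sd_step * diag_px),
                             xlim[1L], xlim[2L])
      gy[t] <- .reflect_into(gy[t - 1L] + stats::rnorm(1, 0, sd_step * diag_px),
                             ylim[1L], ylim[2L])
      rho <- if (state[t] == "move") behavior$rho_move else behavior$rho_rest
      offs <- rho * offs + sqrt(1 - rho^2) *
        matrix(stats::rnorm(np * 2L, 0, config$dispersion * diag_px), np, 2L)
      p_repose <- if (state[t] == "move") 0.6 else 0.1
      reposed <- stats::runif(np) < p_repose
      if (any(reposed)) {
        probs <- if (state[t] == "move") .POSE_MOVE else .POSE_REST
        pose[reposed] <- sample(names(probs), sum(reposed), replace = TRUE,
                                prob = probs)
        heading[reposed] <- (heading[reposed] +
                               stats::rnorm(sum(reposed), 0, 0.8)) %% (2 * pi)
      }
    }
    cx <- pmin(pmax(gx[t] + offs[, 1L], xlim[1L]), xlim[2L])
    cy <- pmin(pmax(gy[t] + offs[, 2L], ylim[1L]), ylim[2L])
    conf <- stats::rbeta(np, 30, 1.2)  # detector-like confidences, mean ~0.96
    detected <- stats::runif(np) >= config$dropout
    polys <- lapply(seq_len(np), function(i) {
      generate_pig_polygon(c(cx[i], cy[i]), pose[i], body_len[i], heading[i])
    })
    centers[[t]] <- data.frame(frame_id = frame_id[t], pig = seq_len(np),
                               x = cx, y = cy, pose = pose,
                               heading = heading, body_length = body_len,
                               confidence = conf, detected = detected)
    polygons[[t]] <- polys
  }

  frames <- data.frame(frame_id = frame_id, timestamp = ts, hour = hour,
                       state = state, gx = gx, gy = gy)
  geom <- frame_geometry(W, H)
  latent_track <- data.frame(frame_id = frame_id, timestamp = ts,
                             x = gx, y = gy, n_pigs = np)
  series <- displacement_series(latent_track, geom, "skip")
  structure(list(config = config, behavior = behavior,
                 schedule = activity_schedule,
                 frames = frames,
                 centers = do.call(rbind, centers),
                 polygons = polygons,
                 daily = aggregate_daily(series),
                 hourly = hourly_profile(series)),
            class = "herd_scene")
}

#' Write a simulated scene as label files, manifest and ground truth
#'
#' Emits one segmentation label file per frame (class 0, normalized
#' coordinates, trailing confidence), a `manifest.csv`, and the ground-truth
#' CSVs (`ground_truth.csv` with the latent trajectory,
#' `ground_truth_daily.csv` / `ground_truth_hourly.csv` with the latent
#' movement sums). Dropped-out detections are omitted from the label files
#' but remain in the scene object.
#'
#' @param scene A `"herd_scene"` from [simulate_group_walk()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible list with `manifest`, `labels_dir` and ground-truth
#'   file paths.
#' @export
write_scene <- function(scene, out_dir) {
  stopifnot(inherits(scene, "herd_scene"))
  labels_dir <- file.path(out_dir, "labels")
  dir.create(labels_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(labels_dir))
    stop(sprintf("cannot create output directory %s", labels_dir), call. = FALSE)
  W <- scene$config$width; H <- scene$config$height
  n_frames <- nrow(scene$frames)
  rel_paths <- file.path("labels", paste0(scene$frames$frame_id, ".txt"))
  for (t in seq_len(n_frames)) {
    ctr <- scene$centers[scene$centers$frame_id == scene$frames$frame_id[t], ]
    lines <- character(0)
    for (i in which(ctr$detected)) {
      v <- unclass(scene$polygons[[t]][[i]])
      xs <- pmin(pmax(v[, 1L] / W, 0), 1)
      ys <- pmin(pmax(v[, 2L] / H, 0), 1)
      coords <- sprintf("%.6f", as.vector(rbind(xs, ys)))
      lines <- c(lines, paste("0", paste(coords, collapse = " "),
                              sprintf("%.6f", ctr$confidence[i])))
    }
    writeLines(lines, file.path(out_dir, rel_paths[t]))
  }
  man <- make_manifest(rel_paths, start = scene$config$start,
                       interval = scene$config$interval,
                       width = W, height = H,
                       frame_ids = scene$frames$frame_id)
  man_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE, quote = FALSE)
  gt_path <- file.path(out_dir, "ground_truth.csv")
  gt <- scene$frames
  gt$timestamp <- format(gt$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(gt, gt_path, row.names = FALSE, quote = FALSE)
  gtd_path <- file.path(out_dir, "ground_truth_daily.csv")
  utils::write.csv(scene$daily, gtd_path, row.names = FALSE, quote = FALSE)
  gth_path <- file.path(out_dir, "ground_truth_hourly.csv")
  utils::write.csv(scene$hourly, gth_path, row.names = FALSE, quote = FALSE)
  invisible(list(manifest = man_path, labels_dir = labels_dir,
                 ground_truth = gt_path, ground_truth_daily = gtd_path,
                 ground_truth_hourly = gth_path))
}
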